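# Literal triple-loop transcription of the coding routine: the independent
# oracle the vectorized extractor is checked against.
cubicpat_reference <- function(x) {
  n <- ncol(x)
  ln <- nrow(x)
  histo <- integer(n^3)
  for (i in seq_len(ln)) {
    C <- numeric(n)
    for (k in seq_len(n)) C[k] <- x[i, k]
    id <- order(-C, method = "radix")
    for (j in seq_len(n - 2L)) {
      map <- (id[j] - 1L) * n^2 + (id[j + 1L] - 1L) * n + (id[j + 2L] - 1L)
      histo[map + 1L] <- histo[map + 1L] + 1L
    }
  }
  histo
}

random_epoch <- function(ln, n) matrix(rnorm(ln * n), nrow = ln, ncol = n)

# small feature matrix with `d_inf` informative columns separating two classes
separable_features <- function(n_per_class = 20, d = 10, d_inf = 2,
                               shift = 5, noise = 1) {
  y <- rep(c("a", "b"), each = n_per_class)
  x <- matrix(rnorm(2 * n_per_class * d, sd = noise), ncol = d)
  x[y == "b", seq_len(d_inf)] <- x[y == "b", seq_len(d_inf)] + shift
  list(x = x, y = y)
}

# a tiny subject-structured dataset for classifier tests
tiny_dataset <- function(seed = 42, ...) {
  generate_dataset(sim_config(n_channels = 6, fs = 32, epoch_seconds = 2,
                              n_subjects_per_class = 3, epochs_per_subject = 4,
                              seed = seed, ...))
}
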