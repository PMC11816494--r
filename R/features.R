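#' Rank channels of one time sample in descending order
#'
#' Returns the channel indices sorted by decreasing value. Ties are broken
#' stably: equal values keep ascending channel order. This ordinal pattern is
#' the primitive the whole feature extractor is built on — every downstream
#' feature is invariant to strictly increasing transforms of the signal.
#'
#' @param sample Numeric vector of channel values at one time sample (length
#'   `n >= 3`).
#' @return Integer vector: a permutation of `1:n`, the first element being the
#'   channel with the largest value.
#' @examples
#' rank_channels(c(10, 40, 20, 30)) # 2 4 3 1
#' @export
rank_channels <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 3L) {
    abort("cubic coding requires >= 3 channels.", class = "cubicpat_config_error")
  }
  order(-sample, method = "radix")
}

#' Cubic-code a channel-rank permutation
#'
#' Encodes every consecutive triplet of the descending rank permutation as a
#' base-`n` integer: `(id_j - 1) n^2 + (id_{j+1} - 1) n + (id_{j+2} - 1)` for
#' `j = 1 .. n - 2`, yielding `n - 2` codes in `[0, n^3 - 1]`.
#'
#' @param perm Integer permutation of `1:n` (from [rank_channels()]).
#' @param n Channel count; defaults to `length(perm)`.
#' @return Integer vector of `n - 2` codes (0-based bin indices).
#' @examples
#' cubic_code(c(2, 4, 3, 1)) # 30 56
#' @export
cubic_code <- function(perm, n = length(perm)) {
  perm <- as.integer(perm)
  if (n < 3L) {
    abort("cubic coding requires >= 3 channels.", class = "cubicpat_config_error")
  }
  j <- seq_len(n - 2L)
  (perm[j] - 1L) * n^2 + (perm[j + 1L] - 1L) * n + (perm[j + 2L] - 1L)
}

rank_matrix <- function(x) {
  t(apply(x, 1L, function(r) order(-r, method = "radix")))
}

#' Extract the cubic-pattern histogram features of one epoch
#'
#' At every time sample the channels are descending-rank sorted and each
#' consecutive rank triplet is encoded as a base-`n` integer; the feature
#' vector is the histogram of these codes over the whole epoch, of fixed
#' length `n^3` (32,768 for 32 channels, 2,744 for 14). Each of the `ln` time
#' samples contributes `n - 2` codes, so the histogram always sums to
#' `ln * (n - 2)`.
#'
#' @param epoch An [epoch_matrix()], or a bare numeric matrix (samples x
#'   channels).
#' @return An integer vector of length `n^3` of class `cubicpat_features` with
#'   attributes `n` and `ln`.
#' @examples
#' f <- extract_features(make_worked_epoch("tiny3"))
#' which(f > 0) - 1L # code 5 <- ranks (1,2,3)
#' @export
extract_features <- function(epoch) {
  x <- if (inherits(epoch, "epoch_matrix")) epoch$data else as.matrix(epoch)
  n <- ncol(x)
  ln <- nrow(x)
  if (n < 3L) {
    abort("cubic coding requires >= 3 channels.", class = "cubicpat_config_error")
  }
  if (anyNA(x)) {
    bad <- which(rowSums(is.na(x)) > 0L)[1L]
    abort(sprintf("epoch contains missing values (first at time sample %d).", bad),
          class = "cubicpat_data_error")
  }
  ids <- rank_matrix(x) # ln x n
  codes <- integer(0L)
  n2 <- n^2
  # one vector of codes per triplet offset, accumulated over all time samples
  codes <- unlist(lapply(seq_len(n - 2L), function(j) {
    (ids[, j] - 1L) * n2 + (ids[, j + 1L] - 1L) * n + (ids[, j + 2L] - 1L)
  }), use.names = FALSE)
  counts <- tabulate(codes + 1L, nbins = n^3)
  structure(counts, n = n, ln = ln, class = "cubicpat_features")
}

#' Extract features for a list of epochs
#'
#' @param epochs List of [epoch_matrix()] objects sharing the same channel
#'   count.
#' @return A list with `x` (integer matrix, epochs x `n^3`, rownames =
#'   epoch_id) and `meta` (tibble with `epoch_id`, `subject_id`, `label`).
#' @export
extract_features_batch <- function(epochs) {
  if (length(epochs) == 0L) {
    return(list(x = matrix(integer(0L), nrow = 0L, ncol = 0L),
                meta = tibble(epoch_id = character(), subject_id = character(),
                              label = character())))
  }
  ns <- vapply(epochs, function(e) ncol(e$data), integer(1L))
  if (length(unique(ns)) > 1L) {
    abort(sprintf("all epochs must share one channel count; found %s.",
                  paste(sort(unique(ns)), collapse = ", ")),
          class = "cubicpat_shape_error")
  }
  rows <- lapply(epochs, function(e) as.integer(extract_features(e)))
  x <- do.call(rbind, rows)
  meta <- tibble(
    epoch_id = vapply(epochs, function(e) e$epoch_id, character(1L)),
    subject_id = vapply(epochs, function(e) e$subject_id, character(1L)),
    label = vapply(epochs, function(e) as.character(e$label), character(1L))
  )
  rownames(x) <- meta$epoch_id
  list(x = x, meta = meta)
}

#' @export
print.cubicpat_features <- function(x, ...) {
  cat(sprintf("<cubicpat_features> length %d (n = %d, ln = %d), %d nonzero bins, sum %d\n",
              length(x), attr(x, "n"), attr(x, "ln"), sum(x > 0L), sum(x)))
  invisible(x)
}
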