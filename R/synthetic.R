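#' Configuration for the synthetic EEG generator
#'
#' The generator emulates the shape of subject-structured multichannel EEG
#' classification data: binary labels, several epochs per subject, 14 or 32
#' channels, 15 s epochs at 128 or 256 Hz. Because the feature extractor is a
#' pure rank statistic, the class signal is planted in per-channel GAIN
#' (amplitude ordering), not in the spectrum: epochs of the second class have
#' the gain of a designated channel subset multiplied by `1 + effect_size`
#' (so `effect_size = 0` makes labels independent of the data by
#' construction). Each subject additionally carries a multiplicative
#' log-normal per-channel gain (`exp(subject_sd * z)`), giving
#' leave-one-subject-out validation a genuine generalization gap relative to
#' 10-fold.
#'
#' @param n_channels Channel count (>= 3; default 14, the stress-cap shape).
#' @param fs Sampling frequency in Hz (default 128).
#' @param epoch_seconds Epoch duration (default 15).
#' @param n_subjects_per_class Subjects per class (default 10).
#' @param epochs_per_subject Epochs per subject (default 10; defaults give
#'   200 epochs).
#' @param effect_size Class gain contrast (>= 0); affected channels of the
#'   second class are scaled by `1 + effect_size` (default 2, a 3x contrast).
#' @param subject_sd SD of the per-subject log-gain (default 0.1).
#' @param noise_sd White-noise SD added to the oscillatory base (default 1).
#' @param n_affected Number of gain-contrast channels (default 4, spread
#'   evenly across the montage).
#' @param seed Integer seed; the dataset is fully reproducible from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_channels = 14, fs = 128, epoch_seconds = 15,
                       n_subjects_per_class = 10, epochs_per_subject = 10,
                       effect_size = 2, subject_sd = 0.1, noise_sd = 1,
                       n_affected = 4, seed = 1) {
  cfg <- list(n_channels = as.integer(n_channels), fs = fs,
              epoch_seconds = epoch_seconds,
              n_subjects_per_class = as.integer(n_subjects_per_class),
              epochs_per_subject = as.integer(epochs_per_subject),
              effect_size = effect_size, subject_sd = subject_sd,
              noise_sd = noise_sd, n_affected = as.integer(n_affected),
              seed = as.integer(seed))
  problems <- c(
    if (cfg$n_channels < 3L) "n_channels must be >= 3",
    if (cfg$fs <= 0) "fs must be > 0",
    if (floor(cfg$epoch_seconds * cfg$fs) < 1) "epoch must span >= 1 sample",
    if (cfg$n_subjects_per_class < 1L) "n_subjects_per_class must be >= 1",
    if (cfg$epochs_per_subject < 1L) "epochs_per_subject must be >= 1",
    if (cfg$effect_size < 0) "effect_size must be >= 0",
    if (cfg$subject_sd < 0) "subject_sd must be >= 0",
    if (cfg$noise_sd <= 0) "noise_sd must be > 0",
    if (cfg$n_affected < 1L || cfg$n_affected > cfg$n_channels)
      "n_affected must be in 1..n_channels"
  )
  if (length(problems)) {
    abort(paste0("invalid simulation config: ",
                 paste(problems, collapse = "; "), "."),
          class = "cubicpat_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a labeled, subject-structured synthetic EEG dataset
#'
#' Every epoch is an oscillatory base mixture (alpha/theta/beta sinusoids
#' with random phases, on a fixed per-channel amplitude profile) plus white
#' Gaussian noise, multiplied per channel by the class gain and the subject
#' gain (see [sim_config()]).
#'
#' @param cfg A [sim_config()].
#' @return A list with `epochs` (list of [epoch_matrix()]), `manifest`
#'   (tibble: `epoch_id`, `subject_id`, `label`), and `cfg`.
#' @examples
#' ds <- generate_dataset(sim_config(n_channels = 6, fs = 32,
#'                                   epoch_seconds = 2,
#'                                   n_subjects_per_class = 2,
#'                                   epochs_per_subject = 3, seed = 7))
#' length(ds$epochs) # 12
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_channels
  ln <- floor(cfg$epoch_seconds * cfg$fs)
  classes <- c("low", "high")
  affected <- unique(round(seq(1L, n, length.out = cfg$n_affected)))
  # fixed per-channel base amplitude profile so the baseline rank ordering is
  # non-degenerate even at effect_size = 0
  base_amp <- 1 + 0.2 * sin(2 * pi * seq_len(n) / n)
  freqs <- c(theta = 5, alpha = 10, beta = 22)
  t_sec <- (seq_len(ln) - 1L) / cfg$fs

  withr::with_seed(cfg$seed, {
    epochs <- list()
    rows <- list()
    eid <- 0L
    for (ci in seq_along(classes)) {
      gain_class <- rep(1, n)
      if (ci == 2L) gain_class[affected] <- 1 + cfg$effect_size
      for (s in seq_len(cfg$n_subjects_per_class)) {
        sid <- sprintf("subj_%s_%02d", classes[ci], s)
        gain_subject <- exp(cfg$subject_sd * stats::rnorm(n))
        for (e in seq_len(cfg$epochs_per_subject)) {
          eid <- eid + 1L
          phases <- matrix(stats::runif(length(freqs) * n, 0, 2 * pi),
                           nrow = length(freqs))
          base <- matrix(0, nrow = ln, ncol = n)
          for (fi in seq_along(freqs)) {
            base <- base + sin(outer(2 * pi * freqs[fi] * t_sec, phases[fi, ], "+"))
          }
          x <- sweep(base, 2L, base_amp, "*") +
            matrix(stats::rnorm(ln * n, sd = cfg$noise_sd), nrow = ln)
          x <- sweep(x, 2L, gain_class * gain_subject, "*")
          id <- sprintf("e%04d", eid)
          epochs[[eid]] <- epoch_matrix(x, label = classes[ci],
                                        subject_id = sid, epoch_id = id)
          rows[[eid]] <- tibble(epoch_id = id, subject_id = sid,
                                label = classes[ci])
        }
      }
    }
  })
  list(epochs = epochs, manifest = dplyr::bind_rows(rows), cfg = cfg)
}

#' Tiny worked epochs used in the coding examples
#'
#' `tiny3` is the single-sample 3-channel epoch `[3, 2, 1]` (its one rank
#' triplet codes to bin 5); `tiny4` is the single-sample 4-channel epoch
#' `[10, 40, 20, 30]` (rank permutation 2, 4, 3, 1; codes 30 and 56).
#'
#' @param kind `"tiny3"` or `"tiny4"`.
#' @return An [epoch_matrix()].
#' @export
make_worked_epoch <- function(kind = c("tiny3", "tiny4")) {
  kind <- match.arg(kind)
  m <- switch(kind,
              tiny3 = matrix(c(3, 2, 1), nrow = 1L),
              tiny4 = matrix(c(10, 40, 20, 30), nrow = 1L))
  epoch_matrix(m, label = "worked", subject_id = "worked",
               epoch_id = kind)
}
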