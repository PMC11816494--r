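#' Construct a multichannel recording
#'
#' A recording holds a continuous multichannel signal as a numeric matrix with
#' rows as time samples and columns as channels, together with its sampling
#' frequency and channel names. Cubic-pattern coding ranks channels at every
#' time sample, so at least 3 channels are required.
#'
#' @param data Numeric matrix, samples x channels. Microvolts or arbitrary
#'   units; the downstream features are rank statistics and are unaffected by
#'   any strictly increasing rescaling.
#' @param fs Sampling frequency in Hz (> 0).
#' @param channel_names Optional character vector naming the columns; defaults
#'   to `ch01`, `ch02`, ...
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- recording(matrix(rnorm(128 * 4), ncol = 4), fs = 128)
#' rec
#' @export
recording <- function(data, fs, channel_names = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (nrow(data) < 1L || ncol(data) < 3L) {
    abort("`data` must have >= 1 sample and >= 3 channels.",
          class = "cubicpat_shape_error")
  }
  if (anyNA(data)) {
    abort("`data` contains missing values; recordings must be complete.",
          class = "cubicpat_data_error")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).",
          class = "cubicpat_config_error")
  }
  channel_names <- channel_names %||% sprintf("ch%02d", seq_len(ncol(data)))
  if (length(channel_names) != ncol(data)) {
    abort("`channel_names` length must equal the channel count.",
          class = "cubicpat_config_error")
  }
  colnames(data) <- channel_names
  structure(list(data = data, fs = fs, channel_names = channel_names),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d samples x %d channels @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, nrow(x$data) / x$fs))
  invisible(x)
}

#' Construct a single labeled epoch
#'
#' An epoch is one fixed-length multichannel segment treated as a single
#' classification observation (15 s in the reference configuration).
#'
#' @param data Numeric matrix, time samples (`ln`) x channels (`n`); `n >= 3`.
#' @param label Class label (any atomic scalar); may be `NA` for unlabeled data.
#' @param subject_id,epoch_id Identifier strings.
#' @return An object of class `epoch_matrix`.
#' @examples
#' ep <- epoch_matrix(matrix(rnorm(30), ncol = 3), label = "low",
#'                    subject_id = "s1", epoch_id = "e1")
#' @export
epoch_matrix <- function(data, label = NA, subject_id = NA_character_,
                         epoch_id = NA_character_) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) < 3L) {
    abort("cubic coding requires >= 3 channels.", class = "cubicpat_config_error")
  }
  if (nrow(data) < 1L) {
    abort("an epoch needs at least one time sample.", class = "cubicpat_shape_error")
  }
  if (anyNA(data)) {
    bad <- which(rowSums(is.na(data)) > 0L)[1L]
    abort(sprintf("epoch contains missing values (first at time sample %d).", bad),
          class = "cubicpat_data_error")
  }
  structure(list(data = data, label = label,
                 subject_id = as.character(subject_id),
                 epoch_id = as.character(epoch_id)),
            class = "epoch_matrix")
}

#' @export
print.epoch_matrix <- function(x, ...) {
  cat(sprintf("<epoch_matrix> %s: %d x %d, subject %s, label %s\n",
              x$epoch_id, nrow(x$data), ncol(x$data), x$subject_id,
              as.character(x$label)))
  invisible(x)
}

#' Segment a continuous recording into fixed-length epochs
#'
#' Cuts non-overlapping consecutive epochs of exactly
#' `floor(epoch_seconds * fs)` samples from the start of the recording; any
#' trailing remainder shorter than one epoch is dropped.
#'
#' @param rec An [recording()] object.
#' @param epoch_seconds Epoch duration in seconds (15 in the reference setup).
#' @param subject_id Subject identifier stamped on every epoch.
#' @param label Label stamped on every epoch (often assigned later).
#' @return A list of [epoch_matrix()] objects (possibly empty, with a warning,
#'   if the recording is shorter than one epoch).
#' @examples
#' rec <- recording(matrix(rnorm(128 * 45 * 4), ncol = 4), fs = 128)
#' length(segment_recording(rec, 15)) # 3 epochs of 1920 samples
#' @export
segment_recording <- function(rec, epoch_seconds, subject_id = NA_character_,
                              label = NA) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- floor(epoch_seconds * rec$fs)
  if (len < 3L) {
    abort("epoch length (epoch_seconds * fs) must be at least 3 samples.",
          class = "cubicpat_config_error")
  }
  total <- nrow(rec$data)
  n_ep <- total %/% len
  if (n_ep == 0L) {
    warn(sprintf("recording (%d samples) is shorter than one epoch (%d samples); returning no epochs.",
                 total, len))
    return(list())
  }
  lapply(seq_len(n_ep), function(i) {
    rows <- ((i - 1L) * len + 1L):(i * len)
    epoch_matrix(rec$data[rows, , drop = FALSE], label = label,
                 subject_id = subject_id, epoch_id = sprintf("e%03d", i))
  })
}

#' Read a dataset manifest
#'
#' The manifest is a CSV with header `epoch_id,subject_id,label,path` listing
#' one row per epoch file. Paths are resolved relative to the manifest's
#' directory unless absolute.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A tibble with columns `epoch_id`, `subject_id`, `label`, `path`
#'   (paths resolved).
#' @export
read_manifest <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(sprintf("manifest file not found: %s", manifest_path),
          class = "cubicpat_io_error")
  }
  man <- readr::read_csv(manifest_path, col_types = readr::cols(
    epoch_id = readr::col_character(),
    subject_id = readr::col_character(),
    label = readr::col_character(),
    path = readr::col_character()
  ))
  need <- c("epoch_id", "subject_id", "label", "path")
  missing_cols <- setdiff(need, names(man))
  if (length(missing_cols)) {
    abort(sprintf("manifest is missing column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "cubicpat_parse_error")
  }
  if (anyDuplicated(man$epoch_id)) {
    abort("manifest epoch_ids must be unique.", class = "cubicpat_parse_error")
  }
  base <- dirname(manifest_path)
  man$path <- ifelse(grepl("^(/|[A-Za-z]:)", man$path), man$path,
                     file.path(base, man$path))
  man
}

read_epoch_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("epoch file not found: %s", path), class = "cubicpat_io_error")
  }
  m <- tryCatch(
    as.matrix(readr::read_csv(path, col_names = FALSE, col_types = readr::cols(
      .default = readr::col_double()
    ), progress = FALSE)),
    warning = function(w) {
      abort(sprintf("non-numeric cell while parsing %s (%s)", path,
                    conditionMessage(w)),
            class = "cubicpat_parse_error")
    })
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    abort(sprintf("non-numeric or missing cell in %s at row %d, column %d.",
                  path, bad[1L], bad[2L]),
          class = "cubicpat_parse_error")
  }
  unname(m)
}

#' Load a dataset of epochs from a manifest
#'
#' Reads every epoch file listed in the manifest (headerless numeric CSV, one
#' row per time sample) and checks that all epochs share the same shape.
#'
#' @param manifest_path Path to the manifest CSV (see [read_manifest()]).
#' @return A list with elements `epochs` (list of [epoch_matrix()] in manifest
#'   order) and `manifest` (tibble with `n_channels` and `fs` attributes left
#'   to the caller's configuration).
#' @export
load_dataset <- function(manifest_path) {
  man <- read_manifest(manifest_path)
  epochs <- purrr::pmap(man, function(epoch_id, subject_id, label, path, ...) {
    m <- read_epoch_csv(path)
    epoch_matrix(m, label = label, subject_id = subject_id, epoch_id = epoch_id)
  })
  dims <- vapply(epochs, function(e) dim(e$data), integer(2L))
  if (length(epochs) > 1L && (length(unique(dims[1L, ])) > 1L ||
                              length(unique(dims[2L, ])) > 1L)) {
    abort(sprintf(
      "inconsistent epoch shapes across the dataset: found %s.",
      paste(unique(apply(dims, 2L, paste, collapse = "x")), collapse = ", ")),
      class = "cubicpat_shape_error")
  }
  list(epochs = epochs, manifest = man)
}

#' Write epochs and a manifest to a directory
#'
#' Inverse of [load_dataset()]: writes one headerless CSV per epoch plus a
#' `manifest.csv` indexing them.
#'
#' @param epochs List of [epoch_matrix()] objects.
#' @param dir Output directory (created if needed).
#' @param digits Significant digits kept in the CSV payload.
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(epochs, dir, digits = 15) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- purrr::map(epochs, function(e) {
    fn <- paste0(e$epoch_id, ".csv")
    m <- signif(e$data, digits)
    readr::write_csv(as.data.frame(m), file.path(dir, fn), col_names = FALSE)
    tibble(epoch_id = e$epoch_id, subject_id = e$subject_id,
           label = as.character(e$label), path = fn)
  })
  man <- dplyr::bind_rows(rows)
  mp <- file.path(dir, "manifest.csv")
  readr::write_csv(man, mp)
  invisible(mp)
}
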