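#' Pipeline run configuration
#'
#' Bundles every tunable of the extract -> select -> classify -> explain
#' pipeline. The LUT length must match the dataset's channel count; this is
#' validated before any computation.
#'
#' @param cv_scheme `"kfold10"` or `"loso"`.
#' @param t_low,t_high Cumulative-weight thresholds of the selector
#'   (defaults 0.75 / 0.99).
#' @param lut `"lut14"`, `"lut32"`, or a custom symbol vector (see
#'   [dlob_lut()]).
#' @param seed Integer seed used for every stochastic step (fold shuffles).
#' @param out_dir Output directory for artifacts, or `NULL` for an in-memory
#'   run with no files written.
#' @param nested If `TRUE`, feature selection is re-fit inside every
#'   cross-validation training fold (leak-free evaluation); the default
#'   `FALSE` follows the literal pipeline order (selection once on the full
#'   feature matrix, then classification), whose leakage caveat is
#'   documented in the methods vignette.
#' @param nca_control Arguments passed to [nca_weights()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(cv_scheme = c("kfold10", "loso"), t_low = 0.75,
                       t_high = 0.99, lut = "lut14", seed = 1,
                       out_dir = NULL, nested = FALSE, nca_control = list()) {
  cv_scheme <- match.arg(cv_scheme)
  if (!is.numeric(t_low) || !is.numeric(t_high) || t_low <= 0 ||
      t_high > 1 || t_low > t_high) {
    abort("thresholds must satisfy 0 < t_low <= t_high <= 1.",
          class = "cubicpat_config_error")
  }
  structure(list(cv_scheme = cv_scheme, t_low = t_low, t_high = t_high,
                 lut = lut, seed = as.integer(seed), out_dir = out_dir,
                 nested = isTRUE(nested), nca_control = nca_control),
            class = "run_config")
}

pipeline_stage <- function(name, quiet, expr) {
  if (!quiet) message(sprintf("[cubicpat] stage %s ...", name))
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "cubicpat_stage_error", parent = e)
  })
}

#' Run the full explainable pipeline
#'
#' Orchestrates feature extraction, CWINCA selection, tkNN classification and
#' Directed-Lobish explainability over a dataset, optionally writing all
#' artifacts (features, selection JSON, predictions CSV, metrics JSON, DLob
#' sequence, histogram/transition CSVs, connectome GraphML, run-report JSON)
#' to `cfg$out_dir`.
#'
#' @param dataset Either a manifest path (see [load_dataset()]) or a list
#'   with `epochs` (+ optional `manifest`), e.g. from [generate_dataset()].
#' @param cfg A [run_config()].
#' @param quiet Suppress stage messages.
#' @return An object of class `cubicpat_run`: list with `selection`
#'   (`cwinca_selection`), `classifier` (`tknn_result`), `sequence`
#'   (`dlob_sequence`), `transitions` (`dlob_transitions`), `metrics`,
#'   `report` (all parameters used, as written to the run report).
#' @export
run_pipeline <- function(dataset, cfg = run_config(), quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  ds <- pipeline_stage("load", quiet, {
    if (is.character(dataset)) load_dataset(dataset) else dataset
  })
  epochs <- ds$epochs
  if (length(epochs) < 2L) {
    abort("the pipeline needs at least two epochs.",
          class = "cubicpat_config_error")
  }
  lut <- dlob_lut(cfg$lut)
  n_channels <- ncol(epochs[[1L]]$data)
  if (length(lut) != n_channels) {
    abort(sprintf("LUT length %d does not match the %d-channel dataset.",
                  length(lut), n_channels),
          class = "cubicpat_config_error")
  }

  fb <- pipeline_stage("extract", quiet, extract_features_batch(epochs))
  y <- fb$meta$label
  if (length(unique(y)) < 2L) {
    abort("classification needs >= 2 distinct labels.",
          class = "cubicpat_config_error")
  }
  subjects <- fb$meta$subject_id

  sel <- pipeline_stage("select", quiet, {
    cwinca(fb$x, y, t_low = cfg$t_low, t_high = cfg$t_high, seed = cfg$seed,
           nca_control = cfg$nca_control)
  })

  clf <- pipeline_stage("classify", quiet, {
    if (cfg$nested) {
      tknn_nested(fb$x, y, cfg, subjects)
    } else {
      tknn(fb$x[, sel$selected_indices, drop = FALSE], y,
           cv = cfg$cv_scheme, subject_id = subjects, seed = cfg$seed)
    }
  })

  expl <- pipeline_stage("explain", quiet, {
    s <- build_sequence(sel$selected_indices, lut)
    list(sequence = s, transitions = transition_table(s))
  })

  report <- list(
    package_version = as.character(utils::packageVersion("cubicpat")),
    n_epochs = length(epochs), n_channels = n_channels,
    ln = nrow(epochs[[1L]]$data),
    feature_length = n_channels^3,
    cv_scheme = cfg$cv_scheme, seed = cfg$seed,
    thresholds = c(cfg$t_low, cfg$t_high),
    nested_selection = cfg$nested,
    knn_grid = list(k = 1:5,
                    distance = c("cityblock", "chebyshev", "euclidean"),
                    weight = c("inverse", "equal")),
    imv_range = c(3L, 30L),
    n_parameter_outcomes = 30L, n_voted_outcomes = 28L,
    selection = list(sv = sel$sv, fv = sel$fv, best_count = sel$best_count,
                     best_accuracy = sel$best_accuracy),
    lut = as.character(lut),
    metrics = list(accuracy = clf$metrics$accuracy,
                   f1_per_class = as.list(clf$metrics$f1),
                   f1_macro = clf$metrics$f1_macro,
                   geometric_mean = clf$metrics$geometric_mean,
                   chosen_source = clf$chosen_source),
    dlob = list(sequence_length = length(expl$sequence$symbols),
                alphabet_size = length(expl$transitions$alphabet),
                entropy_bits = expl$transitions$entropy_bits,
                complexity_percent = complexity_ratio(
                  expl$transitions$entropy_bits,
                  length(expl$transitions$alphabet)))
  )

  if (!is.null(cfg$out_dir)) {
    pipeline_stage("write", quiet, {
      write_run_artifacts(cfg$out_dir, fb, sel, clf, expl, report)
    })
  }

  structure(list(selection = sel, classifier = clf,
                 sequence = expl$sequence, transitions = expl$transitions,
                 metrics = clf$metrics, report = report),
            class = "cubicpat_run")
}

# leak-free variant: NCA + range + prefix choice re-fit on every training
# fold; the (fixed) tknn grid is then evaluated with out-of-fold predictions
# from per-fold selected columns.
tknn_nested <- function(x, y, cfg, subjects) {
  folds <- if (cfg$cv_scheme == "loso") {
    make_folds(y, "loso", subject_id = subjects)
  } else {
    make_folds(y, "kfold", k = min(10L, length(y)), seed = cfg$seed)
  }
  y <- as.character(y)
  grid <- tknn_param_grid()
  preds <- matrix(NA_character_, nrow = length(y), ncol = nrow(grid))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(y), test_idx)
    sel_f <- cwinca(x[train_idx, , drop = FALSE], y[train_idx],
                    t_low = cfg$t_low, t_high = cfg$t_high, seed = cfg$seed,
                    nca_control = cfg$nca_control)
    cols <- sel_f$selected_indices
    for (m in unique(grid$metric)) {
      dm <- knn_distance(x[train_idx, cols, drop = FALSE],
                         x[test_idx, cols, drop = FALSE], m)
      for (s in which(grid$metric == m)) {
        preds[test_idx, s] <- knn_vote(dm, y[train_idx], grid$k[s],
                                       grid$weight[s])
      }
    }
  }
  pool <- structure(list(predictions = preds,
                         accuracies = colMeans(preds == y),
                         grid = grid, y = y),
                    class = "tknn_pool")
  votes <- iterative_majority_vote(pool)
  res <- select_final(pool, votes)
  res$cv <- cfg$cv_scheme
  res$seed <- cfg$seed
  res
}

write_run_artifacts <- function(dir, fb, sel, clf, expl, report) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dplyr::bind_cols(fb$meta["epoch_id"],
                                    as_tibble(as.data.frame(fb$x),
                                              .name_repair = "minimal")),
                   file.path(dir, "features.csv"))
  write_selection(sel, file.path(dir, "selection.json"))
  readr::write_csv(
    tibble(epoch_id = fb$meta$epoch_id, subject_id = fb$meta$subject_id,
           y_true = fb$meta$label, y_pred = clf$chosen,
           candidate_source = clf$chosen_source),
    file.path(dir, "predictions.csv"))
  jsonlite::write_json(
    list(accuracy = clf$metrics$accuracy,
         f1_per_class = as.list(clf$metrics$f1),
         f1_macro = clf$metrics$f1_macro,
         geometric_mean = clf$metrics$geometric_mean,
         confusion_matrix = unclass(as.matrix(clf$metrics$confusion)),
         cv_scheme = report$cv_scheme, seed = report$seed),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  writeLines(paste(expl$sequence$symbols, collapse = " "),
             file.path(dir, "dlob_sequence.txt"))
  readr::write_csv(tibble(symbol = names(expl$transitions$histogram),
                          count = as.integer(expl$transitions$histogram)),
                   file.path(dir, "dlob_histogram.csv"))
  tt <- as.data.frame(expl$transitions$counts)
  tt <- cbind(from = rownames(expl$transitions$counts), tt)
  readr::write_csv(as_tibble(tt), file.path(dir, "dlob_transitions.csv"))
  export_connectome(expl$transitions, file.path(dir, "connectome.graphml"),
                    "graphml")
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.cubicpat_run <- function(x, ...) {
  cat(sprintf("<cubicpat_run> %d epochs, %d channels | %d features selected | accuracy %.2f%% (%s)\n",
              x$report$n_epochs, x$report$n_channels,
              x$selection$best_count, 100 * x$metrics$accuracy,
              x$report$cv_scheme))
  cat(sprintf("  DLob: %d symbols, entropy %.4f bits, complexity %.2f%%\n",
              x$report$dlob$sequence_length, x$report$dlob$entropy_bits,
              x$report$dlob$complexity_percent))
  invisible(x)
}

#' @describeIn run_pipeline glance method: headline numbers of a run.
#' @param x,... Method arguments.
#' @method glance cubicpat_run
#' @export
glance.cubicpat_run <- function(x, ...) {
  tibble(accuracy = x$metrics$accuracy,
         f1_macro = x$metrics$f1_macro,
         geometric_mean = x$metrics$geometric_mean,
         best_count = x$selection$best_count,
         entropy_bits = x$report$dlob$entropy_bits,
         complexity_percent = x$report$dlob$complexity_percent)
}
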