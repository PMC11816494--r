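#' Cumulative-weight search range
#'
#' Normalizes the descending-sorted feature weights to sum 1 and returns the
#' prefix lengths at which the cumulative weight first reaches the two
#' thresholds: `sv` (start of the selection loop, threshold 0.75) and `fv`
#' (end of the loop, threshold 0.99). This bounds the iterative search to the
#' weight mass that matters instead of sweeping all `n^3` features.
#'
#' @param fw An [nca_weights()] object (or any list with `w` and `idx`).
#' @param t_low,t_high Cumulative-weight thresholds (defaults 0.75 and 0.99).
#' @return A list with integer `sv` and `fv`, `1 <= sv <= fv <= n_features`.
#' @examples
#' fw <- list(w = c(0.5, 0.3, 0.15, 0.05), idx = 1:4)
#' cumulative_weight_range(fw) # sv = 2, fv = 4
#' @export
cumulative_weight_range <- function(fw, t_low = 0.75, t_high = 0.99) {
  w <- pmax(fw$w, 0)
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) {
    abort("all feature weights are zero; the cumulative-weight range is undefined.",
          class = "cubicpat_config_error")
  }
  if (t_low > t_high) {
    abort("`t_low` must not exceed `t_high`.", class = "cubicpat_config_error")
  }
  cw <- cumsum(w[fw$idx]) / tot
  eps <- 1e-9 # guard against cumsum round-off at exact threshold hits
  sv <- which(cw >= t_low - eps)[1L]
  fv <- which(cw >= t_high - eps)[1L]
  list(sv = as.integer(sv), fv = as.integer(fv))
}

#' Iterative prefix selection over the cumulative-weight range
#'
#' For every candidate size `a` in `[sv, fv]` evaluates the top-`a` features
#' (by descending weight) with the inner accuracy calculator and greedily
#' returns the size maximizing accuracy (first maximum on ties, favoring the
#' smaller feature set).
#'
#' @param x Feature matrix (observations x features).
#' @param y Class labels.
#' @param fw An [nca_weights()] object.
#' @param range A list with `sv`, `fv` (from [cumulative_weight_range()]).
#' @param evaluator Function `(x_subset) -> accuracy in [0, 1]`. Defaults to
#'   1-NN (euclidean) 10-fold stratified CV with `seed`.
#' @param seed Fold seed for the default evaluator.
#' @return An object of class `cwinca_selection`: `sv`, `fv`,
#'   `accuracy_trace`, `best_count`, `best_accuracy`, `selected_indices`
#'   (original 1-based feature indices, a prefix of the weight ranking).
#' @export
iterative_select <- function(x, y, fw, range, evaluator = NULL, seed = 1) {
  x <- as.matrix(x)
  sv <- range$sv
  fv <- range$fv
  if (sv < 1L || fv > ncol(x) || sv > fv) {
    abort(sprintf("invalid selection range [%d, %d] for %d features.",
                  sv, fv, ncol(x)),
          class = "cubicpat_config_error")
  }
  if (is.null(evaluator)) {
    folds <- make_folds(y, "kfold", k = min(10L, length(y)), seed = seed)
    evaluator <- function(xs) knn_cv_accuracy(xs, y, folds)
  }
  sizes <- sv:fv
  trace <- vapply(sizes, function(a) {
    acc <- tryCatch(evaluator(x[, fw$idx[seq_len(a)], drop = FALSE]),
                    error = function(e) {
                      abort(sprintf("inner evaluator failed at a = %d: %s",
                                    a, conditionMessage(e)),
                            class = "cubicpat_eval_error")
                    })
    as.numeric(acc)
  }, numeric(1L))
  best <- which.max(trace) # first maximum: parsimony on ties
  best_count <- sizes[best]
  structure(list(sv = sv, fv = fv, accuracy_trace = trace,
                 best_count = best_count, best_accuracy = trace[best],
                 selected_indices = fw$idx[seq_len(best_count)],
                 weights = fw$w),
            class = "cwinca_selection")
}

#' Cumulative-weighted iterative NCA feature selection
#'
#' The full selector: fit NCA weights, bound the search with the cumulative
#' weight thresholds, then pick the accuracy-maximizing prefix. Selected sets
#' are nested — the set of size `a` is a prefix of the set of size `a + 1`.
#'
#' @inheritParams iterative_select
#' @inheritParams cumulative_weight_range
#' @param nca_control List of arguments passed to [nca_weights()].
#' @return A `cwinca_selection` (see [iterative_select()]).
#' @export
cwinca <- function(x, y, t_low = 0.75, t_high = 0.99, evaluator = NULL,
                   seed = 1, nca_control = list()) {
  fw <- do.call(nca_weights, c(list(x = x, y = y), nca_control))
  rng <- cumulative_weight_range(fw, t_low = t_low, t_high = t_high)
  iterative_select(x, y, fw, rng, evaluator = evaluator, seed = seed)
}

#' @export
print.cwinca_selection <- function(x, ...) {
  cat(sprintf("<cwinca_selection> range [%d, %d]; chose %d features (inner CV accuracy %.4f)\n",
              x$sv, x$fv, x$best_count, x$best_accuracy))
  invisible(x)
}

#' @describeIn iterative_select tidy method: accuracy trace, one row per
#'   candidate feature count.
#' @param x,... Method arguments.
#' @method tidy cwinca_selection
#' @export
tidy.cwinca_selection <- function(x, ...) {
  tibble(n_features = x$sv:x$fv, accuracy = x$accuracy_trace)
}

#' @describeIn iterative_select glance method: one-row summary.
#' @method glance cwinca_selection
#' @export
glance.cwinca_selection <- function(x, ...) {
  tibble(sv = x$sv, fv = x$fv, best_count = x$best_count,
         best_accuracy = x$best_accuracy)
}

#' @describeIn iterative_select accuracy trace plot with the chosen size
#'   marked.
#' @param object A `cwinca_selection`.
#' @method autoplot cwinca_selection
#' @export
autoplot.cwinca_selection <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$n_features, y = .data$accuracy)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_vline(xintercept = object$best_count, linetype = 2,
                        color = "firebrick") +
    ggplot2::labs(x = "selected feature count",
                  y = "inner CV accuracy",
                  title = sprintf("CWINCA selection: best = %d features",
                                  object$best_count)) +
    ggplot2::theme_minimal()
}

#' Serialize a selection result to JSON
#'
#' Writes `{sv, fv, best_count, best_accuracy, selected_indices, accuracy_trace}`.
#' Indices are written 0-based in the file (a documented external convention);
#' [read_selection()] restores the in-memory 1-based form.
#'
#' @param sel A `cwinca_selection`.
#' @param path Output path.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(
    list(sv = sel$sv, fv = sel$fv, best_count = sel$best_count,
         best_accuracy = sel$best_accuracy,
         selected_indices = sel$selected_indices - 1L,
         accuracy_trace = sel$accuracy_trace),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection
#' @param path Path to a selection JSON.
#' @export
read_selection <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(sv = as.integer(j$sv), fv = as.integer(j$fv),
                 accuracy_trace = as.numeric(j$accuracy_trace),
                 best_count = as.integer(j$best_count),
                 best_accuracy = as.numeric(j$best_accuracy),
                 selected_indices = as.integer(j$selected_indices) + 1L,
                 weights = NULL),
            class = "cwinca_selection")
}
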