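#' Confusion-matrix classification metrics
#'
#' Computes overall accuracy, per-class recall, precision and F1, macro F1,
#' and the geometric mean of the per-class recalls (for two classes,
#' `sqrt(recall_1 * recall_2)`; for more, the geometric mean of all recalls).
#' A class absent from `y_true` has undefined recall, reported as `NaN` with
#' a warning.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return An object of class `cubicpat_metrics`: list with `confusion`
#'   (table, truth in rows), `accuracy`, `recall`, `precision`, `f1`
#'   (named per-class vectors), `f1_macro`, `geometric_mean` — all
#'   proportions in `[0, 1]`.
#' @examples
#' m <- confusion_metrics(rep(c("a", "b"), c(50, 50)),
#'                        rep(c("a", "b", "a", "b"), c(45, 5, 10, 40)))
#' m$accuracy # 0.85
#' @export
confusion_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length.",
          class = "cubicpat_shape_error")
  }
  lev <- sort(unique(c(as.character(y_true), as.character(y_pred))))
  yt <- factor(as.character(y_true), levels = lev)
  yp <- factor(as.character(y_pred), levels = lev)
  cm <- table(truth = yt, prediction = yp)
  n_per_class <- rowSums(cm)
  if (any(n_per_class == 0L)) {
    warn(sprintf("class(es) absent from y_true: %s; recall reported as NaN.",
                 paste(lev[n_per_class == 0L], collapse = ", ")))
  }
  tp <- diag(cm)
  recall <- tp / n_per_class
  precision <- tp / colSums(cm)
  precision[colSums(cm) == 0L] <- NaN
  f1 <- 2 * precision * recall / (precision + recall)
  f1[is.nan(f1) & !is.nan(precision) & !is.nan(recall)] <- 0 # 0/0 vote: no hits
  accuracy <- sum(tp) / sum(cm)
  gmean <- prod(recall)^(1 / length(recall))
  structure(list(confusion = cm, accuracy = accuracy,
                 recall = setNames(as.numeric(recall), lev),
                 precision = setNames(as.numeric(precision), lev),
                 f1 = setNames(as.numeric(f1), lev),
                 f1_macro = mean(f1, na.rm = FALSE),
                 geometric_mean = gmean),
            class = "cubicpat_metrics")
}

#' @export
print.cubicpat_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  macro F1 %.2f%%  geometric mean %.2f%%\n",
              100 * x$accuracy, 100 * x$f1_macro, 100 * x$geometric_mean))
  print(x$confusion)
  invisible(x)
}

#' @describeIn confusion_metrics tidy method: one row per class.
#' @param x,... Method arguments.
#' @method tidy cubicpat_metrics
#' @export
tidy.cubicpat_metrics <- function(x, ...) {
  tibble(class = names(x$recall), recall = x$recall,
         precision = x$precision, f1 = x$f1)
}

#' @describeIn confusion_metrics glance method: one-row overall summary.
#' @method glance cubicpat_metrics
#' @export
glance.cubicpat_metrics <- function(x, ...) {
  tibble(accuracy = x$accuracy, f1_macro = x$f1_macro,
         geometric_mean = x$geometric_mean)
}
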