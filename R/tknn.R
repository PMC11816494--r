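#' The 30-configuration kNN parameter grid
#'
#' k in 1..5 crossed with the cityblock, chebyshev and euclidean distances and
#' inverse / equal vote weighting: 5 x 3 x 2 = 30 configurations, in nested
#' loop order (k outermost, then distance, then weighting).
#'
#' @return A tibble with columns `outcome` (1..30), `k`, `metric`, `weight`.
#' @export
tknn_param_grid <- function() {
  g <- expand.grid(weight = c("inverse", "equal"),
                   metric = c("cityblock", "chebyshev", "euclidean"),
                   k = 1:5, stringsAsFactors = FALSE)
  tibble(outcome = seq_len(nrow(g)), k = g$k, metric = g$metric,
         weight = g$weight)
}

#' Out-of-fold predictions for all 30 kNN configurations
#'
#' Runs cross-validated kNN for every configuration of [tknn_param_grid()],
#' reusing one distance matrix per fold and metric across all k values and
#' weightings. Every sample receives exactly one out-of-fold prediction per
#' configuration.
#'
#' @param x Feature matrix (observations x features).
#' @param y Class labels.
#' @param folds Fold list from [make_folds()].
#' @return An object of class `tknn_pool`: list with `predictions` (character
#'   matrix, observations x 30), `accuracies` (length 30), `grid`.
#' @export
parameter_outcomes <- function(x, y, folds) {
  x <- as.matrix(x)
  y <- as.character(y)
  grid <- tknn_param_grid()
  all_idx <- seq_along(y)
  dists <- lapply(c("cityblock", "chebyshev", "euclidean"), function(m) {
    lapply(folds, function(test_idx) {
      train_idx <- setdiff(all_idx, test_idx)
      knn_distance(x[train_idx, , drop = FALSE],
                   x[test_idx, , drop = FALSE], m)
    })
  })
  names(dists) <- c("cityblock", "chebyshev", "euclidean")
  preds <- matrix(NA_character_, nrow = length(y), ncol = nrow(grid))
  for (s in seq_len(nrow(grid))) {
    preds[, s] <- oof_predict(dists[[grid$metric[s]]], folds, y,
                              grid$k[s], grid$weight[s])
  }
  acc <- colMeans(preds == y)
  structure(list(predictions = preds, accuracies = acc, grid = grid,
                 y = y),
            class = "tknn_pool")
}

#' Iterative majority voting over the parameter outcomes
#'
#' Sorts the 30 outcome vectors by descending accuracy (stable on ties) and,
#' for every `q` in 3..30, takes the per-sample mode of the top-`q`
#' predictions, yielding 28 voted outcome vectors. Mode ties are broken by the
#' label predicted by the most accurate participating outcome.
#'
#' @param pool A `tknn_pool` from [parameter_outcomes()].
#' @return An object of class `tknn_votes`: list with `voted` (character
#'   matrix, observations x 28), `accuracies` (length 28), `order` (the
#'   accuracy-descending outcome order `dx`).
#' @export
iterative_majority_vote <- function(pool) {
  stopifnot(inherits(pool, "tknn_pool"))
  dx <- order(-pool$accuracies, method = "radix")
  preds <- pool$predictions[, dx, drop = FALSE]
  n <- nrow(preds)
  qs <- 3:30
  voted <- matrix(NA_character_, nrow = n, ncol = length(qs))
  for (qi in seq_along(qs)) {
    q <- qs[qi]
    sub <- preds[, seq_len(q), drop = FALSE]
    voted[, qi] <- apply(sub, 1L, function(lab) {
      tab <- table(lab)
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1L) top else lab[lab %in% top][1L]
    })
  }
  acc <- colMeans(voted == pool$y)
  structure(list(voted = voted, accuracies = acc, order = dx, y = pool$y),
            class = "tknn_votes")
}

#' Greedy choice among the 58 candidate outcomes
#'
#' Pools the 30 parameter-based and 28 voted outcome vectors and returns the
#' one with maximal accuracy (first maximum on ties, so a parameter-based
#' outcome wins against an equally accurate voted one). By construction the
#' final accuracy is never below any single parameter outcome's accuracy.
#'
#' @param pool A `tknn_pool`.
#' @param votes A `tknn_votes`.
#' @return An object of class `tknn_result` (see [tknn()]).
#' @export
select_final <- function(pool, votes) {
  all_acc <- c(pool$accuracies, votes$accuracies)
  indice <- which.max(all_acc)
  chosen <- if (indice <= 30L) pool$predictions[, indice]
            else votes$voted[, indice - 30L]
  metrics <- confusion_metrics(pool$y, chosen)
  structure(list(chosen = chosen,
                 chosen_source = if (indice <= 30L)
                   sprintf("parameter_%02d", indice)
                 else sprintf("voted_q%02d", (indice - 30L) + 2L),
                 indice = indice,
                 candidate_accuracies = all_acc,
                 pool = pool, votes = votes,
                 metrics = metrics,
                 accuracy = all_acc[indice]),
            class = "tknn_result")
}

#' Ensemble kNN with iterative majority voting
#'
#' The full classifier: generates 30 cross-validated kNN outcomes over the
#' parameter grid, adds 28 iterative-majority-vote combinations of the
#' accuracy-sorted outcomes, and greedily returns the best of all 58
#' candidates together with confusion-matrix metrics.
#'
#' @param x Feature matrix (observations x features).
#' @param y Class labels.
#' @param cv `"kfold10"` (stratified, seeded) or `"loso"` (grouped by
#'   `subject_id`).
#' @param subject_id Subject identifiers, required for `"loso"`.
#' @param seed Fold seed for `"kfold10"`.
#' @return An object of class `tknn_result` with elements `chosen` (final
#'   out-of-fold prediction vector), `chosen_source`, `indice`,
#'   `candidate_accuracies` (58), `pool`, `votes`, `metrics`
#'   ([confusion_metrics()]), `accuracy`.
#' @export
tknn <- function(x, y, cv = c("kfold10", "loso"), subject_id = NULL,
                 seed = 1) {
  cv <- match.arg(cv)
  folds <- if (cv == "loso") {
    make_folds(y, "loso", subject_id = subject_id)
  } else {
    make_folds(y, "kfold", k = min(10L, length(y)), seed = seed)
  }
  pool <- parameter_outcomes(x, y, folds)
  votes <- iterative_majority_vote(pool)
  res <- select_final(pool, votes)
  res$cv <- cv
  res$seed <- seed
  res$subject_id <- subject_id
  res
}

#' @export
print.tknn_result <- function(x, ...) {
  cat(sprintf("<tknn_result> final accuracy %.2f%% from %s (candidate %d of 58)\n",
              100 * x$accuracy, x$chosen_source, x$indice))
  print(x$metrics)
  invisible(x)
}

#' @describeIn tknn tidy method: one row per candidate outcome (58 rows) with
#'   its source and accuracy.
#' @param x,... Method arguments.
#' @method tidy tknn_result
#' @export
tidy.tknn_result <- function(x, ...) {
  g <- x$pool$grid
  tibble(
    candidate = seq_len(58L),
    source = c(sprintf("k=%d %s %s", g$k, g$metric, g$weight),
               sprintf("vote top-%d", 3:30)),
    type = rep(c("parameter", "voted"), c(30L, 28L)),
    accuracy = x$candidate_accuracies,
    chosen = seq_len(58L) == x$indice
  )
}

#' @describeIn tknn glance method: one-row summary with the headline metrics.
#' @method glance tknn_result
#' @export
glance.tknn_result <- function(x, ...) {
  tibble(accuracy = x$accuracy, f1_macro = x$metrics$f1_macro,
         geometric_mean = x$metrics$geometric_mean,
         chosen_source = x$chosen_source, cv = x$cv %||% NA_character_)
}

#' @describeIn tknn candidate-accuracy plot (30 parameter + 28 voted).
#' @param object A `tknn_result`.
#' @method autoplot tknn_result
#' @export
autoplot.tknn_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$candidate, y = .data$accuracy,
                               color = .data$type, shape = .data$chosen)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 8),
                                guide = "none") +
    ggplot2::labs(x = "candidate outcome", y = "CV accuracy",
                  title = "tkNN candidates: 30 parameter-based + 28 voted") +
    ggplot2::theme_minimal()
}
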