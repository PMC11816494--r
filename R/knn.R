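#' Cross-validation fold schemes
#'
#' Builds the fold assignments used throughout the package: stratified k-fold
#' (shuffled within class under the given seed, then dealt round-robin) or
#' leave-one-subject-out (every subject's epochs form one test fold, so no
#' prediction for a subject can be influenced by that subject's own epochs).
#'
#' @param y Class labels.
#' @param scheme `"kfold"` or `"loso"`.
#' @param k Number of folds for `"kfold"` (default 10).
#' @param subject_id Subject identifiers, required for `"loso"`.
#' @param seed Integer seed controlling the within-class shuffle for
#'   `"kfold"`; ignored for `"loso"` (which is deterministic).
#' @return A list of integer vectors of test indices, one per fold, jointly a
#'   partition of `seq_along(y)`.
#' @export
make_folds <- function(y, scheme = c("kfold", "loso"), k = 10,
                       subject_id = NULL, seed = 1) {
  scheme <- match.arg(scheme)
  n <- length(y)
  if (scheme == "loso") {
    if (is.null(subject_id)) {
      abort("LOSO folds need `subject_id`.", class = "cubicpat_config_error")
    }
    if (length(subject_id) != n) {
      abort("`subject_id` must match `y` in length.",
            class = "cubicpat_shape_error")
    }
    return(unname(split(seq_len(n), as.character(subject_id))))
  }
  if (k < 2L || k > n) {
    abort("`k` must be between 2 and the number of observations.",
          class = "cubicpat_config_error")
  }
  fold_of <- integer(n)
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold_of[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  unname(split(seq_len(n), fold_of))
}

knn_distance <- function(train, test, metric = c("euclidean", "cityblock",
                                                 "chebyshev")) {
  metric <- match.arg(metric)
  train <- as.matrix(train)
  test <- as.matrix(test)
  if (metric == "euclidean") {
    a <- rowSums(test * test)
    b <- rowSums(train * train)
    d2 <- outer(a, b, "+") - 2 * tcrossprod(test, train)
    d2[d2 < 0] <- 0
    return(sqrt(d2))
  }
  tr <- t(train)
  t(vapply(seq_len(nrow(test)), function(i) {
    ad <- abs(tr - test[i, ])
    if (metric == "cityblock") colSums(ad) else apply(ad, 2L, max)
  }, numeric(nrow(train))))
}

# Predict labels for test rows from a precomputed test x train distance
# matrix. Tie rules are deterministic: neighbor ties are resolved by training
# index (stable sort); label-vote ties go to the label of the nearest
# neighbor carrying a tied label. Inverse weighting uses 1/d, with an exact
# zero distance assigning that neighbor's label outright.
knn_vote <- function(dist_mat, y_train, k, weight = c("equal", "inverse")) {
  weight <- match.arg(weight)
  y_train <- as.character(y_train)
  ntr <- length(y_train)
  if (k > ntr) {
    warn(sprintf("k = %d exceeds training size %d; truncated.", k, ntr))
    k <- ntr
  }
  apply(dist_mat, 1L, function(dv) {
    nb <- order(dv, method = "radix")[seq_len(k)]
    dnb <- dv[nb]
    lnb <- y_train[nb]
    if (weight == "inverse" && any(dnb == 0)) {
      return(lnb[which(dnb == 0)[1L]])
    }
    wts <- if (weight == "inverse") 1 / dnb else rep(1, k)
    score <- tapply(wts, lnb, sum)
    top <- names(score)[score == max(score)]
    if (length(top) == 1L) return(top)
    lnb[lnb %in% top][1L] # nearest neighbor among tied labels
  })
}

#' Weighted k-nearest-neighbor prediction
#'
#' The kNN engine behind the ensemble classifier: supports the three distance
#' metrics and two weighting schemes of the 30-configuration parameter grid.
#'
#' @param train,test Numeric matrices with matching columns.
#' @param y_train Training labels.
#' @param k Number of neighbors (truncated with a warning if it exceeds the
#'   training size).
#' @param metric `"euclidean"`, `"cityblock"`, or `"chebyshev"`.
#' @param weight `"equal"` or `"inverse"` (inverse-distance vote; a
#'   zero-distance neighbor wins outright).
#' @return Character vector of predicted labels, one per test row.
#' @export
knn_predict <- function(train, test, y_train, k = 1,
                        metric = c("euclidean", "cityblock", "chebyshev"),
                        weight = c("equal", "inverse")) {
  metric <- match.arg(metric)
  weight <- match.arg(weight)
  dm <- knn_distance(train, test, metric)
  unname(knn_vote(dm, y_train, k, weight))
}

# Out-of-fold predictions for one kNN configuration given shared
# per-fold distance matrices (list parallel to folds).
oof_predict <- function(dists, folds, y, k, weight) {
  pred <- character(length(y))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(y), test_idx)
    pred[test_idx] <- knn_vote(dists[[f]], y[train_idx], k, weight)
  }
  pred
}

# 10-fold CV accuracy of 1-NN (euclidean) — the inner accuracy calculator of
# the feature selector.
knn_cv_accuracy <- function(x, y, folds, k = 1, metric = "euclidean") {
  y <- as.character(y)
  correct <- 0L
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_along(y), test_idx)
    dm <- knn_distance(x[train_idx, , drop = FALSE],
                       x[test_idx, , drop = FALSE], metric)
    pred <- knn_vote(dm, y[train_idx], k, "equal")
    correct <- correct + sum(pred == y[test_idx])
  }
  correct / length(y)
}
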