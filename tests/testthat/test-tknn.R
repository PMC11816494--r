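test_that("the parameter grid is the full 5 x 3 x 2 cross", {
  g <- tknn_param_grid()
  expect_identical(nrow(g), 30L)
  expect_identical(sort(unique(g$k)), 1:5)
  expect_setequal(unique(g$metric), c("cityblock", "chebyshev", "euclidean"))
  expect_setequal(unique(g$weight), c("inverse", "equal"))
  expect_identical(nrow(dplyr::distinct(g[, c("k", "metric", "weight")])), 30L)
})

test_that("knn_predict agrees with class::knn for 1-NN euclidean", {
  skip_if_not_installed("class")
  set.seed(30)
  for (i in 1:10) {
    tr <- matrix(rnorm(40 * 5), ncol = 5)
    te <- matrix(rnorm(15 * 5), ncol = 5)
    y <- sample(c("a", "b"), 40, replace = TRUE)
    mine <- knn_predict(tr, te, y, k = 1, metric = "euclidean")
    ref <- as.character(class::knn(tr, te, factor(y), k = 1))
    expect_identical(mine, ref)
  }
})

test_that("inverse and equal weighting coincide at k = 1", {
  set.seed(31)
  d <- separable_features(n_per_class = 15, d = 5, shift = 1)
  folds <- make_folds(d$y, "kfold", k = 5, seed = 1)
  pool <- parameter_outcomes(d$x, d$y, folds)
  g <- pool$grid
  for (m in unique(g$metric)) {
    i_inv <- which(g$k == 1 & g$metric == m & g$weight == "inverse")
    i_eq <- which(g$k == 1 & g$metric == m & g$weight == "equal")
    expect_identical(pool$predictions[, i_inv], pool$predictions[, i_eq])
  }
})

test_that("the pool has 30 outcomes, perfect on trivially separable data, reproducible", {
  x <- rbind(matrix(0, 10, 4), matrix(10, 10, 4)) +
    matrix(rnorm(80, sd = 0.01), 20, 4)
  y <- rep(c("a", "b"), each = 10)
  folds <- make_folds(y, "kfold", k = 5, seed = 2)
  pool <- parameter_outcomes(x, y, folds)
  expect_identical(ncol(pool$predictions), 30L)
  expect_true(all(pool$accuracies == 1))
  pool2 <- parameter_outcomes(x, y, folds)
  expect_identical(pool$predictions, pool2$predictions)
})

test_that("iterative majority voting yields 28 outcomes with the documented tie rules", {
  # hand-built pool: 4 samples, y known, controlled predictions
  y <- c("a", "a", "b", "b")
  preds <- cbind(
    c("a", "a", "b", "b"), # acc 1.00 -> rank 1
    c("a", "a", "b", "a"), # acc 0.75 -> rank 2
    c("b", "a", "b", "b")  # acc 0.75 -> rank 3 (stable tie: original order)
  )
  preds <- cbind(preds, preds[, c(1, 2, 3)] [, rep(1:3, length.out = 27)])
  pool <- structure(list(predictions = preds,
                         accuracies = colMeans(preds == y),
                         grid = tknn_param_grid(), y = y),
                    class = "tknn_pool")
  votes <- iterative_majority_vote(pool)
  expect_identical(ncol(votes$voted), 28L)
  # sample 1 at q=3: votes a,a,b -> mode a; sample 4: b,a,b -> b
  expect_identical(votes$voted[, 1], c("a", "a", "b", "b"))
  # stable accuracy sort: the perfect outcome first
  expect_identical(votes$order[1], 1L)

  # unanimity: all outcomes identical -> every voted vector equals them
  pred_u <- matrix(rep(c("a", "a", "b", "b"), 30), ncol = 30)
  pool_u <- structure(list(predictions = pred_u,
                           accuracies = colMeans(pred_u == y),
                           grid = tknn_param_grid(), y = y),
                      class = "tknn_pool")
  votes_u <- iterative_majority_vote(pool_u)
  expect_true(all(votes_u$voted == c("a", "a", "b", "b")))
})

test_that("mode ties go to the most accurate participating outcome", {
  y <- c("a", "b")
  # top-4 predictions for sample 1: a, b, b, a -> tie; most accurate says "a"
  preds <- cbind(c("a", "b"), c("b", "b"), c("b", "a"), c("a", "a"))
  preds <- cbind(preds, matrix(rep(c("a", "b"), 26), ncol = 26))
  acc <- c(1, 0.75, 0.5, 0.25, rep(0, 26))
  pool <- structure(list(predictions = preds, accuracies = acc,
                         grid = tknn_param_grid(), y = y),
                    class = "tknn_pool")
  votes <- iterative_majority_vote(pool)
  expect_identical(votes$voted[1, 2], "a") # q = 4 column
})

test_that("select_final chooses the argmax of 58 candidates and dominates the pool", {
  set.seed(32)
  ds <- tiny_dataset()
  fb <- extract_features_batch(ds$epochs)
  res <- tknn(fb$x, fb$meta$label, cv = "kfold10", seed = 4)
  expect_length(res$candidate_accuracies, 58L)
  expect_gte(res$accuracy, max(res$pool$accuracies))
  expect_identical(res$accuracy, max(res$candidate_accuracies))
  expect_identical(res$indice, which.max(res$candidate_accuracies))
  td <- tidy(res)
  expect_identical(nrow(td), 58L)
  expect_identical(sum(td$chosen), 1L)
  expect_s3_class(autoplot(res), "ggplot")
})

test_that("every voted label appears among the participating outcomes for that sample", {
  set.seed(33)
  ds <- tiny_dataset(seed = 9)
  fb <- extract_features_batch(ds$epochs)
  folds <- make_folds(fb$meta$label, "kfold", k = 5, seed = 5)
  pool <- parameter_outcomes(fb$x, fb$meta$label, folds)
  votes <- iterative_majority_vote(pool)
  sorted <- pool$predictions[, votes$order, drop = FALSE]
  for (qi in c(1L, 14L, 28L)) {
    q <- qi + 2L
    for (i in seq_len(nrow(sorted))) {
      expect_true(votes$voted[i, qi] %in% sorted[i, seq_len(q)])
    }
  }
})

test_that("LOSO predictions for a subject ignore that subject's labels", {
  set.seed(34)
  ds <- tiny_dataset(seed = 5)
  fb <- extract_features_batch(ds$epochs)
  y <- fb$meta$label
  subj <- fb$meta$subject_id
  folds <- make_folds(y, "loso", subject_id = subj)
  # folds partition the data, one subject per fold
  expect_identical(sort(unlist(folds)), seq_along(y))
  for (f in folds) expect_identical(length(unique(subj[f])), 1L)

  pool <- parameter_outcomes(fb$x, y, folds)
  s <- subj[1]
  y_poisoned <- y
  y_poisoned[subj == s] <- "poisoned" # relabel every epoch of subject s
  pool_p <- parameter_outcomes(fb$x, y_poisoned, folds)
  expect_identical(pool$predictions[subj == s, ],
                   pool_p$predictions[subj == s, ])
})

test_that("k larger than the training fold is truncated with a warning", {
  x <- matrix(rnorm(12), ncol = 3)
  y <- c("a", "b", "a", "b")
  expect_warning(
    p <- knn_predict(x[1:2, ], x[3:4, ], y[1:2], k = 5),
    "truncated")
  expect_length(p, 2L)
})

test_that("confusion metrics match hand computations", {
  y <- rep(c("p", "n"), c(50, 50))
  m <- confusion_metrics(y, y)
  expect_equal(m$accuracy, 1)
  expect_equal(m$geometric_mean, 1)
  expect_equal(m$f1_macro, 1)

  # 2x2 table [[45, 5], [10, 40]]
  yt <- rep(c("a", "b"), c(50, 50))
  yp <- rep(c("a", "b", "a", "b"), c(45, 5, 10, 40))
  m2 <- confusion_metrics(yt, yp)
  expect_equal(m2$accuracy, 0.85)
  expect_equal(m2$geometric_mean, sqrt(0.9 * 0.8), tolerance = 1e-12)
  expect_equal(unname(m2$f1["a"]), 2 * (45 / 55) * 0.9 / (45 / 55 + 0.9),
               tolerance = 1e-12)
  expect_equal(round(100 * m2$geometric_mean, 2), 84.85)
  expect_equal(round(100 * m2$f1[["a"]], 2), 85.71)

  # constant prediction: one recall is zero -> geometric mean 0
  m3 <- confusion_metrics(yt, rep("a", 100))
  expect_equal(m3$geometric_mean, 0)

  # class absent from truth -> NaN recall with warning
  expect_warning(m4 <- confusion_metrics(rep("a", 4), c("a", "a", "b", "a")),
                 "absent")
  expect_true(is.nan(m4$recall[["b"]]))
  expect_identical(nrow(tidy(m2)), 2L)
})
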