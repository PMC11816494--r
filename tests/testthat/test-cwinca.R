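test_that("NCA weights rank a perfectly separating feature first", {
  set.seed(20)
  d <- separable_features(n_per_class = 25, d = 8, d_inf = 1, shift = 8)
  fw <- nca_weights(d$x, d$y)
  expect_identical(fw$idx[1], 1L)
  expect_true(all(is.finite(fw$w)) && all(fw$w >= 0))
})

test_that("duplicated feature columns get equal weights; dead columns sink", {
  set.seed(21)
  d <- separable_features(n_per_class = 20, d = 6, d_inf = 1, shift = 6)
  x <- cbind(d$x, d$x[, 1]) # column 7 duplicates the informative column 1
  fw <- nca_weights(x, d$y)
  expect_equal(fw$w[1], fw$w[7], tolerance = 1e-6)

  x0 <- cbind(d$x, 0) # all-zero column
  fw0 <- nca_weights(x0, d$y)
  expect_lte(fw0$w[7], fw0$w[1])

  expect_error(nca_weights(d$x, rep("a", nrow(d$x))), "2 classes",
               class = "cubicpat_config_error")
})

test_that("NCA fitting is deterministic", {
  set.seed(22)
  d <- separable_features()
  f1 <- nca_weights(d$x, d$y)
  f2 <- nca_weights(d$x, d$y)
  expect_identical(f1$w, f2$w)
  expect_identical(f1$idx, f2$idx)
})

test_that("cumulative-weight range hits the documented prefix lengths", {
  fw <- list(w = c(0.5, 0.3, 0.15, 0.05), idx = 1:4)
  rng <- cumulative_weight_range(fw)
  expect_identical(rng, list(sv = 2L, fv = 4L))

  fw100 <- list(w = rep(1, 100), idx = 1:100)
  rng100 <- cumulative_weight_range(fw100)
  expect_identical(rng100, list(sv = 75L, fv = 99L))

  fw1 <- list(w = c(1, 0, 0), idx = 1:3)
  expect_identical(cumulative_weight_range(fw1), list(sv = 1L, fv = 1L))

  expect_error(cumulative_weight_range(list(w = c(0, 0), idx = 1:2)),
               "zero", class = "cubicpat_config_error")
})

test_that("iterative selection finds the informative prefix and is reproducible", {
  set.seed(23)
  d <- separable_features(n_per_class = 25, d = 12, d_inf = 2, shift = 6)
  fw <- nca_weights(d$x, d$y)
  sel <- iterative_select(d$x, d$y, fw, list(sv = 1L, fv = 5L), seed = 7)
  expect_length(sel$accuracy_trace, 5L)
  expect_gte(sel$best_count, 1L)
  expect_true(all(c(1L, 2L) %in% fw$idx[1:5]))
  expect_true(sel$best_accuracy >= max(sel$accuracy_trace) - 1e-12)

  sel2 <- iterative_select(d$x, d$y, fw, list(sv = 1L, fv = 5L), seed = 7)
  expect_identical(sel, sel2)

  deg <- iterative_select(d$x, d$y, fw, list(sv = 3L, fv = 3L), seed = 7)
  expect_length(deg$accuracy_trace, 1L)
  expect_identical(deg$best_count, 3L)
})

test_that("best_accuracy is reproduced by re-evaluating the selected prefix", {
  set.seed(24)
  d <- separable_features(n_per_class = 15, d = 10, d_inf = 2, shift = 4)
  folds <- make_folds(d$y, "kfold", k = 10, seed = 3)
  evaluator <- function(xs) cubicpat:::knn_cv_accuracy(xs, d$y, folds)
  fw <- nca_weights(d$x, d$y)
  sel <- iterative_select(d$x, d$y, fw, list(sv = 1L, fv = 6L),
                          evaluator = evaluator)
  re <- evaluator(d$x[, sel$selected_indices, drop = FALSE])
  expect_identical(re, sel$best_accuracy)
  # prefix property: the selected set is the top-best_count ranked features
  expect_identical(sel$selected_indices, fw$idx[seq_len(sel$best_count)])
})

test_that("selection JSON round-trips through the 0-based external form", {
  set.seed(25)
  d <- separable_features(n_per_class = 10, d = 6)
  sel <- cwinca(d$x, d$y, seed = 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_identical(as.integer(j$selected_indices), sel$selected_indices - 1L)
  back <- read_selection(path)
  expect_identical(back$selected_indices, sel$selected_indices)
  expect_identical(back$best_count, sel$best_count)
  expect_equal(back$accuracy_trace, sel$accuracy_trace)
})

test_that("cwinca end-to-end recovers informative features and tidies", {
  set.seed(26)
  d <- separable_features(n_per_class = 25, d = 10, d_inf = 2, shift = 6)
  sel <- cwinca(d$x, d$y, seed = 5)
  expect_true(all(c(1L, 2L) %in% sel$selected_indices))
  expect_identical(nrow(tidy(sel)), sel$fv - sel$sv + 1L)
  g <- glance(sel)
  expect_identical(g$best_count, sel$best_count)
  p <- autoplot(sel)
  expect_s3_class(p, "ggplot")
})
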