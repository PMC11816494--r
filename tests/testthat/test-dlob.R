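test_that("the channel lookup tables match the published montage assignments", {
  l32 <- dlob_lut("lut32")
  expect_length(l32, 32L)
  expect_identical(as.character(l32), c(
    "Cz", "Fz", "FL", "FL", "FL", "FL", "CL", "FL", "FL", "TL",
    "CL", "CL", "PL", "PL", "PL", "OL", "Pz", "Oz", "OR", "PR",
    "PR", "PR", "CR", "CR", "TR", "FR", "FR", "CR", "FR", "FR",
    "FR", "FR"))
  l14 <- dlob_lut("lut14")
  expect_length(l14, 14L)
  expect_identical(as.character(l14), c(
    "FL", "FL", "FL", "FL", "TL", "PL", "OL", "OR", "PR", "TR",
    "FR", "FR", "FR", "FR"))
  # the 14-channel cap spans an 8-symbol alphabet (no midline/central sites)
  expect_length(attr(l14, "alphabet"), 8L)
  expect_length(attr(l32, "alphabet"), 14L)
  expect_error(dlob_lut("lut99"), "unknown LUT",
               class = "cubicpat_config_error")
  expect_error(dlob_lut(c("FL", "XX", "FR")), "XX",
               class = "cubicpat_config_error")
})

test_that("feature indices decode to channel triplets by digit separation", {
  expect_identical(decode_feature_index(31, 4), c(3L, 4L, 2L))
  expect_identical(decode_feature_index(1, 14), c(1L, 1L, 1L))
  expect_identical(decode_feature_index(2744, 14), c(14L, 14L, 14L))
  expect_error(decode_feature_index(2745, 14), "range",
               class = "cubicpat_index_error")
  expect_error(decode_feature_index(0, 14), "range",
               class = "cubicpat_index_error")
})

test_that("encode-then-decode returns the same channels as a multiset", {
  set.seed(40)
  for (i in 1:50) {
    n <- sample(3:14, 1)
    trip <- sample(n, 3)
    value <- cubic_code(c(trip, setdiff(seq_len(n), trip)), n)[1] + 1
    expect_identical(sort(decode_feature_index(value, n)), sort(trip))
  }
})

test_that("sequences emit three LUT symbols per feature in encoding order", {
  # channels (1, 5, 10) encode to value (1-1)*196 + (5-1)*14 + (10-1) + 1 = 66
  s <- build_sequence(66, dlob_lut("lut14"))
  expect_identical(s$symbols, c("FL", "TL", "TR"))
  # channels (1, 2, 18) on the 32-channel montage
  v32 <- (1 - 1) * 32^2 + (2 - 1) * 32 + (18 - 1) + 1
  s32 <- build_sequence(v32, dlob_lut("lut32"))
  expect_identical(s32$symbols, c("Cz", "Fz", "Oz"))
  # decoded order is the digit order (reversed)
  s_dec <- build_sequence(66, dlob_lut("lut14"), symbol_order = "decoded")
  expect_identical(s_dec$symbols, rev(s$symbols))

  empty <- build_sequence(integer(0), dlob_lut("lut14"))
  expect_length(empty$symbols, 0L)

  multi <- build_sequence(c(1, 66, 2744), dlob_lut("lut14"))
  expect_length(multi$symbols, 9L)
  expect_error(build_sequence(3000, dlob_lut("lut14")), "2744",
               class = "cubicpat_index_error")
})

test_that("transition tables count adjacent pairs and satisfy their invariants", {
  tt <- transition_table(c("FL", "FL", "TL"))
  expect_identical(sum(tt$counts), 2L)
  expect_identical(tt$counts["FL", "FL"], 1L)
  expect_identical(tt$counts["FL", "TL"], 1L)
  expect_identical(sum(tt$histogram), 3L)

  single <- transition_table("FL")
  expect_true(all(single$counts == 0L))
  expect_identical(single$entropy_bits, 0)

  set.seed(41)
  seqs <- sample(c("FL", "FR", "TL", "PL"), 200, replace = TRUE)
  t2 <- transition_table(seqs)
  expect_identical(sum(t2$counts), length(seqs) - 1L)
  expect_identical(sum(t2$histogram), length(seqs))
  expect_gte(t2$entropy_bits, 0)
  expect_lte(t2$entropy_bits, log2(length(t2$alphabet)) + 1e-12)
  expect_equal(nrow(tidy(t2)), length(t2$alphabet)^2)
  expect_s3_class(autoplot(t2), "ggplot")
})

test_that("entropy and complexity analytics match their closed forms", {
  expect_equal(round(sequence_entropy(rep(1, 14)), 4), 3.8074)
  expect_equal(sequence_entropy(rep(5, 8)), 3)
  expect_equal(sequence_entropy(c(10, 0, 0)), 0)
  expect_equal(sequence_entropy(c(1, 1)), 1)
  expect_error(sequence_entropy(c(0, 0)), "positive",
               class = "cubicpat_data_error")
  expect_error(sequence_entropy(c(-1, 2)), "nonnegative",
               class = "cubicpat_data_error")

  expect_equal(round(complexity_ratio(3.4974, 14), 2), 91.86)
  expect_equal(round(complexity_ratio(2.8331, 8), 2), 94.44)
  expect_equal(complexity_ratio(0, 20), 0)
  expect_error(complexity_ratio(3.1, 8), "exceeds",
               class = "cubicpat_invariant_error")
  expect_error(complexity_ratio(1, 1), "alphabet",
               class = "cubicpat_config_error")
})

test_that("entropy is maximal iff the histogram is uniform", {
  set.seed(42)
  for (k in c(2, 8, 14)) {
    expect_equal(sequence_entropy(rep(3, k)), log2(k), tolerance = 1e-12)
    h <- rep(3, k)
    h[1] <- 5
    expect_lt(sequence_entropy(h), log2(k))
  }
})

test_that("connectome export writes a graph matching the transition counts", {
  seqs <- c(rep("FL", 91), "FR", "OL", "FR") # 90 FL->FL self-transitions
  tt <- transition_table(seqs)
  expect_identical(tt$counts["FL", "FL"], 90L)
  g <- connectome_graph(tt)
  expect_equal(igraph::E(g)$weight[igraph::get_edge_ids(g, c("FL", "FL"))], 90)

  path <- withr::local_tempfile(fileext = ".graphml")
  export_connectome(tt, path, "graphml")
  g2 <- igraph::read_graph(path, format = "graphml")
  m1 <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
  m2 <- igraph::as_adjacency_matrix(g2, attr = "weight", sparse = FALSE)
  expect_equal(m2[rownames(m1), colnames(m1)], m1)

  dotp <- withr::local_tempfile(fileext = ".dot")
  export_connectome(tt, dotp, "dot")
  expect_true(file.exists(dotp) && file.size(dotp) > 0)

  zero <- transition_table(character(0))
  expect_equal(igraph::ecount(connectome_graph(zero)), 0)
  expect_error(export_connectome(tt, path, "gexf"), "supported",
               class = "cubicpat_config_error")
})
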