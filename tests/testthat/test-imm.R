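test_that("conditional probabilities are proper distributions", {
  g <- tb_unit_genomes()[[1]]
  m <- imm_train(substr(g$seq, 1, 2e5), max_order = 6)
  for (k in 0:6) {
    expect_equal(unname(rowSums(m$probs[[k + 1]])),
                 rep(1, 4^k), tolerance = 1e-9)
  }
})

test_that("duplicated training data doubles counts; saturated estimates agree", {
  s <- tb_random_seq(20000, seed = 61, gc = 0.55)
  m1 <- imm_train(s, max_order = 4)
  m2 <- imm_train(c(s, s), max_order = 4)
  expect_equal(m2$counts[[1]], 2L * m1$counts[[1]])
  expect_equal(m2$counts[[5]], 2L * m1$counts[[5]])
  # interpolation weights grow with absolute counts, so the interpolated
  # probabilities are NOT invariant under duplication in general; where the
  # context is fully trusted in both models they are identical MLEs
  c1 <- matrix(m1$counts[[5]], ncol = 4, byrow = TRUE)
  sat <- which(rowSums(c1) >= m1$interpolation_threshold)
  if (length(sat)) {
    expect_equal(m1$probs[[5]][sat, , drop = FALSE],
                 m2$probs[[5]][sat, , drop = FALSE], tolerance = 1e-12)
  }
  # with an interpolation threshold of 1 every observed context is a pure
  # MLE, and duplication is then a no-op for those contexts
  m3 <- imm_train(s, max_order = 3, interpolation_threshold = 1)
  m4 <- imm_train(c(s, s), max_order = 3, interpolation_threshold = 1)
  obs <- which(rowSums(matrix(m3$counts[[4]], ncol = 4, byrow = TRUE)) > 0)
  expect_equal(m3$probs[[4]][obs, , drop = FALSE],
               m4$probs[[4]][obs, , drop = FALSE], tolerance = 1e-12)
})

test_that("order-0 component is the smoothed base composition", {
  s <- strrep("ACGGG", 2000) # 10000 bases, strand-symmetrized internally
  m <- imm_train(s, max_order = 2, pseudocount = 1)
  c0 <- m$counts[[1]]
  expect_equal(as.numeric(m$probs[[1]]), (c0 + 1) / (sum(c0) + 4))
  # GC-rich training: order-0 gives G more mass than A
  mg <- imm_train(tb_unit_genomes()[[3]]$seq, max_order = 2) # gc 0.62
  expect_gt(mg$probs[[1]][1, 3], mg$probs[[1]][1, 1])
})

test_that("scores order sequences by compositional fit", {
  polyA <- imm_train(strrep("A", 5000))
  score_a <- imm_score(polyA, strrep("A", 200))
  score_c <- imm_score(polyA, strrep("C", 200))
  expect_gt(score_a, score_c)
  expect_gt(score_a / 200, -0.05) # near 0 per base
  expect_true(is.finite(score_c))
})

test_that("saturated contexts use the pure maximum-likelihood estimate", {
  s <- tb_random_seq(3e5, seed = 62)
  C <- 400L
  m <- imm_train(s, max_order = 3, interpolation_threshold = C)
  cm <- matrix(m$counts[[4]], ncol = 4, byrow = TRUE)
  tot <- rowSums(cm)
  sat <- which(tot >= C)
  expect_gt(length(sat), 0)
  expect_equal(m$probs[[4]][sat, ], cm[sat, ] / tot[sat], tolerance = 1e-12)
})

test_that("scoring is nearly additive over concatenation", {
  g <- tb_unit_genomes()[[2]]
  m <- imm_train(substr(g$seq, 1, 3e5))
  s1 <- substr(g$seq, 300001, 302000)
  s2 <- substr(g$seq, 350001, 352000)
  d <- abs(imm_score(m, paste0(s1, s2)) -
             (imm_score(m, s1) + imm_score(m, s2)))
  expect_lte(d, m$max_order * log(4))
})

test_that("non-ACGT positions contribute zero and reset the context", {
  m <- imm_train(tb_random_seq(50000, seed = 63))
  s1 <- tb_random_seq(500, seed = 64)
  s2 <- tb_random_seq(500, seed = 65)
  joined <- paste0(s1, strrep("N", 20), s2)
  expect_equal(imm_score(m, joined), imm_score(m, s1) + imm_score(m, s2),
               tolerance = 1e-9)
})

test_that("models prefer their own training genome", {
  gs <- tb_unit_genomes()
  mods <- lapply(gs, function(g) imm_train(substr(g$seq, 1, 2e5)))
  set.seed(66)
  for (r in 1:10) {
    pair <- sample.int(3, 2)
    test <- sample_fragments(gs[[pair[1]]], 5000, 1, seed = 600 + r)[[1]]
    own <- imm_score(mods[[pair[1]]], test)
    other <- imm_score(mods[[pair[2]]], test)
    expect_gt(own, other)
  }
})

test_that("assignment picks the arg-max and ignores model order", {
  gs <- tb_unit_genomes()
  comm <- tb_unit_community()
  cs <- comm$contigs[1:20, , drop = FALSE]
  class(cs) <- class(comm$contigs)
  mods <- lapply(gs, function(g) imm_train(substr(g$seq, 1, 2e5)))
  names(mods) <- c("m1", "m2", "m3")
  a1 <- imm_assign(mods, cs)
  a2 <- imm_assign(rev(mods), cs)
  expect_equal(a1$model, a2$model)
  # a single model takes everything
  single <- imm_assign(mods[2], cs)
  expect_true(all(single$model == "m2"))
  # well-separated genomes, 200 kb training: essentially perfect recovery
  ev <- evaluate_partition(
    data.frame(id = a1$id, length = cs$length,
               bin = match(a1$model, c("m1", "m2", "m3"))),
    setNames(comm$truth$genome, comm$truth$id))
  expect_gte(ev$overall_accuracy, 95)
})

test_that("seed-bin selection applies the three good-bin gates", {
  mkbin <- function(id, lens, covs) {
    list(id = id, members = paste0("b", id, "_", seq_along(lens)),
         total_length = sum(lens), mean_vector = NULL,
         coverage_values = covs)
  }
  res <- structure(list(confidence = 95, bins = list(
    mkbin(1, c(3e5, 3e5), c(10, 11)),   # passes everything
    mkbin(2, c(5e4, 5e4), c(10, 10)),   # fails the length floor
    mkbin(3, c(4e5, 4e5), c(5, 60)),    # fails the coverage CV gate
    mkbin(4, 6e5, 42)),                 # single coverage value: CV 0
    unassigned = character(), assignments = NULL),
    class = "binning_result")
  sel <- select_seed_bins(res, min_bin_length = 2e5, max_coverage_cv = 0.5)
  expect_equal(sel$candidate[match(1:4, sel$bin)],
               c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(sel$coverage_cv[sel$bin == 4], 0)
  expect_false(2 %in% sel$bin[sel$candidate])
  # taxonomy gate: a profile dominated below the majority fraction fails
  profs <- list("1" = data.frame(rank = "genus", taxon = "X", hits = 2L,
                                 total_hits = 10L, median_evalue = 1e-5))
  sel2 <- select_seed_bins(res, profiles = profs, min_bin_length = 2e5)
  expect_false(sel2$candidate[sel2$bin == 1])
})

test_that("models round-trip through the text serialization", {
  m <- imm_train(tb_random_seq(30000, seed = 67), max_order = 5)
  f <- withr::local_tempfile(fileext = ".imm")
  write_imm(m, f)
  back <- read_imm(f)
  expect_equal(back$max_order, m$max_order)
  expect_identical(back$counts, m$counts)
  expect_equal(back$probs, m$probs, tolerance = 1e-15)
  expect_equal(back$train_nt, m$train_nt)
  s <- tb_random_seq(2000, seed = 68)
  expect_equal(imm_score(back, s), imm_score(m, s))
})
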