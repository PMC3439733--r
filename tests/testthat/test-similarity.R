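test_that("similarity matches hand-computed values", {
  a <- gene_set("A", c("A", "B"))
  b <- gene_set("B", c("A", "B", "C", "D"))
  e <- set_similarity(a, b, similarity_params(alpha = 0.8))
  expect_equal(e$s_l, 0.5)     # 2 / 4
  expect_equal(e$s_r, 1.0)     # 2 / min(2, 4): containment
  expect_equal(e$score, 0.6)   # 0.8 * 0.5 + 0.2 * 1
  e2 <- set_similarity(gene_set("A", c("A", "B")),
                       gene_set("B", c("B", "C")), 0.8)
  expect_equal(e2$s_l, 1 / 3)
  expect_equal(e2$s_r, 1 / 2)
  expect_equal(e2$score, 0.8 / 3 + 0.1, tolerance = 1e-12)
})

test_that("identity and disjointness are the score extremes", {
  for (alpha in c(0, 0.3, 0.8, 1)) {
    same <- set_similarity(gene_set("A", c("A", "B", "C")),
                           gene_set("B", c("C", "B", "A")), alpha)
    expect_equal(same$score, 1.0)
    disj <- set_similarity(gene_set("A", c("A", "B")),
                           gene_set("B", c("C", "D")), alpha)
    expect_equal(disj$score, 0.0)
  }
  expect_error(set_similarity(gene_set("A", "X"), gene_set("A", "Y")),
               "different")
})

test_that("similarity equals the brute-force oracle on random small sets", {
  set.seed(101)
  universe <- sprintf("U%02d", 1:30)
  for (k in 1:300) {
    a <- random_small_set("A", universe)
    b <- random_small_set("B", universe)
    alpha <- runif(1)
    got <- set_similarity(a, b, alpha)
    want <- oracle_similarity(a$genes, b$genes, alpha)
    expect_equal(got$overlap, want$overlap)
    expect_equal(got$union_size, want$union_size)
    expect_equal(got$score, want$score, tolerance = 1e-12)
    # bounds and ordering of the two terms
    expect_true(got$s_l >= 0 && got$s_l <= got$s_r && got$s_r <= 1)
    expect_true(got$score >= 0 && got$score <= 1)
    # symmetry in argument order
    rev <- set_similarity(gene_set("B2", b$genes), gene_set("A2", a$genes),
                          alpha)
    expect_equal(rev$score, got$score, tolerance = 1e-15)
    expect_equal(rev$overlap, got$overlap)
  }
})

test_that("containment gives s_r = 1 and the closed-form score", {
  small <- gene_set("S", sprintf("G%02d", 1:7))
  big <- gene_set("B", sprintf("G%02d", 1:20))
  for (alpha in c(0.2, 0.8)) {
    e <- set_similarity(small, big, alpha)
    expect_equal(e$s_r, 1)
    expect_equal(e$score, alpha * 7 / 20 + (1 - alpha), tolerance = 1e-12)
  }
})

test_that("per-pair score is non-increasing in alpha", {
  set.seed(77)
  universe <- sprintf("U%02d", 1:30)
  grid <- seq(0, 1, by = 0.1)
  for (k in 1:50) {
    a <- random_small_set("A", universe)
    b <- random_small_set("B", universe)
    scores <- vapply(grid, function(al) set_similarity(a, b, al)$score,
                     numeric(1))
    expect_true(all(diff(scores) <= 1e-12))
  }
})

test_that("pairwise similarity enumerates exactly the overlapping pairs", {
  # chain: A-B overlap, B-C overlap, A-C disjoint
  coll <- gene_set_collection(list(A = c("X", "Y"), B = c("Y", "Z"),
                                   C = c("Z", "W")))
  edges <- pairwise_similarity(coll, 0.8, min_score = 0)
  expect_equal(nrow(edges), 2L)
  expect_equal(edges$set_i, c("A", "B"))
  expect_equal(edges$set_j, c("B", "C"))
  # disjoint sets yield no edges
  disj <- gene_set_collection(list(A = "X", B = "Y", C = "Z"))
  expect_equal(nrow(pairwise_similarity(disj, 0.8)), 0L)
  # n identical copies: complete graph, all scores 1
  n <- 5L
  copies <- gene_set_collection(
    stats::setNames(rep(list(c("P", "Q", "R")), n), sprintf("C%d", 1:n)))
  full <- pairwise_similarity(copies, 0.8)
  expect_equal(nrow(full), n * (n - 1L) / 2L)
  expect_true(all(full$score == 1))
  expect_error(pairwise_similarity(gene_set_collection(list(A = "X")), 0.8),
               "at least 2")
})

test_that("pairwise similarity agrees with per-pair calls on a random collection", {
  spec <- synth_spec(seed = 13L, n_sets = 15L, universe_size = 60L,
                     max_scale = 20L)
  coll <- generate_collection(spec)
  edges <- pairwise_similarity(coll, 0.8, min_score = 0)
  for (r in seq_len(nrow(edges))) {
    e <- set_similarity(get_set(coll, edges$set_i[r]),
                        get_set(coll, edges$set_j[r]), 0.8)
    expect_equal(edges$score[r], e$score, tolerance = 1e-12)
    expect_equal(edges$overlap[r], e$overlap)
    expect_equal(edges$union_size[r], e$union_size)
  }
  # min_score filters but never reorders
  strict <- pairwise_similarity(coll, 0.8, min_score = 0.2)
  expect_true(all(strict$score >= 0.2))
  expect_true(nrow(strict) <= nrow(edges))
})

test_that("alpha sensitivity reports decreasing means on a nested fixture", {
  coll <- nested_collection(20L)
  scan <- alpha_sensitivity(coll, alphas = seq(0.1, 0.9, by = 0.1),
                            bins = 20L)
  means <- scan$summary$mean_score
  expect_true(all(diff(means) < 0))  # strictly decreasing in alpha
  # histogram counts per alpha sum to the number of overlapping pairs
  by_alpha <- tapply(scan$histogram$count, scan$histogram$alpha, sum)
  expect_true(all(by_alpha == scan$summary$n_pairs))
  # brute-force mean at one alpha
  ids <- coll$info$set_id
  scores <- c()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i < j) {
      o <- oracle_similarity(coll$sets[[i]], coll$sets[[j]], 0.5)
      if (o$overlap >= 1) scores <- c(scores, o$score)
    }
  }
  expect_equal(scan$summary$mean_score[scan$summary$alpha == 0.5],
               mean(scores), tolerance = 1e-12)
  # skewness agrees with the reference moment implementation
  expect_equal(scan$summary$skewness[scan$summary$alpha == 0.5],
               e1071::skewness(scores, type = 1), tolerance = 1e-12)
})

test_that("identical sets put all histogram mass in the top bin", {
  copies <- gene_set_collection(
    stats::setNames(rep(list(c("P", "Q")), 4L), sprintf("C%d", 1:4)))
  scan <- alpha_sensitivity(copies, alphas = c(0, 0.5, 1), bins = 10L)
  top <- scan$histogram[scan$histogram$bin_high == 1, ]
  expect_true(all(top$count == 6L))
  expect_true(all(scan$histogram$count[scan$histogram$bin_high < 1] == 0L))
  expect_error(alpha_sensitivity(copies, alphas = 0.5, bins = 0L), "bins")
})

test_that("similarity matrix is symmetric with unit diagonal", {
  spec <- synth_spec(seed = 3L, n_sets = 10L, universe_size = 50L,
                     max_scale = 15L)
  coll <- generate_collection(spec)
  m <- similarity_matrix(coll, 0.8)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 1))
  edges <- pairwise_similarity(coll, 0.8)
  for (r in seq_len(nrow(edges))) {
    expect_equal(m[edges$set_i[r], edges$set_j[r]], edges$score[r])
  }
})
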