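test_that("GSAN edges equal brute-force all-pairs filtering", {
  for (seed in c(21L, 22L)) {
    spec <- synth_spec(seed = seed, n_sets = 30L, universe_size = 120L,
                       max_scale = 30L, overlap_model = "block",
                       n_blocks = 3L)
    coll <- generate_collection(spec)
    g <- build_gsan(coll, 0.8, min_similarity = 0.1, fisher_filter = TRUE,
                    universe = spec$universe_size)
    want <- oracle_gsan_edges(coll, 0.8, 0.1, spec$universe_size,
                              0.05, 0.05)
    expect_equal(nrow(g$edges), nrow(want))
    expect_equal(g$edges$set_i, want$set_i)
    expect_equal(g$edges$set_j, want$set_j)
    expect_equal(g$edges$score, want$score, tolerance = 1e-10)
    expect_equal(g$edges$p_value, want$p_value, tolerance = 1e-10)
    expect_equal(g$edges$fdr, want$fdr, tolerance = 1e-10)
  }
})

test_that("degenerate graphs: identical pair and fully disjoint sets", {
  twin <- gene_set_collection(list(A = c("X", "Y", "Z"),
                                   B = c("X", "Y", "Z")))
  g <- build_gsan(twin, 0.8, universe = 10)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$score, 1.0)
  disj <- gene_set_collection(list(A = c("X1", "X2"), B = c("Y1", "Y2"),
                                   C = c("Z1", "Z2")))
  g2 <- build_gsan(disj, 0.8)
  expect_equal(nrow(g2$edges), 0L)
  expect_equal(nrow(g2$nodes), 3L)   # isolates kept
  expect_true(all(g2$nodes$degree == 0L))
  expect_error(build_gsan(gene_set_collection(list(A = "X"))),
               "at least 2")
})

test_that("raising any threshold never adds edges", {
  spec <- synth_spec(seed = 40L, n_sets = 40L, universe_size = 150L,
                     max_scale = 30L, overlap_model = "block",
                     n_blocks = 4L)
  coll <- generate_collection(spec)
  base <- build_gsan(coll, 0.8, min_similarity = 0, fisher_filter = TRUE,
                     universe = 150, p_threshold = 0.2,
                     fdr_threshold = 0.2)
  key <- function(g) paste(g$edges$set_i, g$edges$set_j)
  for (ms in c(0.05, 0.1, 0.3)) {
    g <- build_gsan(coll, 0.8, min_similarity = ms, fisher_filter = TRUE,
                    universe = 150, p_threshold = 0.2, fdr_threshold = 0.2)
    expect_true(all(key(g) %in% key(base)))
  }
  for (pt in c(0.1, 0.05, 0.01)) {
    g <- build_gsan(coll, 0.8, min_similarity = 0, fisher_filter = TRUE,
                    universe = 150, p_threshold = pt, fdr_threshold = 0.2)
    expect_true(all(key(g) %in% key(base)))
  }
})

test_that("with filtering off, edges are exactly the overlapping pairs", {
  spec <- synth_spec(seed = 41L, n_sets = 25L, universe_size = 100L,
                     max_scale = 25L)
  coll <- generate_collection(spec)
  g <- build_gsan(coll, 0.8, min_similarity = 0, fisher_filter = FALSE)
  edges <- pairwise_similarity(coll, 0.8, min_score = 0)
  expect_equal(nrow(g$edges), nrow(edges))
  expect_equal(g$edges$set_i, edges$set_i)
  expect_equal(g$edges$score, edges$score)
})

test_that("graph is invariant to input set order", {
  spec <- synth_spec(seed = 42L, n_sets = 20L, universe_size = 80L,
                     max_scale = 20L, overlap_model = "block")
  coll <- generate_collection(spec)
  perm <- rev(coll$info$set_id)
  coll2 <- subset_collection(coll, perm)
  g1 <- build_gsan(coll, 0.8, universe = 80)
  g2 <- build_gsan(coll2, 0.8, universe = 80)
  expect_equal(g1$edges, g2$edges)
  expect_equal(g1$nodes, g2$nodes)
})

test_that("expression annotation fills node colors; planted set is maximal", {
  spec0 <- synth_spec(seed = 43L, n_sets = 30L, universe_size = 150L,
                      max_scale = 30L, overlap_model = "block")
  coll <- generate_collection(spec0)
  target <- coll$info$set_id[which.min(coll$info$scale)]
  spec <- synth_spec(seed = 43L, n_sets = 30L, universe_size = 150L,
                     max_scale = 30L, overlap_model = "block",
                     target_sets = target, effect_size = 4)
  expr <- generate_expression(spec, coll)
  g <- annotate_expression(build_gsan(coll, 0.8, universe = 150),
                           coll, expr, 6)
  expect_true(all(!is.na(g$nodes$norm_abs_fc)))  # full coverage
  expect_equal(g$nodes$set_id[which.max(g$nodes$norm_abs_fc)], target)
  # empty coverage: every node undefined
  alien <- expression_table("ZZZZ", 2)
  g2 <- annotate_expression(g, coll, alien, 6)
  expect_true(all(is.na(g2$nodes$norm_abs_fc)))
})

test_that("table exports round-trip losslessly", {
  spec <- synth_spec(seed = 44L, n_sets = 15L, universe_size = 60L,
                     max_scale = 20L, overlap_model = "block")
  coll <- generate_collection(spec)
  expr <- generate_expression(spec, coll)
  g <- annotate_expression(build_gsan(coll, 0.8, universe = 60), coll,
                           expr, 6)
  prefix <- file.path(tempdir(), "gsan_rt")
  export_gsan(g, prefix, format = "tables")
  back <- read_gsan_tables(prefix)
  expect_equal(back$nodes, g$nodes, tolerance = 1e-12)
  expect_equal(back$edges, g$edges, tolerance = 1e-12)
  expect_equal(back$params$alpha, g$params$alpha)
  expect_equal(back$params$universe_size, g$params$universe_size)
})

test_that("SIF export lists one line per edge plus bare isolated nodes", {
  coll <- gene_set_collection(list(A = c("X", "Y"), B = c("X", "Y"),
                                   C = c("Q1", "Q2")))
  g <- build_gsan(coll, 0.8, universe = 10, fisher_filter = FALSE,
                  min_similarity = 0.1)
  prefix <- file.path(tempdir(), "gsan_sif")
  export_gsan(g, prefix, format = "sif")
  lines <- readLines(paste0(prefix, ".sif"))
  expect_equal(lines, c("A\tgsan\tB", "C"))
  expect_error(export_gsan(g, prefix, format = "dot"), "unknown")
})

test_that("GraphML export is readable and preserves attributes", {
  spec <- synth_spec(seed = 45L, n_sets = 12L, universe_size = 50L,
                     max_scale = 15L, overlap_model = "block")
  coll <- generate_collection(spec)
  g <- build_gsan(coll, 0.8, universe = 50, fisher_filter = FALSE,
                  min_similarity = 0)
  prefix <- file.path(tempdir(), "gsan_gml")
  export_gsan(g, prefix, format = "graphml")
  ig <- igraph::read_graph(paste0(prefix, ".graphml"), format = "graphml")
  expect_equal(igraph::vcount(ig), nrow(g$nodes))
  expect_equal(igraph::ecount(ig), nrow(g$edges))
  expect_setequal(igraph::V(ig)$name, g$nodes$set_id)
  expect_equal(sort(igraph::E(ig)$score), sort(g$edges$score),
               tolerance = 1e-9)
})

test_that("exports are byte-identical across repeated runs", {
  spec <- synth_spec(seed = 46L, n_sets = 15L, universe_size = 60L,
                     max_scale = 20L, overlap_model = "block")
  coll <- generate_collection(spec)
  p1 <- file.path(tempdir(), "det1")
  p2 <- file.path(tempdir(), "det2")
  export_gsan(build_gsan(coll, 0.8, universe = 60), p1, "tables")
  export_gsan(build_gsan(coll, 0.8, universe = 60), p2, "tables")
  for (suffix in c("_nodes.tsv", "_edges.tsv")) {
    expect_identical(readLines(paste0(p1, suffix)),
                     readLines(paste0(p2, suffix)))
  }
})
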