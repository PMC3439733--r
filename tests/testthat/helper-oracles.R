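# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (explicit element enumeration, exhaustive draws) so
# they cannot share a defect with the implementation they check.

# Weighted Jaccard/cover similarity by explicit element enumeration.
oracle_similarity <- function(genes_a, genes_b, alpha) {
  ov <- 0L
  for (g in genes_a) if (any(g == genes_b)) ov <- ov + 1L
  un <- length(genes_a)
  for (g in genes_b) if (!any(g == genes_a)) un <- un + 1L
  s_l <- ov / un
  s_r <- ov / min(length(genes_a), length(genes_b))
  list(overlap = ov, union_size = un, s_l = s_l, s_r = s_r,
       score = alpha * s_l + (1 - alpha) * s_r)
}

# One-sided over-representation p-value by exhaustive enumeration of all
# C(N, q) equally likely query draws. Feasible for N <= 12.
oracle_fisher_enum <- function(hits, query_size, set_scale, universe_size) {
  if (query_size == 0L) return(1)
  draws <- utils::combn(universe_size, query_size)
  inside <- seq_len(set_scale)  # which universe elements are in the set
  at_least <- 0L
  for (k in seq_len(ncol(draws))) {
    if (sum(draws[, k] %in% inside) >= hits) at_least <- at_least + 1L
  }
  at_least / ncol(draws)
}

# Benjamini-Hochberg step-up by direct hand computation.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in rev(seq_len(m))) {
    val <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- val
    prev <- val
  }
  adj
}

# Random small gene set over an alphabet of <= 30 symbols.
random_small_set <- function(id, universe) {
  gene_set(id, sample(universe, sample(seq_along(universe), 1L)))
}

# Nested chain fixture: set k strictly contains set k-1.
nested_collection <- function(n_sets = 20L, step = 3L) {
  genes <- sprintf("N%03d", seq_len(n_sets * step + 2L))
  sets <- lapply(seq_len(n_sets), function(k) genes[seq_len(2L + k * step)])
  names(sets) <- sprintf("NEST%02d", seq_len(n_sets))
  gene_set_collection(sets, collection_id = "nested")
}

# Write a GMT file from raw lines in a temp file.
tmp_gmt <- function(lines) {
  path <- tempfile(fileext = ".gmt")
  writeLines(lines, path)
  path
}

# Brute-force GSAN edge list: loop over every pair, apply the same
# thresholds, with fisher.test() as the independent p-value route and the
# hand BH above for FDR.
oracle_gsan_edges <- function(collection, alpha, min_similarity,
                              universe_size, p_threshold, fdr_threshold,
                              fisher_filter = TRUE) {
  ids <- collection$info$set_id
  rows <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i >= j) next
      sim <- oracle_similarity(collection$sets[[i]], collection$sets[[j]],
                               alpha)
      if (sim$overlap < 1L) next
      a <- min(length(collection$sets[[i]]), length(collection$sets[[j]]))
      b <- max(length(collection$sets[[i]]), length(collection$sets[[j]]))
      tab <- matrix(c(sim$overlap, a - sim$overlap, b - sim$overlap,
                      universe_size - a - b + sim$overlap), nrow = 2L)
      p <- stats::fisher.test(tab, alternative = "greater")$p.value
      key_i <- min(ids[i], ids[j])
      key_j <- max(ids[i], ids[j])
      rows[[length(rows) + 1L]] <- data.frame(
        set_i = key_i, set_j = key_j, score = sim$score, p_value = p,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(set_i = character(), set_j = character()))
  }
  cand <- do.call(rbind, rows)
  cand$fdr <- oracle_bh(cand$p_value)
  keep <- cand$score >= min_similarity
  if (fisher_filter) {
    keep <- keep & cand$p_value < p_threshold & cand$fdr < fdr_threshold
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$set_i, out$set_j), , drop = FALSE]
}
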