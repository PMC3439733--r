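# Gene-set similarity: weighted combination of the Jaccard coefficient and
# the cover (overlap) coefficient,
#   S = alpha * |A n B| / |A u B| + (1 - alpha) * |A n B| / min(|A|, |B|).
# The cover term guarantees a high score when a large set contains a small
# one, where the Jaccard term alone would be near zero.

#' Similarity parameters
#'
#' @param alpha Weight in `[0, 1]` given to the Jaccard term; the remainder
#'   `1 - alpha` weights the cover term. Default 0.8, the value at which the
#'   score distribution over real collections is well-behaved (neither the
#'   cover term's inflation at small alpha nor the Jaccard term's deflation
#'   at large alpha dominates).
#' @return Object of class `similarity_params`.
#' @export
similarity_params <- function(alpha = 0.8) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1)
  structure(list(alpha = alpha), class = "similarity_params")
}

.alpha_of <- function(params) {
  if (inherits(params, "similarity_params")) return(params$alpha)
  stopifnot(is.numeric(params), length(params) == 1L,
            params >= 0, params <= 1)
  as.numeric(params)
}

#' Similarity score between two gene sets
#'
#' Computes the weighted Jaccard/cover similarity between two distinct gene
#' sets. The Jaccard term `s_l = |A n B| / |A u B|` measures overall overlap;
#' the cover term `s_r = |A n B| / min(|A|, |B|)` equals 1 whenever one set
#' contains the other. Since `min(|A|, |B|) <= |A u B|`, `s_l <= s_r` always,
#' so the score is non-increasing in `alpha`. The score is symmetric in its
#' arguments and lies in `[0, 1]`, with 1 iff the sets are equal and 0 iff
#' they are disjoint.
#'
#' @param set_a,set_b `gene_set` objects with distinct ids.
#' @param params A `similarity_params` object or a bare numeric alpha.
#' @return A one-row data frame (class `similarity_edge`) with columns
#'   `set_i`, `set_j`, `overlap`, `union_size`, `s_l`, `s_r`, `score`.
#' @examples
#' a <- gene_set("A", c("TP53", "KRAS"))
#' b <- gene_set("B", c("TP53", "KRAS", "APC", "BRAF"))
#' set_similarity(a, b, similarity_params(alpha = 0.8))  # score 0.6
#' @export
set_similarity <- function(set_a, set_b, params = similarity_params()) {
  stopifnot(inherits(set_a, "gene_set"), inherits(set_b, "gene_set"))
  if (identical(set_a$set_id, set_b$set_id)) {
    stop("similarity is defined for two *different* gene sets (i != j); ",
         "both arguments have id '", set_a$set_id, "'")
  }
  alpha <- .alpha_of(params)
  na <- length(set_a$genes)
  nb <- length(set_b$genes)
  ov <- length(intersect(set_a$genes, set_b$genes))
  union_size <- na + nb - ov
  s_l <- ov / union_size
  s_r <- ov / min(na, nb)
  edge <- data.frame(set_i = set_a$set_id, set_j = set_b$set_id,
                     overlap = ov, union_size = union_size,
                     s_l = s_l, s_r = s_r,
                     score = alpha * s_l + (1 - alpha) * s_r,
                     stringsAsFactors = FALSE)
  class(edge) <- c("similarity_edge", class(edge))
  edge
}

#' All-pairs gene-set similarity within a collection
#'
#' Scores every unordered pair of distinct sets that share at least one gene
#' and returns those with `score >= min_score`. Pairs with zero overlap are
#' omitted entirely (they would carry score 0 and are not candidate
#' associations). Overlap counting uses a sparse set-by-gene incidence
#' matrix, so memory is proportional to the number of overlapping pairs,
#' not to the square of the collection size.
#'
#' @param collection A `gene_set_collection` with at least two sets.
#' @param params A `similarity_params` or bare alpha.
#' @param min_score Minimum retained score (default 0).
#' @param organism Optional organism label; when given, only sets annotated
#'   with that organism are paired.
#' @return Data frame of edges, one row per retained unordered pair, in
#'   canonical order (by `set_i` then `set_j` id); columns as in
#'   [set_similarity()].
#' @export
pairwise_similarity <- function(collection, params = similarity_params(),
                                min_score = 0, organism = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"),
            is.numeric(min_score), min_score >= 0)
  alpha <- .alpha_of(params)
  sets <- collection$sets
  if (!is.null(organism)) {
    keep <- !is.na(collection$info$organism) &
      collection$info$organism == organism
    sets <- sets[keep]
  }
  if (length(sets) < 2L) {
    stop("pairwise similarity needs at least 2 gene sets",
         if (!is.null(organism)) paste0(" for organism '", organism, "'"))
  }
  edges <- .overlap_pairs(sets)
  if (nrow(edges) == 0L) return(.edge_frame(edges, alpha, min_score))
  .edge_frame(edges, alpha, min_score)
}

# Sparse all-pairs overlap counts. Returns data frame with i, j (indices,
# i < j in list order), overlap, size_i, size_j for pairs with overlap >= 1.
.overlap_pairs <- function(sets) {
  ids <- names(sets)
  genes <- sort(unique(unlist(sets, use.names = FALSE)))
  m <- Matrix::sparseMatrix(
    i = rep.int(seq_along(sets), lengths(sets)),
    j = match(unlist(sets, use.names = FALSE), genes),
    x = 1,
    dims = c(length(sets), length(genes))
  )
  ov <- Matrix::tcrossprod(m)
  trip <- Matrix::summary(ov)  # symmetric storage: upper or lower triangle
  trip <- trip[trip$i < trip$j, , drop = FALSE]
  sizes <- lengths(sets)
  data.frame(i = trip$i, j = trip$j, overlap = as.integer(trip$x),
             size_i = sizes[trip$i], size_j = sizes[trip$j],
             id_i = ids[trip$i], id_j = ids[trip$j],
             stringsAsFactors = FALSE)
}

# Score raw overlap pairs, filter, canonicalize order.
.edge_frame <- function(pairs, alpha, min_score) {
  if (nrow(pairs) == 0L) {
    out <- data.frame(set_i = character(), set_j = character(),
                      overlap = integer(), union_size = integer(),
                      s_l = numeric(), s_r = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  union_size <- pairs$size_i + pairs$size_j - pairs$overlap
  s_l <- pairs$overlap / union_size
  s_r <- pairs$overlap / pmin(pairs$size_i, pairs$size_j)
  score <- alpha * s_l + (1 - alpha) * s_r
  # canonical endpoint order: lexicographically smaller id first
  flip <- pairs$id_j < pairs$id_i
  set_i <- ifelse(flip, pairs$id_j, pairs$id_i)
  set_j <- ifelse(flip, pairs$id_i, pairs$id_j)
  out <- data.frame(set_i = set_i, set_j = set_j,
                    overlap = pairs$overlap, union_size = union_size,
                    s_l = s_l, s_r = s_r, score = score,
                    stringsAsFactors = FALSE)
  out <- out[out$score >= min_score, , drop = FALSE]
  out <- out[order(out$set_i, out$set_j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sensitivity of the similarity-score distribution to alpha
#'
#' For each candidate alpha, computes all pairwise scores (overlap >= 1)
#' over the collection, bins them into a histogram over `[0, 1]`, and
#' reports the sample skewness and mean. Because the Jaccard term never
#' exceeds the cover term, every per-pair score is non-increasing in alpha:
#' small alpha inflates scores (right mass, cover-dominated), large alpha
#' deflates them (left mass, Jaccard-dominated). The distribution shape is
#' reported descriptively; no formal distributional test is applied.
#'
#' @param collection A `gene_set_collection` with at least two sets.
#' @param alphas Numeric vector of weights in `[0, 1]`.
#' @param bins Positive number of histogram bins over `[0, 1]` (default 20).
#' @return List of class `alpha_sensitivity` with elements `histogram`
#'   (data frame: alpha, bin_low, bin_high, count) and `summary` (data
#'   frame: alpha, n_pairs, mean_score, skewness).
#' @export
alpha_sensitivity <- function(collection, alphas = seq(0, 1, by = 0.1),
                              bins = 20L) {
  stopifnot(inherits(collection, "gene_set_collection"),
            length(collection$sets) >= 2L,
            is.numeric(alphas), length(alphas) >= 1L,
            all(alphas >= 0 & alphas <= 1))
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 1L) stop("'bins' must be a positive count")
  pairs <- .overlap_pairs(collection$sets)
  s_l <- if (nrow(pairs)) {
    pairs$overlap / (pairs$size_i + pairs$size_j - pairs$overlap)
  } else numeric()
  s_r <- if (nrow(pairs)) {
    pairs$overlap / pmin(pairs$size_i, pairs$size_j)
  } else numeric()
  breaks <- seq(0, 1, length.out = bins + 1L)
  hist_rows <- list()
  summ_rows <- list()
  for (k in seq_along(alphas)) {
    a <- alphas[k]
    scores <- a * s_l + (1 - a) * s_r
    cnt <- if (length(scores)) {
      tabulate(findInterval(scores, breaks, rightmost.closed = TRUE,
                            all.inside = TRUE), nbins = bins)
    } else integer(bins)
    hist_rows[[k]] <- data.frame(alpha = a,
                                 bin_low = breaks[-(bins + 1L)],
                                 bin_high = breaks[-1L],
                                 count = cnt)
    summ_rows[[k]] <- data.frame(alpha = a, n_pairs = length(scores),
                                 mean_score = mean(scores),
                                 skewness = .sample_skewness(scores))
  }
  structure(list(histogram = do.call(rbind, hist_rows),
                 summary = do.call(rbind, summ_rows)),
            class = "alpha_sensitivity")
}

# Moment-based sample skewness m3 / m2^(3/2); NA for degenerate input.
.sample_skewness <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  d <- x - mean(x)
  m2 <- mean(d^2)
  if (m2 == 0) return(NA_real_)
  mean(d^3) / m2^1.5
}

#' Write a similarity edge list as TSV
#' @param edges Edge data frame from [pairwise_similarity()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Square similarity matrix for a (small) collection
#'
#' Dense set-by-set score matrix with unit diagonal, suitable for CSV export
#' and heat-map display of gene-set similarities. Intended for collections
#' of up to a few hundred sets.
#'
#' @param collection A `gene_set_collection`.
#' @param params A `similarity_params` or bare alpha.
#' @return Numeric matrix with set ids as dimnames.
#' @export
similarity_matrix <- function(collection, params = similarity_params()) {
  stopifnot(inherits(collection, "gene_set_collection"))
  edges <- pairwise_similarity(collection, params, min_score = 0)
  ids <- collection$info$set_id
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  if (nrow(edges)) {
    idx_i <- match(edges$set_i, ids)
    idx_j <- match(edges$set_j, ids)
    m[cbind(idx_i, idx_j)] <- edges$score
    m[cbind(idx_j, idx_i)] <- edges$score
  }
  m
}
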