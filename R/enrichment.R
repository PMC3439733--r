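# Over-representation search: hit counting, one-sided Fisher's exact test
# under the hypergeometric null, Benjamini-Hochberg FDR, and ranked search
# of query gene lists against gene-set collections.

#' Count query genes present in a gene set
#'
#' @param query A `query_gene_list` (or character vector of normalized
#'   symbols).
#' @param gene_set A `gene_set` (or character vector).
#' @return Integer overlap count.
#' @export
count_hits <- function(query, gene_set) {
  q <- if (inherits(query, "query_gene_list")) query$symbols else query
  g <- if (inherits(gene_set, "gene_set")) gene_set$genes else gene_set
  length(intersect(q, g))
}

#' One-sided Fisher's exact p-value for over-representation
#'
#' Probability of observing at least `hits` query genes inside a gene set
#' under the hypergeometric null: `query_size` genes drawn without
#' replacement from a universe of `universe_size` genes of which
#' `set_scale` belong to the set. This upper-tail hypergeometric
#' probability is the one-sided Fisher's exact test on the 2x2 overlap
#' table; it is computed with `stats::phyper`. Arguments are vectorized.
#'
#' @param hits Observed overlap count(s).
#' @param query_size Number of query genes.
#' @param set_scale Number of genes in the set.
#' @param universe_size Background population size.
#' @return p-value(s) in `(0, 1]`; `hits = 0` gives exactly 1.
#' @export
fisher_pvalue <- function(hits, query_size, set_scale, universe_size) {
  n <- max(length(hits), length(query_size), length(set_scale),
           length(universe_size))
  hits <- rep_len(as.numeric(hits), n)
  query_size <- rep_len(as.numeric(query_size), n)
  set_scale <- rep_len(as.numeric(set_scale), n)
  universe_size <- rep_len(as.numeric(universe_size), n)
  if (any(universe_size < 1)) stop("'universe_size' must be >= 1")
  if (any(hits < 0 | query_size < 0 | set_scale < 0)) {
    stop("counts must be non-negative")
  }
  if (any(hits > pmin(query_size, set_scale))) {
    stop("'hits' cannot exceed min(query_size, set_scale)")
  }
  if (any(query_size > universe_size | set_scale > universe_size)) {
    stop("'query_size' and 'set_scale' cannot exceed 'universe_size'")
  }
  # feasibility of the 2x2 table: overlap >= query + set - universe
  if (any(hits < query_size + set_scale - universe_size)) {
    stop("inconsistent counts: hits below the minimum feasible overlap")
  }
  stats::phyper(hits - 1, set_scale, universe_size - set_scale, query_size,
                lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over a family of tests, order-aligned with the
#' input; every adjusted value is at least its raw p and at most 1. Thin
#' validated wrapper around `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) stop("'p_values' must be non-empty")
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("all p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

# Resolve the Fisher background size. "auto" = union of all loaded
# collection universes — the widest population the data itself defines.
.resolve_universe <- function(universe, collections) {
  if (identical(universe, "auto")) {
    length(unique(unlist(lapply(collections, `[[`, "universe"),
                         use.names = FALSE)))
  } else {
    u <- as.numeric(universe)
    if (is.na(u) || u < 1) stop("'universe' must be \"auto\" or a count >= 1")
    u
  }
}

#' Search collections for gene sets enriched in a query gene list
#'
#' Tests every gene set (optionally excluding whole sources) for
#' over-representation of the query, keeps sets with at least `min_hits`
#' query genes and one-sided Fisher p-value below `p_threshold`, adjusts
#' for multiplicity with Benjamini-Hochberg over the retained family, and
#' ranks by decreasing hits (ties: increasing p, then set id).
#'
#' Query genes absent from the background universe still count toward
#' `query_size` but their number is reported via `message()` — a query
#' drawn from outside the collections weakens the test rather than
#' invalidating it silently.
#'
#' @param query A `query_gene_list`.
#' @param collections A `gene_set_collection` or list of them.
#' @param min_hits Minimum overlap for a set to be reported (default 2).
#' @param p_threshold Fisher p-value cut-off (default 0.05).
#' @param universe `"auto"` (size of the union of collection universes) or
#'   an explicit background count. The background materially changes
#'   p-values; the value used should be recorded with any published result.
#' @param exclude_sources Source tags removed before testing (their sets
#'   are neither tested nor counted in the FDR family).
#' @return Data frame of class `enrichment_result` with columns `set_id`,
#'   `name`, `source`, `organism`, `hits`, `set_scale`, `query_size`,
#'   `universe_size`, `p_value`, `fdr`, `rank`.
#' @export
search_by_genes <- function(query, collections, min_hits = 2L,
                            p_threshold = 0.05, universe = "auto",
                            exclude_sources = character()) {
  stopifnot(inherits(query, "query_gene_list"))
  if (inherits(collections, "gene_set_collection")) {
    collections <- list(collections)
  }
  stopifnot(length(collections) >= 1L,
            all(vapply(collections, inherits, logical(1),
                       "gene_set_collection")))
  universe_size <- .resolve_universe(universe, collections)
  full_universe <- unique(unlist(lapply(collections, `[[`, "universe"),
                                 use.names = FALSE))
  n_absent <- sum(!query$symbols %in% full_universe)
  if (n_absent > 0L) {
    message("search_by_genes: ", n_absent, " of ", length(query$symbols),
            " query genes are absent from the collection universe")
  }
  query_size <- length(query$symbols)
  if (query_size > universe_size) {
    stop("query (", query_size, " genes) is larger than the universe (",
         universe_size, "); supply a larger explicit 'universe'")
  }
  tabs <- lapply(collections, function(coll) {
    info <- coll$info
    keep <- !info$source %in% exclude_sources
    if (!any(keep)) return(NULL)
    info <- info[keep, , drop = FALSE]
    hits <- vapply(coll$sets[keep], function(g) {
      length(intersect(query$symbols, g))
    }, integer(1))
    data.frame(set_id = info$set_id, name = info$name, source = info$source,
               organism = info$organism, hits = unname(hits),
               set_scale = info$scale, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))])
  if (is.null(tab) || nrow(tab) == 0L) {
    stop("no gene sets left to test after source exclusion")
  }
  if (any(tab$set_scale > universe_size)) {
    stop("a gene set is larger than the stated universe; ",
         "supply a larger explicit 'universe'")
  }
  tab$query_size <- query_size
  tab$universe_size <- universe_size
  tab$p_value <- fisher_pvalue(tab$hits, query_size, tab$set_scale,
                               universe_size)
  tab <- tab[tab$hits >= min_hits & tab$p_value < p_threshold, ,
             drop = FALSE]
  if (nrow(tab) == 0L) {
    tab$fdr <- numeric()
    tab$rank <- integer()
    class(tab) <- c("enrichment_result", class(tab))
    return(tab)
  }
  tab$fdr <- bh_fdr(tab$p_value)
  tab <- tab[order(-tab$hits, tab$p_value, tab$set_id), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  class(tab) <- c("enrichment_result", class(tab))
  tab
}

#' Disease-profile search: name match, then enrichment of the profile
#'
#' Two-stage search mirroring disease-centric querying: all sets from the
#' designated disease sources whose name matches `term` are pooled into a
#' disease gene profile (the union of their members), and that profile is
#' then used as the query against all remaining sources. The disease
#' sources themselves are excluded from the enrichment stage so the answer
#' is not dominated by the sets that defined the profile.
#'
#' @param term Disease term matched case-insensitively against set names.
#' @param disease_sources Source tags (e.g. disease-gene databases) whose
#'   name-matching sets define the profile.
#' @param collections A `gene_set_collection` or list of them.
#' @param min_hits,p_threshold,universe Passed to [search_by_genes()].
#' @return List with elements `profile` (a `query_gene_list`), `matched`
#'   (data frame of the name-matched disease sets) and `results` (an
#'   `enrichment_result` table).
#' @export
disease_profile_search <- function(term, disease_sources, collections,
                                   min_hits = 2L, p_threshold = 0.05,
                                   universe = "auto") {
  if (inherits(collections, "gene_set_collection")) {
    collections <- list(collections)
  }
  matched <- name_search(term, collections, sources = disease_sources)
  if (nrow(matched) == 0L) {
    stop("no gene set in sources [", paste(disease_sources, collapse = ", "),
         "] matches term '", term, "'; cannot build a disease profile")
  }
  coll_by_id <- stats::setNames(collections,
                                vapply(collections, `[[`, character(1),
                                       "collection_id"))
  profile_genes <- unique(unlist(lapply(seq_len(nrow(matched)), function(i) {
    coll <- coll_by_id[[matched$collection_id[i]]]
    coll$sets[[match(matched$set_id[i], coll$info$set_id)]]
  }), use.names = FALSE))
  profile <- query_gene_list(profile_genes,
                             label = paste0("profile:", term))
  results <- search_by_genes(profile, collections, min_hits = min_hits,
                             p_threshold = p_threshold, universe = universe,
                             exclude_sources = disease_sources)
  list(profile = profile, matched = matched, results = results)
}

#' Write enrichment results as CSV
#' @param results An `enrichment_result` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(results, path) {
  cols <- c("set_id", "name", "source", "organism", "hits", "set_scale",
            "p_value", "fdr", "rank")
  utils::write.csv(results[, cols, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}
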