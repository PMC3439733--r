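# Gene-set association network (GSAN): an undirected graph whose nodes are
# gene sets and whose edges are similarity associations. Node attributes
# map to display channels (size = scale, color = NORM_ABS_FC, line color =
# source); edge width maps to the similarity score. Exports target
# Cytoscape (SIF, GraphML) plus plain node/edge attribute tables.

#' Build a gene-set association network
#'
#' Candidate edges are all unordered pairs of sets sharing at least one
#' gene. Each candidate is scored by the weighted Jaccard/cover similarity
#' and, when `fisher_filter` is on, tested for overlap significance under
#' the hypergeometric null — the smaller set plays the role of the query
#' drawn against the larger, with Benjamini-Hochberg FDR over all
#' candidates. Retained edges satisfy `score >= min_similarity` and, with
#' filtering on, `p < p_threshold` and `fdr < fdr_threshold`. Every input
#' set appears as a node; isolates are kept (and counted in the summary)
#' since an unconnected set is still part of the displayed selection.
#'
#' @param collection A `gene_set_collection` with at least two sets.
#' @param params A `similarity_params` or bare alpha (default 0.8).
#' @param min_similarity Minimum similarity score for an edge (default 0.1).
#' @param fisher_filter Apply the edge-level Fisher/FDR filter (default
#'   `TRUE`).
#' @param universe `"auto"` (collection universe size) or explicit count
#'   used as the hypergeometric background for edge tests.
#' @param p_threshold,fdr_threshold Edge-level significance cut-offs
#'   (defaults 0.05).
#' @param orientation `"smaller_as_query"` (default) or
#'   `"larger_as_query"`: which set of each pair is treated as the drawn
#'   sample in the 2x2 table. The choice is a documented convention; both
#'   give identical overlap counts but different margins.
#' @return Object of class `gsan` with elements `nodes` (data frame:
#'   set_id, name, source, organism, scale, norm_abs_fc, degree), `edges`
#'   (data frame: set_i, set_j, overlap, union_size, s_l, s_r, score,
#'   p_value, fdr) and `params` (list echoing all thresholds and the
#'   universe size actually used).
#' @export
build_gsan <- function(collection, params = similarity_params(),
                       min_similarity = 0.1, fisher_filter = TRUE,
                       universe = "auto", p_threshold = 0.05,
                       fdr_threshold = 0.05,
                       orientation = c("smaller_as_query",
                                       "larger_as_query")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) < 2L) {
    stop("a GSAN needs at least 2 gene sets")
  }
  orientation <- match.arg(orientation)
  alpha <- .alpha_of(params)
  universe_size <- .resolve_universe(universe, list(collection))
  if (any(collection$info$scale > universe_size)) {
    stop("a gene set is larger than the stated universe")
  }
  edges <- pairwise_similarity(collection, alpha, min_score = 0)
  if (nrow(edges) > 0L) {
    scale_of <- stats::setNames(collection$info$scale,
                                collection$info$set_id)
    si <- scale_of[edges$set_i]
    sj <- scale_of[edges$set_j]
    qs <- if (orientation == "smaller_as_query") pmin(si, sj) else
      pmax(si, sj)
    ss <- if (orientation == "smaller_as_query") pmax(si, sj) else
      pmin(si, sj)
    edges$p_value <- fisher_pvalue(edges$overlap, qs, ss, universe_size)
    edges$fdr <- bh_fdr(edges$p_value)  # over all overlap >= 1 candidates
    keep <- edges$score >= min_similarity
    if (fisher_filter) {
      keep <- keep & edges$p_value < p_threshold & edges$fdr < fdr_threshold
    }
    edges <- edges[keep, , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges$p_value <- numeric()
    edges$fdr <- numeric()
  }
  nodes <- collection$info[, c("set_id", "name", "source", "organism",
                               "scale"), drop = FALSE]
  nodes <- nodes[order(nodes$set_id), , drop = FALSE]
  nodes$norm_abs_fc <- NA_real_
  deg <- table(c(edges$set_i, edges$set_j))
  nodes$degree <- as.integer(deg[nodes$set_id])
  nodes$degree[is.na(nodes$degree)] <- 0L
  rownames(nodes) <- NULL
  structure(
    list(nodes = nodes, edges = edges,
         params = list(alpha = alpha, min_similarity = min_similarity,
                       fisher_filter = fisher_filter,
                       universe_size = universe_size,
                       p_threshold = p_threshold,
                       fdr_threshold = fdr_threshold,
                       orientation = orientation)),
    class = "gsan"
  )
}

#' @export
print.gsan <- function(x, ...) {
  cat("<gsan> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges (",
      sum(x$nodes$degree == 0L), " isolated)\n", sep = "")
  cat("  alpha ", x$params$alpha, ", min similarity ",
      x$params$min_similarity, ", universe ", x$params$universe_size,
      if (x$params$fisher_filter) {
        paste0(", edge Fisher p < ", x$params$p_threshold, " & FDR < ",
               x$params$fdr_threshold)
      } else ", no Fisher filter",
      "\n", sep = "")
  invisible(x)
}

#' Annotate GSAN nodes with differential gene-set expression
#'
#' Fills the `norm_abs_fc` node attribute (the node-color channel) from an
#' expression table; nodes whose sets have no measured gene stay `NA`.
#'
#' @param graph A `gsan` object.
#' @param collection The `gene_set_collection` the graph was built from
#'   (memberships are needed to aggregate per-gene fold changes).
#' @param expr An `expression_table`.
#' @param params A `norm_params` or bare `p` (default 6).
#' @return The annotated `gsan`.
#' @export
annotate_expression <- function(graph, collection, expr,
                                params = norm_params()) {
  stopifnot(inherits(graph, "gsan"),
            inherits(collection, "gene_set_collection"))
  p <- .p_of(params)
  idx <- match(graph$nodes$set_id, collection$info$set_id)
  if (anyNA(idx)) stop("graph contains nodes absent from 'collection'")
  graph$nodes$norm_abs_fc <- vapply(collection$sets[idx], function(g) {
    norm_abs_fc(g, expr, p)
  }, numeric(1))
  graph
}

#' Export a GSAN
#'
#' `"tables"` writes `<prefix>_nodes.tsv` and `<prefix>_edges.tsv` (these
#' round-trip through [read_gsan_tables()]); `"sif"` writes a Cytoscape
#' simple-interaction file with interaction type `gsan`, isolated nodes
#' appended as bare node lines; `"graphml"` writes GraphML with all node
#' and edge attributes. Output is deterministic: nodes and edges are held
#' in canonical id order.
#'
#' @param graph A `gsan` object.
#' @param prefix Output path prefix (directory must exist).
#' @param format One or more of `"tables"`, `"sif"`, `"graphml"`.
#' @return Invisibly, character vector of the files written.
#' @export
export_gsan <- function(graph, prefix, format = c("tables", "sif",
                                                  "graphml")) {
  stopifnot(inherits(graph, "gsan"))
  bad <- setdiff(format, c("tables", "sif", "graphml"))
  if (length(bad) > 0L) {
    stop("unknown export format(s): ", paste(bad, collapse = ", "))
  }
  if (nrow(graph$nodes) == 0L) stop("cannot export an empty graph")
  written <- character()
  if ("tables" %in% format) {
    node_path <- paste0(prefix, "_nodes.tsv")
    edge_path <- paste0(prefix, "_edges.tsv")
    utils::write.table(graph$nodes, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(graph$edges, edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    params_path <- paste0(prefix, "_params.json")
    jsonlite::write_json(graph$params, params_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    written <- c(written, node_path, edge_path, params_path)
  }
  if ("sif" %in% format) {
    sif_path <- paste0(prefix, ".sif")
    lines <- character()
    if (nrow(graph$edges) > 0L) {
      lines <- paste(graph$edges$set_i, "gsan", graph$edges$set_j,
                     sep = "\t")
    }
    isolated <- setdiff(graph$nodes$set_id,
                        c(graph$edges$set_i, graph$edges$set_j))
    writeLines(c(lines, isolated), sif_path)
    written <- c(written, sif_path)
  }
  if ("graphml" %in% format) {
    gml_path <- paste0(prefix, ".graphml")
    igraph::write_graph(.gsan_to_igraph(graph), gml_path,
                        format = "graphml")
    written <- c(written, gml_path)
  }
  invisible(written)
}

#' Convert a GSAN to an igraph object
#' @param graph A `gsan`.
#' @return An undirected `igraph` graph with node/edge attributes.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "gsan"))
  .gsan_to_igraph(graph)
}

.gsan_to_igraph <- function(graph) {
  # igraph wants the vertex id column named 'name'
  nodes <- data.frame(name = graph$nodes$set_id,
                      label = graph$nodes$name,
                      source = graph$nodes$source,
                      organism = graph$nodes$organism,
                      scale = graph$nodes$scale,
                      norm_abs_fc = graph$nodes$norm_abs_fc,
                      stringsAsFactors = FALSE)
  edges <- graph$edges
  igraph::graph_from_data_frame(
    d = if (nrow(edges)) edges else
      data.frame(set_i = character(), set_j = character()),
    directed = FALSE, vertices = nodes)
}

#' Re-read a GSAN from its exported node/edge tables
#'
#' Inverse of the `"tables"` export: reconstructs a `gsan` object equal to
#' the one written (node and edge attributes, parameters).
#'
#' @param prefix The prefix used at export time.
#' @return A `gsan` object.
#' @export
read_gsan_tables <- function(prefix) {
  node_path <- paste0(prefix, "_nodes.tsv")
  edge_path <- paste0(prefix, "_edges.tsv")
  params_path <- paste0(prefix, "_params.json")
  for (f in c(node_path, edge_path)) {
    if (!file.exists(f)) stop("missing exported table: ", f)
  }
  nodes <- utils::read.table(node_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "",
                             colClasses = c(set_id = "character",
                                            name = "character",
                                            source = "character",
                                            norm_abs_fc = "numeric"))
  edges <- utils::read.table(edge_path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, quote = "",
                             comment.char = "",
                             colClasses = c(set_i = "character",
                                            set_j = "character"))
  if (nrow(edges) == 0L) {
    edges <- data.frame(set_i = character(), set_j = character(),
                        overlap = integer(), union_size = integer(),
                        s_l = numeric(), s_r = numeric(),
                        score = numeric(), p_value = numeric(),
                        fdr = numeric(), stringsAsFactors = FALSE)
  }
  params <- if (file.exists(params_path)) {
    jsonlite::read_json(params_path, simplifyVector = TRUE)
  } else list()
  nodes$organism <- as.character(nodes$organism)
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "gsan")
}
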