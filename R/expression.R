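# Differential gene-set expression. Per-gene absolute fold changes
# (ABS_FC) are aggregated over a gene set's measured members with a
# normalised p-norm,
#   NORM_ABS_FC = ((1/n) * sum x_i^p)^(1/p),
# a power mean that interpolates between the arithmetic mean (p = 1) and
# the maximum (p -> Inf). Large p accentuates the most strongly
# differential genes in a set; p = 6 is the default.

#' Norm parameters for differential gene-set expression
#'
#' @param p Norm order, a real `>= 1`. Default 6, which accentuates highly
#'   differential genes while still integrating over the whole set.
#' @return Object of class `norm_params`.
#' @export
norm_params <- function(p = 6) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 1)
  structure(list(p = p), class = "norm_params")
}

.p_of <- function(params) {
  if (inherits(params, "norm_params")) return(params$p)
  stopifnot(is.numeric(params), length(params) == 1L, params >= 1)
  as.numeric(params)
}

#' Read a per-gene expression table
#'
#' Ingests a delimited file (delimiter sniffed from the header: tab or
#' comma) of per-gene fold changes and optional p-values, as produced by an
#' upstream differential-expression analysis. Symbols are normalized;
#' duplicate genes (e.g. multiple probes per gene) are resolved by keeping
#' the row with maximal `|FC|`. Rows with non-numeric or missing fold
#' change are dropped with a warning.
#'
#' @param path Path to the table.
#' @param gene_col,fc_col,p_col Column names; `p_col = NULL` if the table
#'   has no p-value column.
#' @param abs_log2 If `TRUE`, fold changes are interpreted as log2 ratios
#'   and `abs_fc` is `|log2 FC|`; by default fold changes are consumed as
#'   given.
#' @return Data frame of class `expression_table` with columns `gene`,
#'   `fc`, `abs_fc` and (when available) `p_value`, one row per gene.
#' @export
read_expression <- function(path, gene_col = "gene", fc_col = "fc",
                            p_col = "p_value", abs_log2 = FALSE) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  for (col in c(gene_col, fc_col, p_col)) {
    if (!is.null(col) && !col %in% names(tab)) {
      stop("expression table is missing column '", col, "'")
    }
  }
  fc <- suppressWarnings(as.numeric(tab[[fc_col]]))
  bad <- is.na(fc)
  if (any(bad)) {
    warning("dropping ", sum(bad), " row(s) with missing/non-numeric fold ",
            "change (first at data row ", which(bad)[1L], ")")
  }
  p <- if (!is.null(p_col)) suppressWarnings(as.numeric(tab[[p_col]])) else NULL
  expression_table(gene = tab[[gene_col]][!bad], fc = fc[!bad],
                   p_value = if (is.null(p)) NULL else p[!bad],
                   abs_log2 = abs_log2)
}

#' Construct an expression table from vectors
#'
#' @param gene Character vector of gene symbols.
#' @param fc Signed fold changes, same length.
#' @param p_value Optional p-values in `[0, 1]`.
#' @param abs_log2 Interpret `fc` as log2 ratios when computing `abs_fc`.
#' @return Data frame of class `expression_table` (one row per gene;
#'   duplicates keep the row with maximal `|FC|`).
#' @export
expression_table <- function(gene, fc, p_value = NULL, abs_log2 = FALSE) {
  stopifnot(length(gene) == length(fc))
  gene <- toupper(trimws(as.character(gene)))
  keep <- nzchar(gene) & !is.na(fc)
  gene <- gene[keep]
  fc <- as.numeric(fc[keep])
  if (!is.null(p_value)) p_value <- as.numeric(p_value[keep])
  if (length(gene) == 0L) stop("expression table has no usable rows")
  if (abs_log2) {
    if (any(fc <= 0)) {
      stop("abs_log2 = TRUE requires strictly positive fold-change ratios")
    }
    abs_fc <- abs(log2(fc))
  } else {
    abs_fc <- abs(fc)
  }
  # per-gene winner: maximal |FC| (probe-collapsing rule); stable tie-break
  ord <- order(gene, -abs_fc)
  first <- !duplicated(gene[ord])
  idx <- ord[first]
  tab <- data.frame(gene = gene[idx], fc = fc[idx], abs_fc = abs_fc[idx],
                    stringsAsFactors = FALSE)
  if (!is.null(p_value)) tab$p_value <- p_value[idx]
  rownames(tab) <- NULL
  class(tab) <- c("expression_table", class(tab))
  tab
}

#' Differential gene-set expression (NORM_ABS_FC)
#'
#' Normalised p-norm of the absolute fold changes of the gene set's
#' *available* genes — the members present in the expression table. With
#' values `x_1..x_n`, returns `((1/n) * sum x_i^p)^(1/p)`. A set with no
#' measured genes yields `NA` (undefined), never 0: an unmeasured set
#' carries no evidence and must not outrank measured ones. The computation
#' factors out `max(x)` before raising to `p`, so large fold changes at
#' large `p` do not overflow.
#'
#' @param gene_set A `gene_set` (or character vector of symbols).
#' @param expr An `expression_table`.
#' @param params A `norm_params` or bare numeric `p >= 1`.
#' @return Scalar score, or `NA_real_` when no member gene is measured.
#' @examples
#' et <- expression_table(c("A", "B"), c(1, 2))
#' norm_abs_fc(gene_set("S", c("A", "B")), et, norm_params(p = 6))
#' # ((1 + 2^6)/2)^(1/6) = 1.7860...
#' @export
norm_abs_fc <- function(gene_set, expr, params = norm_params()) {
  stopifnot(inherits(expr, "expression_table"))
  p <- .p_of(params)
  g <- if (inherits(gene_set, "gene_set")) gene_set$genes else
    normalize_symbols(gene_set)
  x <- expr$abs_fc[match(g, expr$gene)]
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  m <- max(x)
  if (m == 0) return(0)
  m * mean((x / m)^p)^(1 / p)
}

#' Top differentially expressed genes as a query list
#'
#' Selects the genes with p-value below `p_threshold`, ranked by decreasing
#' absolute fold change (ties broken by symbol), truncated to the top `n`.
#' The classic construction of an expression-derived query gene list.
#'
#' @param expr An `expression_table` with a `p_value` column.
#' @param n Number of genes to keep (default 100).
#' @param p_threshold Significance cut-off (default 0.05).
#' @return A `query_gene_list`; if fewer than `n` genes survive the filter
#'   all survivors are returned with a warning.
#' @export
top_differential_genes <- function(expr, n = 100L, p_threshold = 0.05) {
  stopifnot(inherits(expr, "expression_table"))
  if (!"p_value" %in% names(expr)) {
    stop("expression table has no 'p_value' column; cannot filter")
  }
  sel <- expr[!is.na(expr$p_value) & expr$p_value < p_threshold, ,
              drop = FALSE]
  sel <- sel[order(-sel$abs_fc, sel$gene), , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("no genes pass p < ", p_threshold)
    return(structure(list(symbols = character(),
                          label = "top_differential"),
                     class = "query_gene_list"))
  }
  if (nrow(sel) < n) {
    warning("only ", nrow(sel), " genes pass p < ", p_threshold,
            " (requested top ", n, ")")
  }
  query_gene_list(utils::head(sel$gene, n), label = "top_differential")
}

#' Prioritize gene sets by differential gene-set expression
#'
#' Computes NORM_ABS_FC for every set and ranks descending; sets with no
#' measured gene (undefined score) are placed last. Ties break by set id.
#'
#' @param collection A `gene_set_collection`, or a list of `gene_set`s.
#' @param expr An `expression_table`.
#' @param params A `norm_params` or bare numeric `p`.
#' @return Data frame (set_id, name, scale, source, n_measured,
#'   norm_abs_fc, rank) in rank order.
#' @export
prioritize_sets <- function(collection, expr, params = norm_params()) {
  if (inherits(collection, "gene_set_collection")) {
    sets <- collection$sets
    info <- collection$info
  } else {
    stopifnot(length(collection) >= 1L,
              all(vapply(collection, inherits, logical(1), "gene_set")))
    coll <- gene_set_collection(collection)
    sets <- coll$sets
    info <- coll$info
  }
  p <- .p_of(params)
  scores <- vapply(sets, function(g) norm_abs_fc(g, expr, p), numeric(1))
  n_meas <- vapply(sets, function(g) sum(g %in% expr$gene), integer(1))
  out <- data.frame(set_id = info$set_id, name = info$name,
                    scale = info$scale, source = info$source,
                    n_measured = unname(n_meas),
                    norm_abs_fc = unname(scores),
                    stringsAsFactors = FALSE)
  ord <- order(is.na(out$norm_abs_fc), -ifelse(is.na(out$norm_abs_fc),
                                               -Inf, out$norm_abs_fc),
               out$set_id)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a prioritization table as CSV
#' @param prioritized Output of [prioritize_sets()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_prioritization <- function(prioritized, path) {
  utils::write.csv(prioritized, path, row.names = FALSE)
  invisible(path)
}
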