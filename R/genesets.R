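# Core domain types: gene sets, collections, query gene lists, and their I/O.

#' Normalize gene symbols
#'
#' Trims surrounding whitespace, uppercases, drops empty tokens and removes
#' duplicates preserving first occurrence. All gene symbols entering the
#' package pass through this function so that membership tests are exact
#' string comparisons on official-symbol-style identifiers.
#'
#' @param x Character vector of raw symbols.
#' @return Character vector of unique, uppercase, non-empty symbols.
#' @export
normalize_symbols <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- x[!is.na(x) & nzchar(x)]
  x[!duplicated(x)]
}

#' Construct a gene set
#'
#' A gene set is an identified, source-annotated group of gene symbols at any
#' level of biological organisation (pathway members, disease genes,
#' signature genes, microRNA targets, network modules). Symbols are
#' normalized on construction; the set must retain at least one member.
#'
#' @param set_id Unique opaque identifier.
#' @param genes Character vector of member gene symbols.
#' @param name Free-text label (defaults to `set_id`).
#' @param source Data-source tag, e.g. `"KEGG"`, `"user"`.
#' @param organism Free-text organism label.
#' @return An object of class `gene_set` with fields `set_id`, `name`,
#'   `source`, `organism` and `genes`; `scale(gs)` gives the member count.
#' @export
gene_set <- function(set_id, genes, name = set_id, source = "user",
                     organism = NA_character_) {
  stopifnot(is.character(set_id), length(set_id) == 1L, nzchar(set_id))
  genes <- normalize_symbols(genes)
  if (length(genes) < 1L) {
    stop("gene set '", set_id, "' has no usable gene symbols after normalization")
  }
  structure(
    list(set_id = set_id, name = name, source = source,
         organism = organism, genes = genes),
    class = "gene_set"
  )
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$set_id, " (", x$source, "): ",
      length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Number of genes in a gene set (its scale)
#' @param x A `gene_set`.
#' @return Integer member count.
#' @export
set_scale <- function(x) {
  stopifnot(inherits(x, "gene_set"))
  length(x$genes)
}

#' Construct a gene-set collection
#'
#' A collection is a named group of gene sets together with the derived gene
#' universe (the exact union of all member genes). Set identifiers must be
#' pairwise distinct. Sets whose membership is empty after normalization are
#' dropped with a warning since they cannot take part in any similarity or
#' enrichment computation.
#'
#' @param sets A list of `gene_set` objects, or a named list of character
#'   vectors (names become set ids).
#' @param collection_id Opaque identifier for the collection.
#' @param info Optional data frame with columns `set_id`, `name`, `source`,
#'   `organism` supplying annotation when `sets` is a plain named list.
#' @return Object of class `gene_set_collection` with elements
#'   `collection_id`, `sets` (named list of gene vectors), `info`
#'   (annotation data frame with a `scale` column) and `universe`.
#' @export
gene_set_collection <- function(sets, collection_id = "collection", info = NULL) {
  if (length(sets) == 0L) stop("collection '", collection_id, "' has no gene sets")
  if (all(vapply(sets, inherits, logical(1), "gene_set"))) {
    ids <- vapply(sets, `[[`, character(1), "set_id")
    gene_lists <- lapply(sets, `[[`, "genes")
    names(gene_lists) <- ids
    info <- data.frame(
      set_id   = ids,
      name     = vapply(sets, `[[`, character(1), "name"),
      source   = vapply(sets, `[[`, character(1), "source"),
      organism = vapply(sets, `[[`, character(1), "organism"),
      stringsAsFactors = FALSE
    )
  } else {
    if (is.null(names(sets)) || anyNA(names(sets)) || any(!nzchar(names(sets)))) {
      stop("when 'sets' is a plain list of gene vectors it must be fully named")
    }
    gene_lists <- lapply(sets, normalize_symbols)
    ids <- names(sets)
    if (is.null(info)) {
      info <- data.frame(set_id = ids, name = ids, source = "user",
                         organism = NA_character_, stringsAsFactors = FALSE)
    } else {
      stopifnot(is.data.frame(info), "set_id" %in% names(info))
      info <- info[match(ids, info$set_id), , drop = FALSE]
      if (anyNA(info$set_id)) stop("'info' is missing rows for some set ids")
      for (col in c("name", "source", "organism")) {
        if (!col %in% names(info)) {
          info[[col]] <- if (col == "name") ids else
            if (col == "source") "user" else NA_character_
        }
      }
      info <- info[, c("set_id", "name", "source", "organism"), drop = FALSE]
    }
  }
  if (anyDuplicated(ids)) {
    stop("duplicate set ids in collection: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  empty <- lengths(gene_lists) == 0L
  if (any(empty)) {
    warning(sum(empty), " gene set(s) empty after normalization dropped: ",
            paste(utils::head(ids[empty], 5L), collapse = ", "))
    gene_lists <- gene_lists[!empty]
    info <- info[!empty, , drop = FALSE]
    if (length(gene_lists) == 0L) {
      stop("collection '", collection_id, "' has no usable gene sets")
    }
  }
  info$scale <- lengths(gene_lists)
  rownames(info) <- NULL
  structure(
    list(collection_id = collection_id,
         sets = gene_lists,
         info = info,
         universe = sort(unique(unlist(gene_lists, use.names = FALSE)))),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("<gene_set_collection> ", x$collection_id, ": ",
      length(x$sets), " sets, universe of ", length(x$universe),
      " genes\n", sep = "")
  cat("  scales: min ", min(x$info$scale), ", median ",
      stats::median(x$info$scale), ", max ", max(x$info$scale), "\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Extract one gene set from a collection
#' @param collection A `gene_set_collection`.
#' @param set_id Identifier of the set to extract.
#' @return A `gene_set` object.
#' @export
get_set <- function(collection, set_id) {
  stopifnot(inherits(collection, "gene_set_collection"))
  i <- match(set_id, collection$info$set_id)
  if (is.na(i)) stop("no gene set with id '", set_id, "' in collection")
  gene_set(set_id = collection$info$set_id[i],
           genes = collection$sets[[i]],
           name = collection$info$name[i],
           source = collection$info$source[i],
           organism = collection$info$organism[i])
}

#' Subset a collection to selected gene sets
#'
#' @param collection A `gene_set_collection`.
#' @param set_ids Ids of the sets to keep.
#' @return A `gene_set_collection` containing the selected sets (universe
#'   recomputed).
#' @export
subset_collection <- function(collection, set_ids) {
  stopifnot(inherits(collection, "gene_set_collection"))
  idx <- match(set_ids, collection$info$set_id)
  if (anyNA(idx)) {
    stop("set id(s) not in collection: ",
         paste(set_ids[is.na(idx)], collapse = ", "))
  }
  gene_set_collection(
    collection$sets[idx],
    collection_id = collection$collection_id,
    info = collection$info[idx, c("set_id", "name", "source", "organism"),
                           drop = FALSE]
  )
}

#' Construct a query gene list
#'
#' @param symbols Character vector of gene symbols; normalized, order of
#'   first occurrence preserved.
#' @param label Free-text label.
#' @return Object of class `query_gene_list`.
#' @export
query_gene_list <- function(symbols, label = "query") {
  symbols <- normalize_symbols(symbols)
  if (length(symbols) == 0L) stop("query gene list '", label, "' is empty")
  structure(list(symbols = symbols, label = label), class = "query_gene_list")
}

#' @export
print.query_gene_list <- function(x, ...) {
  cat("<query_gene_list> ", x$label, ": ", length(x$symbols), " genes\n", sep = "")
  invisible(x)
}

# ---- file I/O ---------------------------------------------------------------

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set carrier format: one set per line with
#' fields id, description, then one or more gene symbols. Gene symbols are
#' normalized (trimmed, uppercased, de-duplicated preserving first
#' occurrence) and empty tokens dropped. Ingestion counts (sets read, genes
#' read, duplicates collapsed) are reported via `message()`.
#'
#' @param path Path to a GMT file.
#' @param source Source tag stored on every set.
#' @param organism Organism label stored on every set.
#' @param collection_id Identifier of the returned collection; defaults to
#'   the file name without extension.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, source = "user", organism = NA_character_,
                     collection_id = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  if (is.null(collection_id)) {
    collection_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("GMT file contains no gene sets: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3L
  if (any(bad)) {
    stop("malformed GMT line ", line_no[which(bad)[1L]], " in ", path,
         ": expected at least 3 tab-separated fields (id, description, genes)")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  descs <- vapply(fields, `[[`, character(1), 2L)
  raw_genes <- lapply(fields, function(f) f[-(1:2)])
  n_raw <- sum(lengths(raw_genes))
  gene_lists <- lapply(raw_genes, normalize_symbols)
  n_kept <- sum(lengths(gene_lists))
  info <- data.frame(set_id = ids, name = descs, source = source,
                     organism = organism, stringsAsFactors = FALSE)
  names(gene_lists) <- ids
  coll <- gene_set_collection(gene_lists, collection_id = collection_id,
                              info = info)
  message("read_gmt: ", length(coll$sets), " sets, ", n_raw,
          " gene tokens read, ", n_raw - n_kept,
          " duplicate/empty tokens collapsed, universe ",
          length(coll$universe), " genes")
  coll
}

#' Write a collection to a GMT file
#'
#' The set name is written as the GMT description field, so a read/write
#' round trip preserves ids, names and memberships (gene order canonical).
#'
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(collection$info$set_id[i], collection$info$name[i],
            collection$sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a tabular gene-set membership file
#'
#' Alternative to GMT carrying per-set source and organism annotation: a
#' delimited file with header columns `set_id`, `name`, `source`,
#' `organism`, `gene` and one row per set membership. The delimiter is
#' sniffed from the header (tab or comma).
#'
#' @param path Path to the membership table.
#' @param collection_id Identifier for the returned collection.
#' @return A `gene_set_collection`.
#' @export
read_membership_table <- function(path, collection_id = NULL) {
  if (!file.exists(path)) stop("membership table not found: ", path)
  if (is.null(collection_id)) {
    collection_id <- sub("\\.[^.]*$", "", basename(path))
  }
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  required <- c("set_id", "gene")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0L) {
    stop("membership table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (col in c("name", "source", "organism")) {
    if (!col %in% names(tab)) {
      tab[[col]] <- if (col == "name") tab$set_id else
        if (col == "source") "user" else NA_character_
    }
  }
  ids <- unique(tab$set_id)
  gene_lists <- split(tab$gene, factor(tab$set_id, levels = ids))
  first <- tab[!duplicated(tab$set_id), , drop = FALSE]
  info <- data.frame(set_id = first$set_id, name = first$name,
                     source = first$source, organism = first$organism,
                     stringsAsFactors = FALSE)
  gene_lists <- lapply(gene_lists, normalize_symbols)
  gene_set_collection(gene_lists, collection_id = collection_id, info = info)
}

#' Read a newline-delimited query gene list
#'
#' One symbol per line; blank lines ignored, whitespace trimmed, symbols
#' uppercased and de-duplicated preserving order of first occurrence.
#'
#' @param path Path to the gene-list file.
#' @param label Label for the query (defaults to the file name).
#' @return A `query_gene_list`.
#' @export
read_gene_list <- function(path, label = NULL) {
  if (!file.exists(path)) stop("gene list file not found: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  symbols <- normalize_symbols(readLines(path, warn = FALSE))
  if (length(symbols) == 0L) {
    stop("gene list file contains no usable symbols: ", path)
  }
  query_gene_list(symbols, label = label)
}

#' Write a query gene list
#' @param query A `query_gene_list`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_list <- function(query, path) {
  stopifnot(inherits(query, "query_gene_list"))
  writeLines(query$symbols, path)
  invisible(path)
}

# ---- symbol mapping ---------------------------------------------------------

#' Apply an alias-to-official-symbol map to a collection
#'
#' Integrating gene sets from heterogeneous sources requires unifying
#' identifiers to official gene symbols. Every gene present in `mapping` is
#' replaced by its mapped symbol; unmapped genes pass through verbatim
#' (sources with incomplete mappings are common and dropping members would
#' silently shrink sets). Duplicates arising from mapping collisions are
#' collapsed and the universe is recomputed. The number of unmapped symbols
#' is reported via `message()`.
#'
#' @param collection A `gene_set_collection`.
#' @param mapping A data frame with columns `alias` and `symbol` (or any
#'   two columns, taken in order), or a named character vector
#'   `c(alias = symbol)`; many aliases may map to one symbol.
#' @return A new `gene_set_collection` with mapped memberships.
#' @export
apply_symbol_map <- function(collection, mapping) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.data.frame(mapping)) {
    if (all(c("alias", "symbol") %in% names(mapping))) {
      map <- stats::setNames(as.character(mapping$symbol),
                             as.character(mapping$alias))
    } else {
      map <- stats::setNames(as.character(mapping[[2L]]),
                             as.character(mapping[[1L]]))
    }
  } else if (is.character(mapping)) {
    map <- mapping
  } else {
    stop("'mapping' must be a data frame or a named character vector")
  }
  names(map) <- toupper(trimws(names(map)))
  map <- toupper(trimws(map))
  if (anyDuplicated(names(map))) map <- map[!duplicated(names(map))]
  n_unmapped <- 0L
  mapped <- lapply(collection$sets, function(genes) {
    hit <- genes %in% names(map)
    n_unmapped <<- n_unmapped + sum(!hit)
    genes[hit] <- unname(map[genes[hit]])
    normalize_symbols(genes)
  })
  message("apply_symbol_map: ", n_unmapped,
          " gene occurrences left unmapped (passed through verbatim)")
  gene_set_collection(mapped, collection_id = collection$collection_id,
                      info = collection$info[, c("set_id", "name", "source",
                                                 "organism")])
}

#' Read a two-column alias map (TSV: alias, symbol)
#' @param path Path to the alias map.
#' @return Data frame with columns `alias`, `symbol`.
#' @export
read_symbol_map <- function(path) {
  if (!file.exists(path)) stop("alias map not found: ", path)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(tab) < 2L) stop("alias map must have two tab-separated columns")
  tab <- tab[, 1:2]
  names(tab) <- c("alias", "symbol")
  tab
}

# ---- collection-level statistics -------------------------------------------

#' Pairwise gene overlap between collections (sources)
#'
#' For a list of collections, builds the symmetric matrix whose diagonal
#' holds each collection's universe size and whose off-diagonal entries
#' count the genes shared between two universes. This is the standard
#' content-overlap summary used to compare integrated data sources.
#'
#' @param collections A list of `gene_set_collection` objects, or a single
#'   collection.
#' @return Symmetric integer matrix with collection ids as dimnames.
#' @export
source_overlap_matrix <- function(collections) {
  if (inherits(collections, "gene_set_collection")) {
    collections <- list(collections)
  }
  stopifnot(length(collections) >= 1L,
            all(vapply(collections, inherits, logical(1),
                       "gene_set_collection")))
  ids <- vapply(collections, `[[`, character(1), "collection_id")
  if (anyDuplicated(ids)) ids <- make.unique(ids)
  n <- length(collections)
  m <- matrix(0L, n, n, dimnames = list(ids, ids))
  universes <- lapply(collections, `[[`, "universe")
  for (i in seq_len(n)) {
    m[i, i] <- length(universes[[i]])
    if (i < n) for (j in seq(i + 1L, n)) {
      ov <- length(intersect(universes[[i]], universes[[j]]))
      m[i, j] <- ov
      m[j, i] <- ov
    }
  }
  m
}

#' Search gene sets by name
#'
#' Case-insensitive substring match of `term` against set names across one
#' or more collections; results ordered by decreasing scale (ties broken by
#' set id), the ordering used when browsing disease-term matches.
#'
#' @param term Non-empty search term.
#' @param collections A `gene_set_collection` or list of them.
#' @param sources Optional character vector restricting the search to sets
#'   whose source tag is listed.
#' @return Data frame (set_id, name, source, organism, scale,
#'   collection_id), possibly with zero rows.
#' @export
name_search <- function(term, collections, sources = NULL) {
  stopifnot(is.character(term), length(term) == 1L)
  if (!nzchar(trimws(term))) stop("search term must be non-empty")
  if (inherits(collections, "gene_set_collection")) {
    collections <- list(collections)
  }
  hits <- lapply(collections, function(coll) {
    info <- coll$info
    sel <- grepl(tolower(term), tolower(info$name), fixed = TRUE)
    if (!is.null(sources)) sel <- sel & info$source %in% sources
    out <- info[sel, , drop = FALSE]
    if (nrow(out) > 0L) out$collection_id <- coll$collection_id
    out
  })
  hits <- hits[vapply(hits, nrow, integer(1)) > 0L]
  if (length(hits) == 0L) {
    return(data.frame(set_id = character(), name = character(),
                      source = character(), organism = character(),
                      scale = integer(), collection_id = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(-out$scale, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
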