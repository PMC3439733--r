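# Seeded synthetic data: gene-set collections with controlled overlap
# structure and expression tables with planted differential signal. The
# generator makes every analysis in the package testable end-to-end with
# known ground truth: which set carries signal, how sets overlap, what the
# scale law is.

#' Specification for synthetic gene-set data
#'
#' Bundles every parameter of the generator so that one spec object fully
#' determines the output: identical specs give identical collections,
#' expression tables and queries.
#'
#' Scales are drawn from a truncated discrete power law
#' `P(scale = s) proportional to s^(-scale_exponent)` on
#' `[min_scale, max_scale]`, mimicking the heavy-tailed scale frequencies
#' of curated collections. Background absolute fold changes are log-normal
#' with median `exp(fc_meanlog)`; the default `fc_meanlog = log(1.2)`,
#' `fc_sdlog = 0.31` puts roughly 5% of background genes above `|FC| = 2`,
#' a typical microarray regime. Genes of `target_sets` have `|FC|`
#' multiplied by `effect_size` and p-values drawn below 0.05.
#'
#' @param seed Integer seed; all randomness flows from it.
#' @param universe_size Number of synthetic genes (`G000001`, ...).
#' @param n_sets Number of gene sets.
#' @param min_scale,max_scale Scale bounds; `max_scale` must not exceed
#'   `universe_size`.
#' @param scale_exponent Power-law exponent of the scale distribution.
#' @param overlap_model `"independent"` (uniform membership sampling),
#'   `"nested"` (each set a strict superset of the previous) or `"block"`
#'   (sets within a block share a core of genes).
#' @param n_blocks Number of blocks for the block model.
#' @param core_fraction Fraction of a set drawn from its block core.
#' @param target_sets Set ids carrying planted differential signal.
#' @param effect_size Multiplier applied to target-gene `|FC|` (1 = null).
#' @param fc_meanlog,fc_sdlog Log-normal parameters of background `|FC|`.
#' @return Object of class `synth_spec`.
#' @export
synth_spec <- function(seed, universe_size = 1000L, n_sets = 200L,
                       min_scale = 5L, max_scale = 200L,
                       scale_exponent = 2,
                       overlap_model = c("independent", "nested", "block"),
                       n_blocks = 5L, core_fraction = 0.5,
                       target_sets = character(), effect_size = 1,
                       fc_meanlog = log(1.2), fc_sdlog = 0.31) {
  overlap_model <- match.arg(overlap_model)
  stopifnot(is.numeric(seed), length(seed) == 1L,
            universe_size >= 1, n_sets >= 1,
            min_scale >= 1, max_scale >= min_scale,
            scale_exponent >= 0, n_blocks >= 1,
            core_fraction >= 0, core_fraction <= 1,
            effect_size > 0, fc_sdlog > 0)
  if (max_scale > universe_size) {
    stop("max_scale (", max_scale, ") exceeds universe_size (",
         universe_size, ")")
  }
  structure(
    list(seed = as.integer(seed), universe_size = as.integer(universe_size),
         n_sets = as.integer(n_sets), min_scale = as.integer(min_scale),
         max_scale = as.integer(max_scale),
         scale_exponent = scale_exponent, overlap_model = overlap_model,
         n_blocks = as.integer(n_blocks), core_fraction = core_fraction,
         target_sets = as.character(target_sets),
         effect_size = effect_size, fc_meanlog = fc_meanlog,
         fc_sdlog = fc_sdlog),
    class = "synth_spec"
  )
}

.synth_symbols <- function(n) sprintf("G%06d", seq_len(n))
.synth_ids <- function(n) sprintf("SET%04d", seq_len(n))

# Draw n scales from the truncated discrete power law.
.draw_scales <- function(spec) {
  support <- spec$min_scale:spec$max_scale
  w <- support^(-spec$scale_exponent)
  support[sample.int(length(support), spec$n_sets, replace = TRUE,
                     prob = w / sum(w))]
}

#' Generate a synthetic gene-set collection
#'
#' Memberships follow the spec's overlap model: `"independent"` samples
#' each set uniformly from the universe; `"nested"` builds a chain in
#' which every set strictly contains the previous one (so every
#' consecutive pair has cover coefficient 1); `"block"` partitions sets
#' into blocks sharing a core gene pool, giving community structure in the
#' association network.
#'
#' @param spec A `synth_spec`.
#' @return A `gene_set_collection` (source tag `"synthetic"`).
#' @export
generate_collection <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  genes <- .synth_symbols(spec$universe_size)
  ids <- .synth_ids(spec$n_sets)
  scales <- .draw_scales(spec)
  sets <- switch(
    spec$overlap_model,
    independent = lapply(scales, function(s) sample(genes, s)),
    nested = {
      scales <- sort(scales)
      for (k in seq_along(scales)[-1L]) {
        scales[k] <- max(scales[k], scales[k - 1L] + 1L)
      }
      if (scales[length(scales)] > spec$universe_size) {
        stop("nested chain cannot fit: need a universe of at least ",
             scales[length(scales)], " genes")
      }
      out <- vector("list", length(scales))
      out[[1L]] <- sample(genes, scales[1L])
      for (k in seq_along(scales)[-1L]) {
        pool <- setdiff(genes, out[[k - 1L]])
        out[[k]] <- c(out[[k - 1L]],
                      sample(pool, scales[k] - scales[k - 1L]))
      }
      out
    },
    block = {
      block_of <- rep_len(seq_len(spec$n_blocks), spec$n_sets)
      core_size <- min(spec$max_scale, spec$universe_size)
      cores <- lapply(seq_len(spec$n_blocks), function(b) {
        sample(genes, core_size)
      })
      lapply(seq_len(spec$n_sets), function(k) {
        s <- scales[k]
        n_core <- round(spec$core_fraction * s)
        core <- cores[[block_of[k]]]
        # shared prefix of the block core: any two block members overlap
        # in min of their core portions, giving community structure
        inside <- core[seq_len(min(n_core, length(core)))]
        rest <- sample(setdiff(genes, inside), s - length(inside))
        c(inside, rest)
      })
    }
  )
  names(sets) <- ids
  info <- data.frame(set_id = ids, name = ids, source = "synthetic",
                     organism = "synthetic", stringsAsFactors = FALSE)
  gene_set_collection(sets, collection_id = sprintf("synth_seed%d",
                                                    spec$seed),
                      info = info)
}

#' Generate a synthetic expression table with planted signal
#'
#' Every gene of the collection universe receives a signed fold change
#' whose magnitude is log-normal background noise and a uniform p-value.
#' Genes belonging to the spec's `target_sets` have their `|FC|`
#' multiplied by `effect_size` and their p-values drawn uniformly below
#' 0.05, planting a recoverable differential signal; at `effect_size = 1`
#' the target and background `|FC|` distributions coincide in law.
#'
#' @param spec A `synth_spec`.
#' @param collection The `gene_set_collection` generated from `spec` (or
#'   any collection containing the target set ids).
#' @return An `expression_table` covering the whole universe.
#' @export
generate_expression <- function(spec, collection) {
  stopifnot(inherits(spec, "synth_spec"),
            inherits(collection, "gene_set_collection"))
  missing_targets <- setdiff(spec$target_sets, collection$info$set_id)
  if (length(missing_targets) > 0L) {
    stop("target set(s) not in collection: ",
         paste(missing_targets, collapse = ", "))
  }
  set.seed(spec$seed + 1L)
  genes <- collection$universe
  n <- length(genes)
  mag <- stats::rlnorm(n, meanlog = spec$fc_meanlog, sdlog = spec$fc_sdlog)
  sgn <- sample(c(-1, 1), n, replace = TRUE)
  p <- stats::runif(n)
  if (length(spec$target_sets) > 0L) {
    target_genes <- unique(unlist(
      collection$sets[match(spec$target_sets, collection$info$set_id)],
      use.names = FALSE))
    hit <- genes %in% target_genes
    mag[hit] <- mag[hit] * spec$effect_size
    p[hit] <- stats::runif(sum(hit), 0, 0.0499)
  }
  expression_table(gene = genes, fc = sgn * mag, p_value = p)
}

#' Generate a synthetic query gene list
#'
#' Samples `k_inside` genes from the target set (without replacement) and
#' `k_outside` genes from outside it, emulating a partially informative
#' user query for enrichment recovery and null-calibration experiments
#' (`k_inside = 0` gives a pure null query).
#'
#' @param spec A `synth_spec`.
#' @param collection A `gene_set_collection` containing `target`.
#' @param target Set id of the planted target.
#' @param k_inside Number of query genes drawn from the target set.
#' @param k_outside Number of query genes drawn from the rest of the
#'   universe.
#' @return A `query_gene_list`.
#' @export
generate_query <- function(spec, collection, target, k_inside, k_outside) {
  stopifnot(inherits(spec, "synth_spec"),
            inherits(collection, "gene_set_collection"))
  i <- match(target, collection$info$set_id)
  if (is.na(i)) stop("target set '", target, "' not in collection")
  inside_pool <- collection$sets[[i]]
  outside_pool <- setdiff(collection$universe, inside_pool)
  if (k_inside > length(inside_pool)) {
    stop("k_inside (", k_inside, ") exceeds target scale (",
         length(inside_pool), ")")
  }
  if (k_outside > length(outside_pool)) {
    stop("k_outside (", k_outside, ") exceeds genes outside the target (",
         length(outside_pool), ")")
  }
  if (k_inside + k_outside < 1L) stop("query must contain at least 1 gene")
  set.seed(spec$seed + 2L)
  query_gene_list(c(sample(inside_pool, k_inside),
                    sample(outside_pool, k_outside)),
                  label = sprintf("synth_query_%s_%din_%dout", target,
                                  k_inside, k_outside))
}

#' Persist / restore a synthetic-data spec as JSON
#'
#' Fixtures are re-generable from the stored spec instead of being shipped
#' as data files.
#'
#' @param spec A `synth_spec`.
#' @param path JSON path.
#' @return `write_synth_spec` returns `path` invisibly; `read_synth_spec`
#'   returns the restored `synth_spec`.
#' @export
write_synth_spec <- function(spec, path) {
  stopifnot(inherits(spec, "synth_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_synth_spec
#' @export
read_synth_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(synth_spec, x[setdiff(names(x), character())])
}
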