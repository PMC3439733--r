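# Gene-set scale distributions. The scale of a gene set is its number of
# unique gene symbols; collections of curated sets typically show
# power-law-like frequency decay over scale, summarised here by ordinary
# least squares on the log-log frequency plot.

#' Frequency distribution of gene-set scales
#'
#' Counts, for each distinct scale, how many sets in the collection have
#' that scale. No binning is applied: one point per distinct scale.
#'
#' @param collection A `gene_set_collection`.
#' @return Object of class `scale_distribution`: a data frame with columns
#'   `scale` and `frequency` (frequencies sum to the number of sets), with
#'   a `fit` attribute set to `NULL` until [loglog_fit()] is called.
#' @export
scale_distribution <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$sets) == 0L) stop("empty collection")
  tab <- table(collection$info$scale)
  out <- data.frame(scale = as.integer(names(tab)),
                    frequency = as.integer(tab))
  out <- out[order(out$scale), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fit") <- NULL
  class(out) <- c("scale_distribution", class(out))
  out
}

#' Log-log linear regression of a scale distribution
#'
#' Fits ordinary least squares to `(log10 scale, log10 frequency)` across
#' all distinct scales, the usual straight-line summary of a
#' power-law-like distribution: a frequency proportional to
#' `scale^(-gamma)` gives slope `-gamma`. At least 3 distinct scales are
#' required. When all frequencies are equal (zero variance in the
#' response) the slope is 0 but R-squared is undefined; the fit is then
#' flagged `degenerate` and R-squared reported as `NA` rather than a
#' misleading 0 or 1.
#'
#' @param dist A `scale_distribution`.
#' @return The same object with its `fit` attribute populated: a list
#'   `(slope, intercept, r_squared, degenerate, n_points)`. Retrieve it
#'   with `attr(dist, "fit")` or [scale_fit()].
#' @export
loglog_fit <- function(dist) {
  stopifnot(inherits(dist, "scale_distribution"))
  if (nrow(dist) < 3L) {
    stop("log-log fit needs at least 3 distinct scales (got ", nrow(dist),
         ")")
  }
  lx <- log10(dist$scale)
  ly <- log10(dist$frequency)
  if (stats::var(ly) == 0) {
    fit <- list(slope = 0, intercept = ly[1L], r_squared = NA_real_,
                degenerate = TRUE, n_points = nrow(dist))
  } else {
    model <- stats::lm(ly ~ lx)
    fit <- list(slope = unname(stats::coef(model)[2L]),
                intercept = unname(stats::coef(model)[1L]),
                r_squared = summary(model)$r.squared,
                degenerate = FALSE, n_points = nrow(dist))
  }
  attr(dist, "fit") <- fit
  dist
}

#' Retrieve the log-log fit of a scale distribution
#' @param dist A `scale_distribution` (after [loglog_fit()]).
#' @return The fit list, or `NULL` if not yet fitted.
#' @export
scale_fit <- function(dist) attr(dist, "fit")

#' Write a scale distribution (and fit, if present) as TSV
#' @param dist A `scale_distribution`.
#' @param path Output path; the fit is appended as `# key value` comment
#'   lines.
#' @return Invisibly, `path`.
#' @export
write_scale_distribution <- function(dist, path) {
  utils::write.table(as.data.frame(dist), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  fit <- attr(dist, "fit")
  if (!is.null(fit)) {
    con <- file(path, open = "a")
    on.exit(close(con))
    writeLines(sprintf("# %s\t%s", names(fit),
                       vapply(fit, format, character(1))), con)
  }
  invisible(path)
}

#' Plot a scale distribution on log-log axes
#'
#' Scatter of frequency against scale on log10 axes with the fitted trend
#' line (if present) overlaid.
#'
#' @param x A `scale_distribution`.
#' @param ... Passed to `plot()`.
#' @return Invisibly, `x`.
#' @export
plot.scale_distribution <- function(x, ...) {
  plot(x$scale, x$frequency, log = "xy", xlab = "gene-set scale",
       ylab = "number of gene sets", pch = 19, ...)
  fit <- attr(x, "fit")
  if (!is.null(fit) && !isTRUE(fit$degenerate)) {
    xs <- range(x$scale)
    graphics::lines(xs, 10^(fit$intercept + fit$slope * log10(xs)),
                    col = "red", lwd = 2)
  }
  invisible(x)
}
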