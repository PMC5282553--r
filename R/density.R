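# Per-cytosine modification densities: coverage filter, saturation filter,
# and region aggregation.

#' Compute per-cytosine modification densities
#'
#' Density is `meth / total` for cells whose read total is strictly greater
#' than `min_reads` (default 30); all other cells are missing. No density
#' ever exists at a cell with `total <= min_reads`.
#'
#' @param counts A [meth_counts()] object.
#' @param min_reads Coverage threshold; a cell needs `total > min_reads`.
#' @return An object of class `density_matrix`: list with `sites` and a
#'   numeric `density` matrix (sites x samples, values in `[0,1]` or `NA`).
#' @export
compute_density <- function(counts, min_reads = 30) {
  stopifnot(inherits(counts, "meth_counts"))
  d <- counts$meth / counts$total
  d[counts$total <= min_reads] <- NA_real_
  structure(list(sites = counts$sites, density = d),
            class = "density_matrix")
}

#' @export
print.density_matrix <- function(x, ...) {
  cat("density_matrix: ", nrow(x$sites), " sites x ", ncol(x$density),
      " samples; ", sum(is.na(x$density)), " missing cells\n", sep = "")
  invisible(x)
}

#' Remove saturated sites
#'
#' Drops (marks missing across all samples) every site whose mean density
#' over the non-missing samples of the analysis group exceeds `threshold`.
#' Heavily modified sites carry no deviation to analyze, so they are removed
#' before the diet contrasts. The operation is idempotent.
#'
#' @param dm A [compute_density()] result.
#' @param threshold Mean-density cutoff (default 0.90; strictly greater
#'   removes).
#' @param samples Optional character vector restricting the mean to an
#'   analysis group; default all samples.
#' @return A `density_matrix` with saturated sites set to `NA`; the removed
#'   site row indices are in `attr(, "removed_sites")`.
#' @export
saturation_filter <- function(dm, threshold = 0.90, samples = NULL) {
  stopifnot(inherits(dm, "density_matrix"))
  cols <- samples %||% colnames(dm$density)
  sub <- dm$density[, cols, drop = FALSE]
  n <- rowSums(!is.na(sub))
  mu <- rowMeans(sub, na.rm = TRUE)
  drop <- n > 0 & mu > threshold
  dm$density[drop, ] <- NA_real_
  attr(dm, "removed_sites") <- which(drop)
  dm
}

#' Average density over a genomic region
#'
#' Per-sample unweighted mean of the member-site densities, ignoring missing
#' cells; a sample with no member data is missing. The result is invariant to
#' site ordering and to adding fully-missing sites.
#'
#' @param dm A `density_matrix`.
#' @param region Either `c(start, end)` (1-based, inclusive) or a list/vector
#'   with `chrom`, `start`, `end`.
#' @param contexts Contexts to include (`"CpG"`, `"CpH"` or both).
#' @return Named numeric vector of per-sample mean densities (`NA` where no
#'   member site has data).
#' @export
aggregate_region <- function(dm, region, contexts = c("CpG", "CpH")) {
  stopifnot(inherits(dm, "density_matrix"))
  if (is.list(region) || !is.null(names(region))) {
    chrom <- region[["chrom"]]
    start <- as.numeric(region[["start"]]); end <- as.numeric(region[["end"]])
  } else {
    chrom <- NULL
    start <- as.numeric(region[1]); end <- as.numeric(region[2])
  }
  keep <- dm$sites$pos >= start & dm$sites$pos <= end &
    dm$sites$context %in% contexts
  if (!is.null(chrom)) keep <- keep & dm$sites$chrom == chrom
  if (!any(keep))
    stop_invalid("empty region: no member sites in [", start, ", ", end, "]")
  sub <- dm$density[keep, , drop = FALSE]
  out <- colMeans(sub, na.rm = TRUE)
  out[colSums(!is.na(sub)) == 0] <- NA_real_
  out
}
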