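# Orchestration of the gradient-association stage: density computation,
# filters, association, cluster calling, file outputs and a run log that
# records every filter count and the testing-universe size.

#' Run the gradient-association analysis end to end
#'
#' Computes densities with the coverage filter, optionally applies the
#' saturation filter, associates every site with the expression gradient,
#' calls clusters, and (if `outdir` is given) writes the association TSV,
#' cluster BED6 + JSON sidecar, and the run log. Deterministic given the
#' inputs and thresholds.
#'
#' @param counts A [meth_counts()] table.
#' @param annot Sample annotation.
#' @param expr Expression table with `sample`, `rel_mrna`.
#' @param alpha Family-wise level after Bonferroni (default 0.01).
#' @param min_reads Coverage threshold (cells need `total > min_reads`).
#' @param min_cluster_size,max_gap_bp Cluster-calling parameters.
#' @param saturation Apply the >90% saturation filter (default off; the diet
#'   analysis turns it on).
#' @param saturation_threshold Saturation cutoff.
#' @param min_sample_fraction Missing-data threshold per site.
#' @param contexts Site contexts to analyze.
#' @param normality Compute advisory Shapiro-Wilk statistics per site.
#' @param outdir Optional output directory.
#' @param verbose Emit the log lines as messages.
#' @return list with `density`, `association`, `clusters`, `m` and `log`
#'   (character vector of log lines).
#' @export
run_gradient_analysis <- function(counts, annot, expr, alpha = 0.01,
                                  min_reads = 30, min_cluster_size = 3,
                                  max_gap_bp = 500, saturation = FALSE,
                                  saturation_threshold = 0.90,
                                  min_sample_fraction = 0.75,
                                  contexts = c("CpG", "CpH"),
                                  normality = FALSE,
                                  outdir = NULL, verbose = TRUE) {
  log <- character(0)
  note <- function(...) {
    line <- paste0(...)
    if (verbose) message(line)
    log <<- c(log, line)
  }
  note("samples: ", ncol(counts$meth), "; sites: ", nrow(counts$sites),
       " (", sum(counts$sites$context == "CpG"), " CpG)")
  dens <- compute_density(counts, min_reads = min_reads)
  note("coverage filter (> ", min_reads, " reads): ",
       sum(counts$total <= min_reads), " of ", length(counts$total),
       " cells set missing")
  if (saturation) {
    dens <- saturation_filter(dens, threshold = saturation_threshold)
    note("saturation filter (mean > ", saturation_threshold, "): ",
         length(attr(dens, "removed_sites")), " sites removed")
  }
  assoc <- associate_gradient(dens, annot, expr, alpha = alpha,
                              min_sample_fraction = min_sample_fraction,
                              contexts = contexts, normality = normality)
  m <- attr(assoc, "m")
  note("association: ", sum(assoc$tested), " sites tested; ",
       sum(assoc$degenerate), " degenerate; ",
       sum(!assoc$tested & !assoc$degenerate),
       " skipped by the missing-data rule; testing universe m = ", m)
  note("Bonferroni-significant sites (p_adj < ", alpha, "): ",
       sum(assoc$significant))
  clusters <- detect_clusters(assoc, min_size = min_cluster_size,
                              max_gap_bp = max_gap_bp)
  note("clusters called (>= ", min_cluster_size, " sites within ",
       max_gap_bp, " bp): ", nrow(clusters))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    out_cols <- setdiff(names(assoc), character(0))
    utils::write.table(assoc[, out_cols], file.path(outdir, "association.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(clusters) > 0) {
      bed <- data.frame(chrom = clusters$chrom, start = clusters$start,
                        end = clusters$end, name = clusters$label,
                        score = clusters$n_members,
                        strand = ifelse(clusters$direction < 0, "-", "+"))
      write_bed6(bed, file.path(outdir, "clusters.bed"))
    } else {
      writeLines(character(0), file.path(outdir, "clusters.bed"))
    }
    sidecar <- lapply(seq_len(nrow(clusters)), function(i) {
      list(label = clusters$label[i], chrom = clusters$chrom[i],
           start = clusters$start[i], end = clusters$end[i],
           direction = clusters$direction[i],
           members_pos = clusters$members_pos[[i]])
    })
    jsonlite::write_json(sidecar, file.path(outdir, "clusters.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log, file.path(outdir, "run.log"))
  }

  invisible(list(density = dens, association = assoc, clusters = clusters,
                 m = m, log = log))
}
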