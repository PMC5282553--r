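#' Generate a synthetic targeted locus
#'
#' Builds a site map for a padlock-style targeted bisulfite experiment: an
#' ordered set of cytosine positions (CpG and CpH context) over a contiguous
#' span, with `n_clusters` planted CpG clusters. Each planted cluster spans
#' less than 500 bp and carries at least 3 CpG members, so that it satisfies
#' the downstream cluster-calling rule when its members reach significance.
#' Background sites are kept out of the planted windows so a planted cluster
#' is never interrupted by a non-member site.
#'
#' @param n_cpg Total number of CpG sites (including planted cluster members).
#' @param n_cph Total number of CpH sites.
#' @param span_bp Length of the locus in bp; positions are drawn from
#'   `1:span_bp`.
#' @param n_clusters Number of planted clusters.
#' @param seed Integer seed; the same seed reproduces the locus exactly.
#' @param cluster_sizes Integer vector of CpG members per planted cluster
#'   (default 6 each; every entry must be >= 3).
#' @param chrom Chromosome label used for all sites.
#' @param locus_name Free-text name stored on the object.
#'
#' @return An object of class `locus_model`: a list with `sites` (data.frame
#'   `chrom`, `pos` (1-based), `strand`, `context`, sorted by position),
#'   `clusters` (data.frame `cluster_id`, `start`, `end`, `n_members`) and
#'   `members` (list of site row indices per cluster).
#' @export
generate_locus <- function(n_cpg, n_cph, span_bp, n_clusters = 0, seed = 1,
                           cluster_sizes = NULL, chrom = "chr1",
                           locus_name = "synthetic_locus") {
  if (!is.numeric(n_cpg) || !is.numeric(n_cph) || length(n_cpg) != 1 ||
      length(n_cph) != 1 || is.na(n_cpg) || is.na(n_cph) ||
      n_cpg < 0 || n_cph < 0)
    stop_invalid("invalid argument: site counts must be non-negative numbers")
  if (n_cpg + n_cph < 1)
    stop_invalid("invalid argument: locus must contain at least one site")
  if (!is.numeric(span_bp) || length(span_bp) != 1 || span_bp <= 0)
    stop_invalid("invalid argument: span_bp must be positive")
  if (n_clusters < 0)
    stop_invalid("invalid argument: n_clusters must be non-negative")
  if (is.null(cluster_sizes)) cluster_sizes <- rep(6L, n_clusters)
  if (length(cluster_sizes) != n_clusters)
    stop_invalid("invalid argument: cluster_sizes must have one entry per cluster")
  if (n_clusters > 0 && any(cluster_sizes < 3))
    stop_invalid("invalid argument: each planted cluster needs >= 3 CpG members")
  if (n_cpg < sum(cluster_sizes))
    stop_invalid("invalid argument: n_cpg must cover the planted cluster members ",
                 "(need >= ", sum(cluster_sizes), ")")

  set.seed(seed)
  win_width <- 480L  # planted members live in a < 500 bp window
  if (n_clusters > 0) {
    spacing <- span_bp / (n_clusters + 1)
    if (spacing < win_width + 501)
      stop_invalid("invalid argument: span_bp too small to separate ", n_clusters,
                   " clusters by more than the 500 bp chaining gap")
    win_starts <- as.integer(round(seq_len(n_clusters) * spacing))
  } else {
    win_starts <- integer(0)
  }

  pos <- integer(0); context <- character(0); member_of <- integer(0)
  for (k in seq_len(n_clusters)) {
    pk <- sort(sample(seq.int(win_starts[k], win_starts[k] + win_width - 1L),
                      cluster_sizes[k]))
    pos <- c(pos, pk)
    context <- c(context, rep("CpG", cluster_sizes[k]))
    member_of <- c(member_of, rep.int(k, cluster_sizes[k]))
  }

  excl <- unlist(lapply(win_starts,
                        function(s) seq.int(s, s + win_width - 1L)))
  bg_pool <- setdiff(seq_len(span_bp), c(excl, pos))
  n_bg_cpg <- n_cpg - sum(cluster_sizes)
  n_bg <- n_bg_cpg + n_cph
  if (length(bg_pool) < n_bg)
    stop_invalid("invalid argument: span_bp too small for ", n_bg + sum(cluster_sizes),
                 " distinct site positions")
  if (n_bg > 0) {
    bg <- sample(bg_pool, n_bg)
    bg_ctx <- sample(c(rep("CpG", n_bg_cpg), rep("CpH", n_cph)))
    pos <- c(pos, bg)
    context <- c(context, bg_ctx)
    member_of <- c(member_of, rep.int(0L, n_bg))
  }

  ord <- order(pos)
  sites <- data.frame(
    chrom = chrom,
    pos = as.integer(pos[ord]),
    strand = sample(c("+", "-"), length(pos), replace = TRUE),
    context = context[ord],
    stringsAsFactors = FALSE
  )
  member_of <- member_of[ord]
  members <- lapply(seq_len(n_clusters), function(k) which(member_of == k))
  clusters <- data.frame(
    cluster_id = if (n_clusters > 0) paste0("C", seq_len(n_clusters)) else character(0),
    start = vapply(members, function(i) min(sites$pos[i]), integer(1)),
    end = vapply(members, function(i) max(sites$pos[i]), integer(1)),
    n_members = vapply(members, length, integer(1)),
    stringsAsFactors = FALSE
  )

  structure(
    list(locus_name = locus_name, span_bp = as.integer(span_bp),
         sites = sites, clusters = clusters, members = members),
    class = "locus_model"
  )
}

#' Default study locus
#'
#' The locus scale used by the shipped scenarios: 609 CpG and 6,971 CpH sites
#' (7,580 cytosines) over 100 kb, with four planted clusters of 18, 6, 6 and
#' 6 CpGs. Cluster C1 plays the role of the large enhancer-region cluster;
#' C2-C4 play the roles of the smaller diet-responsive clusters.
#'
#' @param seed Integer seed passed to [generate_locus()].
#' @return A `locus_model`.
#' @export
default_locus <- function(seed = 1) {
  generate_locus(n_cpg = 609, n_cph = 6971, span_bp = 100000, n_clusters = 4,
                 seed = seed, cluster_sizes = c(18L, 6L, 6L, 6L),
                 chrom = "chr1", locus_name = "Lct-Mcm6-like")
}

#' @export
print.locus_model <- function(x, ...) {
  cat("locus_model '", x$locus_name, "': ", nrow(x$sites), " sites (",
      sum(x$sites$context == "CpG"), " CpG, ",
      sum(x$sites$context == "CpH"), " CpH) over ", x$span_bp, " bp; ",
      nrow(x$clusters), " planted cluster(s)\n", sep = "")
  invisible(x)
}
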