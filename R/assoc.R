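# Per-cytosine association of modification density with the expression
# gradient: Pearson correlation, signed log p (SLP), Bonferroni control,
# cluster calling and regulatory-track overlap annotation.

#' Pearson correlation of one site's densities with relative mRNA
#'
#' Pairs are dropped where either value is missing. The two-sided p-value
#' comes from the t-transform `t = r * sqrt((n-2) / (1-r^2))` with `n - 2`
#' degrees of freedom. Sites with fewer than 3 complete pairs or zero
#' variance in either vector are degenerate (`r` undefined); sites with
#' exactly 3 pairs report `r` but remain flagged degenerate and are excluded
#' from the testing universe, which requires `n >= 4`.
#'
#' @param density Numeric vector of per-sample densities.
#' @param mrna Numeric vector of per-sample relative mRNA, same length.
#' @return list with `n`, `r`, `r_squared`, `p`, `degenerate`.
#' @export
correlate_site <- function(density, mrna) {
  if (length(density) != length(mrna))
    stop_invalid("invalid argument: density and mrna lengths differ")
  ok <- !is.na(density) & !is.na(mrna)
  x <- density[ok]; y <- mrna[ok]; n <- length(x)
  degen <- list(n = n, r = NA_real_, r_squared = NA_real_, p = NA_real_,
                degenerate = TRUE)
  if (n < 3) return(degen)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(degen)
  r <- stats::cor(x, y)
  p <- .pearson_p(r, n)
  list(n = n, r = r, r_squared = r^2, p = p, degenerate = n < 4)
}

# Two-sided p for a Pearson r at sample size n via the t-transform.
.pearson_p <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & n >= 3
  rr <- pmin(pmax(r[ok], -1), 1)
  exact1 <- abs(rr) >= 1
  tt <- rr * sqrt((n[ok] - 2) / pmax(1 - rr^2, .Machine$double.xmin))
  pv <- 2 * stats::pt(-abs(tt), n[ok] - 2)
  pv[exact1] <- 0
  p[ok] <- pv
  p
}

#' Signed log p-value
#'
#' `sign(r) * min(-log10(p), cap)`: the magnitude reflects evidence strength,
#' the sign the direction of the correlation (or of the group difference).
#' `p = 0` (underflow) is capped at `+/- cap`.
#'
#' @param r Correlation (or any signed effect) giving the sign.
#' @param p Two-sided p-value in `[0, 1]`.
#' @param cap Magnitude cap (default 300).
#' @return Numeric SLP, vectorized over `r` and `p`.
#' @export
slp <- function(r, p, cap = 300) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop_invalid("invalid argument: p must be in [0, 1]")
  mag <- ifelse(p <= 0, cap, pmin(-log10(p), cap))
  sign(r) * mag
}

#' Bonferroni adjustment over a declared testing universe
#'
#' `p_adj = min(1, m * p)`; a test is significant iff `p_adj < alpha`.
#'
#' @param p Vector of nominal p-values.
#' @param m Testing-universe size; must be at least the number of tested
#'   p-values supplied.
#' @param alpha Family-wise significance level (default 0.01).
#' @return data.frame with `p_adj` and logical `significant`.
#' @export
bonferroni_adjust <- function(p, m = length(p), alpha = 0.01) {
  if (m < sum(!is.na(p)))
    stop_invalid("invalid argument: universe m smaller than the number of tests")
  p_adj <- pmin(1, m * p)
  data.frame(p_adj = p_adj, significant = !is.na(p_adj) & p_adj < alpha)
}

#' Associate every cytosine with the expression gradient
#'
#' For each site, computes the Pearson correlation between per-sample
#' modification density and relative mRNA, the t-transform p-value, the
#' Bonferroni-adjusted p over the testing universe, and the SLP. Each sample
#' is paired with its own mouse's relative mRNA when present in `expr`,
#' otherwise with its segment's mean. Sites enter the testing universe only
#' if they have non-missing density in at least `min_sample_fraction` of
#' samples (and at least 4), and are not variance-degenerate; the universe
#' size `m` defaults to the number of such sites.
#'
#' @param dm A [compute_density()] result.
#' @param annot Sample annotation (`sample`, `segment`, ...).
#' @param expr Expression table with `sample` and `rel_mrna`.
#' @param alpha Family-wise level after Bonferroni (default 0.01).
#' @param m Testing-universe size override.
#' @param min_sample_fraction Minimum fraction of samples with data.
#' @param contexts Site contexts to analyze.
#' @param normality If `TRUE`, adds advisory Shapiro-Wilk `shapiro_w` /
#'   `shapiro_p` columns per site (never gates results).
#' @param cap SLP magnitude cap.
#' @return data.frame (class `association_result`) with one row per analyzed
#'   site: site columns, `n`, `r`, `r_squared`, `p`, `p_bonferroni`, `slp`,
#'   `significant`, `tested`, `degenerate`; `attr(, "m")` holds the universe
#'   size.
#' @export
associate_gradient <- function(dm, annot, expr, alpha = 0.01, m = NULL,
                               min_sample_fraction = 0.75,
                               contexts = c("CpG", "CpH"),
                               normality = FALSE, cap = 300) {
  stopifnot(inherits(dm, "density_matrix"))
  samples <- colnames(dm$density)
  mr <- expr$rel_mrna[match(samples, expr$sample)]
  if (anyNA(mr)) {
    seg <- annot$segment[match(samples, annot$sample)]
    seg_mean <- tapply(expr$rel_mrna, annot$segment[match(expr$sample, annot$sample)],
                       mean, na.rm = TRUE)
    mr[is.na(mr)] <- seg_mean[as.character(seg[is.na(mr)])]
  }
  if (anyNA(mr))
    stop_invalid("invalid input: no mRNA value resolvable for sample(s) ",
                 paste(samples[is.na(mr)][1], collapse = ", "))

  keep <- dm$sites$context %in% contexts
  sites <- dm$sites[keep, , drop = FALSE]
  D <- dm$density[keep, , drop = FALSE]
  N <- length(samples)
  nvec <- rowSums(!is.na(D))

  suppressWarnings(
    r <- as.vector(stats::cor(t(D), mr, use = "pairwise.complete.obs"))
  )
  degenerate <- is.na(r) | nvec < 4
  p <- .pearson_p(r, nvec)
  tested <- !degenerate & nvec >= ceiling(min_sample_fraction * N)
  p[!tested] <- NA_real_

  m_use <- m %||% sum(tested)
  adj <- bonferroni_adjust(p, m = max(m_use, sum(tested)), alpha = alpha)

  res <- cbind(
    sites,
    data.frame(
      n = nvec, r = r, r_squared = r^2, p = p,
      p_bonferroni = adj$p_adj,
      slp = ifelse(is.na(p), NA_real_, slp(r, p, cap = cap)),
      significant = adj$significant,
      tested = tested, degenerate = degenerate
    )
  )
  if (normality) {
    sw <- t(vapply(seq_len(nrow(D)), function(i) {
      x <- D[i, ][!is.na(D[i, ])]
      if (length(x) >= 3 && length(x) <= 5000 && stats::sd(x) > 0) {
        s <- stats::shapiro.test(x); c(s$statistic, s$p.value)
      } else c(NA_real_, NA_real_)
    }, numeric(2)))
    res$shapiro_w <- sw[, 1]; res$shapiro_p <- sw[, 2]
  }
  attr(res, "m") <- max(m_use, sum(tested))
  class(res) <- c("association_result", "data.frame")
  res
}

#' Call clusters of significantly associated cytosines
#'
#' Scans sites in genomic order and chains consecutive significant sites
#' whose positions differ by at most `max_gap_bp`; a non-significant tested
#' site between two significant ones breaks the chain, as does a change in
#' the sign of the correlation. Chains with at least `min_size` members
#' become cluster calls. With `rule = "span"` the total cluster span is also
#' capped at `max_gap_bp` (the alternative reading of "within 500 bp").
#'
#' @param assoc An [associate_gradient()] result (or any data.frame with
#'   `chrom`, `pos`, `r`, `significant`).
#' @param min_size Minimum members per cluster (default 3).
#' @param max_gap_bp Maximum gap between consecutive members (default 500).
#' @param rule `"chain"` (default) or `"span"`.
#' @return data.frame with one row per cluster: `label`, `chrom`, `start`,
#'   `end`, `n_members`, `direction` (+1/-1), and list-columns `members_pos`
#'   and `members_idx` (row indices into the position-sorted `assoc`).
#' @export
detect_clusters <- function(assoc, min_size = 3, max_gap_bp = 500,
                            rule = c("chain", "span")) {
  rule <- match.arg(rule)
  a <- assoc[order(assoc$chrom, assoc$pos), , drop = FALSE]
  sig <- a$significant & !is.na(a$r)
  out <- list()

  for (ch in unique(a$chrom)) {
    idx <- which(a$chrom == ch)
    cur <- integer(0); cur_sign <- 0
    flush <- function() {
      if (length(cur) >= min_size) {
        out[[length(out) + 1L]] <<- data.frame(
          chrom = ch,
          start = min(a$pos[cur]), end = max(a$pos[cur]),
          n_members = length(cur), direction = cur_sign,
          members_pos = I(list(a$pos[cur])), members_idx = I(list(cur)),
          stringsAsFactors = FALSE
        )
      }
    }
    for (i in idx) {
      if (!sig[i]) { flush(); cur <- integer(0); next }
      s <- sign(a$r[i])
      if (length(cur) == 0) {
        cur <- i; cur_sign <- s
      } else {
        gap <- a$pos[i] - a$pos[cur[length(cur)]]
        brk <- gap > max_gap_bp || s != cur_sign ||
          (rule == "span" && a$pos[i] - a$pos[cur[1]] > max_gap_bp)
        if (brk) { flush(); cur <- i; cur_sign <- s } else cur <- c(cur, i)
      }
    }
    flush()
  }

  if (!length(out)) {
    return(data.frame(label = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_members = integer(0), direction = numeric(0)))
  }
  res <- do.call(rbind, out)
  res <- cbind(label = sprintf("CL%02d", seq_len(nrow(res))), res,
               stringsAsFactors = FALSE)
  res
}

#' One-way ANOVA of region density across segments
#'
#' @param values Numeric per-sample region means (e.g. from
#'   [aggregate_region()]).
#' @param groups Group labels (segments), same length.
#' @return list with `F`, `p`, `df` (c(between, within)) and the fitted `aov`.
#' @export
region_anova <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  g <- factor(groups[ok]); v <- values[ok]
  tab <- table(g)
  if (nlevels(g) < 2 || any(tab < 2))
    stop_invalid("invalid design: need >= 2 groups with >= 2 samples each")
  fit <- stats::aov(v ~ g)
  s <- summary(fit)[[1]]
  list(F = s$`F value`[1], p = s$`Pr(>F)`[1], df = s$Df, fit = fit)
}

#' Tukey HSD pairwise comparisons for a one-way layout
#'
#' @inheritParams region_anova
#' @param reference Optional group label; keep only comparisons involving it.
#' @return data.frame `comparison`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, groups, reference = NULL) {
  ok <- !is.na(values) & !is.na(groups)
  g <- factor(groups[ok]); v <- values[ok]
  tab <- table(g)
  if (nlevels(g) < 2 || any(tab < 2))
    stop_invalid("invalid design: need >= 2 groups with >= 2 samples each")
  th <- stats::TukeyHSD(stats::aov(v ~ g))$g
  res <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                    lwr = th[, "lwr"], upr = th[, "upr"],
                    p_adj = th[, "p adj"], row.names = NULL,
                    stringsAsFactors = FALSE)
  if (!is.null(reference)) {
    parts <- strsplit(res$comparison, "-", fixed = TRUE)
    hit <- vapply(parts, function(pp) as.character(reference) %in% pp, logical(1))
    res <- res[hit, , drop = FALSE]
  }
  res
}

#' Read a BED track (0-based, half-open)
#'
#' Minimal strict reader: `track`/`browser`/comment lines are skipped; every
#' other line needs at least chrom, start, end with `0 <= start < end`.
#' A malformed line raises a parse error naming the line number.
#'
#' @param path Path to a BED file.
#' @return data.frame `chrom`, `start`, `end`, `name`, `score`, `strand`.
#' @export
read_bed_track <- function(path) {
  if (!file.exists(path))
    stop_invalid("file not found: ", path)
  lines <- readLines(path)
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || grepl("^(#|track|browser)", ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop_invalid("BED parse error at line ", i, ": expected >= 3 fields")
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || start >= end)
      stop_invalid("BED parse error at line ", i,
                   ": need integer 0 <= start < end")
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = f[1], start = start, end = end,
      name = if (length(f) >= 4) f[4] else ".",
      score = if (length(f) >= 5) suppressWarnings(as.numeric(f[5])) else 0,
      strand = if (length(f) >= 6) f[6] else ".",
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), name = character(0),
                      score = numeric(0), strand = character(0)))
  do.call(rbind, rows)
}

#' Annotate clusters with regulatory-track overlap
#'
#' A cluster overlaps a track iff any member position (converted to the
#' track's 0-based, half-open frame) falls inside any interval. Overlap is
#' computed with `GenomicRanges::findOverlaps` on single-base ranges.
#'
#' @param clusters A [detect_clusters()] result (needs `chrom` and
#'   `members_pos`).
#' @param tracks Named list of BED data.frames from [read_bed_track()].
#' @return Logical matrix, clusters x tracks.
#' @export
annotate_overlap <- function(clusters, tracks) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks))))
    stop_invalid("invalid argument: tracks must be a named list")
  n <- nrow(clusters)
  out <- matrix(FALSE, nrow = n, ncol = length(tracks),
                dimnames = list(clusters$label, names(tracks)))
  if (n == 0) return(out)
  pts <- GenomicRanges::GRanges(
    rep(clusters$chrom, lengths(clusters$members_pos)),
    IRanges::IRanges(start = unlist(clusters$members_pos), width = 1)
  )
  cluster_of <- rep(seq_len(n), lengths(clusters$members_pos))
  for (j in seq_along(tracks)) {
    tr <- tracks[[j]]
    if (nrow(tr) == 0) next
    gr <- GenomicRanges::GRanges(tr$chrom,
                                 IRanges::IRanges(start = tr$start + 1L,
                                                  end = tr$end))
    hits <- GenomicRanges::findOverlaps(pts, gr)
    out[unique(cluster_of[S4Vectors::queryHits(hits)]), j] <- TRUE
  }
  out
}
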