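# Independent oracle implementations used to cross-check the package's
# algorithms. Each is deliberately coded differently from the production
# path (vectorized cumsum partition vs state machine; per-point lm() vs
# closed-form weighted sums; all-pairs scan vs interval trees).

# Cluster-calling oracle: partition the significant sites with an explicit
# break vector, then enumerate groups.
oracle_clusters <- function(pos, sig, r, min_size = 3, max_gap = 500) {
  idx <- which(sig & !is.na(r))
  if (length(idx) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_members = integer(0), direction = numeric(0)))
  }
  brk <- logical(length(idx))
  if (length(idx) > 1) {
    for (k in 2:length(idx)) {
      i1 <- idx[k - 1]; i2 <- idx[k]
      between <- if (i2 - i1 > 1) seq(i1 + 1, i2 - 1) else integer(0)
      brk[k] <- (pos[i2] - pos[i1] > max_gap) ||
        (sign(r[i2]) != sign(r[i1])) ||
        (length(between) > 0 && any(!sig[between]))
    }
  }
  grp <- cumsum(brk)
  out <- lapply(split(idx, grp), function(members) {
    if (length(members) < min_size) return(NULL)
    data.frame(start = min(pos[members]), end = max(pos[members]),
               n_members = length(members),
               direction = sign(r[members[1]]))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      n_members = integer(0), direction = numeric(0)))
  }
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}

# Textbook LOESS oracle: per-point tricube-weighted lm().
oracle_loess <- function(x, y, span = 0.3, degree = 1) {
  n <- length(x)
  q <- min(max(ceiling(span * n), degree + 2), n)
  vapply(seq_len(n), function(i) {
    d <- abs(x - x[i])
    h <- sort(d)[q]
    if (h == 0) return(mean(y[d == 0]))
    w <- pmax(1 - (d / h)^3, 0)^3
    if (sum(w > 0) < degree + 1) w <- as.numeric(d / h <= 1)
    df <- data.frame(xx = x - x[i], yy = y)
    if (degree == 0 || length(unique(df$xx[w > 0])) < 2)
      return(sum(w * y) / sum(w))
    fit <- stats::lm(yy ~ poly(xx, degree = degree, raw = TRUE),
                     data = df[w > 0, ], weights = w[w > 0])
    unname(stats::predict(fit, newdata = data.frame(xx = 0)))
  }, numeric(1))
}

# Overlap oracle: brute-force all-pairs scan of member positions against
# 0-based half-open intervals.
oracle_overlap <- function(clusters, tracks) {
  out <- matrix(FALSE, nrow = nrow(clusters), ncol = length(tracks),
                dimnames = list(clusters$label, names(tracks)))
  for (i in seq_len(nrow(clusters))) {
    for (j in seq_along(tracks)) {
      tr <- tracks[[j]]
      hit <- FALSE
      for (p in clusters$members_pos[[i]]) {
        p0 <- p - 1L
        for (k in seq_len(nrow(tr))) {
          if (tr$chrom[k] == clusters$chrom[i] &&
              p0 >= tr$start[k] && p0 < tr$end[k]) { hit <- TRUE; break }
        }
        if (hit) break
      }
      out[i, j] <- hit
    }
  }
  out
}

# A small locus + scenario for fast tests: 30 CpG / 40 CpH over 10 kb with
# one planted 6-CpG cluster.
tiny_locus <- function(seed = 1) {
  generate_locus(n_cpg = 30, n_cph = 40, span_bp = 10000, n_clusters = 1,
                 seed = seed, cluster_sizes = 6L)
}

tiny_grad_scenario <- function(...) {
  gradient_scenario(
    segment_mrna_means = c(0.55, 0.80, 1.00, 0.95, 0.85, 0.60, 0.35, 0.20, 0.10),
    d_min = 0.347, d_max = 0.771, gradient_clusters = "C1",
    n_mice_per_segment = 3, name = "tiny", ...
  )
}
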