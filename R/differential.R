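# Group contrasts of per-cytosine densities: age and diet contrasts on
# matched segments, between-segment scans within a group, LOESS-smoothed
# positional delta profiles, and factorial region ANOVA.

# Row-wise two-proportion z-test on read counts pooled within each group,
# restricted to the cells that survived the coverage filter (non-NA in the
# density matrix). The alternative to the Welch route for users who prefer
# read-level inference; note it treats reads, not mice, as replicates.
.row_proportion <- function(methA, totA, methB, totB) {
  MA <- rowSums(methA, na.rm = TRUE); TA <- rowSums(totA, na.rm = TRUE)
  MB <- rowSums(methB, na.rm = TRUE); TB <- rowSums(totB, na.rm = TRUE)
  pA <- MA / TA; pB <- MB / TB
  pp <- (MA + MB) / (TA + TB)
  se <- sqrt(pp * (1 - pp) * (1 / TA + 1 / TB))
  z <- (pA - pB) / se
  p <- 2 * stats::pnorm(-abs(z))
  zv <- !is.na(se) & se == 0
  p[zv] <- ifelse(pA[zv] == pB[zv], 1, 0)
  z[zv] <- ifelse(pA[zv] == pB[zv], 0, sign(pA[zv] - pB[zv]) * Inf)
  list(delta = pA - pB, t = z, df = rep(Inf, length(z)), p = p,
       mean_a = pA, mean_b = pB)
}

# Row-wise Welch t-test between two site-by-sample matrices.
# Zero-variance special cases: equal means give p = 1, unequal means p = 0.
.row_welch <- function(A, B) {
  nA <- rowSums(!is.na(A)); nB <- rowSums(!is.na(B))
  mA <- rowMeans(A, na.rm = TRUE); mB <- rowMeans(B, na.rm = TRUE)
  vA <- row_vars_na(A); vB <- row_vars_na(B)
  seA <- vA / nA; seB <- vB / nB
  se2 <- seA + seB
  delta <- mA - mB
  t <- delta / sqrt(se2)
  df <- se2^2 / (seA^2 / pmax(nA - 1, 1) + seB^2 / pmax(nB - 1, 1))
  p <- 2 * stats::pt(-abs(t), df)
  zv <- !is.na(se2) & se2 == 0
  p[zv] <- ifelse(delta[zv] == 0, 1, 0)
  t[zv] <- ifelse(delta[zv] == 0, 0, sign(delta[zv]) * Inf)
  df[zv] <- nA[zv] + nB[zv] - 2
  list(n_a = nA, n_b = nB, mean_a = mA, mean_b = mB,
       delta = delta, t = t, df = df, p = p)
}

#' Per-cytosine group contrast on matched segments
#'
#' For each segment, compares per-mouse densities between two groups with a
#' two-sided Welch t-test per site: `delta = mean(group A) - mean(group B)`
#' in density-fraction units. P-values are Bonferroni-corrected over all
#' tests performed (tested sites x segments). A LOESS curve of delta against
#' position is fitted per segment. The contrast is antisymmetric:
#' swapping the groups negates deltas and leaves p-values unchanged.
#'
#' @param dm A [compute_density()] result.
#' @param annot Sample annotation with `sample`, `mouse`, `segment` and the
#'   grouping column.
#' @param group_a,group_b Group labels (e.g. `"P60"` vs `"P6"`, or `"lac-"`
#'   vs `"LAC+"`).
#' @param group_var Annotation column holding the group label (`"age"` or
#'   `"diet"`).
#' @param segments Segments to compare (default: all segments present in
#'   both groups). A requested segment absent from either group is an
#'   invalid design.
#' @param alpha Family-wise level after Bonferroni.
#' @param min_sample_fraction Minimum fraction of each group's samples with
#'   non-missing density for a site to be tested.
#' @param contexts Site contexts to test (default CpG only, where the age
#'   and diet effects live).
#' @param span,degree LOESS parameters for the positional delta curve.
#' @param smooth If `FALSE`, skip the LOESS fit.
#' @param test `"welch"` (default; Welch t on per-mouse densities, the mouse
#'   being the unit of replication) or `"proportion"` (two-proportion z on
#'   read counts pooled within each group; requires `counts`).
#' @param counts The [meth_counts()] table backing `dm`; only needed for
#'   `test = "proportion"`.
#' @return Object of class `delta_profile`: list with `results` (one row per
#'   site x segment: site columns, `segment`, `n_a`, `n_b`, `delta`, `t`,
#'   `df`, `p`, `p_bonferroni`, `slp`, `significant`, `tested`), `loess`
#'   (per-segment data.frame `pos`, `delta`, `fitted`), `m`, `span`,
#'   `degree`, `groups`.
#' @export
site_contrast <- function(dm, annot, group_a, group_b, group_var = "age",
                          segments = NULL, alpha = 0.01,
                          min_sample_fraction = 0.75, contexts = "CpG",
                          span = 0.3, degree = 1, smooth = TRUE,
                          test = c("welch", "proportion"), counts = NULL) {
  stopifnot(inherits(dm, "density_matrix"))
  test <- match.arg(test)
  if (test == "proportion" && is.null(counts))
    stop_invalid("invalid argument: test = 'proportion' needs the counts table")
  if (!group_var %in% names(annot))
    stop_invalid("invalid argument: annotation lacks column '", group_var, "'")
  ga <- annot[[group_var]]
  for (g in c(group_a, group_b))
    if (!g %in% ga)
      stop_invalid("invalid design: group '", g, "' absent from annotation")

  segs <- segments %||%
    sort(intersect(annot$segment[ga == group_a], annot$segment[ga == group_b]))
  keep <- dm$sites$context %in% contexts
  sites <- dm$sites[keep, , drop = FALSE]
  D <- dm$density[keep, , drop = FALSE]
  samp <- colnames(D)

  res <- list()
  for (s in segs) {
    sa <- annot$sample[ga == group_a & annot$segment == s]
    sb <- annot$sample[ga == group_b & annot$segment == s]
    for (nm in list(c(group_a, length(sa)), c(group_b, length(sb))))
      if (as.integer(nm[2]) == 0)
        stop_invalid("invalid design: segment ", s, " absent from group '",
                     nm[1], "'")
    ma <- unique(annot$mouse[annot$sample %in% sa])
    mb <- unique(annot$mouse[annot$sample %in% sb])
    if (length(ma) < 2 || length(mb) < 2)
      stop_invalid("invalid design: segment ", s,
                   " has fewer than 2 mice in a group")
    DA <- D[, intersect(sa, samp), drop = FALSE]
    DB <- D[, intersect(sb, samp), drop = FALSE]
    n_a <- rowSums(!is.na(DA)); n_b <- rowSums(!is.na(DB))
    if (test == "welch") {
      w <- .row_welch(DA, DB)
    } else {
      mask <- function(cols) {
        mm <- counts$meth[keep, cols, drop = FALSE]
        tt <- counts$total[keep, cols, drop = FALSE]
        ok <- !is.na(dm$density[keep, cols, drop = FALSE])
        mm[!ok] <- NA_integer_; tt[!ok] <- NA_integer_
        list(m = mm, t = tt)
      }
      a <- mask(intersect(sa, samp)); b <- mask(intersect(sb, samp))
      w <- .row_proportion(a$m, a$t, b$m, b$t)
      w$n_a <- n_a; w$n_b <- n_b
    }
    tested <- n_a >= max(2, ceiling(min_sample_fraction * length(sa))) &
      n_b >= max(2, ceiling(min_sample_fraction * length(sb)))
    res[[as.character(s)]] <- cbind(
      sites,
      data.frame(segment = s, n_a = w$n_a, n_b = w$n_b, delta = w$delta,
                 t = w$t, df = w$df,
                 p = ifelse(tested, w$p, NA_real_), tested = tested)
    )
  }
  all <- do.call(rbind, res)
  rownames(all) <- NULL
  m <- sum(all$tested)
  adj <- bonferroni_adjust(all$p, m = m, alpha = alpha)
  all$p_bonferroni <- adj$p_adj
  all$significant <- adj$significant
  all$slp <- ifelse(is.na(all$p), NA_real_, slp(all$delta, all$p))

  curves <- list()
  if (smooth) {
    for (s in segs) {
      sub <- all[all$segment == s & all$tested & !is.na(all$delta), ]
      sub <- sub[order(sub$pos), ]
      if (nrow(sub) >= degree + 2) {
        curves[[as.character(s)]] <- data.frame(
          pos = sub$pos, delta = sub$delta,
          fitted = loess_smooth(sub$pos, sub$delta, span = span,
                                degree = degree)
        )
      }
    }
  }

  structure(list(results = all, loess = curves, m = m, span = span,
                 degree = degree, groups = c(group_a, group_b)),
            class = "delta_profile")
}

#' Per-cytosine scan between intestinal segments within one group
#'
#' Welch t-test per site between the mice of two segments within a group;
#' the SLP is signed by the direction of the density difference (first minus
#' second segment of the pair). Bonferroni correction runs over sites x
#' pairs. Comparing a segment with itself is an invalid design.
#'
#' @inheritParams site_contrast
#' @param group Group label to scan within.
#' @param segment_pairs List of length-2 vectors, or a 2-column matrix, of
#'   segment pairs.
#' @return data.frame: site columns, `segment_a`, `segment_b`, `pair`,
#'   `delta`, `p`, `p_bonferroni`, `slp`, `significant`, `tested`;
#'   `attr(, "m")` holds the number of tests.
#' @export
between_segment_scan <- function(dm, annot, group, segment_pairs,
                                 group_var = "age", alpha = 0.01,
                                 min_sample_fraction = 0.75,
                                 contexts = "CpG") {
  stopifnot(inherits(dm, "density_matrix"))
  if (is.matrix(segment_pairs))
    segment_pairs <- lapply(seq_len(nrow(segment_pairs)),
                            function(i) segment_pairs[i, ])
  ga <- annot[[group_var]]
  if (!group %in% ga)
    stop_invalid("invalid design: group '", group, "' absent from annotation")
  keep <- dm$sites$context %in% contexts
  sites <- dm$sites[keep, , drop = FALSE]
  D <- dm$density[keep, , drop = FALSE]

  res <- list()
  for (pr in segment_pairs) {
    s1 <- pr[1]; s2 <- pr[2]
    if (s1 == s2)
      stop_invalid("invalid design: self-comparison of segment ", s1)
    sa <- annot$sample[ga == group & annot$segment == s1]
    sb <- annot$sample[ga == group & annot$segment == s2]
    if (length(sa) < 2 || length(sb) < 2)
      stop_invalid("invalid design: fewer than 2 mice in segment ", s1,
                   " or ", s2)
    w <- .row_welch(D[, sa, drop = FALSE], D[, sb, drop = FALSE])
    tested <- w$n_a >= max(2, ceiling(min_sample_fraction * length(sa))) &
      w$n_b >= max(2, ceiling(min_sample_fraction * length(sb)))
    res[[length(res) + 1L]] <- cbind(
      sites,
      data.frame(segment_a = s1, segment_b = s2,
                 pair = paste0("s", s1, "_vs_s", s2),
                 delta = w$delta, p = ifelse(tested, w$p, NA_real_),
                 tested = tested)
    )
  }
  all <- do.call(rbind, res)
  rownames(all) <- NULL
  m <- sum(all$tested)
  adj <- bonferroni_adjust(all$p, m = m, alpha = alpha)
  all$p_bonferroni <- adj$p_adj
  all$significant <- adj$significant
  all$slp <- ifelse(is.na(all$p), NA_real_, slp(all$delta, all$p))
  attr(all, "m") <- m
  all
}

#' LOESS smoothing of positional density deltas
#'
#' Local weighted polynomial regression: for each point, the
#' `ceiling(span * n)` nearest neighbors (by distance along the position
#' axis) receive tricube weights and a degree-`degree` weighted least-squares
#' fit is evaluated at that point. No robustness iterations. Degree-0 and
#' degree-1 polynomials in `x` are reproduced exactly.
#'
#' @param x Numeric positions.
#' @param y Numeric responses, same length.
#' @param span Neighborhood fraction in (0, 1].
#' @param degree Local polynomial degree (0, 1 or 2; default 1).
#' @return Fitted values at each `x`.
#' @export
loess_smooth <- function(x, y, span = 0.3, degree = 1) {
  n <- length(x)
  if (length(y) != n)
    stop_invalid("invalid argument: x and y lengths differ")
  if (!degree %in% 0:2)
    stop_invalid("invalid argument: degree must be 0, 1 or 2")
  if (n < degree + 2)
    stop_invalid("invalid argument: need at least degree + 2 points")
  if (span <= 0 || span > 1)
    stop_invalid("invalid argument: span must be in (0, 1]")
  q <- max(ceiling(span * n), degree + 2)
  q <- min(q, n)

  fitted <- numeric(n)
  for (i in seq_len(n)) {
    d <- abs(x - x[i])
    h <- sort(d, partial = q)[q]
    if (h == 0) {
      w <- as.numeric(d == 0)
    } else {
      u <- d / h
      w <- ifelse(u < 1, (1 - u^3)^3, 0)
      if (sum(w > 0) < degree + 1) w <- as.numeric(u <= 1)  # tie-heavy fallback
    }
    use <- w > 0
    xw <- x[use] - x[i]
    deg_i <- min(degree, length(unique(xw)) - 1)
    if (deg_i == 0) {
      fitted[i] <- sum(w[use] * y[use]) / sum(w[use])
      next
    }
    X <- cbind(1, stats::poly(xw, degree = deg_i, raw = TRUE, simple = TRUE))
    fit <- stats::lm.wfit(X, y[use], w[use])
    b0 <- fit$coefficients[1]
    fitted[i] <- if (is.na(b0)) sum(w[use] * y[use]) / sum(w[use]) else b0
  }
  fitted
}

#' Factorial ANOVA of region density over diet x segment
#'
#' Two-way ANOVA with interaction using Type II sums of squares (robust to
#' the unbalanced 5-7 mice/arm design), plus Tukey HSD for the first factor
#' within each level of the second.
#'
#' @param values Named per-sample region densities (names = sample ids).
#' @param annot Sample annotation.
#' @param factor_a,factor_b Annotation columns for the two factors
#'   (default `diet` and `segment`).
#' @return list with `anova` (data.frame `term`, `F`, `df`, `p`),
#'   `tukey_within` (per level of `factor_b`, Tukey HSD of `factor_a`), and
#'   the fitted `lm`.
#' @export
factorial_region_anova <- function(values, annot, factor_a = "diet",
                                   factor_b = "segment") {
  idx <- match(names(values), annot$sample)
  if (anyNA(idx))
    stop_invalid("invalid input: sample(s) missing from annotation: ",
                 names(values)[is.na(idx)][1])
  d <- data.frame(v = as.numeric(values),
                  a = factor(annot[[factor_a]][idx]),
                  b = factor(annot[[factor_b]][idx]))
  d <- d[!is.na(d$v), ]
  if (nlevels(droplevels(d$a)) < 2 || nlevels(droplevels(d$b)) < 2)
    stop_invalid("invalid design: both factors need >= 2 levels")
  tab <- table(d$a, d$b)
  if (any(tab == 0)) {
    bad <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop_invalid("invalid design: empty cell (", factor_a, "=",
                 rownames(tab)[bad[1]], ", ", factor_b, "=",
                 colnames(tab)[bad[2]], ")")
  }
  fit <- stats::lm(v ~ a * b, data = d)
  an <- car::Anova(fit, type = 2)
  rows <- rownames(an) != "Residuals"
  terms <- data.frame(
    term = sub("^a$", factor_a,
               sub("^b$", factor_b,
                   sub("^a:b$", paste0(factor_a, ":", factor_b),
                       rownames(an)[rows]))),
    F = an$`F value`[rows], df = an$Df[rows], p = an$`Pr(>F)`[rows],
    stringsAsFactors = FALSE
  )
  tk <- list()
  for (lev in levels(d$b)) {
    sub <- d[d$b == lev, ]
    if (all(table(sub$a) >= 2) && nlevels(droplevels(sub$a)) >= 2)
      tk[[lev]] <- tukey_hsd(sub$v, sub$a)
  }
  list(anova = terms, tukey_within = tk, fit = fit)
}
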