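# Relative expression by the delta-delta-Ct method and segment-wise
# repeated-measures ANOVA.

#' Delta-delta-Ct relative quantification
#'
#' Technical replicates are averaged per sample and gene first. Then, per
#' sample, `dCt = mean Ct(target) - mean Ct(control)`;
#' `ddCt = dCt - mean dCt(reference group)`; `fold = 2^-ddCt`.
#' Amplification efficiency is fixed at 2 (no efficiency correction). The
#' reference group's geometric-mean fold is 1 by construction, and shifting
#' every control Ct by a constant leaves folds unchanged.
#'
#' @param ct data.frame with columns `sample`, `gene`, `ct` (and optionally
#'   `replicate`); all Ct values must be positive.
#' @param target Target gene name.
#' @param control Endogenous-control gene name (the Villin-1 role).
#' @param reference_samples Character vector of sample ids forming the
#'   reference (calibrator) group, e.g. the segment-3 samples of the same
#'   age/diet stratum.
#' @return data.frame `sample`, `delta_ct`, `delta_delta_ct`, `fold`.
#' @export
delta_delta_ct <- function(ct, target, control, reference_samples) {
  need <- c("sample", "gene", "ct")
  if (!is.data.frame(ct) || !all(need %in% names(ct)))
    stop_invalid("invalid input: Ct table needs columns ",
                 paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop_invalid("invalid input: Ct values must be positive and finite")
  agg <- stats::aggregate(ct ~ sample + gene, data = ct, FUN = mean)
  tgt <- agg[agg$gene == target, ]
  ctl <- agg[agg$gene == control, ]
  if (nrow(tgt) == 0)
    stop_invalid("invalid input: no rows for target gene '", target, "'")
  miss <- setdiff(tgt$sample, ctl$sample)
  if (length(miss))
    stop_invalid("invalid input: sample(s) missing control-gene rows: ",
                 paste(utils::head(miss, 3), collapse = ", "))
  dct <- tgt$ct - ctl$ct[match(tgt$sample, ctl$sample)]
  in_ref <- tgt$sample %in% reference_samples
  if (!any(in_ref))
    stop_invalid("invalid input: reference group is empty or absent")
  ddct <- dct - mean(dct[in_ref])
  data.frame(sample = tgt$sample, delta_ct = dct, delta_delta_ct = ddct,
             fold = 2^-ddct, stringsAsFactors = FALSE)
}

#' Repeated-measures ANOVA of relative expression across segments
#'
#' One-way RM-ANOVA with mouse as the repeated (blocking) factor: the
#' uncorrected univariate F for the segment effect from
#' `aov(value ~ segment + mouse)`, which for two segments equals the square
#' of the paired t statistic. Tukey HSD compares segment means, optionally
#' filtered to comparisons against a reference segment.
#'
#' Mice contributing a single segment are dropped with a warning; fewer than
#' 3 remaining mice is an invalid design.
#'
#' @param expr data.frame with columns `sample`, `fold` (or `value_col`) and,
#'   if `annot` is NULL, `mouse` and `segment`.
#' @param annot Optional annotation supplying `mouse`/`segment` by `sample`.
#' @param value_col Response column name (default `"fold"`).
#' @param reference_segment Segment for the Tukey comparisons (default 3,
#'   the expression peak); `NULL` keeps all pairs.
#' @param gg Also report a Greenhouse-Geisser sphericity-corrected p
#'   (`p_gg`, with the estimated epsilon as `gg_epsilon`); needs a complete
#'   balanced mouse x segment layout, otherwise both are `NA` with a
#'   warning.
#' @return list with `F`, `p`, `df`, `tukey`, `n_mice` and the fitted
#'   `aov`; plus `p_gg` and `gg_epsilon` when `gg = TRUE`.
#' @export
rm_anova_segments <- function(expr, annot = NULL, value_col = "fold",
                              reference_segment = 3, gg = FALSE) {
  if (!is.null(annot)) {
    idx <- match(expr$sample, annot$sample)
    expr$mouse <- annot$mouse[idx]
    expr$segment <- annot$segment[idx]
  }
  if (!all(c("mouse", "segment", value_col) %in% names(expr)))
    stop_invalid("invalid input: need columns mouse, segment and ", value_col)
  d <- data.frame(v = expr[[value_col]], mouse = as.character(expr$mouse),
                  segment = factor(expr$segment))
  d <- d[!is.na(d$v), ]
  nseg <- tapply(d$segment, d$mouse, function(s) length(unique(s)))
  single <- names(nseg)[nseg < 2]
  if (length(single)) {
    warning("dropping mouse/mice with a single segment: ",
            paste(single, collapse = ", "))
    d <- d[!d$mouse %in% single, ]
  }
  if (length(unique(d$mouse)) < 3)
    stop_invalid("invalid design: fewer than 3 mice with >= 2 segments")
  d$mouse <- factor(d$mouse)
  d$segment <- droplevels(d$segment)
  fit <- stats::aov(v ~ segment + mouse, data = d)
  s <- summary(fit)[[1]]
  i <- trimws(rownames(s)) == "segment"
  th <- stats::TukeyHSD(fit, "segment")$segment
  tukey <- data.frame(comparison = rownames(th), diff = th[, "diff"],
                      lwr = th[, "lwr"], upr = th[, "upr"],
                      p_adj = th[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  if (!is.null(reference_segment)) {
    parts <- strsplit(tukey$comparison, "-", fixed = TRUE)
    hit <- vapply(parts, function(pp) as.character(reference_segment) %in% pp,
                  logical(1))
    tukey <- tukey[hit, , drop = FALSE]
  }
  out <- list(F = s$`F value`[i], p = s$`Pr(>F)`[i],
              df = c(s$Df[i], s$Df[trimws(rownames(s)) == "Residuals"]),
              tukey = tukey, n_mice = length(unique(d$mouse)), fit = fit)
  if (gg) {
    wide <- tapply(d$v, list(d$mouse, d$segment), mean)
    if (anyNA(wide) || ncol(wide) < 2) {
      warning("Greenhouse-Geisser correction needs a complete mouse x ",
              "segment layout; returning NA")
      out$gg_epsilon <- NA_real_; out$p_gg <- NA_real_
    } else {
      S <- stats::cov(wide)
      k <- ncol(S)
      sbar <- mean(S); sdiag <- mean(diag(S)); srow <- rowMeans(S)
      eps <- (k * (sdiag - sbar))^2 /
        ((k - 1) * (sum(S^2) - 2 * k * sum(srow^2) + k^2 * sbar^2))
      eps <- min(1, max(eps, 1 / (k - 1)))
      out$gg_epsilon <- eps
      out$p_gg <- stats::pf(out$F, eps * out$df[1], eps * out$df[2],
                            lower.tail = FALSE)
    }
  }
  out
}
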