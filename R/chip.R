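# ChIP-qPCR enrichment: percent input with dilution adjustment, IgG
# background subtraction, and per-locus segment ANOVA.

#' Percent input from IP and input cycle thresholds
#'
#' The input Ct is first put on the full-input scale by subtracting
#' `log2(1/input_fraction)`; enrichment is then
#' `100 * 2^(adjusted_input_ct - ct_ip)`. Strictly decreasing in `ct_ip` and
#' strictly increasing in `ct_input`.
#'
#' @param ct_ip IP cycle threshold(s).
#' @param ct_input Input-control cycle threshold(s).
#' @param input_fraction Fraction of chromatin used as input, in (0, 1].
#' @return Percent input (%), vectorized.
#' @export
percent_input <- function(ct_ip, ct_input, input_fraction) {
  if (any(input_fraction <= 0) || any(input_fraction > 1))
    stop_invalid("invalid argument: input_fraction must be in (0, 1]")
  100 * 2^((ct_input - log2(1 / input_fraction)) - ct_ip)
}

#' Subtract the IgG background from a percent-input value
#'
#' `max(0, target - igg)`, elementwise; enrichment below the matched IgG
#' background is floored at zero.
#'
#' @param target Target-antibody percent input (%).
#' @param igg Matched IgG percent input (%).
#' @return Net percent input (%).
#' @export
background_normalize <- function(target, igg) {
  pmax(0, target - igg)
}

#' Compute enrichment from a ChIP Ct table
#'
#' Applies [percent_input()] to the IP and IgG reactions of each row and
#' subtracts the IgG background. An infinite IgG Ct (no amplification) gives
#' zero background.
#'
#' @param chip data.frame with columns `locus`, `segment`, `mouse`, `ct_ip`,
#'   `ct_input`, `ct_igg`, `input_fraction` (e.g. from [simulate_chip()]).
#' @return The input with added columns `percent_input`,
#'   `percent_input_igg`, `net_percent_input`.
#' @export
chip_enrichment <- function(chip) {
  need <- c("locus", "segment", "ct_ip", "ct_input", "ct_igg", "input_fraction")
  if (!all(need %in% names(chip)))
    stop_invalid("invalid input: ChIP table needs columns ",
                 paste(need, collapse = ", "))
  chip$percent_input <- percent_input(chip$ct_ip, chip$ct_input,
                                      chip$input_fraction)
  chip$percent_input_igg <- percent_input(chip$ct_igg, chip$ct_input,
                                          chip$input_fraction)
  chip$net_percent_input <- background_normalize(chip$percent_input,
                                                 chip$percent_input_igg)
  chip
}

#' One-way ANOVA of net percent input across segments at one locus
#'
#' @param enrichment A [chip_enrichment()] result.
#' @param locus Locus name to analyze.
#' @return list with `F`, `p`, `df`, `tukey` (all pairwise segment
#'   comparisons) and the per-segment means.
#' @export
segment_anova <- function(enrichment, locus) {
  sub <- enrichment[enrichment$locus == locus, ]
  if (nrow(sub) == 0)
    stop_invalid("invalid input: no rows for locus '", locus, "'")
  an <- region_anova(sub$net_percent_input, sub$segment)
  tk <- tukey_hsd(sub$net_percent_input, sub$segment)
  means <- tapply(sub$net_percent_input, sub$segment, mean)
  list(F = an$F, p = an$p, df = an$df, tukey = tk, segment_means = means)
}
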