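# Simulation scenarios: the study conditions under which the synthetic data
# generator operates. The shipped scenario constants plant the effect sizes
# the analysis is expected to recover (gradient anchors 34.7% / 77.1%,
# age shifts +30/+18/+12 pp, diet decreases 5.2/4.7/3.6/6.4 pp).

apply_link <- function(link, mrna) link$intercept + link$slope * mrna

#' Gradient scenario for the synthetic-data generator
#'
#' Defines the adult steady-state condition: per-segment relative mRNA means
#' and an affine link mapping relative mRNA to planted cluster modification
#' density, anchored so that the segment with the highest mRNA has density
#' `d_min` and the segment with the lowest mRNA has density `d_max`
#' (an inverse density-expression relationship). Alternatively a fixed
#' `cluster_density` can be supplied (uniform cluster density, no link), which
#' is how null and infant states are expressed.
#'
#' @param segment_mrna_means Length-9 vector of relative mRNA means, one per
#'   intestinal segment, all positive (unitless, segment-3 adult mean = 1 in
#'   the shipped scenarios).
#' @param d_min,d_max Cluster density anchors (fractions) for the affine link;
#'   both or neither must be given, with `0 <= d_min < d_max <= 1`.
#' @param cluster_density Fixed cluster density: a single fraction for all
#'   planted clusters, or a named vector keyed by cluster id. Ignored for
#'   clusters listed in `gradient_clusters` when a link is present.
#' @param gradient_clusters Character vector of planted cluster ids whose
#'   density follows the mRNA link (default `"C1"`).
#' @param background_density Density of non-cluster CpG sites (fraction).
#' @param biological_sd SD of the per-site, per-mouse biological density
#'   offset (fraction); also the SD of per-mouse relative mRNA noise.
#' @param coverage_mean Mean per-cell read total (reads).
#' @param n_mice_per_segment Mice per segment.
#' @param saturated_fraction Fraction of non-cluster CpG sites planted at
#'   density 0.95, so the >90% saturation filter has sites to act on.
#' @param cph_density Planted density of CpH sites (near zero).
#' @param name Scenario label.
#' @return An object of class `gradient_scenario`.
#' @export
gradient_scenario <- function(segment_mrna_means,
                              d_min = NULL, d_max = NULL,
                              cluster_density = NULL,
                              gradient_clusters = "C1",
                              background_density = 0.5,
                              biological_sd = 0.02,
                              coverage_mean = 200,
                              n_mice_per_segment = 6,
                              saturated_fraction = 0.05,
                              cph_density = 0.01,
                              name = "custom") {
  if (length(segment_mrna_means) != 9 || any(!is.finite(segment_mrna_means)) ||
      any(segment_mrna_means <= 0))
    stop_invalid("invalid scenario: segment_mrna_means must be 9 positive values")
  if (background_density < 0 || background_density > 1)
    stop_invalid("invalid scenario: background_density must be in [0,1]")
  if (biological_sd < 0)
    stop_invalid("invalid scenario: biological_sd must be non-negative")
  if (n_mice_per_segment < 1)
    stop_invalid("invalid scenario: n_mice_per_segment must be >= 1")

  link <- NULL
  if (!is.null(d_min) || !is.null(d_max)) {
    if (is.null(d_min) || is.null(d_max))
      stop_invalid("invalid scenario: supply both d_min and d_max or neither")
    if (!(d_min >= 0 && d_min < d_max && d_max <= 1))
      stop_invalid("invalid scenario: need 0 <= d_min < d_max <= 1")
    hi <- max(segment_mrna_means); lo <- min(segment_mrna_means)
    if (hi == lo)
      stop_invalid("invalid scenario: mRNA means are constant, link undefined")
    slope <- (d_min - d_max) / (hi - lo)
    link <- list(intercept = d_max - slope * lo, slope = slope,
                 d_min = d_min, d_max = d_max)
  }
  if (!is.null(cluster_density) &&
      (any(cluster_density < 0) || any(cluster_density > 1)))
    stop_invalid("invalid scenario: cluster_density must be in [0,1]")

  structure(
    list(name = name,
         segment_mrna_means = segment_mrna_means,
         link = link,
         cluster_density = cluster_density,
         gradient_clusters = gradient_clusters,
         background_density = background_density,
         biological_sd = biological_sd,
         coverage_mean = coverage_mean,
         n_mice_per_segment = n_mice_per_segment,
         saturated_fraction = saturated_fraction,
         cph_density = cph_density),
    class = c("gradient_scenario", "scenario")
  )
}

#' Aging scenario: an infant base state plus adult density shifts
#'
#' The infant state carries a uniform planted-cluster density (no gradient);
#' the adult state adds `segment_shifts` (fractions) to the target cluster in
#' the named segments.
#'
#' @param base A [gradient_scenario()] with a fixed uniform `cluster_density`
#'   and no mRNA link (the infant state).
#' @param segment_shifts Named numeric vector, names are segment numbers,
#'   values are density shifts (fractions) applied in adults.
#' @param adult_mrna_means Length-9 relative mRNA means for the adult group.
#' @param target_cluster Cluster id receiving the shift (default `"C1"`).
#' @param name Scenario label.
#' @return An object of class `aging_scenario`.
#' @export
aging_scenario <- function(base, segment_shifts,
                           adult_mrna_means = base$segment_mrna_means,
                           target_cluster = "C1", name = "custom-age") {
  if (!inherits(base, "gradient_scenario"))
    stop_invalid("invalid scenario: base must be a gradient_scenario")
  if (!is.null(base$link))
    stop_invalid("invalid scenario: infant base state must have no mRNA-density ",
                 "link (uniform cluster density)")
  if (is.null(base$cluster_density))
    stop_invalid("invalid scenario: infant base state needs a cluster_density")
  if (is.null(names(segment_shifts)) || any(!names(segment_shifts) %in% as.character(1:9)))
    stop_invalid("invalid scenario: segment_shifts must be named by segment 1-9")
  base_d <- unname(base$cluster_density[1])
  shifted <- base_d + segment_shifts
  if (any(shifted < 0 | shifted > 1))
    stop_invalid("invalid scenario: shifted cluster density outside [0,1]")
  structure(
    list(name = name, base = base, segment_shifts = segment_shifts,
         adult_mrna_means = adult_mrna_means, target_cluster = target_cluster),
    class = c("aging_scenario", "scenario")
  )
}

#' Diet scenario: two feeding arms with planted cluster density decreases
#'
#' The lactose-free arm (`lac-`) sits at the base state; the lactose-fed arm
#' (`LAC+`) has its planted cluster density decreased by `cluster_shifts`
#' at specific (cluster, segment) combinations.
#'
#' @param base A [gradient_scenario()] giving the `lac-` state (fixed cluster
#'   densities, no link).
#' @param cluster_shifts data.frame with columns `cluster_id`, `segment`,
#'   `decrease` (fraction removed in the `LAC+` arm).
#' @param n_lacplus,n_lacminus Mice per segment in each arm.
#' @param lacplus_mrna_fold Length-9 multiplicative change of relative mRNA in
#'   the `LAC+` arm (lactose feeding raises distal-segment expression).
#' @param name Scenario label.
#' @return An object of class `diet_scenario`.
#' @export
diet_scenario <- function(base, cluster_shifts, n_lacplus = 6, n_lacminus = 7,
                          lacplus_mrna_fold = rep(1, 9), name = "custom-diet") {
  if (!inherits(base, "gradient_scenario"))
    stop_invalid("invalid scenario: base must be a gradient_scenario")
  need <- c("cluster_id", "segment", "decrease")
  if (!is.data.frame(cluster_shifts) || !all(need %in% names(cluster_shifts)))
    stop_invalid("invalid scenario: cluster_shifts needs columns ",
                 paste(need, collapse = ", "))
  cd <- base$cluster_density
  if (is.null(cd))
    stop_invalid("invalid scenario: diet base state needs fixed cluster densities")
  base_for <- function(id) {
    if (!is.null(names(cd)) && id %in% names(cd)) unname(cd[[id]]) else unname(cd[1])
  }
  shifted <- vapply(seq_len(nrow(cluster_shifts)), function(i) {
    base_for(cluster_shifts$cluster_id[i]) - cluster_shifts$decrease[i]
  }, numeric(1))
  if (any(shifted < 0 | shifted > 1))
    stop_invalid("invalid scenario: shifted cluster density outside [0,1]")
  if (length(lacplus_mrna_fold) != 9 || any(lacplus_mrna_fold <= 0))
    stop_invalid("invalid scenario: lacplus_mrna_fold must be 9 positive values")
  structure(
    list(name = name, base = base, cluster_shifts = cluster_shifts,
         n_lacplus = n_lacplus, n_lacminus = n_lacminus,
         lacplus_mrna_fold = lacplus_mrna_fold),
    class = c("diet_scenario", "scenario")
  )
}

# ---- Shipped scenario constants -------------------------------------------

# Relative mRNA shape shared by the adult scenarios: a peak in the proximal
# jejunum (segment 3) declining toward both the duodenum and the distal ileum.
.adult_mrna_means <- c(0.55, 0.80, 1.00, 0.95, 0.85, 0.60, 0.35, 0.20, 0.10)

#' GRAD-1: adult gradient scenario
#'
#' Planted inverse gradient at cluster C1: cluster density is affine in
#' relative mRNA, anchored at 34.7% in segment 3 (mRNA peak) and 77.1% in
#' segment 9 (mRNA trough). Background CpG density 0.50, biological SD 0.02,
#' coverage mean 200 reads, 6 mice per segment.
#' @return A `gradient_scenario`.
#' @export
scenario_grad1 <- function() {
  gradient_scenario(
    segment_mrna_means = .adult_mrna_means,
    d_min = 0.347, d_max = 0.771,
    gradient_clusters = "C1",
    background_density = 0.50,
    biological_sd = 0.02,
    coverage_mean = 200,
    n_mice_per_segment = 6,
    name = "GRAD-1"
  )
}

#' NULL-1: no density-mRNA link anywhere
#'
#' Identical study design to GRAD-1 but every planted cluster sits at the
#' background density and no site is linked to mRNA; used for type-I-error
#' calibration.
#' @return A `gradient_scenario`.
#' @export
scenario_null1 <- function() {
  gradient_scenario(
    segment_mrna_means = .adult_mrna_means,
    cluster_density = 0.50,
    gradient_clusters = character(0),
    background_density = 0.50,
    biological_sd = 0.02,
    coverage_mean = 200,
    n_mice_per_segment = 6,
    name = "NULL-1"
  )
}

#' AGE-1: infant-to-adult density shifts
#'
#' Infant cluster density 0.45, uniform across segments (no gradient, matching
#' the flat infant expression profile); adult shifts of +0.30 (segment 7),
#' +0.18 (segment 1) and +0.12 (segment 3) at cluster C1. Infant relative mRNA
#' is uniform at 8x the adult segment-3 level.
#' @return An `aging_scenario`.
#' @export
scenario_age1 <- function() {
  infant <- gradient_scenario(
    segment_mrna_means = rep(8, 9),
    cluster_density = 0.45,
    gradient_clusters = character(0),
    background_density = 0.50,
    biological_sd = 0.02,
    coverage_mean = 200,
    n_mice_per_segment = 6,
    name = "AGE-1-infant"
  )
  aging_scenario(
    base = infant,
    segment_shifts = c(`7` = 0.30, `1` = 0.18, `3` = 0.12),
    adult_mrna_means = .adult_mrna_means,
    target_cluster = "C1",
    name = "AGE-1"
  )
}

#' DIET-1: lactose-feeding density decreases
#'
#' The `lac-` arm sits at cluster densities C1 = 0.75 (the aged, unresponsive
#' enhancer-region cluster) and C2-C4 = 0.60. The `LAC+` arm decreases
#' C2 (exon-12-like) by 0.052 in segment 7 and 0.047 in segment 8,
#' C3 (intron-8-like) by 0.036 in segment 8, and C4 (intron-2-like) by 0.064
#' in segment 8. 6 `LAC+` and 7 `lac-` mice per segment; `LAC+` relative mRNA
#' is raised 1.5x in segment 7 and 2x in segment 8.
#' @return A `diet_scenario`.
#' @export
scenario_diet1 <- function() {
  base <- gradient_scenario(
    segment_mrna_means = .adult_mrna_means,
    cluster_density = c(C1 = 0.75, C2 = 0.60, C3 = 0.60, C4 = 0.60),
    gradient_clusters = character(0),
    background_density = 0.50,
    biological_sd = 0.02,
    coverage_mean = 200,
    n_mice_per_segment = 7,
    name = "DIET-1-base"
  )
  diet_scenario(
    base = base,
    cluster_shifts = data.frame(
      cluster_id = c("C2", "C2", "C3", "C4"),
      segment = c(7L, 8L, 8L, 8L),
      decrease = c(0.052, 0.047, 0.036, 0.064),
      stringsAsFactors = FALSE
    ),
    n_lacplus = 6, n_lacminus = 7,
    lacplus_mrna_fold = c(1, 1, 1, 1, 1, 1, 1.5, 2, 1),
    name = "DIET-1"
  )
}

#' Simulation configuration
#'
#' Coverage model and seed for [simulate_methylation()]. Per-cell read totals
#' are negative binomial with mean `coverage_mean` and dispersion (size)
#' `coverage_dispersion`; `coverage_dispersion = Inf` fixes every total at
#' `coverage_mean` (the infinite-coverage limiting design). A fraction
#' `low_coverage_fraction` of cells is resampled to totals in 5..30 so the
#' >30-read coverage filter is exercised.
#'
#' @param seed Integer seed.
#' @param coverage_mean Mean reads per site x sample cell.
#' @param coverage_dispersion Negative-binomial size parameter.
#' @param low_coverage_fraction Fraction of cells forced below the coverage
#'   filter.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1, coverage_mean = 200, coverage_dispersion = 5,
                       low_coverage_fraction = 0.05) {
  if (length(seed) != 1 || is.na(seed))
    stop_invalid("invalid argument: seed must be a single integer")
  if (coverage_mean <= 0 || coverage_dispersion <= 0)
    stop_invalid("invalid argument: coverage model parameters must be positive")
  if (low_coverage_fraction < 0 || low_coverage_fraction >= 1)
    stop_invalid("invalid argument: low_coverage_fraction must be in [0,1)")
  structure(list(seed = as.integer(seed), coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 low_coverage_fraction = low_coverage_fraction),
            class = "sim_config")
}
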