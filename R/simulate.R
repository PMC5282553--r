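# Synthetic-data generator: expression tables, methylation count tables and
# ChIP-qPCR Ct tables with the statistical structure the analysis assumes.

#' Simulate a per-mouse expression table
#'
#' Draws per-mouse relative mRNA around the scenario's segment means
#' (additive Normal noise with SD `biological_sd`) and emits paired qPCR Ct
#' values constructed so that the delta-delta-Ct identity recovers the
#' relative level exactly: `ct_control` is constant and
#' `ct_target = 28 - log2(rel_mrna)`.
#'
#' @param scenario A [gradient_scenario()].
#' @param seed Integer seed.
#' @param age_group Age label stored in the annotation (`"P6"`, `"P60"`,
#'   `"P90"`).
#' @param diet Diet label (`"none"`, `"LAC+"`, `"lac-"`).
#' @param n_mice Mice per segment (default from the scenario).
#' @param segment_mrna_means Override of the scenario's segment means.
#' @param mouse_prefix Prefix for mouse ids, so mice from different groups
#'   never share an id.
#' @return data.frame with one row per mouse x segment: `sample`, `mouse`,
#'   `segment`, `age`, `diet`, `sex`, `rel_mrna`, `ct_target`, `ct_control`.
#' @export
simulate_expression <- function(scenario, seed = 1, age_group = "P60",
                                diet = "none", n_mice = NULL,
                                segment_mrna_means = NULL,
                                mouse_prefix = NULL) {
  if (!inherits(scenario, "gradient_scenario"))
    stop_invalid("invalid argument: scenario must be a gradient_scenario")
  set.seed(seed)
  means <- segment_mrna_means %||% scenario$segment_mrna_means
  n <- n_mice %||% scenario$n_mice_per_segment
  prefix <- mouse_prefix %||%
    if (diet == "none") age_group else paste0(age_group, "_", gsub("[+-]", "", diet))

  grid <- expand.grid(mouse = seq_len(n), segment = 1:9)
  rel <- pmax(1e-6, means[grid$segment] +
                stats::rnorm(nrow(grid), 0, scenario$biological_sd))
  mouse_id <- sprintf("%s_M%02d", prefix, grid$mouse)
  data.frame(
    sample = sprintf("%s_S%d", mouse_id, grid$segment),
    mouse = mouse_id,
    segment = grid$segment,
    age = age_group,
    diet = diet,
    sex = ifelse(grid$mouse %% 2 == 1, "F", "M"),
    rel_mrna = rel,
    ct_target = 28 - log2(rel),
    ct_control = 20,
    stringsAsFactors = FALSE
  )
}

#' Long-format qPCR Ct table from an expression table
#'
#' Reshapes the paired T values of [simulate_expression()] into the
#' (sample, gene, replicate, ct) layout consumed by [delta_delta_ct()].
#'
#' @param expr Expression table from [simulate_expression()].
#' @param target,control Gene names to use for the target and the endogenous
#'   control.
#' @return data.frame `sample`, `gene`, `replicate`, `ct`.
#' @export
ct_table_from_expression <- function(expr, target = "Lct", control = "Vil1") {
  data.frame(
    sample = rep(expr$sample, 2),
    gene = rep(c(target, control), each = nrow(expr)),
    replicate = 1L,
    ct = c(expr$ct_target, expr$ct_control),
    stringsAsFactors = FALSE
  )
}

# Scenario-specific planted density matrix (sites x samples), before
# biological noise. Errors if a planted shift pushes a density outside [0,1].
site_base_matrix <- function(locus, scenario, expression) {
  UseMethod("site_base_matrix", scenario)
}

# Shared scaffold: background CpG / saturated CpG / CpH baselines.
.base_scaffold <- function(locus, gs, n_samples) {
  S <- nrow(locus$sites)
  site_base <- rep(gs$background_density, S)
  site_base[locus$sites$context == "CpH"] <- gs$cph_density
  cluster_rows <- unlist(locus$members)
  bg_cpg <- setdiff(which(locus$sites$context == "CpG"), cluster_rows)
  n_sat <- round(gs$saturated_fraction * length(bg_cpg))
  if (n_sat > 0) site_base[sample(bg_cpg, n_sat)] <- 0.95
  matrix(site_base, nrow = S, ncol = n_samples)
}

.cluster_base_density <- function(gs, cluster_id) {
  cd <- gs$cluster_density
  if (is.null(cd)) return(gs$background_density)
  if (!is.null(names(cd)) && cluster_id %in% names(cd)) return(unname(cd[[cluster_id]]))
  unname(cd[1])
}

#' @export
site_base_matrix.gradient_scenario <- function(locus, scenario, expression) {
  base <- .base_scaffold(locus, scenario, nrow(expression))
  for (k in seq_len(nrow(locus$clusters))) {
    id <- locus$clusters$cluster_id[k]
    rows <- locus$members[[k]]
    if (id %in% scenario$gradient_clusters && !is.null(scenario$link)) {
      d <- apply_link(scenario$link, expression$rel_mrna)
      if (any(d < -1e-9 | d > 1 + 1e-9))
        stop_invalid("invalid scenario: linked cluster density outside [0,1]")
      base[rows, ] <- matrix(clamp01(d), nrow = length(rows),
                             ncol = length(d), byrow = TRUE)
    } else {
      base[rows, ] <- .cluster_base_density(scenario, id)
    }
  }
  base
}

#' @export
site_base_matrix.aging_scenario <- function(locus, scenario, expression) {
  gs <- scenario$base
  base <- .base_scaffold(locus, gs, nrow(expression))
  infant_d <- unname(gs$cluster_density[1])
  for (k in seq_len(nrow(locus$clusters))) {
    id <- locus$clusters$cluster_id[k]
    rows <- locus$members[[k]]
    if (id == scenario$target_cluster) {
      shift <- scenario$segment_shifts[as.character(expression$segment)]
      shift[is.na(shift)] <- 0
      is_adult <- expression$age != "P6"
      d <- infant_d + ifelse(is_adult, shift, 0)
      if (any(d < 0 | d > 1))
        stop_invalid("invalid scenario: shifted cluster density outside [0,1]")
      base[rows, ] <- matrix(d, nrow = length(rows), ncol = length(d), byrow = TRUE)
    } else {
      base[rows, ] <- .cluster_base_density(gs, id)
    }
  }
  base
}

#' @export
site_base_matrix.diet_scenario <- function(locus, scenario, expression) {
  gs <- scenario$base
  base <- .base_scaffold(locus, gs, nrow(expression))
  for (k in seq_len(nrow(locus$clusters))) {
    id <- locus$clusters$cluster_id[k]
    rows <- locus$members[[k]]
    d <- rep(.cluster_base_density(gs, id), nrow(expression))
    sh <- scenario$cluster_shifts[scenario$cluster_shifts$cluster_id == id, ,
                                  drop = FALSE]
    for (i in seq_len(nrow(sh))) {
      hit <- expression$diet == "LAC+" & expression$segment == sh$segment[i]
      d[hit] <- d[hit] - sh$decrease[i]
    }
    if (any(d < 0 | d > 1))
      stop_invalid("invalid scenario: shifted cluster density outside [0,1]")
    base[rows, ] <- matrix(d, nrow = length(rows), ncol = length(d), byrow = TRUE)
  }
  base
}

#' Simulate a methylation count table
#'
#' For each site x sample cell, a read total is drawn from the configured
#' negative-binomial coverage model (with a planted fraction of low-coverage
#' cells) and the methylated count is Binomial(total, density), where density
#' is the scenario's planted value for that cell plus a per-site, per-mouse
#' biological offset Normal(0, biological_sd), truncated to `[0,1]`.
#'
#' @param locus A [generate_locus()] result.
#' @param scenario A gradient, aging or diet scenario.
#' @param expression Expression/annotation table covering every sample to
#'   simulate (from [simulate_expression()], possibly row-bound over groups).
#' @param config A [sim_config()].
#' @return An object of class `meth_counts`: list with `sites` (as in the
#'   locus) and integer matrices `meth`, `total` (sites x samples).
#' @export
simulate_methylation <- function(locus, scenario, expression,
                                 config = sim_config()) {
  if (!inherits(locus, "locus_model"))
    stop_invalid("invalid argument: locus must be a locus_model")
  if (!inherits(scenario, "scenario"))
    stop_invalid("invalid argument: scenario must be a scenario object")
  set.seed(config$seed)
  S <- nrow(locus$sites)
  N <- nrow(expression)
  base <- site_base_matrix(locus, scenario, expression)

  bio_sd <- if (inherits(scenario, "gradient_scenario")) scenario$biological_sd
            else scenario$base$biological_sd
  d <- clamp01(base + matrix(stats::rnorm(S * N, 0, bio_sd), S, N))

  if (is.infinite(config$coverage_dispersion)) {
    tot <- rep.int(as.integer(round(config$coverage_mean)), S * N)
  } else {
    tot <- stats::rnbinom(S * N, size = config$coverage_dispersion,
                          mu = config$coverage_mean)
    tot <- pmax(tot, 1L)
  }
  if (config$low_coverage_fraction > 0) {
    low <- stats::runif(S * N) < config$low_coverage_fraction
    tot[low] <- sample(5:30, sum(low), replace = TRUE)
  }
  meth <- stats::rbinom(S * N, tot, as.vector(d))

  meth_counts(
    sites = locus$sites,
    meth = matrix(as.integer(meth), S, N, dimnames = list(NULL, expression$sample)),
    total = matrix(as.integer(tot), S, N, dimnames = list(NULL, expression$sample))
  )
}

#' Simulate a full study for a scenario
#'
#' Convenience wrapper: builds the locus (default [default_locus()]),
#' simulates the expression table(s) for every group the scenario defines,
#' and draws the methylation count table over the combined samples.
#'
#' @param scenario A gradient, aging or diet scenario.
#' @param seed Integer seed driving locus, expression and count sampling.
#' @param locus Optional pre-built `locus_model`.
#' @param config Optional [sim_config()]; defaults to the scenario's coverage
#'   mean with dispersion 5 and 5% low-coverage cells.
#' @return list with `scenario`, `locus`, `expression`, `annotation` (sample,
#'   mouse, segment, age, diet, sex) and `counts` (`meth_counts`).
#' @export
simulate_study <- function(scenario, seed = 1, locus = NULL, config = NULL) {
  if (!inherits(scenario, "scenario"))
    stop_invalid("invalid argument: scenario must be a scenario object")
  locus <- locus %||% default_locus(seed)
  gs <- if (inherits(scenario, "gradient_scenario")) scenario else scenario$base
  config <- config %||% sim_config(seed = seed, coverage_mean = gs$coverage_mean)

  if (inherits(scenario, "gradient_scenario")) {
    expr <- simulate_expression(scenario, seed = seed + 1L)
  } else if (inherits(scenario, "aging_scenario")) {
    infant <- simulate_expression(scenario$base, seed = seed + 1L,
                                  age_group = "P6")
    adult <- simulate_expression(scenario$base, seed = seed + 2L,
                                 age_group = "P60",
                                 segment_mrna_means = scenario$adult_mrna_means)
    expr <- rbind(infant, adult)
  } else if (inherits(scenario, "diet_scenario")) {
    lacm <- simulate_expression(scenario$base, seed = seed + 1L,
                                age_group = "P90", diet = "lac-",
                                n_mice = scenario$n_lacminus)
    lacp <- simulate_expression(scenario$base, seed = seed + 2L,
                                age_group = "P90", diet = "LAC+",
                                n_mice = scenario$n_lacplus,
                                segment_mrna_means =
                                  scenario$base$segment_mrna_means *
                                  scenario$lacplus_mrna_fold)
    expr <- rbind(lacm, lacp)
  } else {
    stop_invalid("invalid argument: unknown scenario class")
  }

  counts <- simulate_methylation(locus, scenario, expr, config)
  list(
    scenario = scenario,
    locus = locus,
    expression = expr,
    annotation = expr[, c("sample", "mouse", "segment", "age", "diet", "sex")],
    counts = counts
  )
}

#' Simulate a ChIP-qPCR Ct table
#'
#' Emits IP, input and IgG cycle thresholds such that recomputing percent
#' input (with the dilution adjustment) and subtracting the IgG background
#' recovers the planted net enrichment in expectation; exactly, when
#' `noise_sd = 0`.
#'
#' @param profile Named list: locus -> named numeric vector of true net
#'   percent-input enrichment (%) by segment.
#' @param segments Segments to emit (default those named in the profile).
#' @param age_group Age label for the table.
#' @param seed Integer seed.
#' @param n_mice Mice per segment.
#' @param input_fraction Fraction of chromatin taken as the input control,
#'   in (0, 1].
#' @param igg_percent IgG background as percent input (>= 0; 0 yields an
#'   infinite IgG Ct, i.e. no background amplification).
#' @param ct_input_mean Mean input Ct.
#' @param noise_sd SD (cycles) of Gaussian noise added to each Ct.
#' @return data.frame `locus`, `segment`, `mouse`, `age`, `ct_ip`,
#'   `ct_input`, `ct_igg`, `input_fraction`.
#' @export
simulate_chip <- function(profile, segments = NULL, age_group = "P60",
                          seed = 1, n_mice = 3, input_fraction = 0.01,
                          igg_percent = 0.2, ct_input_mean = 30,
                          noise_sd = 0) {
  if (input_fraction <= 0 || input_fraction > 1)
    stop_invalid("invalid argument: input_fraction must be in (0, 1]")
  if (igg_percent < 0)
    stop_invalid("invalid argument: igg_percent must be non-negative")
  set.seed(seed)
  segs <- segments %||% sort(unique(unlist(lapply(profile, function(v)
    as.integer(names(v))))))
  out <- list()
  for (loc in names(profile)) {
    for (s in segs) {
      net <- profile[[loc]][[as.character(s)]]
      if (is.null(net) || is.na(net)) net <- 0
      if (net < 0) stop_invalid("invalid argument: planted enrichment must be >= 0")
      for (m in seq_len(n_mice)) {
        ct_in <- ct_input_mean + stats::rnorm(1, 0, noise_sd)
        adj <- ct_in + log2(input_fraction)  # input Ct on the full-input scale
        pct_target <- net + igg_percent
        ct_ip <- adj - log2(pct_target / 100) + stats::rnorm(1, 0, noise_sd)
        ct_igg <- if (igg_percent > 0)
          adj - log2(igg_percent / 100) + stats::rnorm(1, 0, noise_sd)
        else Inf
        out[[length(out) + 1L]] <- data.frame(
          locus = loc, segment = s,
          mouse = sprintf("%s_chip_M%02d", age_group, m),
          age = age_group, ct_ip = ct_ip, ct_input = ct_in, ct_igg = ct_igg,
          input_fraction = input_fraction, stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}
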