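mk_dm <- function(d, pos = NULL, context = "CpG") {
  S <- nrow(d)
  sites <- data.frame(chrom = "chr1",
                      pos = if (is.null(pos)) seq_len(S) * 10L else pos,
                      strand = "+", context = context,
                      stringsAsFactors = FALSE)
  structure(list(sites = sites, density = d), class = "density_matrix")
}

mk_annot <- function(samples, segment, group, group_var = "age") {
  a <- data.frame(sample = samples, mouse = paste0(group, "_", samples),
                  segment = segment, stringsAsFactors = FALSE)
  a[[group_var]] <- group
  a
}

test_that("site contrast reproduces the Welch t-test per site", {
  set.seed(3)
  d <- matrix(runif(5 * 12, 0.2, 0.8), nrow = 5)
  colnames(d) <- paste0("s", 1:12)
  dm <- mk_dm(d)
  annot <- rbind(mk_annot(paste0("s", 1:6), 7, "P60"),
                 mk_annot(paste0("s", 7:12), 7, "P6"))
  dp <- site_contrast(dm, annot, "P60", "P6", segments = 7)
  for (i in 1:5) {
    tt <- t.test(d[i, 1:6], d[i, 7:12])
    expect_equal(dp$results$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(dp$results$t[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(dp$results$delta[i],
                 mean(d[i, 1:6]) - mean(d[i, 7:12]), tolerance = 1e-12)
  }
  # frozen hand-computed 2x3 worked example
  a <- c(0.50, 0.44, 0.47); b <- c(0.40, 0.36, 0.38)
  dm2 <- mk_dm(matrix(c(a, b), nrow = 1))
  colnames(dm2$density) <- paste0("s", 1:6)
  annot2 <- rbind(mk_annot(paste0("s", 1:3), 1, "P60"),
                  mk_annot(paste0("s", 4:6), 1, "P6"))
  w <- site_contrast(dm2, annot2, "P60", "P6", segments = 1,
                     min_sample_fraction = 0.5)$results
  expect_equal(w$t, 4.32346015273735, tolerance = 1e-10)
  expect_equal(w$df, 3.48453608247423, tolerance = 1e-10)
  expect_equal(w$p, 1.670650597618924e-02, tolerance = 1e-10)
})

test_that("identical groups give delta 0 and p = 1; contrasts are antisymmetric", {
  d <- matrix(rep(c(0.3, 0.5, 0.7), 4), nrow = 1)
  colnames(d) <- paste0("s", 1:12)
  dm <- mk_dm(d)
  annot <- rbind(mk_annot(paste0("s", 1:6), 2, "A"),
                 mk_annot(paste0("s", 7:12), 2, "B"))
  w <- site_contrast(dm, annot, "A", "B", group_var = "age", segments = 2)$results
  expect_equal(w$delta, 0)
  expect_equal(w$p, 1)
  # antisymmetry on random data
  set.seed(4)
  d2 <- matrix(runif(8 * 12, 0.1, 0.9), nrow = 8)
  colnames(d2) <- paste0("s", 1:12)
  dm2 <- mk_dm(d2)
  ab <- site_contrast(dm2, annot, "A", "B", segments = 2)$results
  ba <- site_contrast(dm2, annot, "B", "A", segments = 2)$results
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$p, ba$p)
})

test_that("invalid contrast designs are rejected", {
  d <- matrix(runif(12, 0.2, 0.8), nrow = 1)
  colnames(d) <- paste0("s", 1:12)
  dm <- mk_dm(d)
  annot <- rbind(mk_annot(paste0("s", 1:6), 1, "A"),
                 mk_annot(paste0("s", 7:12), 2, "B"))
  expect_error(site_contrast(dm, annot, "A", "B", segments = 1),
               "invalid design")
  expect_error(site_contrast(dm, annot, "A", "C", segments = 1),
               "absent")
  expect_error(between_segment_scan(dm, annot, "A", list(c(1, 1))),
               "self-comparison")
})

test_that("AGE-1 planted shifts are recovered at the cluster cytosines", {
  st <- simulate_study(scenario_age1(), seed = 41)
  dens <- compute_density(st$counts)
  dp <- site_contrast(dens, st$annotation, "P60", "P6", segments = c(1, 3, 7))
  c1 <- st$locus$clusters[1, ]
  r <- dp$results
  inC1 <- r$pos >= c1$start & r$pos <= c1$end
  expect_lt(abs(mean(r$delta[inC1 & r$segment == 7]) - 0.30), 0.03)
  expect_lt(abs(mean(r$delta[inC1 & r$segment == 1]) - 0.18), 0.03)
  expect_lt(abs(mean(r$delta[inC1 & r$segment == 3]) - 0.12), 0.03)
  # non-cluster CpGs centre on zero
  expect_lt(abs(mean(r$delta[!inC1 & r$segment == 7])), 0.01)
})

test_that("DIET-1 decreases carry the right sign at all four planted spots", {
  hits <- matrix(0, nrow = 4, ncol = 8)
  for (s in 1:8) {
    st <- simulate_study(scenario_diet1(), seed = 600 + s)
    dens <- saturation_filter(compute_density(st$counts))
    dp <- site_contrast(dens, st$annotation, "lac-", "LAC+",
                        group_var = "diet", segments = c(7, 8))
    cl <- st$locus$clusters
    r <- dp$results
    spots <- list(c(2, 7), c(2, 8), c(3, 8), c(4, 8))
    for (k in seq_along(spots)) {
      ci <- spots[[k]][1]; seg <- spots[[k]][2]
      inC <- r$pos >= cl$start[ci] & r$pos <= cl$end[ci] & r$segment == seg
      hits[k, s] <- mean(r$delta[inC]) > 0
    }
  }
  expect_true(all(rowMeans(hits) >= 0.9))
})

test_that("the infant state shows no significant between-segment differences", {
  sc <- scenario_age1()
  st <- simulate_study(sc, seed = 51)
  dens <- compute_density(st$counts)
  inf <- between_segment_scan(dens, st$annotation, "P6",
                              list(c(1, 3), c(3, 7), c(1, 7)))
  expect_equal(sum(inf$significant, na.rm = TRUE), 0)
  # while the adult state separates the planted cluster between segments
  ad <- between_segment_scan(dens, st$annotation, "P60", list(c(3, 7)))
  c1 <- st$locus$clusters[1, ]
  inC1 <- ad$pos >= c1$start & ad$pos <= c1$end
  expect_gt(sum(ad$significant[inC1], na.rm = TRUE), 0)
})

test_that("LOESS reproduces low-degree polynomials exactly", {
  set.seed(5)
  x <- sort(runif(40, 0, 100))
  y_lin <- 2 + 0.5 * x
  for (span in c(0.2, 0.5, 1)) {
    expect_equal(loess_smooth(x, y_lin, span = span), y_lin,
                 tolerance = 1e-10)
  }
  expect_equal(loess_smooth(x, rep(3, 40), span = 0.3), rep(3, 40),
               tolerance = 1e-12)
  expect_error(loess_smooth(1:2, 1:2), "degree \\+ 2")
  expect_error(loess_smooth(1:10, 1:10, span = 0), "span")
})

test_that("LOESS matches an independently coded textbook implementation", {
  set.seed(6)
  x <- sort(runif(60, 0, 2 * pi))
  y <- sin(x) + rnorm(60, 0, 0.2)
  expect_equal(loess_smooth(x, y, span = 0.3, degree = 1),
               oracle_loess(x, y, span = 0.3, degree = 1), tolerance = 1e-8)
  expect_equal(loess_smooth(x, y, span = 0.5, degree = 2),
               oracle_loess(x, y, span = 0.5, degree = 2), tolerance = 1e-8)
})

test_that("factorial ANOVA detects the planted diet-by-segment interaction", {
  ps <- vapply(1:5, function(s) {
    st <- simulate_study(scenario_diet1(), seed = 700 + s)
    dens <- saturation_filter(compute_density(st$counts))
    cl <- st$locus$clusters
    agg <- aggregate_region(dens, c(cl$start[2], cl$end[2]), contexts = "CpG")
    keep <- names(agg) %in%
      st$annotation$sample[st$annotation$segment %in% c(1, 3, 4, 7, 8)]
    fa <- factorial_region_anova(agg[keep & !is.na(agg)], st$annotation)
    fa$anova$p[fa$anova$term == "diet:segment"]
  }, numeric(1))
  expect_gte(sum(ps < 0.05), 3)
})

test_that("factorial ANOVA boundary behaviour and error contract", {
  set.seed(7)
  annot <- data.frame(sample = paste0("s", 1:16),
                      diet = rep(c("LAC+", "lac-"), each = 8),
                      segment = rep(c(7, 8), times = 8),
                      stringsAsFactors = FALSE)
  # identical cell means with within-cell spread: all F exactly zero
  cell <- interaction(annot$diet, annot$segment)
  v <- stats::setNames(numeric(16), annot$sample)
  for (cc in levels(cell)) v[cell == cc] <- c(0.48, 0.49, 0.51, 0.52)
  fa <- factorial_region_anova(v, annot)
  expect_true(all(fa$anova$F < 1e-20))
  # empty cell named in the error
  annot2 <- annot[!(annot$diet == "LAC+" & annot$segment == 8), ]
  v2 <- v[annot2$sample]
  expect_error(factorial_region_anova(v2, annot2), "empty cell")
  # null calibration: interaction p roughly uniform under no planted effect
  ps <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    vv <- stats::setNames(rnorm(16, 0.5, 0.05), annot$sample)
    fa <- factorial_region_anova(vv, annot)
    fa$anova$p[fa$anova$term == "diet:segment"]
  }, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps), 0.75)
  expect_lte(sum(ps < 0.05), 6)
})

test_that("the proportion-test route matches prop.test without continuity correction", {
  st <- simulate_study(scenario_age1(), seed = 77, locus = tiny_locus(77))
  dens <- compute_density(st$counts)
  dp <- site_contrast(dens, st$annotation, "P60", "P6", segments = 7,
                      test = "proportion", counts = st$counts)
  r <- dp$results
  annot <- st$annotation
  sa <- annot$sample[annot$age == "P60" & annot$segment == 7]
  sb <- annot$sample[annot$age == "P6" & annot$segment == 7]
  tested_pos <- r$pos[r$tested]
  cpg <- which(st$counts$sites$context == "CpG" &
                 st$counts$sites$pos %in% tested_pos)
  for (i in cpg[c(1, 5, 10)]) {
    okA <- !is.na(dens$density[i, sa]); okB <- !is.na(dens$density[i, sb])
    MA <- sum(st$counts$meth[i, sa][okA]); TA <- sum(st$counts$total[i, sa][okA])
    MB <- sum(st$counts$meth[i, sb][okB]); TB <- sum(st$counts$total[i, sb][okB])
    pt_ <- suppressWarnings(prop.test(c(MA, MB), c(TA, TB), correct = FALSE))
    j <- which(r$pos == st$counts$sites$pos[i])
    expect_equal(r$p[j], pt_$p.value, tolerance = 1e-10)
    expect_equal(r$delta[j], MA / TA - MB / TB, tolerance = 1e-12)
  }
  expect_error(site_contrast(dens, st$annotation, "P60", "P6", segments = 7,
                             test = "proportion"), "counts")
})
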