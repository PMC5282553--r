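test_that("per-site Pearson correlation matches cor.test and handles degeneracy", {
  # collinear three-point case: perfect inverse correlation
  r3 <- correlate_site(c(0.5, 0.3, 0.1), c(1, 2, 3))
  expect_equal(r3$r, -1)
  expect_true(r3$degenerate)   # n < 4: excluded from the testing universe
  # constant density: undefined correlation
  expect_true(correlate_site(rep(0.4, 6), 1:6)$degenerate)
  # frozen 9-point worked example (values from cor.test)
  x <- c(0.35, 0.42, 0.31, 0.58, 0.44, 0.61, 0.70, 0.66, 0.73)
  y <- c(1.00, 0.95, 0.85, 0.60, 0.80, 0.55, 0.35, 0.20, 0.10)
  got <- correlate_site(x, y)
  expect_equal(got$r, -0.931386013845233, tolerance = 1e-12)
  expect_equal(got$p, 2.60404614766028e-04, tolerance = 1e-10)
  expect_equal(got$r_squared, got$r^2)
  # and against the closed covariance/sd form
  r_manual <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(got$r, r_manual, tolerance = 1e-12)
  # missing pairs are dropped
  x[3] <- NA
  expect_equal(correlate_site(x, y)$n, 8)
})

test_that("SLP has the sign of the correlation and the -log10 p magnitude", {
  expect_equal(slp(-0.9, 1e-6), -6)
  expect_equal(slp(0.5, 0.01), 2)
  expect_equal(slp(-1, 0), -300)               # underflow cap
  expect_equal(slp(0.7, 1e-400, cap = 300), 300)
  expect_error(slp(0.5, 1.5), "\\[0, 1\\]")
  # |slp| strictly decreasing in p, sign(slp) = sign(r)
  p <- sort(10^-runif(20, 0, 10))
  s <- slp(rep(-0.5, 20), p)
  expect_true(all(diff(abs(s)) <= 0))
  expect_true(all(sign(s) == -1))
})

test_that("Bonferroni adjustment clamps, flags and stays monotone", {
  adj <- bonferroni_adjust(1e-5, m = 609)
  expect_equal(adj$p_adj, 6.09e-3)
  expect_true(adj$significant)
  expect_equal(bonferroni_adjust(0.5, m = 1000)$p_adj, 1)
  expect_error(bonferroni_adjust(runif(10), m = 5), "universe")
  # Bonferroni-significant set is a subset of the nominal p < alpha set
  p <- runif(200, 0, 0.05)
  adj <- bonferroni_adjust(p, m = 200, alpha = 0.01)
  expect_true(all(p[adj$significant] < 0.01))
})

test_that("associate_gradient matches correlate_site per site", {
  st <- simulate_study(scenario_grad1(), seed = 21, locus = tiny_locus(21))
  dens <- compute_density(st$counts)
  assoc <- associate_gradient(dens, st$annotation, st$expression)
  mr <- st$expression$rel_mrna[match(colnames(dens$density),
                                     st$expression$sample)]
  for (i in c(1, 10, 25, nrow(assoc))) {
    row <- assoc[i, ]
    j <- which(dens$sites$pos == row$pos & dens$sites$strand == row$strand)
    ref <- correlate_site(dens$density[j, ], mr)
    expect_equal(row$r, ref$r, tolerance = 1e-12)
    expect_equal(row$p, ref$p, tolerance = 1e-12)
  }
  # testing universe excludes degenerate/skipped sites and backs the flags
  expect_equal(attr(assoc, "m"), sum(assoc$tested))
  expect_true(all(assoc$p_bonferroni[assoc$significant] < 0.01))
  expect_true(all(sign(assoc$slp) == sign(assoc$r), na.rm = TRUE))
})

test_that("one-way region ANOVA behaves at its boundary cases", {
  set.seed(1)
  # equal group means with within-group spread: F near zero
  v <- rep(c(-1, 0, 1), times = 4)
  g <- rep(letters[1:4], each = 3)
  an <- region_anova(v, g)
  expect_lt(an$F, 1e-20)
  expect_gt(an$p, 0.999)
  # two groups: F equals the pooled-t squared
  v2 <- c(rnorm(6, 0), rnorm(7, 0.8))
  g2 <- rep(c("a", "b"), c(6, 7))
  tt <- t.test(v2[g2 == "a"], v2[g2 == "b"], var.equal = TRUE)
  expect_equal(region_anova(v2, g2)$F, unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_error(region_anova(c(1, 2, 3), c("a", "a", "b")), "invalid design")
})

test_that("Tukey HSD matches the studentized-range computation", {
  set.seed(2)
  v <- c(rnorm(5, 0), rnorm(5, 1), rnorm(5, 2))
  g <- rep(c("g1", "g2", "g3"), each = 5)
  tk <- tukey_hsd(v, g)
  expect_equal(nrow(tk), 3)
  # manual studentized-range p for one pair
  fit <- aov(v ~ factor(g))
  mse <- summary(fit)[[1]]$`Mean Sq`[2]
  diff12 <- mean(v[g == "g2"]) - mean(v[g == "g1"])
  q <- abs(diff12) / sqrt(mse / 5)
  p_manual <- ptukey(q, nmeans = 3, df = 12, lower.tail = FALSE)
  expect_equal(tk$p_adj[tk$comparison == "g2-g1"], p_manual, tolerance = 1e-8)
  expect_equal(nrow(tukey_hsd(v, g, reference = "g1")), 2)
})

test_that("GRAD-1 planted-cluster region shows a strong segment effect", {
  st <- simulate_study(scenario_grad1(), seed = 30)
  dens <- compute_density(st$counts)
  c1 <- st$locus$clusters[1, ]
  agg <- aggregate_region(dens, c(c1$start, c1$end), contexts = "CpG")
  seg <- st$annotation$segment[match(names(agg), st$annotation$sample)]
  expect_lt(region_anova(agg, seg)$p, 1e-3)
})

test_that("BED reading enforces the format and names offending lines", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=test", "chr1\t100\t200\tpk1\t0\t+",
               "chr1\t300\t250"), path)
  expect_error(read_bed_track(path), "line 3")
  writeLines(c("chr1\t100\t200", "chr1\t300"), path)
  expect_error(read_bed_track(path), "line 2")
  writeLines(c("# comment", "chr1\t100\t200\tpk1"), path)
  tr <- read_bed_track(path)
  expect_equal(tr$start, 100L)
  expect_equal(tr$name, "pk1")
})

test_that("cluster-track overlap handles the coordinate conventions", {
  clusters <- data.frame(label = c("CL1", "CL2"), chrom = "chr1",
                         start = c(1000L, 5000L), end = c(1400L, 5300L),
                         stringsAsFactors = FALSE)
  clusters$members_pos <- list(c(1000L, 1200L, 1400L), c(5000L, 5300L))
  # 1-based position 1400 is 0-based 1399: first base of [1399, 1500)
  tracks <- list(enh = data.frame(chrom = "chr1", start = 1399L, end = 1500L,
                                  stringsAsFactors = FALSE),
                 empty = data.frame(chrom = character(0), start = integer(0),
                                    end = integer(0)))
  ov <- annotate_overlap(clusters, tracks)
  expect_true(ov["CL1", "enh"])
  expect_false(ov["CL2", "enh"])
  expect_false(any(ov[, "empty"]))
})

test_that("overlap annotation agrees with a brute-force all-pairs scan", {
  set.seed(99)
  for (rep in 1:20) {
    n_cl <- sample(1:5, 1)
    clusters <- data.frame(label = paste0("CL", seq_len(n_cl)), chrom = "chr1",
                           stringsAsFactors = FALSE)
    clusters$members_pos <- lapply(seq_len(n_cl), function(i)
      sort(sample(1:2000, sample(3:6, 1))))
    clusters$start <- vapply(clusters$members_pos, min, integer(1))
    clusters$end <- vapply(clusters$members_pos, max, integer(1))
    tracks <- lapply(1:3, function(j) {
      s <- sort(sample(0:1999, sample(1:4, 1)))
      data.frame(chrom = "chr1", start = s,
                 end = s + sample(1:300, length(s), replace = TRUE),
                 stringsAsFactors = FALSE)
    })
    names(tracks) <- paste0("t", 1:3)
    expect_identical(annotate_overlap(clusters, tracks),
                     oracle_overlap(clusters, tracks))
  }
})
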