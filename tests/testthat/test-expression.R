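mk_ct <- function(samples, dct, ct_control = 20) {
  data.frame(
    sample = rep(samples, 2),
    gene = rep(c("Lct", "Vil1"), each = length(samples)),
    replicate = 1L,
    ct = c(ct_control + dct, rep(ct_control, length(samples))),
    stringsAsFactors = FALSE
  )
}

test_that("delta-delta-Ct closed forms hold", {
  # sample dCt 5 against a reference mean dCt of 8: ddCt -3, fold 8
  ct <- mk_ct(c("a", "r1", "r2"), c(5, 8, 8))
  rel <- delta_delta_ct(ct, "Lct", "Vil1", c("r1", "r2"))
  expect_equal(rel$delta_delta_ct[rel$sample == "a"], -3)
  expect_equal(rel$fold[rel$sample == "a"], 8)
  # a reference sample at the reference mean has fold exactly 1
  expect_equal(rel$fold[rel$sample == "r1"], 1)
  # reference group geometric-mean fold is 1 by construction
  ct2 <- mk_ct(c("r1", "r2", "r3", "x"), c(7.2, 8.4, 8.1, 6.0))
  rel2 <- delta_delta_ct(ct2, "Lct", "Vil1", c("r1", "r2", "r3"))
  gm <- exp(mean(log(rel2$fold[rel2$sample != "x"])))
  expect_equal(gm, 1, tolerance = 1e-12)
  # one cycle less target Ct doubles the fold
  ct3 <- mk_ct(c("a", "b", "r"), c(5, 4, 8))
  rel3 <- delta_delta_ct(ct3, "Lct", "Vil1", "r")
  expect_equal(rel3$fold[rel3$sample == "b"] / rel3$fold[rel3$sample == "a"], 2)
})

test_that("folds are invariant to a constant shift of the control gene", {
  ct <- mk_ct(c("a", "b", "r"), c(5, 6.5, 8))
  shifted <- ct
  shifted$ct[shifted$gene == "Vil1"] <- shifted$ct[shifted$gene == "Vil1"] + 3.7
  shifted$ct[shifted$gene == "Lct"] <- shifted$ct[shifted$gene == "Lct"] + 3.7
  expect_equal(delta_delta_ct(shifted, "Lct", "Vil1", "r")$fold,
               delta_delta_ct(ct, "Lct", "Vil1", "r")$fold)
})

test_that("technical replicates are averaged and missing controls rejected", {
  ct <- rbind(mk_ct(c("a", "r"), c(5, 8)),
              data.frame(sample = "a", gene = "Lct", replicate = 2L,
                         ct = 27, stringsAsFactors = FALSE))
  rel <- delta_delta_ct(ct, "Lct", "Vil1", "r")
  expect_equal(rel$delta_ct[rel$sample == "a"], (25 + 27) / 2 - 20)
  bad <- ct[!(ct$sample == "a" & ct$gene == "Vil1"), ]
  expect_error(delta_delta_ct(bad, "Lct", "Vil1", "r"), "missing control")
  expect_error(delta_delta_ct(mk_ct("a", 5), "Lct", "Vil1", "zz"),
               "reference")
})

test_that("noise-free simulated Ct pairs recover scenario mRNA exactly", {
  sc <- scenario_grad1(); sc$biological_sd <- 0
  expr <- simulate_expression(sc, seed = 1)
  ct <- ct_table_from_expression(expr)
  rel <- delta_delta_ct(ct, "Lct", "Vil1", expr$sample[expr$segment == 3])
  expect_equal(rel$fold[match(expr$sample, rel$sample)], expr$rel_mrna,
               tolerance = 1e-12)
})

test_that("RM-ANOVA respects its boundary and identity cases", {
  # Latin-square layout: segment means exactly equal, residual positive -> F = 0
  vals <- c(1, 2, 3, 4)
  d <- expand.grid(mouse = paste0("m", 1:4), segment = 1:4)
  d$sample <- paste0(d$mouse, "_", d$segment)
  d$fold <- vals[((as.integer(factor(d$mouse)) + d$segment) %% 4) + 1]
  rma <- rm_anova_segments(d)
  expect_lt(rma$F, 1e-20)
  # two segments: F equals the paired t squared
  set.seed(8)
  d2 <- expand.grid(mouse = paste0("m", 1:6), segment = c(3, 7))
  d2$sample <- paste0(d2$mouse, "_", d2$segment)
  d2$fold <- rnorm(12, mean = ifelse(d2$segment == 3, 1, 0.4), sd = 0.2)
  rma2 <- rm_anova_segments(d2)
  tt <- t.test(d2$fold[d2$segment == 3], d2$fold[d2$segment == 7],
               paired = TRUE)
  expect_equal(rma2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(rma2$p, tt$p.value, tolerance = 1e-10)
})

test_that("RM-ANOVA drops single-segment mice and needs 3 complete mice", {
  d <- expand.grid(mouse = paste0("m", 1:3), segment = c(3, 7))
  d$sample <- paste0(d$mouse, "_", d$segment)
  d$fold <- runif(6, 0.5, 1.5)
  d <- rbind(d, data.frame(mouse = "m4", segment = 5, sample = "m4_5",
                           fold = 1))
  expect_warning(rma <- rm_anova_segments(d), "single segment")
  expect_equal(rma$n_mice, 3)
  d2 <- d[d$mouse %in% c("m1", "m2", "m4"), ]
  expect_warning(expect_error(rm_anova_segments(d2), "fewer than 3 mice"))
})

test_that("the simulated gradient produces a strong RM segment effect", {
  st <- simulate_study(scenario_grad1(), seed = 10, locus = tiny_locus(10))
  expr <- st$expression
  rel <- delta_delta_ct(ct_table_from_expression(expr), "Lct", "Vil1",
                        expr$sample[expr$segment == 3])
  rel <- merge(rel, expr[, c("sample", "mouse", "segment")])
  rma <- rm_anova_segments(rel, reference_segment = 3)
  expect_lt(rma$p, 1e-3)
  expect_true(all(grepl("(^3-|-3$)", rma$tukey$comparison)))
})

test_that("the Greenhouse-Geisser correction bounds epsilon and never lowers the p-value", {
  set.seed(9)
  d <- expand.grid(mouse = paste0("m", 1:6), segment = 1:5)
  d$sample <- paste0(d$mouse, "_", d$segment)
  d$fold <- rnorm(30, 1 + 0.1 * d$segment, 0.2)
  rma <- rm_anova_segments(d, gg = TRUE)
  expect_gte(rma$gg_epsilon, 1 / 4)
  expect_lte(rma$gg_epsilon, 1)
  expect_gte(rma$p_gg, rma$p)
  # incomplete layout: NA with a warning
  d2 <- d[-1, ]
  expect_warning(rma2 <- rm_anova_segments(d2, gg = TRUE), "complete")
  expect_true(is.na(rma2$p_gg))
})
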