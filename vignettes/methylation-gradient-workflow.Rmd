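---
title: "Linking per-cytosine DNA modification density to a within-cell-type expression gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking per-cytosine DNA modification density to a within-cell-type expression gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific setting

Enterocytes along the proximal-to-distal axis of the mouse small intestine
are histologically one cell type, yet the lactase gene (*Lct*) shows a
pronounced transcriptional gradient across the nine intestinal segments:
expression peaks in the proximal jejunum (segment 3) and declines toward
both the duodenum and the distal ileum. `methgrad` implements the analysis
chain that asks whether per-cytosine DNA modification densities at a
targeted locus (the *Lct*–*Mcm6* region, assayed by padlock bisulfite
sequencing) track that gradient, and whether age and diet reshape both
together.

The pipeline has five analysis stages, each backed by a module in `R/`:

1. **Density** — per-cytosine modification density from methylated/total
   read counts, with a coverage filter and a saturation filter.
2. **Gradient association** — per-cytosine Pearson correlation with
   relative mRNA, expressed as a signed log p-value (SLP), Bonferroni
   control, and calling of clusters of associated cytosines.
3. **Differential contrasts** — age and diet group contrasts per cytosine
   (Welch t), between-segment scans, LOESS positional delta curves, and
   factorial region ANOVA.
4. **Expression** — ΔΔCt relative quantification against an endogenous
   control with repeated-measures ANOVA across segments.
5. **ChIP** — percent-input quantification of ChIP-qPCR with IgG
   background subtraction and segment ANOVA.

A sixth module, the synthetic-data generator, defines the study conditions
under which every stage is validated.

## The statistical model

**Density.** At cytosine $i$ in sample $j$, the modification density is
$\hat d_{ij} = m_{ij}/t_{ij}$, the fraction of reads reporting a protected
(modified) base. A cell contributes only if $t_{ij} > 30$ reads — the
threshold is strict, so exactly 30 reads is excluded. For the diet analysis
only, sites whose mean density exceeds 90% are removed beforehand: a
saturated site has no room for deviation and only adds to the testing
burden. Whether that mean should be taken per analysis group or globally is
ambiguous; we use the analysis-group mean (all samples entering the
contrast), which is the more conservative reading because a site saturated
in the pooled data is saturated in both arms.

**Association.** For each cytosine the Pearson correlation $r$ between
$\hat d_{ij}$ and relative *Lct* mRNA is tested with the t-transform
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom. Evidence is
reported as the signed log p-value,
$\mathrm{SLP} = \mathrm{sign}(r)\,\min(-\log_{10} p,\ 300)$;
the cap guards against floating-point underflow at $|r| \to 1$. Family-wise
error is controlled by Bonferroni ($p_{\text{adj}} = \min(1, m\,p)$,
significance at $p_{\text{adj}} < 0.01$). The testing universe $m$ is the
number of sites that actually enter testing — those passing the coverage,
missingness and degeneracy rules — not the full site panel: sites that were
never tested cannot inflate the family. The run log states $m$ explicitly,
and `associate_gradient(m = ...)` accepts any larger universe (e.g. all
CpGs) for users who prefer the fixed-panel convention.

Each sample is paired with its own mouse's relative mRNA when available,
falling back to the segment mean: the mouse is the biological replicate, so
pairing within mouse preserves the replicate structure.

**Cluster calling.** A cluster is a run of at least 3 significantly
associated cytosines in which consecutive members are at most 500 bp
apart. We read "within 500 bp" as a chaining rule on consecutive gaps, not
a fixed window: chaining is scale-free and does not depend on an arbitrary
window origin. The window reading (total span capped at 500 bp) remains
available via `detect_clusters(rule = "span")`. A non-significant tested
site between two significant ones breaks the chain, and chains are split
where the correlation sign flips, so every reported cluster has a coherent
direction. The implementation is a single-pass state machine, verified
against an independent chain-enumeration oracle on randomized
configurations in the test suite.

**Contrasts.** Age (adult minus infant) and diet (lactose-free minus
lactose-fed) contrasts compare per-mouse densities on matched segments with
a two-sided Welch t-test per cytosine. The per-cytosine test is not named
in the field's convention for this design, and two choices are defensible:
a read-count proportion test, or a t-test on per-mouse densities. We test
per-mouse densities because the mouse — not the read — is the unit of
replication; pooling reads across mice would treat technical depth as
biological sample size. Positional structure of the deltas is summarized
with a LOESS curve per segment.

**LOESS.** The smoother is local weighted regression with tricube weights
over the $\lceil \text{span} \cdot n \rceil$ nearest neighbors of each
point, polynomial degree 1 by default, and no robustness iterations.
Defaults are span 0.3 and degree 1: with roughly 600 CpGs over 100 kb,
span 0.3 averages over ~180 neighboring sites, wide enough to suppress
single-site noise while preserving cluster-scale features. Degree-0 and
degree-1 polynomials are reproduced exactly (a property the tests assert),
and the implementation is checked against an independently coded textbook
LOESS. Note two deliberate conventions that differ from `stats::loess`:
the neighborhood is $\lceil \text{span}\,n \rceil$ (not
$\lfloor \text{span}\,n \rfloor$), and distances are raw positional
distances. When every neighborhood distance ties at the bandwidth (all
weights zero), the fit falls back to uniform weights, and a neighborhood
with a single distinct position falls back to the weighted mean.

**Region ANOVA.** Region-level summaries use the unweighted mean density
over member sites per sample. One-way ANOVA tests the segment effect; the
diet experiment uses a two-way diet × segment ANOVA with interaction and
Type II sums of squares (via `car::Anova`), because the arms are unbalanced
(6 vs 7 mice) and Type II does not depend on term order. Tukey HSD handles
post-hoc pairwise comparisons throughout, including diet-within-segment
after the factorial fit.

**Expression.** ΔΔCt with efficiency fixed at 2:
$\Delta Ct = Ct_{\text{target}} - Ct_{\text{control}}$,
$\Delta\Delta Ct = \Delta Ct - \overline{\Delta Ct}_{\text{ref}}$, fold
$= 2^{-\Delta\Delta Ct}$. The reference group defaults to segment 3 of the
same stratum (the expression peak, which makes all folds interpretable as
"fraction of the jejunal maximum"); any calibrator sample set can be
passed instead, since the assay itself does not fix whether the reference
is a segment, an age group, or a pooled pool. Folds are invariant to
constant shifts of the control gene, and the reference group's geometric
mean fold is 1 by construction — the arithmetic mean exceeds 1 under noise
(Jensen), so the identity is stated and tested on the geometric scale. The
segment effect is tested by repeated-measures ANOVA with mouse as the
repeated factor, computed as the randomized-block univariate F
(`aov(value ~ segment + mouse)`), uncorrected for sphericity by default;
for two segments this F equals the squared paired t.

**ChIP.** Percent input is
$100 \times 2^{(Ct_{\text{input}} - \log_2(1/f)) - Ct_{\text{IP}}}$ where
$f$ is the input fraction — the dilution adjustment puts the input Ct on
the full-input scale. $f$ is a required input field, never assumed: kits
differ and the value does not survive into the Ct table. Background is
removed by subtracting the matched IgG *percent input* (not the IgG Ct),
floored at zero; subtracting percent input keeps the correction on the
scale on which results are reported, and the floor encodes that negative
recovery is measurement noise.

## What the generator emulates

The generator produces count tables with the structure the analysis
assumes: a ~100 kb locus with 609 CpG and 6,971 CpH sites (7,580
cytosines), 9 segments × 5–7 mice, negative-binomial read coverage, and
binomial methylated counts around planted densities. Its shipped scenarios
are the package's study conditions:

- **GRAD-1** — adult gradient. Relative mRNA means
  (0.55, 0.80, 1.00, 0.95, 0.85, 0.60, 0.35, 0.20, 0.10) for segments 1–9:
  a declared scenario shape with the jejunal peak and monotone decline on
  both sides, not a reconstruction of any measured profile. Cluster C1
  (18 CpGs) follows an affine inverse link anchored at 34.7% density in
  segment 3 and 77.1% in segment 9. Background CpGs sit at 50%, coverage
  mean 200, 6 mice/segment.
- **AGE-1** — uniform infant cluster density of 0.45 (infants have no
  gradient, matching their flat expression profile) with adult gains of
  +0.30, +0.18 and +0.12 in segments 7, 1 and 3.
- **DIET-1** — lactose-fed decreases of 0.052 (exon-12-like cluster,
  segment 7), 0.047 (same cluster, segment 8), 0.036 (intron-8-like,
  segment 8) and 0.064 (intron-2-like, segment 8), on a 0.60 base; the
  C1-like cluster stays at its aged 0.75 level, unresponsive to diet.
  6 lactose-fed vs 7 lactose-free mice per segment.
- **NULL-1** — the same design with no density–mRNA link anywhere, for
  type-I-error calibration.

Modeling choices the data do not dictate, fixed once:

- **Coverage**: negative binomial with mean 200 and dispersion 5, with 5%
  of cells resampled to 5–30 reads so the coverage filter always has work
  to do. `coverage_dispersion = Inf` gives fixed totals for limiting-case
  checks.
- **Biological noise**: a Normal(0, 0.02) density offset drawn per site ×
  mouse, truncated by clamping to [0, 1]. The offset is site-specific
  rather than a single mouse-wide shift because a locus-wide per-mouse
  displacement of all 7,580 cytosines is not a plausible biological noise
  mode; site-level replicate scatter is. The same SD drives per-mouse mRNA
  noise.
- **CpH sites** are simulated at density 0.01: the age and diet effects
  live in CpG context, and CpH methylation in differentiated tissue is
  near-absent.
- **Saturated sites**: 5% of non-cluster CpGs are planted at 95% density so
  the saturation filter is exercised.
- **mRNA units** are relative to the adult segment-3 mean (= 1); the
  infant level in AGE-1 is a uniform 8× that reference.
- Emitted Ct pairs satisfy the ΔΔCt identity exactly by construction
  (control Ct constant, target Ct $= 28 - \log_2$ relative mRNA), so the
  expression stage has an exact round-trip oracle.

What the generator does **not** emulate: read-level artifacts (bisulfite
conversion failure, mapping bias, strand-specific coverage), spatial
autocorrelation of background methylation, batch effects, and
between-mouse covariance structure beyond the site-level offsets. Passing
tests therefore demonstrate that the statistics recover what was planted
under the stated noise model — they do not certify performance on real
bisulfite data with artifacts outside that model.

## Numerical and degenerate-input policy

- Sites with zero variance (or fewer than 3 complete pairs) are flagged
  degenerate: no correlation is reported and they are excluded from the
  testing universe. Three complete pairs yield an `r` (the collinear case
  is well-defined) but still sit outside the universe, which requires at
  least 4.
- A site enters a test only with non-missing density in ≥ 75% of the
  samples of each compared group; skipped sites are counted in the run
  log. The threshold is a package policy — the underlying assay protocol
  does not state one.
- Welch tests with both group variances zero return p = 1 when the means
  agree and p = 0 otherwise.
- SLP caps at ±300; Bonferroni clamps at 1.
- Normality at individual cytosines is assessed by an advisory
  Shapiro–Wilk statistic (replacing visual QQ inspection with a number);
  it never gates results.
- All internal coordinates are 1-based inclusive; BED output and input are
  0-based half-open, converted at the boundary.
- Opposite-strand cytosines of one CpG are distinct sites; no strand
  collapsing.

## Problem sizes

The validation suite runs the full 7,580-site locus: 100 simulated studies
for the null calibration, 50 for gradient-cluster recovery, and 10 each
for the aging and diet recoveries; the cluster caller is checked against
its oracle on 1,000 random configurations. These sizes put the Monte Carlo
standard error of each recovered effect well inside the ±2 percentage-point
recovery band while keeping the whole suite in the order of a minute of
compute.

## Known limitations

- Bonferroni is the only multiplicity control; no FDR or permutation
  option is provided, by design.
- The P90 age group is handled as a further contrast label, not modeled
  longitudinally.
- 5mC and 5hmC are a single "modification" signal; the assay cannot
  separate them.
- The RM-ANOVA F is uncorrected for sphericity by default
  (`aov` block-design F); with 9 segments and few mice a
  Greenhouse–Geisser-style correction would lower significance somewhat.
- The saturation filter uses the pooled analysis-group mean; a strictly
  group-wise variant would differ for sites saturated in only one arm.
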