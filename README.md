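# methgrad

Analysis of per-cytosine DNA modification densities along a
within-cell-type transcriptional gradient.

## The problem

Enterocytes are one cell type, yet the lactase gene (*Lct*) is expressed in
a pronounced gradient along the nine segments of the mouse small intestine:
highest in the proximal jejunum (segment 3), declining toward the duodenum
and the distal ileum. `methgrad` implements the analysis chain that links
this gradient to the epigenome at a targeted locus assayed by padlock
bisulfite sequencing (~7,600 cytosines over ~100 kb):

- **Density**: per-cytosine modification density `meth/total`, kept only at
  cells with more than 30 reads; optional removal of saturated sites
  (mean density > 90%) before the diet contrasts.
- **Gradient association**: per cytosine, Pearson correlation of density
  with relative mRNA; two-sided p from `t = r·sqrt((n−2)/(1−r²))`;
  evidence reported as the signed log p-value
  `SLP = sign(r)·min(−log10 p, 300)`; Bonferroni control at `p < 0.01`.
- **Cluster calling**: runs of ≥ 3 significantly associated cytosines with
  consecutive gaps ≤ 500 bp (chains break at non-significant sites and at
  sign changes), plus BED-track overlap annotation of the calls.
- **Age / diet contrasts**: per-cytosine Welch t-tests between groups on
  matched segments (a read-count proportion test is available as a
  switch), LOESS-smoothed positional delta curves, and diet × segment
  factorial ANOVA with Type II sums of squares.
- **Expression**: ΔΔCt relative quantification (`fold = 2^−ΔΔCt`) against
  an endogenous control, repeated-measures ANOVA across segments with
  Tukey HSD versus segment 3.
- **ChIP**: ChIP-qPCR percent input
  `100·2^((Ct_input − log2(1/f)) − Ct_IP)` with IgG background subtraction
  and per-locus segment ANOVA.

A first-class synthetic-data module generates methylation count tables,
qPCR Ct tables and ChIP Ct tables with planted effect sizes, so every
stage is verifiable against a known truth. The shipped scenarios plant an
inverse density–expression gradient anchored at 34.7% (segment 3) and
77.1% (segment 9) on an 18-CpG cluster (GRAD-1), adult density gains of
+30/+18/+12 percentage points in segments 7/1/3 (AGE-1), lactose-induced
decreases of 5.2/4.7/3.6/6.4 pp at three clusters (DIET-1), and a fully
null design (NULL-1).

## Worked example

```r
library(methgrad)

st <- simulate_study(scenario_grad1(), seed = 1)   # 7,580 sites x 54 samples
res <- run_gradient_analysis(st$counts, st$annotation, st$expression)
#> samples: 54; sites: 7580 (609 CpG)
#> coverage filter (> 30 reads): 20979 of 409320 cells set missing
#> association: 7580 sites tested; 0 degenerate; 0 skipped by the
#>   missing-data rule; testing universe m = 7580
#> Bonferroni-significant sites (p_adj < 0.01): 18
#> clusters called (>= 3 sites within 500 bp): 1

res$clusters[, c("label", "start", "end", "n_members", "direction")]
#>   label start   end n_members direction
#> 1  CL01 20078 20470        18        -1
```

The single called cluster is the planted 18-CpG cluster C1, with negative
direction: modification density falls where *Lct*-like mRNA rises. Its
density profile across segments recovers the planted anchors:

```r
c1 <- st$locus$clusters[1, ]
dens <- compute_density(st$counts)
agg <- aggregate_region(dens, c(c1$start, c1$end), contexts = "CpG")
seg <- st$annotation$segment[match(names(agg), st$annotation$sample)]
round(100 * tapply(agg, seg, mean), 1)
#>    1    2    3    4    5    6    7    8    9
#> 55.9 43.8 34.9 36.4 42.0 53.9 66.5 71.7 77.0
```

34.9% at the expression peak (segment 3) and 77.0% in the distal ileum
(segment 9), against planted values of 34.7% and 77.1%. Per-cytosine R² at
the cluster ranges 0.88–0.95 on this seed.

## The analysis workflow

The numbered scripts under `analysis/` run the full study and write their
tables under `results/`:

```sh
Rscript analysis/01_simulate.R              # GRAD-1, AGE-1, DIET-1 datasets
Rscript analysis/02_gradient_association.R  # association, SLP, clusters
Rscript analysis/03_age_contrast.R          # adult vs infant deltas + LOESS
Rscript analysis/04_diet_contrast.R         # lactose arms + factorial ANOVA
Rscript analysis/05_expression_chip.R       # ddCt / RM-ANOVA and ChIP
```

Each script is a thin driver over the package functions and reports what
it finds (clusters recovered, deltas at planted clusters, ANOVA summaries)
on the console.

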