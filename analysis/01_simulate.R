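#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study datasets.
#
# Simulates the three study conditions — the adult gradient (GRAD-1), the
# infant/adult aging comparison (AGE-1) and the lactose-feeding experiment
# (DIET-1) — over a 7,580-cytosine target locus (609 CpG), and writes the
# count tables, sample annotation, expression tables and the planted-cluster
# truth set as plain-text files under results/.

suppressPackageStartupMessages(library(methgrad))

seed <- 20260928
out <- "results"

for (sc in list(scenario_grad1(), scenario_age1(), scenario_diet1())) {
  name <- tolower(gsub("-", "", sc$name))
  dir <- file.path(out, name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  st <- simulate_study(sc, seed = seed)
  write_count_table(st$counts, file.path(dir, "counts.tsv"))
  write_sample_annotation(st$annotation, file.path(dir, "annotation.tsv"))
  utils::write.table(st$expression, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- st$locus$clusters
  truth$chrom <- st$locus$sites$chrom[1]
  write_bed6(truth, file.path(dir, "planted_clusters.bed"))
  message(sc$name, ": ", nrow(st$counts$sites), " sites x ",
          ncol(st$counts$meth), " samples -> ", dir)
}
message("done; seed ", seed)
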