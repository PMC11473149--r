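#!/usr/bin/env Rscript
# Stage 1 -- simulate the cohort.
#
# Generates the synthetic CITE-Seq cohort the rest of the workflow analyses:
# 4 healthy donors (D), 7 R1 and 3 R2 recipients, 36 clusters, 137 surface
# markers, 500 cells per patient across 2 batches, with a +1 log-abundance
# effect planted on cluster 1 in R2 and planted QC violations. Writes the
# CellRanger-style MTX triplet plus metadata and the ground truth.

suppressPackageStartupMessages(library(citecompo))

out <- "scratch/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

design <- simulation_design(cells_per_patient = 500, seed = 20240829)
sim <- simulate_dataset(design)
print(sim$dataset)

write_mtx_dataset(sim$dataset, out)
write_abundance_table(sim$truth$abundance,
                      file.path(out, "true_abundances.csv"))
jsonlite::write_json(
  list(cluster = as.list(sim$truth$cluster),
       planted_qc = sim$truth$planted_qc,
       group_abundance_effects = sim$truth$group_abundance_effects),
  file.path(out, "ground_truth.json"), auto_unbox = TRUE)

cat("cells per group:\n")
print(table(sim$dataset$cells$group_id))
cat("planted QC violations:",
    sum(lengths(sim$truth$planted_qc)), "droplets\n")
cat("wrote", out, "\n")
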