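#!/usr/bin/env Rscript
# Stage 2 -- droplet and gene quality control.
#
# Applies, per patient, the five droplet rules (empty; no mitochondrial RNA;
# total < 300; total > 10,000; mitochondrial fraction > 10%), then the
# merged-cohort singleton-transcript filter and the light-chain marker
# blacklist. Writes the QC report and the filtered dataset.

suppressPackageStartupMessages(library(citecompo))

dir.create("results", showWarnings = FALSE)

ds <- read_mtx_dataset("scratch/cohort/matrix.mtx",
                       "scratch/cohort/features.tsv",
                       "scratch/cohort/barcodes.tsv",
                       "scratch/cohort/metadata.csv")
cfg <- run_config()

dropped <- filter_droplets(ds, cfg)
print(dropped$report)
write_qc_report(dropped$report, "results/qc_report.json")

genes <- filter_singleton_genes(dropped$dataset)
cat("singleton transcripts removed:", length(genes$removed_genes), "\n")

clean <- exclude_markers(genes$dataset, cfg$marker_blacklist)
cat("surface markers kept:", sum(clean$features$kind == "surface"), "\n")

write_mtx_dataset(clean, "scratch/filtered")
cat("wrote scratch/filtered\n")
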