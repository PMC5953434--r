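#!/usr/bin/env Rscript
# Stage 5: consolidated run.
#
# Re-executes the whole pipeline through the orchestrator on the same
# simulated inputs and writes one machine-readable summary, demonstrating
# that the staged scripts and the single-call interface agree.
# Reads results/sim/, writes results/full_study/.

suppressPackageStartupMessages(library(bbbqc))

meta <- read.csv("results/sim/sample_metadata.csv")
ct <- read_ct_table("results/sim/ct_main.csv")
# the orchestrator compares GOI dosage between groups, so label the BrMV
# samples by donor genotype while the CDB pool keeps its label
df <- as.data.frame(ct)
df$group <- ifelse(df$group == "BrMV",
                   meta$genotype[match(df$sample_id, meta$sample_id)],
                   df$group)
ct2 <- as_ct_table(df)

std <- read.csv("results/sim/rg_standards.csv")
cfg <- study_config(
  ct2,
  reference_genes = c("Actb", "Gapdh", "Pgk1", "Tbp", "Hmbs"),
  marker_genes = c("Slc2a1", "Cldn5", "Pecam1", "Plvap"),
  goi = "Idua", rg = "auto",
  groups = c("WT", "CDB"),
  goi_groups = c("WT", "Het"), calibrator_group = "Het",
  standards = std[std$source == "CDB", c("gene", "quantity", "ct")],
  copy_standards = read.csv("results/sim/idua_copy_standards.csv"),
  mixing_ct = "results/sim/mixing_ct.csv",
  mixing_design = "results/sim/mixing_design.csv",
  composition = "results/sim/if_counts.csv",
  seed = 1234)
report <- run_full_study(cfg)
print(report)
write_study_report(report, "results/full_study")
cat("\nConsolidated summary written to results/full_study/\n")
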