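#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Emulates the study design: 10 paired brain-microvessel (BrMV) and
# capillary-depleted-brain (CDB) isolations (4 wild-type, 2 heterozygous and
# 4 knockout donors for the Idua gene of interest), reference-gene dilution
# series from two standard sources, a plasmid copy-number series, a
# BrMV-into-CDB mixing series for purity calibration, and
# immunofluorescence nuclei counts for the BrMV samples. All outputs are
# CSVs under results/sim/ that the later stages read back.

suppressPackageStartupMessages(library(bbbqc))
set.seed(1234)
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

panel <- default_panel()
refs <- c("Actb", "Gapdh", "Pgk1", "Tbp", "Hmbs")

## paired BrMV/CDB cohort ----------------------------------------------------
genotype <- c(rep("WT", 4), rep("Het", 2), rep("KO", 4))
alleles <- c(rep(2, 4), rep(1, 2), rep(0, 4))
brmv_comps <- sample_compositions(10, concentration = 15, seed = 101)
cdb_comps <- matrix(rep(default_cdb_composition(), 10), nrow = 10, byrow = TRUE,
                    dimnames = list(sprintf("CDB%02d", 1:10), CELL_CLASSES))
comps <- rbind(brmv_comps, cdb_comps)
# Actb is left stable; the other reference candidates carry per-sample
# instability so that the stability analysis has something to find
instability <- c(Gapdh = 0.45, Pgk1 = 0.6, Tbp = 0.3, Hmbs = 0.2)
cohort <- cohort_spec(
  rownames(comps), comps,
  group = rep(c("BrMV", "CDB"), each = 10),
  allele_count = rep(alleles, 2),
  technical_sd = 0.2, biological_sd = 0.05,
  instability_sd = instability, seed = 102)
ct <- simulate_ct(panel, cohort)
meta <- data.frame(sample_id = rownames(comps),
                   preparation = rep(c("BrMV", "CDB"), each = 10),
                   genotype = rep(genotype, 2))
write_ct_table(ct, file.path(out_dir, "ct_main.csv"))
write.csv(meta, file.path(out_dir, "sample_metadata.csv"), row.names = FALSE)
write.csv(data.frame(sample_id = rownames(comps), round(comps, 5)),
          file.path(out_dir, "true_compositions.csv"), row.names = FALSE)

## dilution series for standard curves ---------------------------------------
# a cell-line-like source (reference genes a little more abundant) and a
# CDB-like source, five 2-to-100 ng points, triplicate
dilutions <- c(100, 50, 25, 10, 2)
std <- do.call(rbind, lapply(seq_along(refs[refs != "Pgk1"]), function(k) {
  g <- refs[refs != "Pgk1"][k]
  rbind(cbind(source = "3T3",
              simulate_dilution_series(panel, g, dilutions, noise_sd = 0.15,
                                       abundance = 1.6, seed = 200 + 2 * k)),
        cbind(source = "CDB",
              simulate_dilution_series(panel, g, dilutions, noise_sd = 0.15,
                                       abundance = 1.0, seed = 201 + 2 * k)))
}))
write.csv(std, file.path(out_dir, "rg_standards.csv"), row.names = FALSE)

## plasmid copy-number series for the GOI -------------------------------------
copy_std <- simulate_dilution_series(panel, "Idua", 10^(2:7),
                                     x_unit = "copies", noise_sd = 0.15,
                                     seed = 202)
write.csv(copy_std, file.path(out_dir, "idua_copy_standards.csv"),
          row.names = FALSE)

## mixing series for purity calibration ---------------------------------------
mix <- simulate_mixing_series(panel, purities = c(0, 10, 25, 50, 75, 100),
                              technical_sd = 0.15, seed = 203)
write_ct_table(mix$ct, file.path(out_dir, "mixing_ct.csv"))
write.csv(mix$design, file.path(out_dir, "mixing_design.csv"), row.names = FALSE)

## immunofluorescence counts for the BrMV samples -----------------------------
counts <- simulate_if_counts(brmv_comps, total_nuclei = 600, seed = 204)
write.csv(counts, file.path(out_dir, "if_counts.csv"), row.names = FALSE)

cat("Simulated study written to", out_dir, "\n")
cat(sprintf("  %d replicate Ct rows (%d censored; knockouts do not amplify Idua)\n",
            nrow(ct), sum(ct$censored)))
cat(sprintf("  BrMV endothelial fractions span %.0f%%-%.0f%%\n",
            100 * min(brmv_comps[, "BrEC"]), 100 * max(brmv_comps[, "BrEC"])))
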