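#!/usr/bin/env Rscript
# Stage 2: reference-gene stability.
#
# Ranks the five candidate reference genes by geNorm M and by the
# BestKeeper descriptive index, tests each gene's Ct difference between the
# BrMV and CDB preparations, and combines everything into a single
# recommendation. Reads results/sim/, writes results/stability/.

suppressPackageStartupMessages(library(bbbqc))
out_dir <- "results/stability"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ct <- read_ct_table("results/sim/ct_main.csv")
refs <- c("Actb", "Gapdh", "Pgk1", "Tbp", "Hmbs")

q <- ct_to_quantities(ct, genes = refs)
gn <- genorm(q)
bk <- bestkeeper(ct, genes = refs)
group_p <- vapply(refs, function(g)
  compare_ct_between_groups(ct, g, "BrMV", "CDB")$p_value, numeric(1))
report <- combine_rankings(gn, bk, group_p = group_p)

write.csv(data.frame(gene = names(gn$m_values),
                     m_value = unname(gn$m_values),
                     stepwise_m = unname(gn$stepwise_m[names(gn$m_values)]),
                     above_threshold = unname(gn$m_values) > gn$m_threshold),
          file.path(out_dir, "m_values.csv"), row.names = FALSE)
write.csv(bk$stats, file.path(out_dir, "bestkeeper.csv"), row.names = FALSE)
write.csv(cbind(report$ranks, group_p = group_p[report$ranks$gene]),
          file.path(out_dir, "ranking.csv"), row.names = FALSE)
v <- pairwise_variation(q)
write.csv(data.frame(pair = names(v), v = unname(v)),
          file.path(out_dir, "pairwise_variation.csv"), row.names = FALSE)

print(gn)
print(bk)
cat("\nBrMV-vs-CDB two-tailed t-test p-values:\n")
print(round(group_p, 4))
print(report)
cat("\ngeNorm V(n/n+1) (adding genes beyond the top pair changes the\nnormalisation factor by):\n")
print(round(v, 4))
cat("\nTables written to", out_dir, "\n")
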