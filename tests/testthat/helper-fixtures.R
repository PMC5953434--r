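# Fixture builders used across test files.

# Build a one-replicate ct_table from a genes x samples matrix of Ct values
# (NA = censored).
ct_table_from_matrix <- function(mat, group = NA_character_, input_ng = 25) {
  genes <- rownames(mat)
  samples <- colnames(mat)
  grp <- rep_len(group, length(samples))
  rows <- expand.grid(gene = genes, sample_id = samples,
                      stringsAsFactors = FALSE)
  rows$run_id <- "run1"
  rows$replicate <- 1L
  rows$ct <- mat[cbind(rows$gene, rows$sample_id)]
  rows$input_ng <- input_ng
  rows$group <- grp[match(rows$sample_id, samples)]
  as_ct_table(rows)
}

# Random positive quantity matrix for oracle-equivalence sweeps.
random_quantity_matrix <- function(n_genes, n_samples) {
  q <- matrix(2^stats::rnorm(n_genes * n_samples, 0, 1),
              nrow = n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  q / apply(q, 1, max)
}

random_ct_matrix <- function(n_genes, n_samples) {
  matrix(stats::runif(n_genes * n_samples, 15, 30),
         nrow = n_genes,
         dimnames = list(paste0("g", seq_len(n_genes)),
                         paste0("s", seq_len(n_samples))))
}
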