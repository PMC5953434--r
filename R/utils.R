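# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random-number stream. seed = NULL leaves the stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

geomean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

# Mean Ct per (sample, gene): replicate duplicates are averaged within each
# run first, then run means are averaged, matching the duplicate-by-three-runs
# replicate design. Censored replicates are dropped; a (sample, gene) cell
# with no surviving replicate comes back NA.
mean_ct_by <- function(table, genes = NULL, samples = NULL) {
  df <- as.data.frame(table)
  if (!is.null(genes)) df <- df[df$gene %in% genes, , drop = FALSE]
  if (!is.null(samples)) df <- df[df$sample_id %in% samples, , drop = FALSE]
  df <- df[!df$censored & !is.na(df$ct), , drop = FALSE]
  if (nrow(df) == 0L) {
    return(data.frame(sample_id = character(), gene = character(),
                      mean_ct = numeric(), stringsAsFactors = FALSE))
  }
  run_means <- stats::aggregate(ct ~ sample_id + gene + run_id, data = df, FUN = mean)
  out <- stats::aggregate(ct ~ sample_id + gene, data = run_means, FUN = mean)
  names(out)[names(out) == "ct"] <- "mean_ct"
  out
}

# Mean Ct matrix (genes x samples); stops if a requested cell is entirely
# censored/missing unless allow_na.
ct_matrix <- function(table, genes = NULL, samples = NULL, allow_na = FALSE,
                      context = "ct_matrix") {
  df <- as.data.frame(table)
  genes <- genes %||% unique(df$gene)
  samples <- samples %||% unique(df$sample_id)
  mm <- mean_ct_by(table, genes = genes, samples = samples)
  mat <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  if (nrow(mm)) {
    mat[cbind(match(mm$gene, genes), match(mm$sample_id, samples))] <- mm$mean_ct
  }
  if (!allow_na && anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)
    stop(context, ": no non-censored Ct for (gene, sample): ",
         paste(sprintf("(%s, %s)", genes[bad[, 1]], samples[bad[, 2]]),
               collapse = "; "), call. = FALSE)
  }
  mat
}
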