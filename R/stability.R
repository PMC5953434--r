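#' Convert Ct values to relative quantities
#'
#' Standard geNorm preprocessing: for each gene, the sample with the lowest
#' mean Ct is anchored at a relative quantity of 1 and the others are scaled
#' by the amplification factor, `q = e^(minCt - Ct)`.
#'
#' @param table A `ct_table`.
#' @param efficiencies Amplification factor per gene: a single number applied
#'   to every gene (default 2, i.e. perfect doubling) or a named vector.
#' @param genes,samples Optional subsets; default all genes/samples present.
#' @return A genes x samples numeric matrix of relative quantities with
#'   attribute `"efficiencies"`. Every entry is positive and each row has
#'   maximum 1.
#' @export
ct_to_quantities <- function(table, efficiencies = 2, genes = NULL,
                             samples = NULL) {
  ct <- ct_matrix(table, genes = genes, samples = samples,
                  context = "ct_to_quantities")
  e <- efficiencies
  if (length(e) == 1L && is.null(names(e))) {
    e <- stats::setNames(rep(as.numeric(e), nrow(ct)), rownames(ct))
  }
  missing_e <- setdiff(rownames(ct), names(e))
  if (length(missing_e)) {
    stop("no amplification factor for gene(s): ",
         paste(missing_e, collapse = ", "), call. = FALSE)
  }
  if (any(e[rownames(ct)] <= 1)) stop("amplification factors must exceed 1")
  q <- ct
  for (g in rownames(ct)) {
    q[g, ] <- e[[g]]^(min(ct[g, ]) - ct[g, ])
  }
  attr(q, "efficiencies") <- e[rownames(ct)]
  q
}

# Single-pass geNorm: V_jk = SD over samples of log2(q_j/q_k), M_j = mean
# of V_jk over k != j.
genorm_pass <- function(lq) {
  n <- nrow(lq)
  genes <- rownames(lq)
  v <- matrix(0, n, n, dimnames = list(genes, genes))
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j < k) {
        s <- stats::sd(lq[j, ] - lq[k, ])
        v[j, k] <- s
        v[k, j] <- s
      }
    }
  }
  list(m = rowSums(v) / (n - 1L), v = v)
}

#' geNorm reference-gene stability
#'
#' Computes the geNorm stability measure M for each candidate reference gene:
#' the average pairwise variation of that gene with all other candidates,
#' where the pairwise variation V_jk is the standard deviation across samples
#' of the log2 expression ratio of genes j and k. Lower M means more stable;
#' genes with M below 0.5 are conventionally acceptable in homogeneous sample
#' sets. With `stepwise = TRUE` the gene with the largest M is repeatedly
#' removed and M recomputed until two genes remain; those two are jointly the
#' most stable (their M values are equal by construction at that stage).
#'
#' @param quantities Genes x samples matrix of positive relative quantities
#'   (see [ct_to_quantities()]); at least 3 genes and 2 samples.
#' @param stepwise Perform stepwise exclusion (default `TRUE`).
#' @param m_threshold Conventional acceptability cutoff carried into the
#'   result (default 0.5).
#' @return An object of class `"genorm_result"`: `m_values` (full-panel
#'   single-pass M per gene), `pairwise_sd` (symmetric V_jk matrix),
#'   `exclusion_order` (genes from least to most stable),
#'   `ranking` (most to least stable; reverse of `exclusion_order`),
#'   `stepwise_m` (M values at the step each gene was excluded),
#'   `m_threshold`.
#' @details Ties in the stepwise argmax are broken by excluding the
#'   lexicographically first of the tied gene identifiers; the final pair is
#'   appended in lexicographic order.
#' @export
genorm <- function(quantities, stepwise = TRUE, m_threshold = 0.5) {
  q <- as.matrix(quantities)
  if (nrow(q) < 3L) stop("insufficient panel: geNorm needs >= 3 genes", call. = FALSE)
  if (ncol(q) < 2L) stop("geNorm needs >= 2 samples", call. = FALSE)
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("relative quantities must be finite and positive", call. = FALSE)
  }
  lq <- log2(q)
  full <- genorm_pass(lq)

  exclusion <- character(0)
  stepwise_m <- numeric(0)
  keep <- rownames(q)
  if (stepwise) {
    while (length(keep) > 2L) {
      m_step <- genorm_pass(lq[keep, , drop = FALSE])$m
      worst_m <- max(m_step)
      worst <- sort(names(m_step)[m_step == worst_m])[1L]
      exclusion <- c(exclusion, worst)
      stepwise_m <- c(stepwise_m, stats::setNames(worst_m, worst))
      keep <- setdiff(keep, worst)
    }
    # the final pair is jointly most stable (equal M by construction);
    # report it ordered by full-panel M, lexicographic on ties
    final <- keep[order(-full$m[keep], keep)]
    final_m <- genorm_pass(lq[keep, , drop = FALSE])$m
    exclusion <- c(exclusion, final)
    stepwise_m <- c(stepwise_m, final_m[final])
  } else {
    exclusion <- names(full$m)[order(-full$m, names(full$m))]
    stepwise_m <- full$m[exclusion]
  }

  structure(list(m_values = full$m,
                 pairwise_sd = full$v,
                 exclusion_order = exclusion,
                 ranking = rev(exclusion),
                 stepwise_m = stepwise_m,
                 m_threshold = m_threshold),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  cat("geNorm stability (single-pass M, full panel):\n")
  m <- sort(x$m_values)
  for (g in names(m)) {
    cat(sprintf("  %-8s M = %.4f%s\n", g, m[[g]],
                if (m[[g]] > x$m_threshold) "  (above threshold)" else ""))
  }
  cat("Stepwise ranking (most -> least stable): ",
      paste(x$ranking, collapse = " > "), "\n", sep = "")
  invisible(x)
}

#' geNorm pairwise-variation sequence V(n/n+1)
#'
#' How many reference genes are enough: the normalisation factor NF_n is the
#' per-sample geometric mean of the n most stable genes' relative quantities;
#' V(n/n+1) is the standard deviation across samples of
#' log2(NF_n / NF_(n+1)). Small V (conventionally < 0.15) means adding the
#' (n+1)-th gene changes the normalisation factor little.
#'
#' @param quantities Genes x samples matrix of positive relative quantities.
#' @param order Stability order, most stable first; defaults to the stepwise
#'   [genorm()] ranking of `quantities`.
#' @return Named numeric vector `V2/3`, `V3/4`, ...
#' @export
pairwise_variation <- function(quantities, order = NULL) {
  q <- as.matrix(quantities)
  if (nrow(q) < 3L) stop("insufficient panel: needs >= 3 genes", call. = FALSE)
  if (any(!is.finite(q)) || any(q <= 0)) {
    stop("relative quantities must be finite and positive", call. = FALSE)
  }
  order <- order %||% genorm(q)$ranking
  if (!setequal(order, rownames(q)) || anyDuplicated(order)) {
    stop("order must be a permutation of the gene panel", call. = FALSE)
  }
  nf <- function(n) apply(q[order[seq_len(n)], , drop = FALSE], 2L, geomean)
  ns <- 2:(nrow(q) - 1L)
  v <- vapply(ns, function(n) stats::sd(log2(nf(n) / nf(n + 1L))), numeric(1L))
  stats::setNames(v, sprintf("V%d/%d", ns, ns + 1L))
}

#' BestKeeper descriptive stability statistics
#'
#' BestKeeper judges candidate reference genes on raw Ct scale: per-gene
#' descriptive statistics of the sample mean Ct (geometric and arithmetic
#' mean, min, max), a dispersion statistic `sd_ct` (mean absolute deviation
#' around the arithmetic mean Ct; around the geometric mean with
#' `sd_around = "geometric"`), `cv_pct = 100 * sd_ct / arith_mean_ct`, and
#' the Pearson correlation of each gene's Ct with the BestKeeper index (the
#' per-sample geometric mean Ct across the panel), with a two-sided p-value
#' from the t distribution on n - 2 degrees of freedom. Genes are ranked by
#' ascending `sd_ct` (lower dispersion = more stable).
#'
#' @param table A `ct_table`.
#' @param genes Candidate panel (default: every gene in `table`); >= 2 genes.
#' @param samples Samples to use (default all); >= 3 samples.
#' @param sd_around Centre for the mean-absolute-deviation dispersion:
#'   `"arithmetic"` (default) or `"geometric"`.
#' @return An object of class `"bestkeeper_result"`: `stats` (one row per
#'   gene), `index_ct` (named per-sample index) and `ranking`. A gene with
#'   zero Ct variance gets `r_index`/`p_index` `NA` with the note
#'   `"constant input"`.
#' @export
bestkeeper <- function(table, genes = NULL, samples = NULL,
                       sd_around = c("arithmetic", "geometric")) {
  sd_around <- match.arg(sd_around)
  ct <- ct_matrix(table, genes = genes, samples = samples,
                  context = "bestkeeper")
  if (nrow(ct) < 2L) stop("BestKeeper needs >= 2 genes", call. = FALSE)
  if (ncol(ct) < 3L) stop("BestKeeper needs >= 3 samples", call. = FALSE)
  index <- apply(ct, 2L, geomean)
  n <- ncol(ct)
  rows <- lapply(rownames(ct), function(g) {
    x <- ct[g, ]
    centre <- if (sd_around == "arithmetic") mean(x) else geomean(x)
    sd_ct <- mean(abs(x - centre))
    note <- ""
    if (stats::sd(x) == 0) {
      r <- NA_real_
      p <- NA_real_
      note <- "constant input"
    } else {
      r <- stats::cor(x, index)
      tstat <- r * sqrt((n - 2L) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2L)
    }
    data.frame(gene = g, n = n,
               geo_mean_ct = geomean(x), arith_mean_ct = mean(x),
               min_ct = min(x), max_ct = max(x),
               sd_ct = sd_ct, cv_pct = 100 * sd_ct / mean(x),
               r_index = r, p_index = p, note = note,
               stringsAsFactors = FALSE)
  })
  stats_df <- do.call(rbind, rows)
  rownames(stats_df) <- NULL
  structure(list(stats = stats_df,
                 index_ct = index,
                 ranking = stats_df$gene[order(stats_df$sd_ct, stats_df$gene)],
                 sd_around = sd_around),
            class = "bestkeeper_result")
}

#' @export
print.bestkeeper_result <- function(x, ...) {
  cat("BestKeeper descriptive statistics (ranked by SD of Ct):\n")
  s <- x$stats[match(x$ranking, x$stats$gene), ]
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s SD = %.3f  CV%% = %.2f  r(index) = %s\n",
                s$gene[i], s$sd_ct[i], s$cv_pct[i],
                if (is.na(s$r_index[i])) paste0("NA (", s$note[i], ")")
                else sprintf("%.3f (p = %.3g)", s$r_index[i], s$p_index[i])))
  }
  invisible(x)
}

#' Combine geNorm and BestKeeper rankings
#'
#' Averages the two methods' ranks per gene (geNorm: stepwise stability order;
#' BestKeeper: ascending SD of Ct). Ties in the average are broken by the
#' lower full-panel geNorm M. Optionally, genes whose expression differs
#' between two sample groups (e.g. BrMV vs CDB, from
#' [compare_ct_between_groups()]) at `p < p_veto` are demoted below all
#' non-vetoed genes — a stability veto across preparations.
#'
#' @param genorm_result A [genorm()] result.
#' @param bestkeeper_result A [bestkeeper()] result on the same gene panel.
#' @param group_p Optional named vector of between-group p-values per gene.
#' @param p_veto Demotion threshold applied to `group_p` (default 0.05).
#' @return An object of class `"stability_report"`: `ranks` (per-gene data
#'   frame with both ranks, the average, `vetoed` and the final
#'   `combined_rank`, a permutation of 1..n), `recommended` (top gene),
#'   plus the two input results.
#' @export
combine_rankings <- function(genorm_result, bestkeeper_result,
                             group_p = NULL, p_veto = 0.05) {
  gn_genes <- names(genorm_result$m_values)
  bk_genes <- bestkeeper_result$stats$gene
  if (!setequal(gn_genes, bk_genes)) {
    stop("gene panel mismatch between geNorm and BestKeeper results: ",
         paste(c(setdiff(gn_genes, bk_genes), setdiff(bk_genes, gn_genes)),
               collapse = ", "), call. = FALSE)
  }
  genes <- sort(gn_genes)
  gn_rank <- match(genes, genorm_result$ranking)
  # final stepwise pair is jointly most stable: share rank 1.5
  gn_rank[gn_rank <= 2L] <- 1.5
  bk_rank <- match(genes, bestkeeper_result$ranking)
  avg <- (gn_rank + bk_rank) / 2
  vetoed <- rep(FALSE, length(genes))
  if (!is.null(group_p)) {
    vetoed <- !is.na(group_p[genes]) & group_p[genes] < p_veto
  }
  m <- genorm_result$m_values[genes]
  ord <- order(vetoed, avg, m, genes)
  combined <- integer(length(genes))
  combined[ord] <- seq_along(genes)
  ranks <- data.frame(gene = genes, genorm_rank = gn_rank,
                      bestkeeper_rank = bk_rank, mean_rank = avg,
                      m_value = unname(m), vetoed = vetoed,
                      combined_rank = combined, stringsAsFactors = FALSE)
  ranks <- ranks[order(ranks$combined_rank), ]
  rownames(ranks) <- NULL
  structure(list(ranks = ranks,
                 recommended = ranks$gene[1L],
                 genorm = genorm_result,
                 bestkeeper = bestkeeper_result),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Combined reference-gene stability ranking:\n")
  print(x$ranks, row.names = FALSE)
  cat("Recommended reference gene:", x$recommended, "\n")
  invisible(x)
}
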