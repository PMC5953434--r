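# Independent brute-force oracles, deliberately written as plain loops over
# definitions so they share no code path with the package implementation.

# geNorm M: for each gene, average over all other genes of the SD across
# samples of the pairwise log2 ratio.
oracle_genorm_m <- function(q) {
  genes <- rownames(q)
  m <- numeric(length(genes))
  names(m) <- genes
  for (j in genes) {
    acc <- c()
    for (k in genes) {
      if (k == j) next
      ratio <- log2(q[j, ] / q[k, ])
      mu <- sum(ratio) / length(ratio)
      acc <- c(acc, sqrt(sum((ratio - mu)^2) / (length(ratio) - 1)))
    }
    m[j] <- mean(acc)
  }
  m
}

# BestKeeper descriptives recomputed from first principles on a Ct matrix
# (genes x samples of per-sample mean Ct).
oracle_bestkeeper <- function(ct) {
  genes <- rownames(ct)
  n <- ncol(ct)
  index <- numeric(n)
  for (s in seq_len(n)) index[s] <- prod(ct[, s])^(1 / nrow(ct))
  out <- list()
  for (g in genes) {
    x <- ct[g, ]
    am <- sum(x) / n
    gm <- prod(x)^(1 / n)
    sd_mad <- sum(abs(x - am)) / n
    # Pearson r by the textbook sum formula
    num <- sum((x - mean(x)) * (index - mean(index)))
    den <- sqrt(sum((x - mean(x))^2) * sum((index - mean(index))^2))
    r <- if (den == 0) NA_real_ else num / den
    p <- if (is.na(r)) NA_real_ else {
      tt <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }
    out[[g]] <- c(geo_mean = gm, arith_mean = am, min = min(x), max = max(x),
                  sd = sd_mad, cv = 100 * sd_mad / am, r = r, p = p)
  }
  out$index <- index
  out
}

# V(n/n+1) from definitions.
oracle_pairwise_variation <- function(q, order) {
  ns <- 2:(nrow(q) - 1)
  v <- numeric(length(ns))
  for (i in seq_along(ns)) {
    n <- ns[i]
    nf_n <- apply(q[order[1:n], , drop = FALSE], 2, function(col) prod(col)^(1 / n))
    nf_n1 <- apply(q[order[1:(n + 1)], , drop = FALSE], 2,
                   function(col) prod(col)^(1 / (n + 1)))
    v[i] <- stats::sd(log2(nf_n / nf_n1))
  }
  v
}

oracle_pearson <- function(x, y) {
  num <- sum((x - mean(x)) * (y - mean(y)))
  num / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
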