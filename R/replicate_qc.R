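#' Replicate summaries: intra- and inter-assay variation
#'
#' Summarises replicate-level Ct values per (sample, gene), following the
#' duplicate-within-run, three-runs design: `"intra_run"` computes the
#' coefficient of variation over duplicates within each run and averages it
#' over runs; `"inter_run"` computes the CV over run-level mean Ct values.
#' The CV is `100 * sd / mean` with the n-1 denominator for sd. Censored
#' replicates are excluded and counted in `n_censored`.
#'
#' @param table A [as_ct_table()] object.
#' @param level `"intra_run"` or `"inter_run"`.
#' @return A data frame with one row per (sample, gene): `mean_ct`, `sd_ct`,
#'   `cv_pct`, `n_runs`, `n_replicates`, `n_censored`, `absent`. A summary is
#'   flagged `absent` (all statistics `NA`, with a warning) when every
#'   replicate is censored or fewer than two usable replicates exist at the
#'   requested level.
#' @examples
#' tab <- as_ct_table(data.frame(sample_id = "S1", gene = "Actb",
#'   run_id = "r1", replicate = 1:2, ct = c(19.8, 20.2)))
#' summarize_replicates(tab, "intra_run")
#' @export
summarize_replicates <- function(table, level = c("intra_run", "inter_run")) {
  level <- match.arg(level)
  df <- as.data.frame(table)
  pieces <- split(df, list(df$sample_id, df$gene), drop = TRUE)
  rows <- lapply(pieces, function(d) {
    obs <- d[!d$censored, , drop = FALSE]
    n_cens <- sum(d$censored)
    base <- data.frame(sample_id = d$sample_id[1L], gene = d$gene[1L],
                       mean_ct = NA_real_, sd_ct = NA_real_, cv_pct = NA_real_,
                       n_runs = 0L, n_replicates = nrow(obs),
                       n_censored = n_cens, absent = TRUE,
                       stringsAsFactors = FALSE)
    if (nrow(obs) == 0L) {
      warning("all replicates censored for (", d$sample_id[1L], ", ",
              d$gene[1L], "); summary flagged absent", call. = FALSE)
      return(base)
    }
    runs <- split(obs$ct, obs$run_id)
    run_means <- vapply(runs, mean, numeric(1L))
    base$n_runs <- length(runs)
    base$mean_ct <- mean(run_means)
    if (level == "intra_run") {
      full <- runs[lengths(runs) >= 2L]
      if (length(full) == 0L) {
        warning("fewer than 2 replicates in every run for (", d$sample_id[1L],
                ", ", d$gene[1L], "); intra-run summary flagged absent",
                call. = FALSE)
        return(base)
      }
      sds <- vapply(full, stats::sd, numeric(1L))
      cvs <- 100 * sds / vapply(full, mean, numeric(1L))
      base$sd_ct <- mean(sds)
      base$cv_pct <- mean(cvs)
    } else {
      if (length(run_means) < 2L) {
        warning("fewer than 2 runs for (", d$sample_id[1L], ", ", d$gene[1L],
                "); inter-run summary flagged absent", call. = FALSE)
        return(base)
      }
      base$sd_ct <- stats::sd(run_means)
      base$cv_pct <- 100 * base$sd_ct / base$mean_ct
    }
    base$absent <- FALSE
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$sample_id, out$gene), , drop = FALSE]
}

#' RNA quality-control gate
#'
#' Checks UV absorbance ratios and the 28S/18S rRNA integrity ratio against
#' configurable windows. A record passes when every *present* ratio is inside
#' its window; a ratio that is absent (`NA`) skips its check and is recorded
#' in `reasons` as "not assessed".
#'
#' @param records Data frame with `sample_id` and any of `a260_280`,
#'   `a260_230`, `rrna_28s_18s` columns.
#' @param thresholds List with `a260_280` (length-2 window, default
#'   `c(1.9, 2.2)`), `a260_230_min` (default 1.8) and `rrna_min` (default
#'   1.0, exclusive).
#' @return Data frame with `sample_id`, `pass` and a `reasons` string
#'   (semicolon-separated; failed checks and "not assessed" notes).
#' @export
qc_gate <- function(records,
                    thresholds = list(a260_280 = c(1.9, 2.2),
                                      a260_230_min = 1.8,
                                      rrna_min = 1.0)) {
  records <- as.data.frame(records)
  if (!"sample_id" %in% names(records)) stop("records need a sample_id column")
  get_col <- function(col) {
    if (col %in% names(records)) as.numeric(records[[col]]) else rep(NA_real_, nrow(records))
  }
  a280 <- get_col("a260_280")
  a230 <- get_col("a260_230")
  rrna <- get_col("rrna_28s_18s")
  present_ok <- function(x) !is.na(x) & x > 0
  if (any(!is.na(c(a280, a230, rrna)) & c(a280, a230, rrna) <= 0)) {
    stop("QC ratios must be positive when present", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(records)), function(i) {
    reasons <- character(0)
    fail <- FALSE
    if (is.na(a280[i])) {
      reasons <- c(reasons, "260/280 not assessed")
    } else if (a280[i] < thresholds$a260_280[1L] || a280[i] > thresholds$a260_280[2L]) {
      fail <- TRUE
      reasons <- c(reasons, sprintf("260/280 = %.2f outside [%.2f, %.2f]",
                                    a280[i], thresholds$a260_280[1L], thresholds$a260_280[2L]))
    }
    if (is.na(a230[i])) {
      reasons <- c(reasons, "260/230 not assessed")
    } else if (a230[i] < thresholds$a260_230_min) {
      fail <- TRUE
      reasons <- c(reasons, sprintf("260/230 = %.2f below %.2f",
                                    a230[i], thresholds$a260_230_min))
    }
    if (is.na(rrna[i])) {
      reasons <- c(reasons, "28S/18S not assessed")
    } else if (rrna[i] <= thresholds$rrna_min) {
      fail <- TRUE
      reasons <- c(reasons, sprintf("28S/18S = %.2f not above %.2f",
                                    rrna[i], thresholds$rrna_min))
    }
    data.frame(sample_id = as.character(records$sample_id[i]),
               pass = !fail,
               reasons = paste(reasons, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compare mean Ct of one gene between two sample groups
#'
#' Two-tailed two-sample t-test on per-sample mean Ct (duplicates averaged
#' within runs, then across runs). The equal-variance Student test is the
#' default; Welch's correction is available via `var_equal = FALSE`.
#'
#' @param table A `ct_table` with a `group` column.
#' @param gene Gene to test.
#' @param group_a,group_b Group labels (e.g. `"BrMV"`, `"CDB"`).
#' @param var_equal Pool variances (Student) if `TRUE` (default).
#' @return List with `gene`, `group_means` (named), `t`, `df`, `p_value`,
#'   `method`, of class `"ct_group_test"`.
#' @export
compare_ct_between_groups <- function(table, gene, group_a, group_b,
                                      var_equal = TRUE) {
  df <- as.data.frame(table)
  df <- df[df$gene == gene, , drop = FALSE]
  means <- mean_ct_by(df)
  grp <- df$group[match(means$sample_id, df$sample_id)]
  xa <- means$mean_ct[grp == group_a]
  xb <- means$mean_ct[grp == group_b]
  if (length(xa) < 2L || length(xb) < 2L) {
    stop("insufficient data: need >= 2 samples with non-censored Ct per group (",
         group_a, ": ", length(xa), ", ", group_b, ": ", length(xb), ")",
         call. = FALSE)
  }
  tt <- stats::t.test(xa, xb, var.equal = var_equal)
  structure(list(gene = gene,
                 group_means = stats::setNames(c(mean(xa), mean(xb)),
                                               c(group_a, group_b)),
                 t = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 method = if (var_equal) "Student" else "Welch"),
            class = "ct_group_test")
}

#' @export
print.ct_group_test <- function(x, ...) {
  cat(sprintf("%s t-test on %s: t = %.3f (df = %.1f), p = %.4g\n",
              x$method, x$gene, x$t, x$df, x$p_value))
  cat(sprintf("  group means (Ct): %s = %.2f, %s = %.2f\n",
              names(x$group_means)[1L], x$group_means[1L],
              names(x$group_means)[2L], x$group_means[2L]))
  invisible(x)
}
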