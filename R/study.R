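# Orchestration of the full evaluation: stability -> reference-gene choice
# -> standard curves -> quantification -> purity -> composition correlation.

#' Configure a full microvessel qPCR study
#'
#' Bundles the input tables and analysis choices for [run_full_study()].
#' Inputs may be in-memory tables or CSV paths (read via [read_ct_table()] /
#' `read.csv`).
#'
#' @param ct Main `ct_table` (or CSV path): BrMV/CDB samples, all genes.
#' @param reference_genes Candidate reference-gene panel.
#' @param marker_genes Purity marker genes.
#' @param goi Gene of interest for dosage validation (optional).
#' @param rg `"auto"` (use the combined-ranking recommendation) or a gene
#'   from `reference_genes`.
#' @param groups Length-2 labels of the preparation groups compared for
#'   stability (default `c("BrMV", "CDB")`).
#' @param calibrator_group Group whose samples form the ddCt calibrator for
#'   the GOI comparison (default the second entry of `goi_groups`).
#' @param goi_groups Length-2 group labels compared for the GOI fold ratio
#'   (e.g. `c("WT", "Het")`); optional.
#' @param standards Optional data frame/CSV of RNA dilution standards:
#'   `gene`, `quantity`, `ct` (replicate rows allowed).
#' @param copy_standards Optional copy-number standards for the GOI:
#'   `quantity` (copies), `ct`.
#' @param mixing_ct,mixing_design Optional mixing-series `ct_table` and
#'   design (`sample_id`, `purity_pct`) for purity calibration.
#' @param composition Optional nuclei-count table (see
#'   [composition_from_counts()]).
#' @param consensus_markers Markers averaged into consensus purity
#'   (default `c("Cldn5", "Pecam1")`).
#' @param thresholds List: `m` (geNorm cutoff, 0.5), `plvap_fold` (40),
#'   `background_ct` (30), `min_nuclei` (500), `p_veto` (0.05).
#' @param seed Seed recorded with the report.
#' @return An object of class `"study_config"`.
#' @export
study_config <- function(ct, reference_genes, marker_genes, goi = NULL,
                         rg = "auto", groups = c("BrMV", "CDB"),
                         calibrator_group = NULL, goi_groups = NULL,
                         standards = NULL, copy_standards = NULL,
                         mixing_ct = NULL, mixing_design = NULL,
                         composition = NULL,
                         consensus_markers = c("Cldn5", "Pecam1"),
                         thresholds = list(), seed = NULL) {
  load_ct <- function(x) {
    if (is.null(x)) NULL
    else if (is.character(x) && length(x) == 1L) read_ct_table(x)
    else as_ct_table(x)
  }
  load_df <- function(x) {
    if (is.null(x)) NULL
    else if (is.character(x) && length(x) == 1L) {
      utils::read.csv(x, stringsAsFactors = FALSE)
    } else as.data.frame(x)
  }
  thr <- utils::modifyList(list(m = 0.5, plvap_fold = 40, background_ct = 30,
                                min_nuclei = 500, p_veto = 0.05), thresholds)
  if (any(unlist(thr) <= 0)) stop("thresholds must be positive", call. = FALSE)
  if (!identical(rg, "auto") && !rg %in% reference_genes) {
    stop("chosen reference gene '", rg, "' is not in the reference panel",
         call. = FALSE)
  }
  if (!all(consensus_markers %in% marker_genes)) {
    stop("consensus markers must be a subset of marker_genes", call. = FALSE)
  }
  structure(list(ct = load_ct(ct), reference_genes = reference_genes,
                 marker_genes = marker_genes, goi = goi, rg = rg,
                 groups = groups,
                 calibrator_group = calibrator_group %||% goi_groups[2L],
                 goi_groups = goi_groups,
                 standards = load_df(standards),
                 copy_standards = load_df(copy_standards),
                 mixing_ct = load_ct(mixing_ct),
                 mixing_design = load_df(mixing_design),
                 composition = load_df(composition),
                 consensus_markers = consensus_markers,
                 thresholds = thr, seed = seed),
            class = "study_config")
}

#' Run the full microvessel evaluation study
#'
#' Executes, in order: reference-gene stability (geNorm + BestKeeper +
#' between-group t-tests, combined ranking), reference-gene selection,
#' standard curves with amplification efficiencies, GOI quantification
#' (ddCt fold ratio between groups, and absolute copies when copy standards
#' are supplied), marker purity calibration and scoring with the Plvap
#' fenestration flag, composition fractions and the purity-vs-lectin
#' correlation. Stages whose inputs are absent are skipped; warnings are
#' accumulated in the bundle.
#'
#' @param config A [study_config()].
#' @return An object of class `"study_report"`: a list with elements
#'   `stability`, `rg`, `curves`, `quantification`, `purity`, `composition`,
#'   `correlation`, `warnings`, `config_summary`.
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  warnings_log <- character(0)
  note <- function(...) warnings_log <<- c(warnings_log, paste0(...))
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      note(conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }
  ct <- config$ct
  groups <- config$groups

  # --- stability on the reference panel -------------------------------------
  q <- ct_to_quantities(ct, genes = config$reference_genes)
  gn <- genorm(q)
  bk <- bestkeeper(ct, genes = config$reference_genes)
  group_p <- vapply(config$reference_genes, function(g) {
    tryCatch(compare_ct_between_groups(ct, g, groups[1L], groups[2L])$p_value,
             error = function(e) NA_real_)
  }, numeric(1L))
  stab <- combine_rankings(gn, bk, group_p = group_p,
                           p_veto = config$thresholds$p_veto)
  rg <- if (identical(config$rg, "auto")) stab$recommended else config$rg

  # --- standard curves ------------------------------------------------------
  curves <- NULL
  if (!is.null(config$standards)) {
    std <- config$standards
    curves <- lapply(split(std, std$gene), function(d) {
      fit_standard_curve(d$quantity, d$ct, x_unit = "ng", gene = d$gene[1L])
    })
  }

  # --- GOI quantification ---------------------------------------------------
  quant <- NULL
  if (!is.null(config$goi) && !is.null(config$goi_groups)) {
    df <- as.data.frame(ct)
    cal_samples <- unique(df$sample_id[df$group == config$calibrator_group])
    test_group <- setdiff(config$goi_groups, config$calibrator_group)[1L]
    test_samples <- unique(df$sample_id[df$group == test_group])
    fc <- collect(delta_delta_ct(ct, goi = config$goi, rg = rg,
                                 calibrator = cal_samples,
                                 samples = union(test_samples, cal_samples)))
    grp <- df$group[match(fc$sample_id, df$sample_id)]
    ratio <- mean(fc$fold_change[grp == test_group]) /
      mean(fc$fold_change[grp == config$calibrator_group])
    quant <- list(fold_changes = fc, fold_ratio = ratio,
                  groups = c(test_group, config$calibrator_group))
    if (!is.null(config$copy_standards)) {
      copy_curve <- fit_standard_curve(config$copy_standards$quantity,
                                       config$copy_standards$ct,
                                       x_unit = "copies", gene = config$goi,
                                       source = "plasmid")
      abs_q <- collect(absolute_quantify(ct, goi = config$goi,
                                         copy_curve = copy_curve,
                                         samples = union(test_samples, cal_samples)))
      agrp <- df$group[match(abs_q$sample_id, df$sample_id)]
      quant$copy_curve <- copy_curve
      quant$copies <- abs_q
      quant$copies_ratio <- mean(abs_q$copies_per_ng[agrp == test_group]) /
        mean(abs_q$copies_per_ng[agrp == config$calibrator_group])
    }
  }

  # --- purity ---------------------------------------------------------------
  purity <- NULL
  if (!is.null(config$mixing_ct) && !is.null(config$mixing_design)) {
    cals <- lapply(config$marker_genes, function(mk) {
      tryCatch(fit_purity_calibration(config$mixing_ct, mk, rg,
                                      config$mixing_design),
               error = function(e) {
                 note("marker ", mk, " calibration failed: ", conditionMessage(e))
                 NULL
               })
    })
    names(cals) <- config$marker_genes
    cals <- Filter(Negate(is.null), cals)
    df <- as.data.frame(ct)
    cdb_pool <- unique(df$sample_id[df$group == groups[2L]])
    # every preparation that is not part of the CDB pool gets a purity score
    brmv_samples <- unique(df$sample_id[df$group != groups[2L]])
    folds <- do.call(rbind, lapply(names(cals), function(mk) {
      fc <- collect(delta_delta_ct(ct, goi = mk, rg = rg,
                                   calibrator = cdb_pool,
                                   samples = brmv_samples))
      data.frame(sample_id = fc$sample_id, marker = mk,
                 fold_change = fc$fold_change, stringsAsFactors = FALSE)
    }))
    scores <- score_purity(folds, cals,
                           consensus_markers = config$consensus_markers)
    flags <- if ("Plvap" %in% df$gene) {
      collect(plvap_indicator(ct, rg = rg, cdb_pool_id = cdb_pool,
                              threshold_fold = config$thresholds$plvap_fold,
                              background_ct = config$thresholds$background_ct,
                              samples = brmv_samples))
    } else NULL
    purity <- list(calibrations = cals, scores = scores, flags = flags)
  }

  # --- composition and correlation ------------------------------------------
  comp <- NULL
  correlation <- NULL
  if (!is.null(config$composition)) {
    comp <- collect(composition_from_counts(config$composition,
                                            min_nuclei = config$thresholds$min_nuclei))
    if (!is.null(purity)) {
      pur_df <- data.frame(sample_id = purity$scores$samples$sample_id,
                           purity_pct = purity$scores$samples$consensus_purity)
      correlation <- tryCatch(correlate_purity(pur_df, comp),
                              error = function(e) {
                                note("correlation skipped: ", conditionMessage(e))
                                NULL
                              })
    }
  }

  structure(list(stability = stab, rg = rg, curves = curves,
                 quantification = quant, purity = purity,
                 composition = comp, correlation = correlation,
                 warnings = warnings_log,
                 config_summary = list(reference_genes = config$reference_genes,
                                       marker_genes = config$marker_genes,
                                       goi = config$goi, rg_mode = config$rg,
                                       thresholds = config$thresholds,
                                       seed = config$seed)),
            class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("== Brain-microvessel qPCR study report ==\n")
  cat("Selected reference gene:", x$rg, "\n")
  print(x$stability)
  if (!is.null(x$quantification)) {
    cat(sprintf("GOI fold ratio (%s / %s): %.3f (ddCt)\n",
                x$quantification$groups[1L], x$quantification$groups[2L],
                x$quantification$fold_ratio))
    if (!is.null(x$quantification$copies_ratio)) {
      cat(sprintf("GOI copies/ng ratio: %.3f (absolute)\n",
                  x$quantification$copies_ratio))
    }
  }
  if (!is.null(x$purity)) print(x$purity$scores)
  if (!is.null(x$correlation)) {
    cat(sprintf("Purity vs lectin+ fraction: r = %.3f, r^2 = %.3f (n = %d)\n",
                x$correlation$r, x$correlation$r_squared, x$correlation$n))
  }
  if (length(x$warnings)) {
    cat(length(x$warnings), "warning(s) accumulated; see $warnings\n")
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits one machine-readable JSON summary (`study_summary.json`, versioned
#' schema) plus tidy CSV side files (`ranking.csv`, `m_values.csv`,
#' `bestkeeper.csv`, and when present `curves.csv`, `fold_changes.csv`,
#' `copies.csv`, `purity.csv`, `flags.csv`, `composition.csv`).
#'
#' @param report A [run_full_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  w(report$stability$ranks, "ranking.csv")
  w(data.frame(gene = names(report$stability$genorm$m_values),
               m_value = unname(report$stability$genorm$m_values)),
    "m_values.csv")
  w(report$stability$bestkeeper$stats, "bestkeeper.csv")
  if (!is.null(report$curves)) {
    w(do.call(rbind, lapply(report$curves, function(cv) {
      data.frame(gene = cv$gene %||% NA, slope = cv$slope,
                 intercept = cv$intercept, efficiency_pct = cv$efficiency_pct,
                 r_squared = cv$r_squared)
    })), "curves.csv")
  }
  if (!is.null(report$quantification)) {
    w(report$quantification$fold_changes, "fold_changes.csv")
    if (!is.null(report$quantification$copies)) w(report$quantification$copies, "copies.csv")
  }
  if (!is.null(report$purity)) {
    w(merge(report$purity$scores$per_marker, report$purity$scores$samples,
            by = "sample_id"), "purity.csv")
    if (!is.null(report$purity$flags)) w(report$purity$flags, "flags.csv")
  }
  if (!is.null(report$composition)) {
    comp <- cbind(sample_id = rownames(report$composition$fractions),
                  report$composition$fractions)
    w(comp, "composition.csv")
  }
  summary <- list(
    schema_version = "1.0",
    reference_gene = report$rg,
    stability = list(
      ranking = report$stability$ranks$gene,
      m_values = as.list(report$stability$genorm$m_values),
      recommended = report$stability$recommended),
    efficiencies = if (!is.null(report$curves)) {
      lapply(report$curves, function(cv) cv$efficiency_pct)
    },
    goi_fold_ratio = report$quantification$fold_ratio,
    goi_copies_ratio = report$quantification$copies_ratio,
    purity = if (!is.null(report$purity)) {
      stats::setNames(as.list(report$purity$scores$samples$consensus_purity),
                      report$purity$scores$samples$sample_id)
    },
    fenestration_flags = if (!is.null(report$purity$flags)) {
      stats::setNames(as.list(report$purity$flags$fenestration_flag),
                      report$purity$flags$sample_id)
    },
    correlation = if (!is.null(report$correlation)) {
      report$correlation[c("n", "r", "r_squared")]
    },
    warnings = report$warnings,
    config = report$config_summary)
  jsonlite::write_json(summary, file.path(dir, "study_summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}
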