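#' Fit a marker-gene relative-purity calibration
#'
#' Calibrates marker-gene fold change (vs a capillary-depleted-brain pool)
#' against relative purity using a mixing series: standards made by mixing a
#' designated "100%" BrMV sample into the "0%" CDB pool at known
#' percentages. Fold changes are computed by [delta_delta_ct()] against the
#' 0% standards, so the 0% point has fold 1 by construction; the line is fit
#' by ordinary least squares of fold on purity percentage with a free
#' intercept and the (0, 1) point included.
#'
#' @param mixing_table A `ct_table` of the mixing standards.
#' @param marker Marker gene (e.g. `Cldn5`).
#' @param rg Reference gene (e.g. `Actb`).
#' @param design Data frame with `sample_id` and `purity_pct` (0-100); must
#'   contain at least 3 distinct purity levels including 0 and 100.
#' @return An object of class `"purity_calibration"`: `marker`, `rg`,
#'   `points` (purity_pct, fold_change), `slope` (fold per percent, must be
#'   positive), `intercept`, `r_squared`, `calibrator_pool_id`,
#'   `reference_sample_id`.
#' @export
fit_purity_calibration <- function(mixing_table, marker, rg, design) {
  design <- as.data.frame(design)
  stopifnot(all(c("sample_id", "purity_pct") %in% names(design)))
  levels_pct <- unique(design$purity_pct)
  if (!(0 %in% levels_pct) || !(100 %in% levels_pct)) {
    stop("design error: mixing series must include 0% and 100% standards",
         call. = FALSE)
  }
  if (length(levels_pct) < 3L) {
    stop("design error: need >= 3 distinct purity levels", call. = FALSE)
  }
  pool <- design$sample_id[design$purity_pct == 0]
  fc <- delta_delta_ct(mixing_table, goi = marker, rg = rg,
                       calibrator = pool, samples = design$sample_id)
  pts <- data.frame(purity_pct = design$purity_pct[match(fc$sample_id, design$sample_id)],
                    fold_change = fc$fold_change)
  fit <- stats::lm(fold_change ~ purity_pct, data = pts)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope <= 1e-10) {
    stop("invalid marker: ", marker,
         " fold change does not increase with purity (slope = ",
         format(slope), ")", call. = FALSE)
  }
  ss_tot <- sum((pts$fold_change - mean(pts$fold_change))^2)
  structure(list(marker = marker, rg = rg, points = pts,
                 slope = slope, intercept = intercept,
                 r_squared = 1 - sum(stats::residuals(fit)^2) / ss_tot,
                 calibrator_pool_id = pool,
                 reference_sample_id = design$sample_id[design$purity_pct == 100]),
            class = "purity_calibration")
}

#' @export
print.purity_calibration <- function(x, ...) {
  cat(sprintf("Purity calibration [%s vs %s]: fold = %.4f + %.4f * purity%%  (R^2 = %.4f)\n",
              x$marker, x$rg, x$intercept, x$slope, x$r_squared))
  invisible(x)
}

#' Score sample purity from marker fold changes
#'
#' Inverts each marker's calibration line,
#' `purity = (fold - intercept) / slope`, and averages the configured
#' consensus markers into a consensus purity. Purities above 100% (samples
#' purer than the designated 100% standard) or below 0% (below the CDB
#' calibrator) are reported verbatim with notes, never clipped.
#'
#' @param sample_folds Data frame with `sample_id`, `marker`, `fold_change`
#'   (e.g. rows of [delta_delta_ct()] per marker).
#' @param calibrations Named list of [fit_purity_calibration()] objects,
#'   one per marker.
#' @param consensus_markers Markers averaged into the consensus (default
#'   `c("Cldn5", "Pecam1")`; Slc2a1 is conventionally reported but excluded).
#' @return An object of class `"purity_result"`: `per_marker` (long data
#'   frame sample x marker with fold and purity), `samples` (one row per
#'   sample with `consensus_purity` and `notes`).
#' @export
score_purity <- function(sample_folds, calibrations,
                         consensus_markers = c("Cldn5", "Pecam1")) {
  sf <- as.data.frame(sample_folds)
  stopifnot(all(c("sample_id", "marker", "fold_change") %in% names(sf)))
  missing_cal <- setdiff(consensus_markers, names(calibrations))
  if (length(missing_cal)) {
    stop("no calibration for consensus marker(s): ",
         paste(missing_cal, collapse = ", "), call. = FALSE)
  }
  missing_fold <- setdiff(consensus_markers, unique(sf$marker))
  if (length(missing_fold)) {
    stop("no fold change for consensus marker(s): ",
         paste(missing_fold, collapse = ", "), call. = FALSE)
  }
  sf <- sf[sf$marker %in% names(calibrations), , drop = FALSE]
  sf$purity_pct <- vapply(seq_len(nrow(sf)), function(i) {
    cal <- calibrations[[sf$marker[i]]]
    (sf$fold_change[i] - cal$intercept) / cal$slope
  }, numeric(1L))
  per_sample <- lapply(split(sf, sf$sample_id), function(d) {
    cp <- mean(d$purity_pct[d$marker %in% consensus_markers])
    notes <- character(0)
    above <- d$marker[d$purity_pct > 100]
    below <- d$marker[d$purity_pct < 0]
    if (length(above)) notes <- c(notes, paste0("above 100% standard: ",
                                                paste(above, collapse = ", ")))
    if (length(below)) notes <- c(notes, paste0("below CDB calibrator: ",
                                                paste(below, collapse = ", ")))
    data.frame(sample_id = d$sample_id[1L], consensus_purity = cp,
               notes = paste(notes, collapse = "; "), stringsAsFactors = FALSE)
  })
  samples <- do.call(rbind, per_sample)
  rownames(samples) <- NULL
  structure(list(per_marker = sf[order(sf$sample_id, sf$marker), ],
                 samples = samples,
                 consensus_markers = consensus_markers),
            class = "purity_result")
}

#' @export
print.purity_result <- function(x, ...) {
  cat("Relative purities (consensus of ",
      paste(x$consensus_markers, collapse = " + "), "):\n", sep = "")
  print(x$samples, row.names = FALSE)
  invisible(x)
}

#' Plvap fenestrated-vessel indicator
#'
#' Brain-barrier endothelium silences Plvap, so a BrMV preparation whose
#' Plvap fold change over the CDB pool strictly exceeds the threshold
#' (default 40-fold) likely carries fenestrated, non-barrier vessels
#' (choroid plexus, meninges) and is flagged. The CDB pool itself should sit
#' at near-background Plvap levels; a pool mean Ct at or below
#' `background_ct` (default 30) triggers a contaminated-calibrator warning.
#'
#' @param table A `ct_table` containing the Plvap gene.
#' @param rg Reference gene for the ddCt fold.
#' @param cdb_pool_id Sample id(s) of the CDB calibrator pool.
#' @param threshold_fold Strict flag threshold (default 40).
#' @param background_ct Background Ct for the pool check (default 30).
#' @param samples Samples to evaluate (default: all but the pool).
#' @param plvap_gene Gene identifier (default `"Plvap"`).
#' @return Data frame per sample: `plvap_fold`, `fenestration_flag`,
#'   `censored`. A censored Plvap maps to fold 0 and no flag.
#' @export
plvap_indicator <- function(table, rg, cdb_pool_id, threshold_fold = 40,
                            background_ct = 30, samples = NULL,
                            plvap_gene = "Plvap") {
  fc <- delta_delta_ct(table, goi = plvap_gene, rg = rg,
                       calibrator = cdb_pool_id, samples = samples)
  pool_ct <- ct_matrix(table, genes = plvap_gene, samples = cdb_pool_id,
                       allow_na = TRUE)[plvap_gene, ]
  if (any(!is.na(pool_ct) & pool_ct <= background_ct)) {
    warning("CDB pool Plvap Ct <= ", background_ct,
            ": calibrator itself may contain fenestrated vessels",
            call. = FALSE)
  }
  data.frame(sample_id = fc$sample_id,
             plvap_fold = fc$fold_change,
             fenestration_flag = fc$fold_change > threshold_fold,
             censored = fc$censored,
             stringsAsFactors = FALSE)
}

#' Rescale qPCR relative purity to endothelial-cell content
#'
#' Relative purity is defined against an arbitrary "100%" standard, so it is
#' anchored to an immunofluorescence-measured endothelial fraction by
#' proportional rescaling: `brec = purity * anchor_brec / anchor_qpcr`
#' (e.g. an anchor pair of 115% qPCR purity corresponding to 92% BrEC).
#'
#' @param purity Relative purity (percent), vectorised.
#' @param anchor Length-2 numeric `c(qpcr = ..., brec = ...)`: one sample's
#'   qPCR purity and its IF-derived BrEC percentage, both positive.
#' @return Estimated BrEC content (percent).
#' @export
rescale_to_brec <- function(purity, anchor) {
  if (missing(anchor) || is.null(anchor) || length(anchor) != 2L ||
      anyNA(anchor) || any(anchor <= 0)) {
    stop("rescaling requires an anchor pair c(qpcr = , brec = ) from an ",
         "IF-anchored sample, both components positive", call. = FALSE)
  }
  anchor <- unname(anchor)
  purity * anchor[2L] / anchor[1L]
}
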