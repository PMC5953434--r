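#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10(quantity) over a dilution series.
#' The amplification efficiency follows from the slope:
#' `E% = 100 * (10^(-1/slope) - 1)`, so a perfect 10-fold series with a Ct
#' step of log2(10) = 3.3219 cycles per dilution gives 100% (doubling per
#' cycle).
#'
#' @param quantity Positive quantities (RNA ng or template copies);
#'   replicate rows at the same quantity are allowed. At least 3 distinct
#'   values are required.
#' @param ct Non-censored Ct values, same length as `quantity`.
#' @param x_unit `"ng"` (RNA mass) or `"copies"` (template copy number).
#' @param gene,source Optional labels (gene assayed; standard-sample type,
#'   e.g. `"3T3"`, `"CDB"`, `"plasmid"`).
#' @return An object of class `"standard_curve"`: `slope` (cycles per log10
#'   unit, negative), `intercept` (Ct at 1 x-unit), `r_squared`,
#'   `efficiency_pct`, `x_unit`, `gene`, `source`, `ct_range` (range of the
#'   fitted Ct values, used to flag extrapolation), `n`.
#' @export
fit_standard_curve <- function(quantity, ct, x_unit = c("ng", "copies"),
                               gene = NULL, source = NULL) {
  x_unit <- match.arg(x_unit)
  quantity <- as.numeric(quantity)
  ct <- as.numeric(ct)
  if (length(quantity) != length(ct)) stop("quantity and ct lengths differ")
  if (anyNA(ct)) stop("censored/missing Ct in standard series", call. = FALSE)
  if (any(quantity <= 0)) stop("quantities must be positive", call. = FALSE)
  if (length(unique(quantity)) < 3L) {
    stop("insufficient points: need >= 3 distinct quantities", call. = FALSE)
  }
  fit <- stats::lm(ct ~ log10(quantity))
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (slope >= 0) {
    stop("degenerate curve: nonnegative slope (", format(slope),
         "); dilution series inverted or corrupt", call. = FALSE)
  }
  ss_tot <- sum((ct - mean(ct))^2)
  r_squared <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(gene = gene, source = source,
                 slope = slope, intercept = intercept,
                 r_squared = r_squared,
                 efficiency_pct = 100 * (10^(-1 / slope) - 1),
                 x_unit = x_unit, ct_range = range(ct),
                 n = length(ct)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("Standard curve%s%s: Ct = %.3f %+.4f * log10(%s)\n",
              if (is.null(x$gene)) "" else paste0(" [", x$gene, "]"),
              if (is.null(x$source)) "" else paste0(" (", x$source, ")"),
              x$intercept, x$slope, x$x_unit))
  cat(sprintf("  efficiency = %.1f%%, R^2 = %.4f, n = %d\n",
              x$efficiency_pct, x$r_squared, x$n))
  invisible(x)
}

#' Interpolate a quantity from a standard curve
#'
#' Inverts the fitted line: `quantity = 10^((ct - intercept) / slope)`.
#' Ct values outside the fitted range are extrapolated but flagged.
#'
#' @param curve A [fit_standard_curve()] object.
#' @param ct Ct values; `NA` means censored (no amplification). For a
#'   copy-number curve a censored Ct maps to 0 copies with a censored flag;
#'   for an RNA-input curve it is an error (the reference gene must amplify).
#' @return Numeric vector of quantities with attributes `"extrapolated"` and
#'   `"censored"` (logical vectors).
#' @export
interpolate_quantity <- function(curve, ct) {
  stopifnot(inherits(curve, "standard_curve"))
  ct <- as.numeric(ct)
  censored <- is.na(ct)
  if (any(censored) && curve$x_unit != "copies") {
    stop("censored Ct cannot be interpolated on an RNA-input curve",
         call. = FALSE)
  }
  q <- 10^((ct - curve$intercept) / curve$slope)
  q[censored] <- 0
  extrap <- !censored & (ct < curve$ct_range[1L] | ct > curve$ct_range[2L])
  if (any(extrap)) {
    warning(sum(extrap), " Ct value(s) outside the fitted range [",
            sprintf("%.2f, %.2f", curve$ct_range[1L], curve$ct_range[2L]),
            "]; extrapolated", call. = FALSE)
  }
  attr(q, "extrapolated") <- extrap
  attr(q, "censored") <- censored
  q
}

#' Relative quantification by the delta-delta-Ct method
#'
#' For each sample, `ddCt = (Ct_goi - Ct_rg)_sample - (Ct_goi - Ct_rg)_cal`
#' and `fold = 2^(-ddCt)`. When several calibrator samples are given (a
#' calibrator group), their mean delta-Ct is the reference, so group-level
#' fold changes are per-sample folds against the group-mean calibrator.
#' Replicates are aggregated to a mean Ct (duplicates within runs, then
#' across runs) before any subtraction. With `efficiency_corrected = TRUE`
#' the Pfaffl form is used instead:
#' `fold = e_goi^(dCt_goi) / e_rg^(dCt_rg)` with `dCt = Ct_cal - Ct_sample`
#' per gene and per-gene amplification factors.
#'
#' @param table A `ct_table`.
#' @param goi Gene of interest.
#' @param rg Reference gene; a censored reference gene is a hard error.
#' @param calibrator Sample id(s) forming the calibrator; must have
#'   non-censored Ct for both genes.
#' @param samples Samples to quantify (default: all samples in `table`).
#' @param efficiency_corrected Use the Pfaffl form (default `FALSE`; the
#'   plain ddCt form assumes amplification factor 2 for both genes).
#' @param efficiencies Named amplification factors (needs `goi` and `rg`
#'   entries) for the Pfaffl form.
#' @return Data frame with one row per sample: `sample_id`, `goi`, `rg`,
#'   `calibrator`, `delta_ct`, `delta_delta_ct`, `fold_change`, `censored`.
#'   A sample with censored GOI (no amplification, e.g. a knockout) gets
#'   `fold_change = 0` and `censored = TRUE`.
#' @export
delta_delta_ct <- function(table, goi, rg, calibrator, samples = NULL,
                           efficiency_corrected = FALSE,
                           efficiencies = c(goi = 2, rg = 2)) {
  df <- as.data.frame(table)
  samples <- samples %||% setdiff(unique(df$sample_id), calibrator)
  all_samp <- union(samples, calibrator)
  mm <- ct_matrix(df, genes = c(goi, rg), samples = all_samp, allow_na = TRUE)
  rg_ct <- mm[rg, ]
  goi_ct <- mm[goi, ]
  if (anyNA(rg_ct)) {
    stop("censored reference gene Ct for sample(s): ",
         paste(all_samp[is.na(rg_ct)], collapse = ", "),
         " (the normalizer must amplify)", call. = FALSE)
  }
  if (anyNA(goi_ct[calibrator])) {
    stop("censored GOI Ct in calibrator sample(s): ",
         paste(calibrator[is.na(goi_ct[calibrator])], collapse = ", "),
         call. = FALSE)
  }
  cal_dct <- mean(goi_ct[calibrator] - rg_ct[calibrator])
  if (efficiency_corrected) {
    e_goi <- efficiencies[["goi"]]
    e_rg <- efficiencies[["rg"]]
    cal_goi <- mean(goi_ct[calibrator])
    cal_rg <- mean(rg_ct[calibrator])
  }
  rows <- lapply(samples, function(s) {
    cens <- is.na(goi_ct[[s]])
    if (cens) {
      dct <- NA_real_
      ddct <- NA_real_
      fold <- 0
    } else {
      dct <- goi_ct[[s]] - rg_ct[[s]]
      ddct <- dct - cal_dct
      fold <- if (efficiency_corrected) {
        e_goi^(cal_goi - goi_ct[[s]]) / e_rg^(cal_rg - rg_ct[[s]])
      } else {
        2^(-ddct)
      }
    }
    data.frame(sample_id = s, goi = goi, rg = rg,
               calibrator = paste(calibrator, collapse = "+"),
               delta_ct = dct, delta_delta_ct = ddct, fold_change = fold,
               censored = cens, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Absolute quantification against a copy-number standard curve
#'
#' Converts each sample's GOI Ct to template copies via a plasmid copy-number
#' curve and divides by the RNA input of the reaction. The input is either
#' the nominal mass recorded with the measurements (`input_mode = "nominal"`)
#' or re-estimated from a reference-gene RNA standard curve
#' (`input_mode = "rg_curve"`).
#'
#' @param table A `ct_table` (with `input_ng` populated for nominal mode).
#' @param goi Gene of interest.
#' @param copy_curve A [fit_standard_curve()] with `x_unit = "copies"`.
#' @param input_mode `"nominal"` or `"rg_curve"`.
#' @param rg,rg_curve Reference gene and its RNA-input curve
#'   (`x_unit = "ng"`), required for `input_mode = "rg_curve"`.
#' @param samples Samples to quantify (default all).
#' @return Data frame per sample: `copies`, `rna_input_ng`, `copies_per_ng`,
#'   `input_source`, `censored`. Censored GOI maps to 0 copies with
#'   `censored = TRUE`.
#' @export
absolute_quantify <- function(table, goi, copy_curve,
                              input_mode = c("nominal", "rg_curve"),
                              rg = NULL, rg_curve = NULL, samples = NULL) {
  input_mode <- match.arg(input_mode)
  stopifnot(inherits(copy_curve, "standard_curve"))
  if (copy_curve$x_unit != "copies") {
    stop("copy_curve must have x_unit = \"copies\"", call. = FALSE)
  }
  df <- as.data.frame(table)
  samples <- samples %||% unique(df$sample_id)
  goi_ct <- ct_matrix(df, genes = goi, samples = samples, allow_na = TRUE)[goi, ]
  copies <- suppressWarnings(interpolate_quantity(copy_curve, goi_ct))
  if (input_mode == "nominal") {
    inp <- vapply(samples, function(s) {
      v <- unique(df$input_ng[df$sample_id == s & !is.na(df$input_ng)])
      if (length(v) == 0L) NA_real_ else mean(v)
    }, numeric(1L))
    if (anyNA(inp)) {
      stop("nominal input_ng missing for sample(s): ",
           paste(samples[is.na(inp)], collapse = ", "), call. = FALSE)
    }
  } else {
    if (is.null(rg) || is.null(rg_curve)) {
      stop("input_mode = \"rg_curve\" requires rg and rg_curve", call. = FALSE)
    }
    stopifnot(inherits(rg_curve, "standard_curve"))
    if (rg_curve$x_unit != "ng") stop("rg_curve must have x_unit = \"ng\"", call. = FALSE)
    rg_ct <- ct_matrix(df, genes = rg, samples = samples, allow_na = TRUE)[rg, ]
    if (anyNA(rg_ct)) {
      stop("censored reference gene Ct for sample(s): ",
           paste(samples[is.na(rg_ct)], collapse = ", "), call. = FALSE)
    }
    inp <- suppressWarnings(as.numeric(interpolate_quantity(rg_curve, rg_ct)))
  }
  if (any(inp <= 0)) stop("nonpositive estimated RNA input", call. = FALSE)
  out <- data.frame(sample_id = samples, goi = goi,
                    copies = as.numeric(copies),
                    rna_input_ng = unname(inp),
                    copies_per_ng = as.numeric(copies) / unname(inp),
                    input_source = input_mode,
                    censored = attr(copies, "censored"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
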