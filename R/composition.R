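# Immunofluorescence composition tables and their correlation with
# qPCR-derived purity.

#' Cell-class labels used for immunofluorescence counts
#'
#' Lectin stains endothelium (the target class), CD68 microglia/brain
#' macrophages, GFAP astrocytes, NeuN neurons, PDGFRb pericytes; the
#' remainder of the DAPI nuclei is `other`.
#' @export
IF_CLASSES <- c("lectin_pos", "cd68_pos", "gfap_pos", "neun_pos", "pdgfrb_pos")

#' Build a composition table from nuclei counts
#'
#' Converts per-class nuclei counts into fractions of total DAPI+ nuclei.
#' The unlabeled remainder (`total - sum of labeled classes`) is assigned to
#' `other`; a labeled sum exceeding the total is an integrity error. Samples
#' with `total_nuclei <= min_nuclei` (default 500, matching the
#' more-than-500-nuclei counting rule) are flagged under-sampled with a
#' warning but are not excluded.
#'
#' @param counts Long data frame with `sample_id`, `class` (subset of
#'   [IF_CLASSES]), `count` (nonnegative integers) and `total_nuclei`.
#' @param min_nuclei Under-sampling threshold (default 500).
#' @return An object of class `"composition_table"`: `counts` (wide, one row
#'   per sample incl. `other` and `total_nuclei`), `fractions` (same shape,
#'   rows sum to 1), `undersampled` (named logical).
#' @export
composition_from_counts <- function(counts, min_nuclei = 500) {
  counts <- as.data.frame(counts)
  stopifnot(all(c("sample_id", "class", "count", "total_nuclei") %in% names(counts)))
  bad_class <- setdiff(unique(counts$class), IF_CLASSES)
  if (length(bad_class)) {
    stop("unknown cell class(es): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts$count < 0) || any(counts$count != round(counts$count))) {
    stop("counts must be nonnegative integers", call. = FALSE)
  }
  per_sample <- lapply(split(counts, counts$sample_id), function(d) {
    total <- unique(d$total_nuclei)
    if (length(total) != 1L) {
      stop("inconsistent total_nuclei for sample ", d$sample_id[1L], call. = FALSE)
    }
    cc <- stats::setNames(rep(0, length(IF_CLASSES)), IF_CLASSES)
    cc[d$class] <- d$count
    labeled <- sum(cc)
    if (labeled > total) {
      stop("integrity error: labeled counts (", labeled, ") exceed total nuclei (",
           total, ") for sample ", d$sample_id[1L], call. = FALSE)
    }
    c(cc, other = total - labeled, total_nuclei = total)
  })
  wide <- do.call(rbind, per_sample)
  classes <- c(IF_CLASSES, "other")
  fractions <- wide[, classes, drop = FALSE] / wide[, "total_nuclei"]
  undersampled <- wide[, "total_nuclei"] <= min_nuclei
  if (any(undersampled)) {
    warning("under-sampled (<= ", min_nuclei, " nuclei): ",
            paste(rownames(wide)[undersampled], collapse = ", "), call. = FALSE)
  }
  structure(list(counts = as.data.frame(wide),
                 fractions = as.data.frame(fractions),
                 undersampled = undersampled,
                 min_nuclei = min_nuclei),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("Cell composition (fractions of DAPI+ nuclei):\n")
  print(round(x$fractions, 3))
  if (any(x$undersampled)) {
    cat("Under-sampled (<= ", x$min_nuclei, " nuclei): ",
        paste(names(x$undersampled)[x$undersampled], collapse = ", "), "\n",
        sep = "")
  }
  invisible(x)
}

#' Correlate qPCR purity with immunofluorescence composition
#'
#' Pearson correlation (r and r^2) between qPCR-derived relative purity and
#' the endothelial (lectin+) nuclei fraction across shared samples, plus the
#' correlation of the lectin+ fraction with each contaminating class's
#' fraction. Spearman rank correlation is available as a robustness check.
#'
#' @param purities Data frame with `sample_id` and `purity_pct` (or a named
#'   numeric vector of purities).
#' @param composition A [composition_from_counts()] object.
#' @param target_class Endothelial class column (default `"lectin_pos"`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List: `n`, `r`, `r_squared`, `p_value` (purity vs target
#'   fraction) and `class_correlations` (named r of target fraction vs each
#'   other class).
#' @export
correlate_purity <- function(purities, composition,
                             target_class = "lectin_pos",
                             method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(composition, "composition_table"))
  if (is.numeric(purities) && !is.null(names(purities))) {
    purities <- data.frame(sample_id = names(purities),
                           purity_pct = as.numeric(purities))
  }
  purities <- as.data.frame(purities)
  stopifnot(all(c("sample_id", "purity_pct") %in% names(purities)))
  shared <- intersect(purities$sample_id, rownames(composition$fractions))
  if (length(shared) < 3L) {
    stop("insufficient data: need >= 3 shared samples (have ",
         length(shared), ")", call. = FALSE)
  }
  x <- purities$purity_pct[match(shared, purities$sample_id)]
  y <- composition$fractions[shared, target_class]
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  others <- setdiff(colnames(composition$fractions), c(target_class, "total_nuclei"))
  class_cor <- vapply(others, function(cl) {
    f <- composition$fractions[shared, cl]
    if (stats::sd(f) == 0) NA_real_ else stats::cor(y, f, method = method)
  }, numeric(1L))
  list(n = length(shared),
       method = method,
       r = unname(ct$estimate),
       r_squared = unname(ct$estimate)^2,
       p_value = ct$p.value,
       class_correlations = class_cor)
}
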