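# Seeded generative model of the study's measurement process: cell-type
# mixtures -> bulk transcript abundance -> Ct values with replicate noise.

#' Cell classes of the neurovascular unit used by the generator
#' @export
CELL_CLASSES <- c("BrEC", "pericyte", "astrocyte", "neuron", "microglia",
                  "fenestrated_EC", "other")

#' Default gene panel for simulated brain-microvessel qPCR
#'
#' Five reference genes (Actb, Gapdh, Pgk1, Tbp, Hmbs; expressed equally in
#' every cell class), four endothelial marker genes (Slc2a1, Cldn5, Pecam1
#' enriched in barrier endothelium; Plvap expressed only in fenestrated
#' endothelium) and one gene of interest (Idua, a ubiquitous lysosomal
#' enzyme whose abundance scales with allele dosage). Per-gene Ct intercepts
#' are calibrated so that a default BrMV-like mixture measured at 25 ng per
#' reaction lands inside the conventional Ct windows for this panel
#' (Actb 14-17 ... Plvap 25-28, Idua 24-26), and a parenchymal sample shows
#' near-background Plvap (Ct > 30).
#'
#' @param input_ng RNA input used for the Ct calibration (default 25).
#' @return An object of class `"panel_spec"`: `genes` (data frame with
#'   `gene`, `role`, `efficiency` amplification factor, `intercept` = Ct of
#'   unit abundance at 1 ng), `expression` (genes x classes abundance per
#'   ng), `classes`, `ct_cap` (censoring cap, 40 cycles), `ct_range`
#'   (calibration windows), `goi`.
#' @export
default_panel <- function(input_ng = 25) {
  classes <- CELL_CLASSES
  genes <- c("Actb", "Gapdh", "Pgk1", "Tbp", "Hmbs",
             "Slc2a1", "Cldn5", "Pecam1", "Plvap", "Idua")
  roles <- c(rep("reference", 5L), rep("marker", 4L), "goi")
  x <- matrix(0, nrow = length(genes), ncol = length(classes),
              dimnames = list(genes, classes))
  x[c("Actb", "Gapdh", "Pgk1", "Tbp", "Hmbs", "Idua"), ] <- 1
  x["Slc2a1", ] <- c(1, 0.03, 0.15, 0.03, 0.03, 0.5, 0.03)
  x["Cldn5", ]  <- c(1, 0.01, 0.01, 0.01, 0.01, 0.3, 0.01)
  x["Pecam1", ] <- c(1, 0.02, 0.02, 0.02, 0.02, 1.0, 0.02)
  x["Plvap", ]  <- c(0, 0, 0, 0, 0, 1, 0)

  # Ct window midpoints the intercepts are calibrated to (BrMV mixture).
  ct_range <- rbind(Actb = c(14, 17), Gapdh = c(15, 17), Pgk1 = c(18, 20),
                    Tbp = c(21, 23), Hmbs = c(22, 24), Slc2a1 = c(15, 17),
                    Cldn5 = c(17, 18), Pecam1 = c(19, 20), Plvap = c(25, 28),
                    Idua = c(24, 26))
  target_ct <- rowMeans(ct_range)
  efficiency <- stats::setNames(rep(2, length(genes)), genes)
  f_brmv <- default_brmv_composition()
  m <- as.numeric(x %*% f_brmv)
  intercept <- target_ct[genes] + log(m * input_ng) / log(efficiency)

  panel <- structure(list(genes = data.frame(gene = genes, role = roles,
                                             efficiency = unname(efficiency),
                                             intercept = unname(intercept),
                                             stringsAsFactors = FALSE),
                          expression = x, classes = classes,
                          ct_cap = 40, ct_range = ct_range, goi = "Idua"),
                     class = "panel_spec")
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  x <- panel$expression
  refs <- panel$genes$gene[panel$genes$role == "reference"]
  if (any(x[refs, , drop = FALSE] <= 0)) {
    stop("reference genes must be expressed (> 0) in every cell class",
         call. = FALSE)
  }
  parenchyma <- setdiff(panel$classes, c("BrEC", "fenestrated_EC"))
  markers <- panel$genes$gene[panel$genes$role == "marker"]
  for (g in markers) {
    plvap_like <- all(x[g, setdiff(panel$classes, "fenestrated_EC")] == 0)
    if (plvap_like) next
    if (any(x[g, parenchyma] >= x[g, "BrEC"])) {
      stop("marker ", g, " must be enriched in BrEC over every parenchymal class",
           call. = FALSE)
    }
  }
  if (any(panel$genes$efficiency <= 1 | panel$genes$efficiency > 2.2)) {
    stop("amplification factors must lie in (1, 2.2]", call. = FALSE)
  }
  invisible(panel)
}

#' Default cell compositions for BrMV and CDB preparations
#'
#' A typical microvessel isolate is about two-thirds endothelium with
#' pericyte, neuron, microglial and astrocytic contaminants and a trace of
#' fenestrated (non-barrier) vessels; the capillary-depleted brain fraction
#' is almost entirely parenchyma.
#' @return Named probability vector over [CELL_CLASSES].
#' @export
default_brmv_composition <- function() {
  stats::setNames(c(0.66, 0.09, 0.04, 0.09, 0.10, 0.005, 0.015), CELL_CLASSES)
}

#' @rdname default_brmv_composition
#' @export
default_cdb_composition <- function() {
  stats::setNames(c(0.01, 0.05, 0.30, 0.40, 0.12, 0.0002, 0.1198), CELL_CLASSES)
}

#' Specify a simulated cohort
#'
#' @param sample_id Sample identifiers.
#' @param compositions Matrix (samples x [CELL_CLASSES]) of cell-class
#'   fractions; rows must be probability vectors.
#' @param group Group label per sample (recycled).
#' @param allele_count GOI expressing-allele count per sample, 0/1/2
#'   (recycled; default 2).
#' @param input_ng RNA input per reaction (recycled; default 25).
#' @param technical_sd Per-replicate technical noise on Ct, cycles
#'   (default 0.3, giving replicate CVs at the 1-2% level around Ct 20).
#' @param biological_sd Per-(sample, gene) biological noise on log2
#'   abundance (default 0.15).
#' @param instability_sd Named per-gene extra instability SD on Ct (cycles);
#'   emulates a gene that is differentially regulated across samples.
#' @param group_ct_shift Optional named list, gene -> named numeric of Ct
#'   shifts per group label; emulates a reference gene whose expression is
#'   confounded with the group (systematically up- or down-regulated in one
#'   preparation or genotype).
#' @param runs,duplicates Replicate design (default 3 runs x 2 duplicates).
#' @param seed RNG seed; fixed seed gives byte-identical output.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(sample_id, compositions, group = "BrMV",
                        allele_count = 2, input_ng = 25,
                        technical_sd = 0.3, biological_sd = 0.15,
                        instability_sd = NULL, group_ct_shift = NULL,
                        runs = 3, duplicates = 2, seed = NULL) {
  compositions <- as.matrix(compositions)
  if (is.null(rownames(compositions))) rownames(compositions) <- sample_id
  compositions <- compositions[sample_id, CELL_CLASSES, drop = FALSE]
  if (any(compositions < 0) ||
      any(abs(rowSums(compositions) - 1) > 1e-8)) {
    stop("invalid composition: rows must be probability vectors over cell classes",
         call. = FALSE)
  }
  if (!all(allele_count %in% c(0, 1, 2))) {
    stop("allele_count must be 0, 1 or 2", call. = FALSE)
  }
  n <- length(sample_id)
  structure(list(samples = data.frame(sample_id = sample_id,
                                      group = rep_len(group, n),
                                      allele_count = rep_len(allele_count, n),
                                      input_ng = rep_len(input_ng, n),
                                      stringsAsFactors = FALSE),
                 compositions = compositions,
                 technical_sd = technical_sd, biological_sd = biological_sd,
                 instability_sd = instability_sd %||% numeric(0),
                 group_ct_shift = group_ct_shift,
                 runs = runs, duplicates = duplicates, seed = seed),
            class = "cohort_spec")
}

#' Simulate a replicate-level Ct table for a cohort
#'
#' For sample s and gene g the bulk abundance is the composition-weighted
#' expression `m = sum_c f_c * x_gc`, scaled by `allele_count / 2` for the
#' gene of interest. The noiseless Ct is
#' `Ct0 = intercept_g - log(m * input_ng) / log(e_g)`; a per-(sample, gene)
#' biological effect (log2-abundance SD `biological_sd`, plus any per-gene
#' instability SD in cycles) and per-replicate technical noise (SD
#' `technical_sd` cycles) are added. Zero abundance, or a Ct beyond the
#' cycle cap, is censored (no amplification by cycle 40).
#'
#' @param panel A [default_panel()]-style `panel_spec`.
#' @param cohort A [cohort_spec()].
#' @param genes Genes to simulate (default: whole panel).
#' @return A [as_ct_table()] object; deterministic given the cohort seed.
#' @export
simulate_ct <- function(panel, cohort, genes = NULL) {
  stopifnot(inherits(panel, "panel_spec"), inherits(cohort, "cohort_spec"))
  genes <- genes %||% panel$genes$gene
  gi <- panel$genes[match(genes, panel$genes$gene), ]
  if (anyNA(gi$gene)) stop("gene(s) not in panel", call. = FALSE)
  samp <- cohort$samples
  with_seed(cohort$seed, {
    rows <- vector("list", nrow(samp) * length(genes))
    idx <- 0L
    for (si in seq_len(nrow(samp))) {
      f <- cohort$compositions[samp$sample_id[si], ]
      for (gj in seq_along(genes)) {
        g <- genes[gj]
        e <- gi$efficiency[gj]
        m <- sum(f * panel$expression[g, ])
        if (g == panel$goi) m <- m * samp$allele_count[si] / 2
        nrep <- cohort$runs * cohort$duplicates
        if (m <= 0) {
          ct <- rep(NA_real_, nrep)
        } else {
          ct0 <- gi$intercept[gj] - log(m * samp$input_ng[si]) / log(e)
          sh <- cohort$group_ct_shift[[g]]
          if (!is.null(sh) && samp$group[si] %in% names(sh)) {
            ct0 <- ct0 + sh[[samp$group[si]]]
          }
          bio <- stats::rnorm(1L, 0, cohort$biological_sd) * log(2) / log(e)
          inst_sd <- cohort$instability_sd[g]
          inst <- if (!is.na(inst_sd) && length(inst_sd) && inst_sd > 0) {
            stats::rnorm(1L, 0, inst_sd)
          } else 0
          ct <- ct0 - bio + inst +
            stats::rnorm(nrep, 0, cohort$technical_sd)
          ct[ct > panel$ct_cap] <- NA_real_
        }
        idx <- idx + 1L
        rows[[idx]] <- data.frame(
          sample_id = samp$sample_id[si], gene = g,
          run_id = paste0("run", rep(seq_len(cohort$runs), each = cohort$duplicates)),
          replicate = rep(seq_len(cohort$duplicates), times = cohort$runs),
          ct = ct, input_ng = samp$input_ng[si], group = samp$group[si],
          stringsAsFactors = FALSE)
      }
    }
    as_ct_table(do.call(rbind, rows))
  })
}

#' Simulate a standard-curve dilution series
#'
#' On-curve Ct values for a gene at the given quantities, plus optional
#' technical noise. For `x_unit = "ng"` the series emulates serially diluted
#' total RNA from a source with per-ng abundance `abundance` for the gene;
#' for `x_unit = "copies"` it emulates a plasmid copy-number series with
#' `ct_at_one_copy` as the Ct of a single template copy.
#'
#' @param panel A `panel_spec`.
#' @param gene Gene assayed.
#' @param quantities Strictly positive quantities (ng or copies).
#' @param replicates Replicate reactions per quantity (default 3).
#' @param noise_sd Technical Ct noise SD (default 0).
#' @param x_unit `"ng"` or `"copies"`.
#' @param abundance Per-ng transcript abundance of the source material
#'   (default 1, a reference-gene-like source).
#' @param ct_at_one_copy Ct of one template copy (default 38).
#' @param seed RNG seed.
#' @return Data frame with `gene`, `quantity`, `x_unit`, `replicate`, `ct`,
#'   ready for [fit_standard_curve()].
#' @export
simulate_dilution_series <- function(panel, gene, quantities, replicates = 3,
                                     noise_sd = 0,
                                     x_unit = c("ng", "copies"),
                                     abundance = 1, ct_at_one_copy = 38,
                                     seed = NULL) {
  x_unit <- match.arg(x_unit)
  stopifnot(inherits(panel, "panel_spec"))
  if (any(quantities <= 0)) stop("quantities must be positive", call. = FALSE)
  gi <- panel$genes[panel$genes$gene == gene, ]
  if (nrow(gi) != 1L) stop("gene not in panel: ", gene, call. = FALSE)
  e <- gi$efficiency
  ct0 <- if (x_unit == "ng") {
    gi$intercept - log(abundance * quantities) / log(e)
  } else {
    ct_at_one_copy - log(quantities) / log(e)
  }
  with_seed(seed, {
    df <- data.frame(gene = gene,
                     quantity = rep(quantities, each = replicates),
                     x_unit = x_unit,
                     replicate = rep(seq_len(replicates), times = length(quantities)),
                     ct = rep(ct0, each = replicates) +
                       stats::rnorm(length(quantities) * replicates, 0, noise_sd),
                     stringsAsFactors = FALSE)
    df
  })
}

#' Simulate a purity mixing series
#'
#' Standards are convex combinations, at the cell-composition level, of a
#' designated 100% BrMV sample and the 0% CDB pool:
#' `f_p = (p/100) * f_brmv + (1 - p/100) * f_cdb`. Ct values are then
#' simulated as in [simulate_ct()].
#'
#' @param panel A `panel_spec`.
#' @param brmv_composition,cdb_composition Endpoint compositions (defaults:
#'   [default_brmv_composition()], [default_cdb_composition()]).
#' @param purities Design purities in percent; must include 0 and 100 and
#'   lie in \[0, 100\].
#' @param input_ng,technical_sd,biological_sd,runs,duplicates,seed Passed to
#'   the cohort; noise defaults to zero (standards are idealised).
#' @param genes Genes to simulate (default whole panel).
#' @return List with `ct` (a `ct_table` of standards `STD000`, `STD025`,
#'   ...) and `design` (`sample_id`, `purity_pct`, `role`).
#' @export
simulate_mixing_series <- function(panel,
                                   brmv_composition = default_brmv_composition(),
                                   cdb_composition = default_cdb_composition(),
                                   purities = c(0, 25, 50, 75, 100),
                                   input_ng = 25, technical_sd = 0,
                                   biological_sd = 0, runs = 3,
                                   duplicates = 2, seed = NULL,
                                   genes = NULL) {
  if (any(purities < 0 | purities > 100)) {
    stop("standard purities must lie in [0, 100]", call. = FALSE)
  }
  p <- purities / 100
  comps <- t(vapply(p, function(w) w * brmv_composition + (1 - w) * cdb_composition,
                    numeric(length(CELL_CLASSES))))
  colnames(comps) <- CELL_CLASSES
  ids <- sprintf("STD%03d", round(purities))
  rownames(comps) <- ids
  cohort <- cohort_spec(ids, comps, group = "standard",
                        input_ng = input_ng, technical_sd = technical_sd,
                        biological_sd = biological_sd,
                        runs = runs, duplicates = duplicates, seed = seed)
  list(ct = simulate_ct(panel, cohort, genes = genes),
       design = data.frame(sample_id = ids, purity_pct = purities,
                           role = "standard", stringsAsFactors = FALSE))
}

#' Simulate immunofluorescence nuclei counts
#'
#' Draws per-class nuclei counts multinomially from each sample's cell
#' composition. The two endothelial classes (BrEC and fenestrated) are
#' pooled into `lectin_pos`, since lectin stains all endothelium.
#'
#' @param compositions Samples x [CELL_CLASSES] matrix of fractions (row
#'   names are sample ids).
#' @param total_nuclei Total DAPI+ nuclei counted per sample (recycled;
#'   default 600, honouring the more-than-500 counting rule).
#' @param seed RNG seed.
#' @return Long data frame `sample_id`, `class`, `count`, `total_nuclei`
#'   suitable for [composition_from_counts()].
#' @export
simulate_if_counts <- function(compositions, total_nuclei = 600, seed = NULL) {
  compositions <- as.matrix(compositions)[, CELL_CLASSES, drop = FALSE]
  n <- nrow(compositions)
  total_nuclei <- rep_len(total_nuclei, n)
  if (any(total_nuclei <= 0)) stop("total_nuclei must be positive", call. = FALSE)
  stain_of <- c(BrEC = "lectin_pos", fenestrated_EC = "lectin_pos",
                microglia = "cd68_pos", astrocyte = "gfap_pos",
                neuron = "neun_pos", pericyte = "pdgfrb_pos", other = "other")
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      draw <- stats::rmultinom(1L, total_nuclei[i], compositions[i, ])[, 1L]
      stain <- tapply(draw, stain_of[names(draw)], sum)
      stain <- stain[names(stain) != "other"]
      data.frame(sample_id = rownames(compositions)[i],
                 class = names(stain), count = as.integer(stain),
                 total_nuclei = total_nuclei[i], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Sample cohort compositions around a mean mixture
#'
#' Convenience Dirichlet sampler for cohort-level Monte Carlo: draws
#' compositions with expectation `mean` and spread controlled by
#' `concentration` (larger = tighter around the mean).
#'
#' @param n Number of samples.
#' @param mean Mean composition (default [default_brmv_composition()]).
#' @param concentration Dirichlet concentration (default 150).
#' @param sample_id Row names (default `BrMV01`, ...).
#' @param seed RNG seed.
#' @return Samples x [CELL_CLASSES] matrix of fractions.
#' @export
sample_compositions <- function(n, mean = default_brmv_composition(),
                                concentration = 150,
                                sample_id = sprintf("BrMV%02d", seq_len(n)),
                                seed = NULL) {
  alpha <- mean * concentration
  with_seed(seed, {
    draws <- t(vapply(seq_len(n), function(i) {
      g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
      g / sum(g)
    }, numeric(length(alpha))))
    dimnames(draws) <- list(sample_id, CELL_CLASSES)
    draws
  })
}
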