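# Standard curves, efficiency, interpolation, ddCt and absolute copies.

test_that("a perfect 10-fold series gives 100% efficiency and R^2 = 1", {
  quantities <- c(100, 10, 1, 0.1)
  ct <- 20 + log2(10) * (2 - log10(quantities))  # exact 3.321928 Ct per dilution
  cv <- fit_standard_curve(quantities, ct, x_unit = "ng")
  expect_equal(cv$efficiency_pct, 100, tolerance = 1e-6)
  expect_equal(cv$r_squared, 1, tolerance = 1e-9)
  expect_equal(cv$slope, -log2(10), tolerance = 1e-9)
})

test_that("efficiency follows the closed form of the slope", {
  # E% = 100 * (10^(-1/slope) - 1)
  mk <- function(slope) {
    q <- 10^(0:3)
    fit_standard_curve(q, 30 + slope * log10(q))$efficiency_pct
  }
  expect_equal(mk(-3.5), 100 * (10^(1 / 3.5) - 1), tolerance = 1e-9)
  expect_equal(mk(-3.5), 93.07, tolerance = 1e-2)
  expect_equal(mk(-3.1), 110.1, tolerance = 1e-1)

  # efficiency strictly decreases as |slope| grows
  eff <- vapply(seq(-2.8, -4.2, by = -0.1), mk, numeric(1))
  expect_true(all(diff(eff) < 0))
})

test_that("degenerate standard series are rejected", {
  expect_error(fit_standard_curve(c(1, 10), c(30, 27)), "insufficient points")
  expect_error(fit_standard_curve(c(1, 10, 100), c(20, 23, 26)),
               "degenerate curve")
  expect_error(fit_standard_curve(c(-1, 10, 100), c(30, 27, 24)), "positive")
})

test_that("interpolation inverts the curve and flags extrapolation", {
  q <- c(100, 25, 10, 1, 0.1)
  ct <- 22 - 3.4 * log10(q)
  cv <- fit_standard_curve(q, ct, x_unit = "ng")
  # ct equal to the intercept -> 1 x-unit
  expect_equal(as.numeric(interpolate_quantity(cv, cv$intercept)), 1,
               tolerance = 1e-9)
  # perfect-fit round trip at a fitted point (25 ng nominal input)
  expect_equal(as.numeric(interpolate_quantity(cv, 22 - 3.4 * log10(25))), 25,
               tolerance = 1e-9)
  got <- interpolate_quantity(cv, ct)
  expect_equal(as.numeric(got), q, tolerance = 1e-9)
  expect_false(any(attr(got, "extrapolated")))
  expect_warning(out <- interpolate_quantity(cv, max(ct) + 5), "extrapolated")
  expect_true(attr(out, "extrapolated"))

  # censored Ct: zero copies on a copy curve, error on an RNA curve
  copy <- fit_standard_curve(10^(1:4), 38 - log2(10) * (1:4), x_unit = "copies")
  z <- interpolate_quantity(copy, NA_real_)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "censored"))
  expect_error(interpolate_quantity(cv, NA_real_), "censored")
})

test_that("generator dilution series round-trips the nominal input", {
  panel <- default_panel()
  std <- simulate_dilution_series(panel, "Actb", c(100, 50, 25, 10, 5, 1))
  cv <- fit_standard_curve(std$quantity, std$ct, x_unit = "ng", gene = "Actb")
  expect_equal(cv$efficiency_pct, 100, tolerance = 1e-6)
  on_curve <- simulate_dilution_series(panel, "Actb", 25, replicates = 1)
  expect_equal(as.numeric(interpolate_quantity(cv, on_curve$ct)), 25,
               tolerance = 1e-6)
})

test_that("ddCt self-calibration, dosage step and input cancellation", {
  mat <- rbind(Idua = c(24, 24, 25), Actb = c(15, 15, 15))
  colnames(mat) <- c("cal", "wt", "het")
  tab <- ct_table_from_matrix(mat)
  fc <- delta_delta_ct(tab, "Idua", "Actb", calibrator = "cal",
                       samples = c("cal", "wt", "het"))
  # sample = calibrator -> ddCt 0, fold 1
  expect_equal(fc$fold_change[fc$sample_id == "cal"], 1)
  expect_equal(fc$delta_delta_ct[fc$sample_id == "cal"], 0)
  # one-cycle dosage step at e = 2 -> fold ratio 2
  expect_equal(fc$fold_change[fc$sample_id == "wt"] /
                 fc$fold_change[fc$sample_id == "het"], 2)

  # scaling a sample's input by 4 drops both genes by 2 cycles: fold unchanged
  mat2 <- mat
  mat2[, "wt"] <- mat2[, "wt"] - 2
  fc2 <- delta_delta_ct(ct_table_from_matrix(mat2), "Idua", "Actb",
                        calibrator = "cal", samples = "wt")
  expect_equal(fc2$fold_change, fc$fold_change[fc$sample_id == "wt"])
})

test_that("ddCt fold is exactly invariant to per-sample and per-gene Ct shifts", {
  set.seed(201)
  for (i in 1:20) {
    mat <- random_ct_matrix(2, 5)
    rownames(mat) <- c("goi", "rg")
    fc0 <- delta_delta_ct(ct_table_from_matrix(mat), "goi", "rg",
                          calibrator = "s1")
    # per-sample global shift (input amount)
    shift_s <- matrix(rep(runif(5, -3, 3), each = 2), nrow = 2)
    fc1 <- delta_delta_ct(ct_table_from_matrix(mat + shift_s), "goi", "rg",
                          calibrator = "s1")
    expect_equal(fc1$fold_change, fc0$fold_change, tolerance = 1e-12)
    # per-gene constant offset (probe brightness)
    shift_g <- matrix(rep(runif(2, -3, 3), times = 5), nrow = 2)
    fc2 <- delta_delta_ct(ct_table_from_matrix(mat + shift_g), "goi", "rg",
                          calibrator = "s1")
    expect_equal(fc2$fold_change, fc0$fold_change, tolerance = 1e-12)
  }
})

test_that("ddCt censoring contracts: knockout fold 0, censored normalizer errors", {
  mat <- rbind(Idua = c(24, NA), Actb = c(15, 15))
  colnames(mat) <- c("cal", "ko")
  fc <- delta_delta_ct(ct_table_from_matrix(mat), "Idua", "Actb",
                       calibrator = "cal", samples = "ko")
  expect_equal(fc$fold_change, 0)
  expect_true(fc$censored)

  mat2 <- rbind(Idua = c(24, 24), Actb = c(15, NA))
  colnames(mat2) <- c("cal", "bad")
  expect_error(delta_delta_ct(ct_table_from_matrix(mat2), "Idua", "Actb",
                              calibrator = "cal"), "normalizer must amplify")
})

test_that("Pfaffl correction reduces to plain ddCt at e = 2", {
  set.seed(202)
  mat <- random_ct_matrix(2, 4)
  rownames(mat) <- c("goi", "rg")
  tab <- ct_table_from_matrix(mat)
  plain <- delta_delta_ct(tab, "goi", "rg", calibrator = "s1")
  pf <- delta_delta_ct(tab, "goi", "rg", calibrator = "s1",
                       efficiency_corrected = TRUE,
                       efficiencies = c(goi = 2, rg = 2))
  expect_equal(pf$fold_change, plain$fold_change, tolerance = 1e-12)
})

test_that("absolute quantification divides curve copies by RNA input", {
  copy <- fit_standard_curve(10^(1:5), 38 - log2(10) * (1:5), x_unit = "copies",
                             gene = "Idua")
  # Ct at the intercept -> 1 copy; 25 ng nominal -> 0.04 copies/ng
  mat <- rbind(Idua = copy$intercept)
  colnames(mat) <- "s1"
  tab <- ct_table_from_matrix(mat, input_ng = 25)
  res <- suppressWarnings(absolute_quantify(tab, "Idua", copy))
  expect_equal(res$copies_per_ng, 0.04, tolerance = 1e-9)

  # knockout: censored -> 0 copies with flag
  mat2 <- rbind(Idua = c(30, NA))
  colnames(mat2) <- c("wt", "ko")
  res2 <- suppressWarnings(absolute_quantify(ct_table_from_matrix(mat2, input_ng = 25),
                                             "Idua", copy))
  expect_equal(res2$copies_per_ng[res2$sample_id == "ko"], 0)
  expect_true(res2$censored[res2$sample_id == "ko"])
})

test_that("absolute and ddCt quantification agree on dosage ratios", {
  # noiseless WT (2 alleles) vs Het (1 allele), stable RG, e = 2
  panel <- default_panel()
  comp <- matrix(rep(default_brmv_composition(), 4), nrow = 4, byrow = TRUE,
                 dimnames = list(c("wt1", "wt2", "het1", "het2"), CELL_CLASSES))
  coh <- cohort_spec(rownames(comp), comp, group = rep(c("WT", "Het"), each = 2),
                     allele_count = c(2, 2, 1, 1), technical_sd = 0,
                     biological_sd = 0, seed = 5)
  tab <- simulate_ct(panel, coh, genes = c("Idua", "Actb"))
  fc <- delta_delta_ct(tab, "Idua", "Actb", calibrator = c("het1", "het2"))
  expect_equal(mean(fc$fold_change[1:2]), 2, tolerance = 1e-9)

  copy <- fit_standard_curve(10^(1:5), 38 - log2(10) * (1:5),
                             x_unit = "copies", gene = "Idua")
  abs_q <- suppressWarnings(absolute_quantify(tab, "Idua", copy))
  ratio <- mean(abs_q$copies_per_ng[1:2]) / mean(abs_q$copies_per_ng[3:4])
  expect_equal(ratio, 2, tolerance = 1e-9)

  # rg_curve input mode recovers the nominal 25 ng on-curve
  rg_curve <- fit_standard_curve(c(100, 50, 25, 10, 5),
                                 simulate_dilution_series(panel, "Actb",
                                                          c(100, 50, 25, 10, 5),
                                                          replicates = 1)$ct,
                                 x_unit = "ng", gene = "Actb")
  abs2 <- suppressWarnings(absolute_quantify(tab, "Idua", copy,
                                             input_mode = "rg_curve",
                                             rg = "Actb", rg_curve = rg_curve))
  expect_equal(abs2$rna_input_ng, rep(25, 4), tolerance = 1e-6)
})
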