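# Purity calibration, scoring, the Plvap flag, composition and correlation.

make_linear_mixing_table <- function(folds = c(1, 9.5, 18, 26.5, 35),
                                     purities = c(0, 25, 50, 75, 100)) {
  # construct Ct values whose ddCt folds vs the 0% standard are exactly `folds`
  ids <- sprintf("STD%03d", purities)
  ct <- rbind(Cldn5 = 25 - log2(folds), Actb = rep(15, length(folds)))
  colnames(ct) <- ids
  list(tab = ct_table_from_matrix(ct),
       design = data.frame(sample_id = ids, purity_pct = purities))
}

test_that("constructed linear folds recover slope, intercept and R^2 = 1", {
  mx <- make_linear_mixing_table()
  cal <- fit_purity_calibration(mx$tab, "Cldn5", "Actb", mx$design)
  expect_equal(cal$slope, 0.34, tolerance = 1e-9)
  expect_equal(cal$intercept, 1, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1, tolerance = 1e-9)
  expect_true(1 %in% cal$points$fold_change)  # the (0, 1) calibrator point
})

test_that("design and marker validity errors are raised", {
  mx <- make_linear_mixing_table()
  expect_error(fit_purity_calibration(mx$tab, "Cldn5", "Actb",
                                      mx$design[mx$design$purity_pct != 0, ]),
               "0% and 100%")
  expect_error(fit_purity_calibration(mx$tab, "Cldn5", "Actb",
                                      mx$design[mx$design$purity_pct %in% c(0, 100), ]),
               ">= 3 distinct")
  # a flat "marker" (equal expression everywhere) has slope ~ 0 -> invalid
  flat <- make_linear_mixing_table(folds = rep(1, 5))
  expect_error(fit_purity_calibration(flat$tab, "Cldn5", "Actb", flat$design),
               "invalid marker")
})

test_that("purity scoring inverts calibrations and reports out-of-range verbatim", {
  mx <- make_linear_mixing_table()
  cal <- fit_purity_calibration(mx$tab, "Cldn5", "Actb", mx$design)
  folds <- data.frame(sample_id = c("a", "b", "c"),
                      marker = "Cldn5",
                      fold_change = c(41, 1, 0.5))
  res <- score_purity(folds, list(Cldn5 = cal), consensus_markers = "Cldn5")
  p <- res$per_marker$purity_pct[match(c("a", "b", "c"), res$per_marker$sample_id)]
  expect_equal(p[1], (41 - 1) / 0.34, tolerance = 1e-9)  # ~117.6%
  expect_equal(p[2], 0, tolerance = 1e-9)
  expect_lt(p[3], 0)
  notes <- res$samples$notes[match(c("a", "c"), res$samples$sample_id)]
  expect_match(notes[1], "above 100%")
  expect_match(notes[2], "below CDB")
})

test_that("consensus purity is the mean of its markers and stays within their range", {
  cal1 <- structure(list(marker = "Cldn5", rg = "Actb", slope = 0.4,
                         intercept = 1, r_squared = 1),
                    class = "purity_calibration")
  cal2 <- structure(list(marker = "Pecam1", rg = "Actb", slope = 0.25,
                         intercept = 1, r_squared = 1),
                    class = "purity_calibration")
  folds <- data.frame(sample_id = "s", marker = c("Cldn5", "Pecam1"),
                      fold_change = c(45, 31))  # purities 110 and 120
  res <- score_purity(folds, list(Cldn5 = cal1, Pecam1 = cal2))
  expect_equal(res$samples$consensus_purity, 115)
  pr <- res$per_marker$purity_pct
  expect_true(res$samples$consensus_purity >= min(pr) &&
                res$samples$consensus_purity <= max(pr))
})

test_that("scoring the standards returns design purities exactly when noiseless", {
  panel <- default_panel()
  mix <- simulate_mixing_series(panel, seed = 9)
  markers <- c("Cldn5", "Pecam1", "Slc2a1")
  cals <- lapply(markers, function(m)
    fit_purity_calibration(mix$ct, m, "Actb", mix$design))
  names(cals) <- markers
  folds <- do.call(rbind, lapply(markers, function(m) {
    fc <- delta_delta_ct(mix$ct, m, "Actb",
                         calibrator = mix$design$sample_id[mix$design$purity_pct == 0],
                         samples = mix$design$sample_id)
    data.frame(sample_id = fc$sample_id, marker = m,
               fold_change = fc$fold_change)
  }))
  res <- score_purity(folds, cals, consensus_markers = c("Cldn5", "Pecam1"))
  got <- res$samples$consensus_purity[match(mix$design$sample_id,
                                            res$samples$sample_id)]
  expect_equal(got, mix$design$purity_pct, tolerance = 1e-9)

  # purity strictly increasing in fold for positive slope
  cal <- cals$Cldn5
  fs <- seq(1, 40, length.out = 10)
  ps <- (fs - cal$intercept) / cal$slope
  expect_true(all(diff(ps) > 0))
})

test_that("mixing calibrations stay linear under generator noise", {
  panel <- default_panel()
  r2 <- vapply(1:100, function(i) {
    mix <- simulate_mixing_series(panel, technical_sd = 0.2, seed = 400 + i,
                                  genes = c("Cldn5", "Actb"))
    fit_purity_calibration(mix$ct, "Cldn5", "Actb", mix$design)$r_squared
  }, numeric(1))
  # r^2 >= 0.95 in the overwhelming majority of seeds, mean in the
  # high-0.9s like a well-behaved mixing experiment
  expect_gte(mean(r2 >= 0.95), 0.95)
  expect_gte(mean(r2), 0.97)
})

test_that("the Plvap flag obeys its strict 40-fold truth table", {
  # folds {1, 40, 41} -> flags {FALSE, FALSE, TRUE}
  ct <- rbind(Plvap = c(32, 32 - log2(1), 32 - log2(40), 32 - log2(41)),
              Actb = rep(15, 4))
  colnames(ct) <- c("pool", "f1", "f40", "f41")
  tab <- ct_table_from_matrix(ct)
  out <- plvap_indicator(tab, rg = "Actb", cdb_pool_id = "pool")
  expect_equal(out$plvap_fold[match(c("f1", "f40", "f41"), out$sample_id)],
               c(1, 40, 41), tolerance = 1e-9)
  expect_equal(out$fenestration_flag[match(c("f1", "f40", "f41"), out$sample_id)],
               c(FALSE, FALSE, TRUE))

  # contaminated calibrator pool: Ct <= background warns
  ct2 <- ct
  ct2["Plvap", "pool"] <- 28
  expect_warning(plvap_indicator(ct_table_from_matrix(ct2), rg = "Actb",
                                 cdb_pool_id = "pool"),
                 "calibrator")

  # censored sample Plvap: fold 0, no flag
  ct3 <- rbind(Plvap = c(32, NA), Actb = c(15, 15))
  colnames(ct3) <- c("pool", "clean")
  out3 <- plvap_indicator(ct_table_from_matrix(ct3), rg = "Actb",
                          cdb_pool_id = "pool")
  expect_equal(out3$plvap_fold, 0)
  expect_false(out3$fenestration_flag)
})

test_that("fenestration flagging tracks the fenestrated fraction deterministically", {
  panel <- default_panel()
  pure_parenchyma <- default_cdb_composition()
  pure_parenchyma["fenestrated_EC"] <- 0
  pure_parenchyma <- pure_parenchyma / sum(pure_parenchyma)
  contaminated <- default_brmv_composition()
  contaminated["fenestrated_EC"] <- 0.05
  contaminated["BrEC"] <- contaminated["BrEC"] - 0.045
  comps <- rbind(pool = default_cdb_composition(), clean = pure_parenchyma,
                 dirty = contaminated)
  coh <- cohort_spec(rownames(comps), comps, technical_sd = 0,
                     biological_sd = 0, seed = 1)
  tab <- simulate_ct(panel, coh, genes = c("Plvap", "Actb"))
  out <- plvap_indicator(tab, rg = "Actb", cdb_pool_id = "pool")
  expect_false(out$fenestration_flag[out$sample_id == "clean"])
  expect_true(out$fenestration_flag[out$sample_id == "dirty"])
})

test_that("composition fractions, residual class and error paths", {
  counts <- data.frame(sample_id = "s1",
                       class = c("lectin_pos", "cd68_pos", "gfap_pos",
                                 "neun_pos", "pdgfrb_pos"),
                       count = c(330, 50, 20, 45, 45),
                       total_nuclei = 500)
  comp <- suppressWarnings(composition_from_counts(counts))
  expect_equal(comp$fractions["s1", "lectin_pos"], 0.66)
  expect_equal(comp$fractions["s1", "other"], 0.02)
  expect_equal(sum(comp$fractions["s1", ]), 1, tolerance = 1e-9)

  # labeled sum exceeding the total is an integrity error
  bad <- counts
  bad$count[1] <- 460
  expect_error(suppressWarnings(composition_from_counts(bad)), "integrity")

  # <= 500 nuclei -> under-sampled warning
  small <- counts
  small$count <- c(264, 40, 16, 36, 36)
  small$total_nuclei <- 400
  expect_warning(composition_from_counts(small), "under-sampled")

  # fractions invariant to scaling all counts by a positive integer
  big <- counts
  big$count <- big$count * 3L
  big$total_nuclei <- 1500
  comp3 <- composition_from_counts(big)
  expect_equal(unlist(comp3$fractions["s1", ]), unlist(comp$fractions["s1", ]))
})

test_that("purity-composition correlation matches the hand Pearson oracle", {
  counts <- do.call(rbind, lapply(1:4, function(i) {
    lect <- c(300, 360, 420, 480)[i]
    data.frame(sample_id = paste0("s", i),
               class = c("lectin_pos", "cd68_pos", "gfap_pos", "neun_pos",
                         "pdgfrb_pos"),
               count = c(lect, 60, 30, 48, 54),
               total_nuclei = 700)
  }))
  comp <- composition_from_counts(counts)
  pur <- data.frame(sample_id = paste0("s", 1:4),
                    purity_pct = c(52, 75, 88, 119))
  res <- correlate_purity(pur, comp)
  expect_equal(res$r,
               oracle_pearson(pur$purity_pct,
                              comp$fractions[paste0("s", 1:4), "lectin_pos"]),
               tolerance = 1e-9)
  expect_equal(res$r_squared, res$r^2, tolerance = 1e-12)

  # perfectly proportional purity -> r = 1
  pur2 <- data.frame(sample_id = paste0("s", 1:4),
                     purity_pct = 200 * comp$fractions[paste0("s", 1:4), "lectin_pos"])
  expect_equal(correlate_purity(pur2, comp)$r, 1, tolerance = 1e-9)

  expect_error(correlate_purity(pur[1:2, ], comp), "insufficient")
})

test_that("a strong marker out-correlates a weakly enriched one across cohorts", {
  panel <- default_panel()
  mix <- simulate_mixing_series(panel, seed = 21)
  cal_cldn5 <- fit_purity_calibration(mix$ct, "Cldn5", "Actb", mix$design)
  cal_slc <- fit_purity_calibration(mix$ct, "Slc2a1", "Actb", mix$design)
  wins <- vapply(1:25, function(i) {
    # nine-sample cohorts whose endothelial fraction spreads like a real
    # isolation series (roughly 50-90% lectin+)
    comps <- sample_compositions(9, concentration = 15, seed = 800 + i)
    # Slc2a1 carries extra per-sample expression variability: it is expressed
    # across endothelium and glia and its cell-level expression varies among
    # samples, which is what decouples its fold change from the endothelial
    # fraction; marker folds are otherwise technical-noise dominated
    coh <- cohort_spec(rownames(comps), comps, technical_sd = 0.2,
                       biological_sd = 0.05,
                       instability_sd = c(Slc2a1 = 0.5), seed = 900 + i)
    tab <- simulate_ct(panel, coh, genes = c("Cldn5", "Slc2a1", "Actb"))
    cdb <- cohort_spec("pool", t(as.matrix(default_cdb_composition())),
                       group = "CDB", technical_sd = 0.2, biological_sd = 0,
                       seed = 950 + i)
    full <- as_ct_table(rbind(as.data.frame(tab),
                              as.data.frame(simulate_ct(panel, cdb,
                                                        genes = c("Cldn5", "Slc2a1", "Actb")))))
    counts <- simulate_if_counts(comps, total_nuclei = 600, seed = 990 + i)
    comp <- suppressWarnings(composition_from_counts(counts))
    r2_of <- function(marker, cal) {
      fc <- delta_delta_ct(full, marker, "Actb", calibrator = "pool",
                           samples = rownames(comps))
      pur <- data.frame(sample_id = fc$sample_id,
                        purity_pct = (fc$fold_change - cal$intercept) / cal$slope)
      correlate_purity(pur, comp)$r_squared
    }
    r2_of("Cldn5", cal_cldn5) > r2_of("Slc2a1", cal_slc)
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("BrEC rescaling is proportional through the anchor pair", {
  anchor <- c(qpcr = 115, brec = 92)
  expect_equal(rescale_to_brec(115, anchor), 92)
  expect_equal(rescale_to_brec(0, anchor), 0)
  expect_equal(rescale_to_brec(57.5, anchor), 46)
  expect_error(rescale_to_brec(100, NULL), "anchor")
  expect_error(rescale_to_brec(100, c(115, -3)), "positive")
})
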