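test_that("window integration matches simple closed forms", {
  grid <- seq(0, 10, by = 0.001)
  expect_equal(integrate_window(nmr_spectrum(grid, rep(0, length(grid))),
                                c(2, 3)), 0)
  # rectangle of height h over width w
  h <- 3.5
  rect <- nmr_spectrum(grid, ifelse(grid >= 4 & grid <= 6, h, 0))
  expect_equal(integrate_window(rect, c(4, 6)), h * 2, tolerance = 1e-3)
  expect_error(integrate_window(rect, c(9.5, 10.5)), "outside")
  expect_error(integrate_window(rect, c(3, 2)), "lo < hi")
})

test_that("a unit Lorentzian truncated at 20 half-widths integrates to 0.968", {
  fwhm <- 0.002
  grid <- seq(0, 10, by = fwhm / 8)
  s <- nmr_spectrum(grid, oracle_lorentz_trace(grid, 5, fwhm))
  hw <- 20 * fwhm / 2
  got <- integrate_window(s, c(5 - hw, 5 + hw))
  expect_equal(got, oracle_lorentz_mass(hw, fwhm), tolerance = 1e-3)
  expect_equal(got, 0.968, tolerance = 0.01)
})

test_that("the internal-reference formula behaves as an identity", {
  expect_equal(eq1_concentration(0, 2, 4), 0)
  expect_equal(eq1_concentration(4, 4, 4), 1000)  # one mol X per mol TG
  expect_equal(eq1_concentration(2.9232, 2, 4), 1461.6)
  expect_error(eq1_concentration(1, 0, 4), "positive")
  expect_error(eq1_concentration(1, 2, 0), "reference")
})

test_that("corrections leave untouched windows alone and clamp to zero", {
  cat_ <- toy_base()
  areas <- data.frame(signal_id = c("x_1", "y_1"), area = c(1.5, 0.7))
  out <- apply_corrections(areas, cat_, a_tg = 4)
  expect_equal(out$corrected_area, areas$area)
  expect_false(any(out$clamped))

  # y's window fully explained by x's co-resonant contribution
  sig <- rbind(
    toy_signal("tg_ref", "TG", 4.14, 4.10, 4.18, n = 4, role = "reference",
               center2 = 4.30, lo2 = 4.26, hi2 = 4.34),
    toy_signal("x_1", "X", 7.00, 6.96, 7.04),
    toy_signal("x_q", "X", 8.00, 7.96, 8.04, role = "qualifier"),
    toy_signal("y_1", "Y", 8.01, 7.96, 8.05, corrections = "x_q"))
  cmp <- rbind(toy_compound("TG", "acyl"), toy_compound("X"), toy_compound("Y"))
  cat2 <- toy_catalogue(sig, cmp)
  # x's area 0.4 implies 400 mmol/mol TG, predicting area 0.4 from its
  # qualifier inside y's window; y's raw area is less, so y clamps to zero
  areas2 <- data.frame(signal_id = c("x_1", "y_1"), area = c(0.4, 0.35))
  out2 <- apply_corrections(areas2, cat2, a_tg = 4)
  expect_equal(out2$corrected_area[out2$signal_id == "y_1"], 0)
  expect_true(out2$clamped[out2$signal_id == "y_1"])

  # a contributor with no area and no concentration is an error
  areas3 <- data.frame(signal_id = "y_1", area = 0.35)
  expect_error(apply_corrections(areas3, cat2, a_tg = 4), "missing contributor")
  # ...but a supplied concentration fixes it
  out3 <- apply_corrections(areas3, cat2, a_tg = 4,
                            concentrations = c(X = 100))
  expect_equal(out3$corrected_area, 0.35 - 100 * 1 * (4 / 4) / 1000,
               tolerance = 1e-9)
})

test_that("a two-compound overlap on the dihydroxy window is unmixed", {
  # dHO_pHO and the hydroxy-epoxide share the 3.38-3.46 ppm window; the
  # hydroxy-epoxide is quantified on its own 5.94-5.95 channel first and its
  # predicted contribution subtracted (generator ground truth as oracle)
  cat_ <- fixture_catalogue()
  conc <- c(dHO_pHO = 8, HO_EPO_mE_1 = 4)
  q <- quantify_spectrum(render_spectrum(conc, cat_), cat_)
  expect_equal(q$concentration[["HO_EPO_mE_1"]], 4, tolerance = 0.02)
  expect_equal(q$concentration[["dHO_pHO"]], 8, tolerance = 0.02)
  # without the correction the window would read ~ 12 mmol/mol TG
  raw <- q$areas$area[q$areas$signal_id == "dho_342"]
  expect_gt(eq1_concentration(raw, 1, q$a_tg), 11)
})

test_that("day-0 fixture quantifies to the original-oil state", {
  q <- fixture_quant(0)
  tr <- truth_row(0)
  expect_equal(q$concentration[["L"]], 1461.6, tolerance = 0.02 * 1461.6)
  oxid <- fixture_catalogue()$compounds$compound_id[
    fixture_catalogue()$compounds$category %in%
      c("primary_oxidation", "secondary_oxidation", "small_molecule",
        "sterol_oxide")]
  present <- intersect(oxid, names(q$concentration))
  expect_true(all(q$concentration[present] == 0))
})

test_that("day-13 maxima of the conjugated-diene hydroperoxides are recovered", {
  q <- fixture_quant(13)
  expect_equal(q$concentration[["mHPO_cEE_dE"]], 140.9,
               tolerance = 0.02 * 140.9)
  expect_equal(q$concentration[["mHPO_cZE_dE"]], 48.5, tolerance = 0.02 * 48.5)
})

test_that("early total hydroperoxide equals the sum of the two isomers", {
  q <- fixture_quant(7)
  tot <- q$concentration[["total_OOH"]]
  isomers <- q$concentration[["mHPO_cZE_dE"]] + q$concentration[["mHPO_cEE_dE"]]
  expect_equal(tot, isomers, tolerance = 0.02 * isomers)
})

test_that("quantification is homogeneous and invariant to intensity scale", {
  cat_ <- fixture_catalogue()
  conc <- c(mHPO_cEE_dE = 60, HPO_EPO_mE = 20, ald_2E_alkenals = 10)
  q1 <- quantify_spectrum(render_spectrum(conc, cat_), cat_)
  qk <- quantify_spectrum(render_spectrum(3 * conc, cat_), cat_)
  for (id in names(conc))
    expect_equal(qk$concentration[[id]] / q1$concentration[[id]], 3,
                 tolerance = 1e-3)
  # doubling the global intensity (area_scale) changes nothing: the
  # reference normalisation cancels it
  qs <- quantify_spectrum(render_spectrum(conc, cat_,
                                          lineshape_params(area_scale = 2)),
                          cat_)
  for (id in names(conc))
    expect_equal(qs$concentration[[id]], q1$concentration[[id]],
                 tolerance = 1e-9)
})

test_that("a spectrum without the backbone signal raises 'reference lost'", {
  grid <- seq(0, 10, by = 0.001)
  expect_error(quantify_spectrum(nmr_spectrum(grid, rep(0, length(grid))),
                                 fixture_catalogue()),
               "reference lost")
})

test_that("replicate averaging is the identity on one or equal results", {
  q <- fixture_quant(13)
  expect_identical(average_replicates(list(q)), q)
  avg <- average_replicates(list(q, q))
  expect_equal(avg$concentration, q$concentration)
})

test_that("averaging noisy replicates beats a single one on average", {
  cat_ <- fixture_catalogue()
  row <- truth_row(13)
  err_avg <- err_one <- numeric(0)
  for (seed in 1:4) {
    qs <- lapply(c(seed * 2 - 1, seed * 2), function(sd_seed)
      quantify_spectrum(render_spectrum(row, cat_,
                                        lineshape_params(noise_sd = 2,
                                                         seed = sd_seed)),
                        cat_, day = 13))
    avg <- average_replicates(qs)
    err_avg <- c(err_avg, abs(avg$concentration[["mHPO_cEE_dE"]] - 140.9))
    err_one <- c(err_one, abs(qs[[1]]$concentration[["mHPO_cEE_dE"]] - 140.9))
  }
  expect_lt(mean(err_avg), mean(err_one))
})

test_that("render -> quantify is the identity across the whole time course", {
  cat_ <- fixture_catalogue()
  tr <- fixture_truth()
  for (d in tr$day) {
    q <- fixture_quant(d)
    row <- truth_row(d)
    for (id in intersect(names(q$concentration), names(row))) {
      est <- q$concentration[[id]]
      below <- q$flags$below_lod[q$flags$compound_id == id]
      if (est == 0 && below) {
        # an undetected channel must correspond to a truly small truth
        # (at most the channel's raised detection limit)
        expect_lt(row[[id]], 1, label = sprintf("below-LOD day %d %s", d, id))
        next
      }
      tol <- max(0.02 * row[[id]], 0.4)  # wing-leakage floor, see vignette
      expect_lt(abs(est - row[[id]]), tol,
                label = sprintf("day %d, %s: |%.3f - %.3f|", d, id,
                                est, row[[id]]))
    }
    # the derived hydroperoxide-group channel counts every OOH proton
    if (d >= 9) {
      ooh_truth <- row[["mHPO_cZE_dE"]] + row[["mHPO_cEE_dE"]] +
        2 * row[["dHPO_nc_dE"]] + row[["HPO_EPO_mE"]]
      expect_equal(q$concentration[["total_OOH"]], ooh_truth,
                   tolerance = 0.02 * ooh_truth)
    }
  }
})

test_that("diepoxides never rise above the detection limit", {
  for (d in c(0, 7, 13, 14, 16)) {
    q <- fixture_quant(d)
    expect_identical(q$concentration[["dEPO"]], 0)
    expect_true(q$flags$below_lod[q$flags$compound_id == "dEPO"])
  }
})
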