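test_that("stage rates recover the linoleic degradation regimes", {
  tr <- fixture_truth()
  r <- stage_rates(tr$day, tr$L)
  # anchors are exactly piecewise linear, so OLS on collinear points is exact
  expect_equal(unname(r["d0_8"]), -7.6, tolerance = 1e-8)
  expect_equal(unname(r["d8_11"]), -28.9, tolerance = 1e-8)
  expect_equal(unname(r["d11_14"]), -256.7, tolerance = 1e-8)
  # the last stage is anchored at the measured day-16 value, within 5 % of
  # the nominal late-stage rate
  expect_equal(unname(r["d14_16"]), -123.7, tolerance = 0.05 * 123.7)
})

test_that("stage rates handle degenerate series", {
  days <- 0:16
  expect_true(all(abs(stage_rates(days, rep(7, 17))) < 1e-12))
  # two-point stage: closed-form slope
  r <- stage_rates(c(0, 4), c(10, 2), stage_scheme(c(0, 4)))
  expect_equal(unname(r), (2 - 10) / 4)
  # < 2 points in a stage: NA, not an error
  r2 <- stage_rates(c(0, 1, 10), c(1, 2, 3), stage_scheme(c(0, 2, 4, 10)))
  expect_true(is.na(r2["d2_4"]))
  expect_error(stage_scheme(c(3, 3)), "strictly increasing")
})

test_that("gamma-tocopherol follows its own two-stage scheme", {
  tr <- fixture_truth()
  r <- stage_rates(tr$day, tr$gT, stage_scheme(c(0, 2, 11)))
  expect_equal(unname(r["d0_2"]), -0.04, tolerance = 1e-8)
  expect_equal(unname(r["d2_11"]), -0.14, tolerance = 1e-8)
})

test_that("event detection finds appearance, maximum and disappearance", {
  tr <- fixture_truth()
  e <- detect_events(tr$day, tr$mHO_cZE_dE, lod = 0.1)
  expect_equal(e$appearance_day, 8)
  expect_equal(e$disappeared_day, 13)
  # all-zero series never appears
  z <- detect_events(0:16, rep(0, 17))
  expect_true(is.na(z$appearance_day))
  # plateau maximum ties break to the earliest day
  p <- detect_events(0:16, c(rep(0, 14), 5, 5, 5), lod = 0.1)
  expect_equal(p$max_day, 14)
  expect_equal(p$max_value, 5)
})

test_that("appearance days of every catalogued class are reproduced", {
  cat_ <- fixture_catalogue()
  tr <- fixture_truth()
  cmp <- cat_$compounds
  for (id in intersect(cmp$compound_id, names(tr))) {
    expected <- cmp$first_detected_day[cmp$compound_id == id]
    if (is.na(expected) || expected == 0) next
    e <- detect_events(tr$day, tr[[id]], lod = 0.1)
    expect_equal(e$appearance_day, expected,
                 label = paste("appearance day of", id))
  }
})

test_that("formation fractions follow the stage-rate ratio", {
  # synthetic series with rates +19.8 and -28.9 over days 8-11
  days <- 8:11
  prod <- 1 + 19.8 * (days - 8)
  sub <- 1400.8 - 28.9 * (days - 8)
  f <- formation_fraction(days, prod, days, sub, stage = c(8, 11))
  expect_equal(f, 100 * 19.8 / 28.9, tolerance = 1e-8)
  expect_equal(formation_fraction(days, rep(2, 4), days, sub, c(8, 11)), 0)
  expect_true(is.na(formation_fraction(days, prod, days, rep(3, 4), c(8, 11))))
  expect_error(formation_fraction(days, prod, days, rev(sub), c(8, 11)),
               "not degrading")
})

test_that("molar percentages convert to mmol/mol TG at three chains per TG", {
  expect_equal(percent_to_mmol(48.7), 1461)
  expect_equal(percent_to_mmol(0), 0)
  expect_equal(percent_to_mmol(100), 3000)
  expect_error(percent_to_mmol(101), "0, 100")
  # the four acyl classes jointly fill all three positions
  expect_equal(sum(percent_to_mmol(c(0.6, 48.7, 33.0, 17.7))), 3000)
})

test_that("exact piecewise-linear series give exact segment slopes", {
  an <- trajectory_anchors(data.frame(
    compound_id = "w", day = c(0, 8, 11, 16), conc = c(100, 60, 90, 15)))
  tab <- make_timecourse(an, 0:16)
  r <- stage_rates(tab$day, tab$w, stage_scheme(c(0, 8, 11, 16)))
  expect_equal(unname(r), c(-5, 10, -15), tolerance = 1e-10)
})

test_that("stage rates survive 2 % concentration noise within 10 %", {
  tr <- fixture_truth()
  i <- which(tr$day >= 11 & tr$day <= 14)
  set.seed(20260928)
  rel_err <- replicate(50, {
    noisy <- tr$L * (1 + stats::rnorm(nrow(tr), 0, 0.02))
    r <- stage_rates(tr$day, noisy, stage_scheme(c(11, 14)))
    abs(unname(r) - (-256.7)) / 256.7
  })
  expect_gte(sum(rel_err <= 0.10), 48)
  expect_lt(stats::median(rel_err), 0.05)
})

test_that("the kinetics summary object aggregates events and rates", {
  tr <- fixture_truth()
  kin <- oxidation_kinetics(tr)
  expect_s3_class(kin, "oxidation_kinetics")
  ev <- kin$events
  expect_equal(ev$max_day[ev$compound_id == "mHPO_cEE_dE"], 13)
  expect_equal(ev$max_value[ev$compound_id == "mHPO_cEE_dE"], 140.9)
  rl <- kin$rates
  expect_equal(rl$rate[rl$compound_id == "L" & rl$stage == "d11_14"], -256.7,
               tolerance = 1e-8)
  # gT picks up its override scheme
  expect_true(any(grepl("d0_2", rl$stage[rl$compound_id == "gT"])))
  smry <- summary(kin)
  expect_true(all(c("appearance_day", "max_day") %in% names(smry)))
  expect_error(oxidation_kinetics(tr[1, ]), "two days")
})
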