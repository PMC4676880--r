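# LOD, LLOQ, ULOQ, calibration regression and carry-over.

exact_fit <- function(slope = 10) fit_curve(c(1, 2, 3), slope * c(1, 2, 3))

test_that("blank-based LOD is mean + 3 sd mapped through the curve", {
  lod <- estimate_lod(c(100, 110, 90), c(50, 50, 50), exact_fit(10))
  expect_equal(lod$value, 13, tolerance = 1e-9)
  expect_false(lod$used_spiked)
})

test_that("spiked-in LOD fallback is 3 sd(lowest point) / slope", {
  # zero-variance limit
  lod0 <- estimate_lod(numeric(0), c(50, 50, 50), exact_fit(10))
  expect_equal(lod0$value, 0)
  expect_true(lod0$used_spiked)
  # undetectable blanks (all zero) also trigger the fallback
  lod <- estimate_lod(c(0, 0, 0), c(40, 50, 60), exact_fit(10))
  expect_true(lod$used_spiked)
  expect_equal(lod$value, 3 * sd(c(40, 50, 60)) / 10)
  # a single detectable blank is not enough to use the blank route
  lod1 <- estimate_lod(c(0, 0, 7), c(40, 50, 60), exact_fit(10))
  expect_true(lod1$used_spiked)
})

test_that("LOD degenerate inputs yield a not-estimable result", {
  both_empty <- estimate_lod(numeric(0), numeric(0), exact_fit())
  expect_true(is.na(both_empty$value))
  expect_warning(bad <- estimate_lod(c(1, 2), c(1, 2),
                                     list(slope = -1, intercept = 0)),
                 "slope")
  expect_true(is.na(bad$value))
})

test_that("fit_curve matches closed-form OLS on hand examples", {
  f1 <- fit_curve(c(1, 2, 3), c(2, 4, 6))
  expect_equal(f1$slope, 2)
  expect_equal(f1$intercept, 0, tolerance = 1e-12)
  expect_equal(f1$r_squared, 1)
  expect_equal(f1$slope_se_pct, 0, tolerance = 1e-8)

  f2 <- fit_curve(c(1, 2, 3), c(2, 4, 7))
  expect_equal(f2$slope, 2.5)
  expect_equal(f2$intercept, -2 / 3)
  expect_equal(f2$r_squared, 75 / 76)          # ~0.9868
  expect_equal(f2$slope_se_pct, 100 * sqrt(1 / 12) / 2.5)  # ~11.55

  expect_error(fit_curve(c(1, 2), c(1, 2)), "3 distinct")
  expect_error(fit_curve(rep(1, 4), 1:4), "3 distinct")
})

test_that("fit_curve agrees with the normal-equations oracle on random instances", {
  set.seed(101)
  for (i in 1:20) {
    n_pts <- sample(3:8, 1)
    conc <- sort(10^runif(n_pts, -2, 2))
    conc <- rep(conc, each = sample(1:4, 1))
    area <- 50 * conc + rnorm(length(conc), 0, 5) + 2
    got <- fit_curve(conc, area)
    want <- ols_oracle(conc, area)
    expect_equal(got$slope, want$slope, tolerance = 1e-9)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-9)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-9)
    expect_equal(got$slope_se_pct, want$slope_se_pct, tolerance = 1e-9)
  }
})

test_that("LLOQ is the lowest point compliant through the ULOQ", {
  m <- 100
  devs <- c(55, 35, 18, 9, 5, 4, 3)  # per-point replicate CVs in percent
  groups <- lapply(devs, function(d) c(m - d, m, m + d))
  names(groups) <- 1:7
  dil <- data.frame(calibration_point = 1:7,
                    theoretical_concentration = 1:7)
  expect_equal(estimate_lloq(groups, dil, cv_threshold = 20), 3L)

  # no point with CV <= 20 %: not estimable (a legal, reportable outcome)
  bad <- lapply(1:7, function(i) c(m - 50, m, m + 50))
  names(bad) <- 1:7
  expect_true(is.na(estimate_lloq(bad, dil, cv_threshold = 20)))

  # noise-free replicates everywhere: LLOQ at the first point
  clean <- lapply(1:7, function(i) rep(10 * i, 3))
  names(clean) <- 1:7
  expect_equal(estimate_lloq(clean, dil), 1L)

  # a non-detectable replicate at an otherwise compliant point disqualifies it
  part <- clean
  part[["1"]] <- c(0, 10, 10)
  expect_equal(estimate_lloq(part, dil), 2L)
})

test_that("ULOQ window search drops a saturating top point", {
  dil <- data.frame(calibration_point = 1:7,
                    theoretical_concentration = 1:7)
  clean <- lapply(1:7, function(i) rep(10 * i, 3))
  names(clean) <- 1:7
  expect_equal(estimate_uloq(clean, dil), 7L)

  sat <- clean
  sat[["7"]] <- rep(45, 3)  # detector saturation: top point falls off the line
  expect_equal(estimate_uloq(sat, dil), 6L)

  # fewer than 3 usable points: not estimable
  tiny <- clean[1:2]
  dil2 <- dil[1:2, ]
  expect_true(is.na(estimate_uloq(tiny, dil2)))
})

test_that("carry-over is the post-high blank signal as a percent of high", {
  co <- assess_carryover(c(5), c(1000, 1000, 1000), lloq_area = 100)
  expect_equal(co$percent, 0.5)
  expect_false(co$flag)
  # above 20 % of the LLOQ-level signal raises the flag
  co2 <- assess_carryover(c(30), c(1000), lloq_area = 100)
  expect_true(co2$flag)
  # no post-high blanks: not applicable
  expect_true(is.na(assess_carryover(numeric(0), c(1000))$percent))
  # all-zero post blanks: 0 %
  expect_equal(assess_carryover(c(0, 0), c(1000))$percent, 0)
})

test_that("noise-free linear data yields the textbook limits", {
  assay <- make_rc_assay(slopes = c(10, 20), concs = 1:7)
  rc <- as.data.frame(response_curve(assay))
  expect_equal(rc$`Curve.Rsquared`, rep(1, 3))
  expect_equal(rc$`Curve.SlopeStdErr(%)`, rep(0, 3), tolerance = 1e-8)
  expect_equal(rc$`LLOQ.CaliPoint`, rep(1L, 3))
  expect_equal(rc$`ULOQ.CaliPoint`, rep(7L, 3))
  expect_equal(rc$`Curve.Slope`, c(10, 20, 30), tolerance = 1e-9)
  # zero-variance blanks at zero: LOD 0 via the spiked fallback
  expect_equal(rc$`LOD.value`, rep(0, 3))
  expect_true(all(rc$`LOD.usedSpiked`))
})

test_that("response-curve measures are scale-equivariant in the areas", {
  noisy <- function(t, conc) {
    set.seed(77 + t)
    10 * t * conc * exp(rnorm(length(conc), 0, 0.05))
  }
  a1 <- make_rc_assay(slopes = c(10, 20), concs = c(0.1, 0.5, 1, 5, 10, 50, 100),
                      areas_fun = noisy)
  a2 <- make_rc_assay(slopes = c(10, 20), concs = c(0.1, 0.5, 1, 5, 10, 50, 100),
                      areas_fun = function(t, conc) 1000 * noisy(t, conc))
  r1 <- as.data.frame(response_curve(a1))
  r2 <- as.data.frame(response_curve(a2))
  expect_equal(r2$`Curve.Slope`, 1000 * r1$`Curve.Slope`, tolerance = 1e-9)
  expect_equal(r2$`LOD.value`, r1$`LOD.value`, tolerance = 1e-9)
  expect_equal(r2$`Curve.Rsquared`, r1$`Curve.Rsquared`, tolerance = 1e-12)
  expect_equal(r2$`Curve.SlopeStdErr(%)`, r1$`Curve.SlopeStdErr(%)`,
               tolerance = 1e-12)
  expect_equal(r2$`LLOQ.CaliPoint`, r1$`LLOQ.CaliPoint`)
  expect_equal(r2$`ULOQ.CaliPoint`, r1$`ULOQ.CaliPoint`)
  expect_equal(r2$`Carryover.percent`, r1$`Carryover.percent`,
               tolerance = 1e-12)
})

test_that("the fitted slope recovers the simulated slope within 3 SE", {
  cfg <- simulation_config(seed = 11, n_peptides = 1, proportional_cv = 5)
  sim <- simulate_response_curve(cfg)
  assay <- mrm_assay(sim$export, sim$metadata, sim$dilution)
  rc <- response_curve(assay)
  for (t in seq_len(cfg$n_transitions)) {
    id <- names(rc$fits)[t]
    fit <- rc$fits[[id]]
    true_slope <- sim$truth$slopes[1, t]
    expect_lt(abs(fit$slope - true_slope), 3 * fit$slope_se)
  }
})
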