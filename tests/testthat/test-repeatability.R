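# CV decomposition, validated LLOQ and transition-ratio specificity.

test_that("cv_components reproduces the hand-worked ANOVA instance", {
  res <- cv_components(list(`1` = c(10, 12), `2` = c(14, 16)))
  # MS_within = 2, MS_between = 16, n0 = 2, sigma2_between = 7, grand mean 13
  expect_equal(res$intra_cv, 100 * sqrt(2) / 13, tolerance = 1e-12)
  expect_equal(res$inter_cv, 100 * sqrt(7) / 13, tolerance = 1e-12)
  expect_equal(res$total_cv, 100 * sqrt(9) / 13, tolerance = 1e-12)
  expect_equal(res$intra_cv, 10.8786, tolerance = 1e-4)
  expect_equal(res$inter_cv, 20.3519, tolerance = 1e-4)
  expect_equal(res$total_cv, 23.0769, tolerance = 1e-4)
})

test_that("cv_components limiting structures behave as forced", {
  # all values identical: every CV is zero
  same <- cv_components(list(`1` = rep(5, 3), `2` = rep(5, 3),
                             `3` = rep(5, 3), `4` = rep(5, 3),
                             `5` = rep(5, 3)))
  expect_equal(same$intra_cv, 0)
  expect_equal(same$inter_cv, 0)
  expect_equal(same$total_cv, 0)
  # within-day identical but day means differ: intra 0, inter > 0
  shift <- cv_components(list(`1` = rep(10, 3), `2` = rep(20, 3)))
  expect_equal(shift$intra_cv, 0)
  expect_gt(shift$inter_cv, 0)
  # a negative between-day moment estimate is clamped to zero
  clamp <- cv_components(list(`1` = c(5, 15), `2` = c(6, 14)))
  expect_true(clamp$clamped)
  expect_equal(clamp$inter_cv, 0)
  expect_equal(clamp$total_cv, clamp$intra_cv)
})

test_that("cv_components degenerate inputs are not estimable", {
  one_day <- cv_components(list(`1` = c(10, 12)))
  expect_true(is.na(one_day$total_cv))
  expect_warning(
    dropped <- cv_components(list(`1` = c(10, 12), `2` = c(14, 16),
                                  `3` = c(5, NA))),
    "dropping")
  expect_equal(dropped$n_days, 2L)
})

test_that("cv_components matches the mean-square oracle on unbalanced instances", {
  set.seed(202)
  for (i in 1:50) {
    n_days <- sample(2:6, 1)
    groups <- lapply(seq_len(n_days), function(d) {
      exp(rnorm(sample(2:5, 1), log(100) + rnorm(1, 0, 0.1), 0.08))
    })
    names(groups) <- seq_len(n_days)
    got <- cv_components(groups)
    want <- cv_oracle(groups)
    expect_equal(got$intra_cv, want$intra, tolerance = 1e-9)
    expect_equal(got$inter_cv, want$inter, tolerance = 1e-9)
    expect_equal(got$total_cv, want$total, tolerance = 1e-9)
  }
})

test_that("total CV is never below either component", {
  set.seed(303)
  for (i in 1:25) {
    groups <- lapply(1:4, function(d) 100 * exp(rnorm(3, rnorm(1, 0, 0.1), 0.05)))
    names(groups) <- 1:4
    res <- cv_components(groups)
    expect_gte(res$total_cv^2 + 1e-9, res$intra_cv^2)
    expect_gte(res$total_cv^2 + 1e-9, res$inter_cv^2)
  }
})

test_that("validated LLOQ picks the lowest compliant level", {
  mk_groups <- function(cv_target, mean = 100) {
    # five days, three replicates, exact within-day spread
    d <- cv_target * mean / 100
    lapply(1:5, function(i) c(mean - d, mean, mean + d))
  }
  lv_groups <- list(low = mk_groups(35), medium = mk_groups(12),
                    high = mk_groups(8))
  lv_results <- lapply(lv_groups, cv_components)
  expect_equal(vapply(lv_results, function(r) r$total_cv > 20, NA),
               c(low = TRUE, medium = FALSE, high = FALSE))
  got <- validated_lloq(lv_results, lv_groups)
  expect_equal(got$level, "medium")
  # day medians are all `mean`, so the median-based total CV is zero
  expect_equal(got$total_cv_me, 0)

  # every level compliant: the low level validates
  all_ok <- list(low = mk_groups(5), medium = mk_groups(5),
                 high = mk_groups(5))
  expect_equal(validated_lloq(lapply(all_ok, cv_components), all_ok)$level,
               "low")

  # no level compliant: not validated, totalCV.Me NA
  none <- list(low = mk_groups(40), medium = mk_groups(40),
               high = mk_groups(40))
  out <- validated_lloq(lapply(none, cv_components), none)
  expect_true(is.na(out$level))
  expect_true(is.na(out$total_cv_me))
})

test_that("a non-detectable replicate blocks level validation", {
  groups <- lapply(1:5, function(i) c(95, 100, 105))
  groups_bad <- groups
  groups_bad[[2]][1] <- 0
  lv <- list(low = groups_bad, medium = groups)
  res <- suppressWarnings(lapply(lv, cv_components))
  expect_equal(validated_lloq(res, lv)$level, "medium")
})

test_that("constant transition ratios give zero deviation; inflation is detected", {
  runs <- sprintf("q%d", 1:6)
  md <- make_metadata_df(runs, "qc", day = rep(1:3, each = 2),
                         replicate_index = rep(1:2, 3),
                         concentration_level = rep(c("low", "high"), 3))
  mk <- function(frag, areas) make_export_df("PEPK", frag, runs, areas)

  base <- c(100, 200, 100, 200, 100, 200)
  ex <- rbind(mk("y4", base), mk("y5", 3 * base), mk("y6", 6 * base))
  assay <- mrm_assay(ex, md)
  pv <- specificity_deviation(assay$sets, runs)
  expect_equal(pv$max_deviation, rep(0, 3), tolerance = 1e-12)
  expect_true(all(pv$specific))
  expect_equal(pv$mean_at_max_dev, c(0.1, 0.3, 0.6), tolerance = 1e-12)

  # inflate y4 by 2x in run q3 (day 2, low level)
  infl <- base
  infl[3] <- infl[3] * 2
  ex2 <- rbind(mk("y4", infl), mk("y5", 3 * base), mk("y6", 6 * base))
  pv2 <- specificity_deviation(mrm_assay(ex2, md)$sets, runs)
  # analytic expectation: inflated-sample ratio vs mean over 6 samples
  r_s <- 0.2 / 1.1
  r_bar <- (5 * 0.1 + r_s) / 6
  expect_equal(pv2$max_deviation[1], 100 * (r_s - r_bar) / r_bar,
               tolerance = 1e-9)
  expect_false(pv2$specific[1])
  expect_equal(pv2$day_at_max_dev[1], 2L)
  expect_equal(pv2$conc_level_at_max_dev[1], "low")
  # the siblings deviate in that sample too, but stay within 30 %
  expect_true(all(pv2$specific[2:3]))
})

test_that("transition ratios sum to one in fully observed samples", {
  cfg <- simulation_config(seed = 9, n_peptides = 1)
  sim <- simulate_repeatability(cfg)
  assay <- mrm_assay(sim$export, sim$metadata)
  runs <- assay$metadata$replicate_name
  areas <- vapply(assay$sets, function(s) {
    s$data$peak_area[match(runs, s$data$replicate_name)]
  }, numeric(length(runs)))
  ratios <- areas / rowSums(areas)
  expect_equal(rowSums(ratios), rep(1, length(runs)), tolerance = 1e-12)
})

test_that("summed rows carry NA for every PVSpec field", {
  for (seed in c(4, 21)) {
    cfg <- simulation_config(seed = seed, n_peptides = 2)
    sim <- simulate_repeatability(cfg)
    rp <- as.data.frame(repeatability(mrm_assay(sim$export, sim$metadata)))
    summed <- rp[rp$Transition == "summed", ]
    expect_equal(nrow(summed), 2L)
    expect_true(all(is.na(summed$`PVSpec.maxDeviation`)))
    expect_true(all(is.na(summed$`PVSpec.meanAtMaxDev`)))
    expect_true(all(is.na(summed$`PVSpec.dayAtMaxDev`)))
    expect_true(all(is.na(summed$`PVSpec.concLevelAtMaxDev`)))
    expect_true(all(is.na(summed$`PVSpec.specific`)))
    # and the written report renders them as the literal "NA"
    path <- withr::local_tempfile(fileext = ".tsv")
    write_report(rp, path)
    lines <- readLines(path)
    header <- strsplit(lines[1], "\t")[[1]]
    pv_cols <- grep("^PVSpec\\.", header)
    summed_lines <- lines[-1][rp$Transition == "summed"]
    for (ln in summed_lines) {
      expect_true(all(strsplit(ln, "\t")[[1]][pv_cols] == "NA"))
    }
  }
})
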