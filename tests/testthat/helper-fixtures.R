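# Shared fixtures and independent oracles.

# --- file fixtures -----------------------------------------------------------

write_export_file <- function(lines, header = "Peptide Sequence\tPrecursor Charge\tFragment Ion\tProduct Charge\tReplicate Name\tArea") {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c(header, lines), path)
  path
}

write_metadata_file <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("Replicate Name\tSample Type\tDay\tReplicate\tConcentration Level\tCalibration Point",
               lines), path)
  path
}

write_dilution_file <- function(points, concs) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(c("Calibration Point\tConcentration",
               paste(points, concs, sep = "\t")), path)
  path
}

# In-memory parsed-form builders (the shape the parsers produce).
make_export_df <- function(peptide, fragment, runs, areas,
                           precursor_charge = 2L, product_charge = 1L) {
  data.frame(peptide_sequence = peptide, precursor_charge = precursor_charge,
             fragment_ion = fragment, product_charge = product_charge,
             replicate_name = runs, peak_area = areas,
             stringsAsFactors = FALSE)
}

make_metadata_df <- function(runs, sample_type, day = NA_integer_,
                             replicate_index = 1L,
                             concentration_level = NA_character_,
                             calibration_point = NA_integer_) {
  df <- data.frame(replicate_name = runs, sample_type = sample_type,
                   day = as.integer(day),
                   replicate_index = as.integer(replicate_index),
                   concentration_level = as.character(concentration_level),
                   calibration_point = as.integer(calibration_point),
                   stringsAsFactors = FALSE)
  df$run_order <- seq_len(nrow(df))
  df
}

# A small noise-free response-curve assay built by hand: `n_trans`
# transitions with the given slopes over `points` (conc = point value),
# `reps` replicates, blanks before and after.
make_rc_assay <- function(slopes = c(10, 20), concs = 1:7, reps = 3,
                          areas_fun = NULL, n_blanks_pre = 3,
                          n_blanks_post = 1, blank_area = 0) {
  np <- length(concs)
  cal_runs <- as.vector(t(outer(seq_len(np), seq_len(reps),
                                function(p, r) sprintf("c%d_r%d", p, r))))
  runs <- c(sprintf("bpre%d", seq_len(n_blanks_pre)), cal_runs,
            if (n_blanks_post > 0) sprintf("bpost%d", seq_len(n_blanks_post)))
  md <- make_metadata_df(
    runs,
    sample_type = c(rep("blank", n_blanks_pre), rep("calibration", np * reps),
                    rep("blank", n_blanks_post)),
    replicate_index = c(seq_len(n_blanks_pre), rep(seq_len(reps), np),
                        seq_len(n_blanks_post)),
    calibration_point = c(rep(NA, n_blanks_pre),
                          rep(seq_len(np), each = reps),
                          rep(NA, n_blanks_post))
  )
  conc_by_run <- rep(concs, each = reps)
  ex <- do.call(rbind, lapply(seq_along(slopes), function(t) {
    if (is.null(areas_fun)) {
      cal_areas <- slopes[t] * conc_by_run
    } else {
      cal_areas <- areas_fun(t, conc_by_run)
    }
    make_export_df("PEPTIDEK", paste0("y", t + 3), runs,
                   c(rep(blank_area, n_blanks_pre), cal_areas,
                     rep(blank_area, n_blanks_post)))
  }))
  dil <- data.frame(calibration_point = seq_len(np),
                    theoretical_concentration = concs)
  mrm_assay(ex, md, dil)
}

# --- independent oracles -----------------------------------------------------

# Normal-equations simple linear regression, written independently of
# fit_curve: closed-form moment sums only.
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - sy / n)^2)
  se_slope <- sqrt(ss_res / (n - 2) / (sxx - sx^2 / n))
  list(slope = slope, intercept = intercept,
       r_squared = 1 - ss_res / ss_tot,
       slope_se_pct = 100 * se_slope / abs(slope))
}

# Explicit mean-square one-way variance-component arithmetic, kept textual
# and loop-based so it shares nothing with cv_components' vectorised path.
cv_oracle <- function(day_groups) {
  groups <- lapply(day_groups, function(g) g[!is.na(g) & g > 0])
  groups <- groups[sapply(groups, length) >= 2]
  D <- length(groups)
  all_y <- c()
  for (g in groups) all_y <- c(all_y, g)
  N <- length(all_y)
  grand <- sum(all_y) / N
  ssw <- 0
  ssb <- 0
  sum_n2 <- 0
  for (g in groups) {
    gm <- sum(g) / length(g)
    for (v in g) ssw <- ssw + (v - gm)^2
    ssb <- ssb + length(g) * (gm - grand)^2
    sum_n2 <- sum_n2 + length(g)^2
  }
  msw <- ssw / (N - D)
  msb <- ssb / (D - 1)
  n0 <- (N - sum_n2 / N) / (D - 1)
  s2b <- (msb - msw) / n0
  if (s2b < 0) s2b <- 0
  list(intra = 100 * sqrt(msw) / grand,
       inter = 100 * sqrt(s2b) / grand,
       total = 100 * sqrt(msw + s2b) / grand)
}
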