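# Seeded synthetic-data generator: Skyline-dialect export + metadata +
# dilution files with known ground truth, emulating the response-curve
# (7-point triplicate serial dilution with blanks) and repeatability
# (3 levels x 5 days x 3 replicates) experiment designs.

# Evaluate expr under a fixed seed without disturbing the caller's RNG.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Log-normal sigma giving exactly the requested percent CV.
.lognorm_sigma <- function(cv_pct) sqrt(log1p((cv_pct / 100)^2))

#' Configure a synthetic assay-development experiment
#'
#' Builds a validated configuration for [simulate_response_curve()] and
#' [simulate_repeatability()]. The defaults reproduce the canonical CPTAC
#' ADWG Tier 2 study design: 15 peptides with 3 monitored transitions each,
#' a seven-point serial dilution acquired in triplicate with pre-curve
#' blank runs, and a repeatability experiment at three concentration levels
#' (low/medium/high) repeated in triplicate on five days. Peak-area noise
#' is multiplicative (log-normal), the empirical regime of integrated MRM
#' peak areas, with the log-scale sigma chosen so the generated CV equals
#' the configured CV exactly.
#'
#' @param seed Integer seed; identical configurations generate byte-identical
#'   files.
#' @param n_peptides,n_transitions Number of peptides and transitions
#'   monitored per peptide.
#' @param calibration_points Strictly increasing theoretical concentrations
#'   of the serial-dilution points (units are arbitrary but fixed, e.g.
#'   fmol/uL).
#' @param n_replicates Replicates per calibration point / per day-level cell.
#' @param n_days Acquisition days in the repeatability design.
#' @param level_concentrations Named numeric vector giving the low, medium
#'   and high QC concentrations.
#' @param slope_per_transition Response slopes (area per concentration unit)
#'   of the transitions within a peptide; recycled to `n_transitions`.
#'   Unequal slopes give the unequal relative transition intensities seen
#'   in practice. Each peptide's slopes are additionally scaled
#'   geometrically across peptides so limits of detection span magnitudes.
#' @param proportional_cv Within-replicate multiplicative noise, percent.
#' @param between_day_cv Day-to-day multiplicative noise, percent (shared by
#'   all transitions of a peptide within a day, as instrument drift is).
#' @param blank_mean,blank_sd Blank-run signal distribution (normal,
#'   truncated at zero). The defaults (0, 0) emulate instruments whose
#'   blanks report no detectable level, forcing the spiked-in LOD fallback.
#' @param n_blanks_pre,n_blanks_post Blank runs acquired before the curve
#'   and after the highest calibration point.
#' @param dropout_below Concentration below which areas are reported missing
#'   (detector dropout at the low end); 0 disables dropout.
#' @param carryover_fraction Fraction of the mean high-point signal leaking
#'   into post-high blank runs, in `[0, 1)`.
#' @param interference Optional specificity violation: a list with elements
#'   `transition` (index within the peptide), `day`, `level`, `replicate`
#'   (selecting one repeatability sample) and `factor` (ratio inflation
#'   multiplier applied to that transition's area in that sample).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_peptides = 15L,
                              n_transitions = 3L,
                              calibration_points = c(0.01, 0.1, 0.5, 1,
                                                     5, 10, 100),
                              n_replicates = 3L,
                              n_days = 5L,
                              level_concentrations = c(low = 1, medium = 10,
                                                       high = 100),
                              slope_per_transition = c(500, 1500, 3000),
                              proportional_cv = 5,
                              between_day_cv = 10,
                              blank_mean = 0,
                              blank_sd = 0,
                              n_blanks_pre = 3L,
                              n_blanks_post = 1L,
                              dropout_below = 0,
                              carryover_fraction = 0,
                              interference = NULL) {
  stopifnot(.is_count(seed + 1), .is_count(n_peptides),
            .is_count(n_transitions), .is_count(n_replicates),
            .is_count(n_days))
  if (length(calibration_points) < 2L || any(diff(calibration_points) <= 0)) {
    stop("simulation_config: calibration_points must increase strictly",
         call. = FALSE)
  }
  if (any(calibration_points <= 0)) {
    stop("simulation_config: calibration points must be positive",
         call. = FALSE)
  }
  if (proportional_cv < 0 || between_day_cv < 0 || blank_sd < 0 ||
      blank_mean < 0) {
    stop("simulation_config: noise parameters must be non-negative",
         call. = FALSE)
  }
  if (carryover_fraction < 0 || carryover_fraction >= 1) {
    stop("simulation_config: carryover_fraction must lie in [0, 1)",
         call. = FALSE)
  }
  if (!setequal(names(level_concentrations), .conc_levels) ||
      any(level_concentrations <= 0)) {
    stop("simulation_config: level_concentrations must be a positive vector ",
         "named low/medium/high", call. = FALSE)
  }
  slope_per_transition <- rep_len(slope_per_transition, n_transitions)
  if (any(slope_per_transition <= 0)) {
    stop("simulation_config: slopes must be positive", call. = FALSE)
  }
  if (!is.null(interference)) {
    need <- c("transition", "day", "level", "replicate", "factor")
    if (!all(need %in% names(interference))) {
      stop("simulation_config: interference needs fields ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    if (interference$transition > n_transitions ||
        !(interference$level %in% .conc_levels) ||
        interference$factor <= 0) {
      stop("simulation_config: invalid interference specification",
           call. = FALSE)
    }
  }
  structure(list(
    seed = as.integer(seed), n_peptides = as.integer(n_peptides),
    n_transitions = as.integer(n_transitions),
    calibration_points = calibration_points,
    n_replicates = as.integer(n_replicates), n_days = as.integer(n_days),
    level_concentrations = level_concentrations[.conc_levels],
    slope_per_transition = slope_per_transition,
    proportional_cv = proportional_cv, between_day_cv = between_day_cv,
    blank_mean = blank_mean, blank_sd = blank_sd,
    n_blanks_pre = as.integer(n_blanks_pre),
    n_blanks_post = as.integer(n_blanks_post),
    dropout_below = dropout_below,
    carryover_fraction = carryover_fraction,
    interference = interference
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic experiment configuration (seed", x$seed, ")\n")
  cat(sprintf("  %d peptide(s) x %d transition(s); %d-point curve x %d reps; %d day(s)\n",
              x$n_peptides, x$n_transitions, length(x$calibration_points),
              x$n_replicates, x$n_days))
  cat(sprintf("  noise: within %g %%, between-day %g %%; dropout below %g\n",
              x$proportional_cv, x$between_day_cv, x$dropout_below))
  invisible(x)
}

# Deterministic peptide sequences and per-peptide slope scales.
.sim_peptides <- function(config) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  seqs <- character(config$n_peptides)
  for (i in seq_len(config$n_peptides)) {
    repeat {
      s <- paste(sample(aa, 10L, replace = TRUE), collapse = "")
      if (!(s %in% seqs)) break
    }
    seqs[i] <- s
  }
  scale <- if (config$n_peptides == 1L) 1 else
    10^seq(-1, 1, length.out = config$n_peptides)
  list(sequences = seqs, scale = scale,
       fragment_ions = paste0("y", 3L + seq_len(config$n_transitions)),
       precursor_charge = 2L, product_charge = 1L)
}

.truncnorm0 <- function(n, mean, sd) {
  if (sd == 0) rep(mean, n) else pmax(0, stats::rnorm(n, mean, sd))
}

.sim_write <- function(export, metadata, dilution, truth, dir) {
  paths <- list(
    export = file.path(dir, "skyline_export.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    dilution = if (!is.null(dilution)) file.path(dir, "dilution.tsv"),
    truth = file.path(dir, "truth.json")
  )
  fmt_area <- function(x) ifelse(is.na(x), "#N/A", sprintf("%.10g", x))
  exp_lines <- c(paste(.sky_export_cols, collapse = "\t"),
                 paste(export$peptide_sequence, export$precursor_charge,
                       export$fragment_ion, export$product_charge,
                       export$replicate_name, fmt_area(export$peak_area),
                       sep = "\t"))
  writeLines(exp_lines, paths$export)
  blank_if_na <- function(x) ifelse(is.na(x), "", as.character(x))
  md_lines <- c(paste(.metadata_cols, collapse = "\t"),
                paste(metadata$replicate_name, metadata$sample_type,
                      blank_if_na(metadata$day),
                      blank_if_na(metadata$replicate_index),
                      blank_if_na(metadata$concentration_level),
                      blank_if_na(metadata$calibration_point),
                      sep = "\t"))
  writeLines(md_lines, paths$metadata)
  if (!is.null(dilution)) {
    writeLines(c(paste(.dilution_cols, collapse = "\t"),
                 paste(dilution$calibration_point,
                       sprintf("%.10g", dilution$theoretical_concentration),
                       sep = "\t")),
               paths$dilution)
  }
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths
}

#' Simulate a response-curve experiment
#'
#' Generates the three input tables of a serial-dilution response-curve
#' experiment — Skyline-dialect transition export, run metadata in
#' acquisition order, and dilution map — under the linear signal model
#' `area = slope * concentration * exp(eps)` with log-normal replicate
#' noise, plus pre-curve blank runs, optional low-end dropout (areas
#' missing below a concentration boundary) and optional carry-over signal
#' in post-high blank runs. The ground truth (true slopes, noise sigmas,
#' dropout boundary) is returned, and written as a JSON sidecar when files
#' are requested, so tests never re-derive expectations from the
#' generator's internals.
#'
#' @param config A [simulation_config()].
#' @param dir Optional directory; when given, `skyline_export.tsv`,
#'   `metadata.tsv`, `dilution.tsv` and `truth.json` are written there.
#' @return A list with data frames `export`, `metadata`, `dilution`
#'   (directly usable by [mrm_assay()]), the `truth` record, and `paths`
#'   (`NULL` when `dir` is not given).
#' @export
simulate_response_curve <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, {
    pep <- .sim_peptides(config)
    pts <- config$calibration_points
    np <- length(pts)

    run_names <- c(
      if (config$n_blanks_pre) sprintf("blank_pre_%02d",
                                       seq_len(config$n_blanks_pre)),
      as.vector(t(outer(seq_len(np), seq_len(config$n_replicates),
                        function(p, r) sprintf("cal_p%d_r%d", p, r)))),
      if (config$n_blanks_post) sprintf("blank_post_%02d",
                                        seq_len(config$n_blanks_post))
    )
    n_pre <- config$n_blanks_pre
    n_cal <- np * config$n_replicates
    metadata <- data.frame(
      replicate_name = run_names,
      sample_type = c(rep("blank", n_pre), rep("calibration", n_cal),
                      rep("blank", config$n_blanks_post)),
      day = NA_integer_,
      replicate_index = c(seq_len(n_pre),
                          rep(seq_len(config$n_replicates), np),
                          seq_len(config$n_blanks_post)),
      concentration_level = NA_character_,
      calibration_point = c(rep(NA_integer_, n_pre),
                            rep(seq_len(np), each = config$n_replicates),
                            rep(NA_integer_, config$n_blanks_post)),
      stringsAsFactors = FALSE
    )
    metadata$run_order <- seq_len(nrow(metadata))
    dilution <- data.frame(calibration_point = seq_len(np),
                           theoretical_concentration = pts)

    sigma_w <- .lognorm_sigma(config$proportional_cv)
    rows <- vector("list", config$n_peptides * config$n_transitions)
    slopes <- matrix(0, config$n_peptides, config$n_transitions)
    k <- 0L
    for (i in seq_len(config$n_peptides)) {
      for (t in seq_len(config$n_transitions)) {
        slope <- config$slope_per_transition[t] * pep$scale[i]
        slopes[i, t] <- slope
        pre <- .truncnorm0(n_pre, config$blank_mean, config$blank_sd)
        conc <- rep(pts, each = config$n_replicates)
        eps <- stats::rnorm(n_cal, 0, sigma_w)
        cal <- slope * conc * exp(eps)
        cal[conc < config$dropout_below] <- NA_real_
        mean_high <- mean(cal[conc == max(pts)], na.rm = TRUE)
        post <- config$carryover_fraction * mean_high +
          .truncnorm0(config$n_blanks_post, config$blank_mean,
                      config$blank_sd)
        k <- k + 1L
        rows[[k]] <- data.frame(
          peptide_sequence = pep$sequences[i],
          precursor_charge = pep$precursor_charge,
          fragment_ion = pep$fragment_ions[t],
          product_charge = pep$product_charge,
          replicate_name = run_names,
          peak_area = c(pre, cal, post),
          stringsAsFactors = FALSE
        )
      }
    }
    export <- do.call(rbind, rows)
    truth <- list(
      kind = "response_curve", seed = config$seed,
      peptides = pep$sequences,
      fragment_ions = pep$fragment_ions,
      slopes = slopes,
      sigma_within = sigma_w,
      proportional_cv = config$proportional_cv,
      calibration_points = pts,
      n_replicates = config$n_replicates,
      dropout_below = config$dropout_below,
      first_fully_detectable_point =
        min(which(pts >= config$dropout_below)),
      blank_mean = config$blank_mean, blank_sd = config$blank_sd,
      carryover_fraction = config$carryover_fraction
    )
    paths <- if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      .sim_write(export, metadata, dilution, truth, dir)
    }
    list(export = export, metadata = metadata, dilution = dilution,
         truth = truth, paths = paths)
  })
}

#' Simulate a mini-validation-of-repeatability experiment
#'
#' Generates QC measurements at the low/medium/high concentration levels
#' over `n_days` days with `n_replicates` replicates per day under the
#' two-component model
#' `area = mu_level * exp(delta_day) * exp(eps)`, where `delta_day` is a
#' shared per-peptide day effect (log-normal, `between_day_cv`) and `eps`
#' is replicate noise (log-normal, `proportional_cv`). An optional
#' interference multiplies one transition's area in one chosen sample,
#' manufacturing a transition-ratio specificity violation of known
#' magnitude.
#'
#' @inheritParams simulate_response_curve
#' @return A list with data frames `export`, `metadata`, the `truth`
#'   record, and `paths` (`NULL` when `dir` is not given).
#' @export
simulate_repeatability <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed + 1L, {
    pep <- .sim_peptides(config)
    lv <- .conc_levels
    grid <- expand.grid(replicate = seq_len(config$n_replicates),
                        level = lv, day = seq_len(config$n_days),
                        stringsAsFactors = FALSE)
    grid <- grid[order(grid$day, match(grid$level, lv), grid$replicate), ]
    run_names <- sprintf("qc_d%d_%s_r%d", grid$day, grid$level,
                         grid$replicate)
    metadata <- data.frame(
      replicate_name = run_names,
      sample_type = "qc",
      day = grid$day,
      replicate_index = grid$replicate,
      concentration_level = grid$level,
      calibration_point = NA_integer_,
      stringsAsFactors = FALSE
    )
    metadata$run_order <- seq_len(nrow(metadata))

    sigma_w <- .lognorm_sigma(config$proportional_cv)
    sigma_b <- .lognorm_sigma(config$between_day_cv)
    conc <- config$level_concentrations[grid$level]
    inter <- config$interference
    hit <- if (!is.null(inter)) {
      grid$day == inter$day & grid$level == inter$level &
        grid$replicate == inter$replicate
    } else rep(FALSE, nrow(grid))

    rows <- vector("list", config$n_peptides * config$n_transitions)
    slopes <- matrix(0, config$n_peptides, config$n_transitions)
    k <- 0L
    for (i in seq_len(config$n_peptides)) {
      delta <- stats::rnorm(config$n_days, 0, sigma_b)
      for (t in seq_len(config$n_transitions)) {
        slope <- config$slope_per_transition[t] * pep$scale[i]
        slopes[i, t] <- slope
        eps <- stats::rnorm(nrow(grid), 0, sigma_w)
        area <- slope * conc * exp(delta[grid$day]) * exp(eps)
        if (!is.null(inter) && inter$transition == t) {
          area[hit] <- area[hit] * inter$factor
        }
        area[conc < config$dropout_below] <- NA_real_
        k <- k + 1L
        rows[[k]] <- data.frame(
          peptide_sequence = pep$sequences[i],
          precursor_charge = pep$precursor_charge,
          fragment_ion = pep$fragment_ions[t],
          product_charge = pep$product_charge,
          replicate_name = run_names,
          peak_area = area,
          stringsAsFactors = FALSE
        )
      }
    }
    export <- do.call(rbind, rows)
    truth <- list(
      kind = "repeatability", seed = config$seed,
      peptides = pep$sequences,
      fragment_ions = pep$fragment_ions,
      slopes = slopes,
      sigma_within = sigma_w, sigma_between = sigma_b,
      proportional_cv = config$proportional_cv,
      between_day_cv = config$between_day_cv,
      level_concentrations = as.list(config$level_concentrations),
      n_days = config$n_days, n_replicates = config$n_replicates,
      interference = inter
    )
    paths <- if (!is.null(dir)) {
      dir.create(dir, recursive = TRUE, showWarnings = FALSE)
      .sim_write(export, metadata, NULL, truth, dir)
    }
    list(export = export, metadata = metadata, truth = truth, paths = paths)
  })
}
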