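# Response-curve performance measures: LOD (with spiked-in fallback),
# LLOQ/ULOQ via a contiguous linear-range search, calibration regression,
# and carry-over.

# Per-calibration-point summary. mean/sd/cv are over detectable areas;
# n counts all exported replicates, n_detect the detectable ones.
.point_stats <- function(groups, dilution) {
  pts <- as.integer(names(groups))
  conc <- dilution$theoretical_concentration[
    match(pts, dilution$calibration_point)]
  if (anyNA(conc)) {
    stop("calibration point(s) ",
         paste(pts[is.na(conc)], collapse = ", "),
         " missing from the dilution map", call. = FALSE)
  }
  stat <- function(x) {
    d <- x[.detectable(x)]
    c(n = length(x), n_detect = length(d),
      mean = if (length(d)) mean(d) else NA_real_,
      sd = if (length(d) > 1L) stats::sd(d) else NA_real_)
  }
  m <- t(vapply(groups, stat, numeric(4)))
  data.frame(point = pts, conc = conc, n = as.integer(m[, "n"]),
             n_detect = as.integer(m[, "n_detect"]),
             mean = m[, "mean"], sd = m[, "sd"],
             cv = ifelse(m[, "mean"] > 0, 100 * m[, "sd"] / m[, "mean"],
                         NA_real_),
             row.names = NULL)
}

#' Fit the calibration regression
#'
#' Ordinary least squares of peak area on theoretical concentration, with
#' every replicate observation entered individually (not averaged) so that
#' the slope standard error reflects replicate scatter. Optional
#' bioanalytical weighting by `1/x` or `1/x^2` is available; the reported
#' coefficient of determination is always the ordinary (unweighted) R^2.
#'
#' @param conc Numeric vector of theoretical concentrations, one per
#'   observation.
#' @param area Numeric vector of peak areas (missing values are dropped).
#' @param weighting `"none"` (default), `"inv_x"` or `"inv_x2"`.
#' @return An object of class `mrm_curve_fit`: a list with `slope`,
#'   `intercept`, `r_squared`, `slope_se`, `slope_se_pct`
#'   (`100 * SE(slope) / |slope|`), `n`, and `weighting`.
#' @examples
#' fit_curve(c(1, 2, 3), c(2, 4, 6))   # exact line: R^2 = 1
#' @export
fit_curve <- function(conc, area, weighting = c("none", "inv_x", "inv_x2")) {
  weighting <- match.arg(weighting)
  keep <- !is.na(area) & !is.na(conc)
  if (weighting != "none") keep <- keep & conc > 0
  conc <- conc[keep]
  area <- area[keep]
  if (length(unique(conc)) < 3L) {
    stop("fit_curve: need at least 3 distinct concentrations with data",
         call. = FALSE)
  }
  if (stats::var(conc) == 0) {
    stop("fit_curve: zero variance in concentrations", call. = FALSE)
  }
  w <- switch(weighting, none = NULL, inv_x = 1 / conc, inv_x2 = 1 / conc^2)
  fit <- if (is.null(w)) stats::lm(area ~ conc) else
    stats::lm(area ~ conc, weights = w)
  cf <- stats::coef(fit)
  # exact (noise-free) data triggers lm's perfect-fit warning; harmless here
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit)))[["conc"]])
  # ordinary R^2 on the raw scale regardless of weighting
  ss_res <- sum((area - stats::fitted(fit))^2)
  ss_tot <- sum((area - mean(area))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(
    slope = unname(cf[["conc"]]),
    intercept = unname(cf[["(Intercept)"]]),
    r_squared = r2,
    slope_se = se,
    slope_se_pct = if (cf[["conc"]] != 0) 100 * se / abs(cf[["conc"]])
    else NA_real_,
    n = length(area),
    weighting = weighting
  ), class = "mrm_curve_fit")
}

#' @export
print.mrm_curve_fit <- function(x, ...) {
  cat(sprintf("Calibration fit (n = %d%s): area = %.6g + %.6g * conc\n",
              x$n,
              if (x$weighting != "none") paste0(", weighting ", x$weighting)
              else "",
              x$intercept, x$slope))
  cat(sprintf("  R^2 = %.6g, SE(slope) = %.4f%% of slope\n",
              x$r_squared, x$slope_se_pct))
  invisible(x)
}

# Search all contiguous calibration-point windows of >= 3 points for the
# widest one in which every point has CV <= cv_threshold, >= 2 detectable
# replicates, and back-calculated accuracy within +/- accuracy_tolerance %
# of nominal under the window's own OLS fit. Ties prefer the higher top
# point, then the lower bottom point.
.find_linear_range <- function(stats_df, obs, control) {
  usable <- stats_df$conc > 0
  pts <- stats_df$point
  np <- length(pts)
  best <- NULL
  for (i in seq_len(np)) {
    for (j in seq_len(np)) {
      if (j - i + 1L < 3L) next
      win <- i:j
      if (!all(usable[win])) next
      s <- stats_df[win, , drop = FALSE]
      if (any(s$n_detect < 2L)) next
      if (any(is.na(s$cv) | s$cv > control$lloq_cv_threshold)) next
      ob <- obs[obs$point %in% pts[win] & !is.na(obs$area), , drop = FALSE]
      fit <- tryCatch(fit_curve(ob$conc, ob$area, control$weighting),
                      error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$slope) || fit$slope <= 0) next
      back <- (s$mean - fit$intercept) / fit$slope
      acc <- 100 * abs(back - s$conc) / s$conc
      if (any(!is.finite(acc) | acc > control$accuracy_tolerance)) next
      cand <- list(lo = i, hi = j, width = j - i + 1L, fit = fit,
                   points = pts[win])
      if (is.null(best) ||
          cand$width > best$width ||
          (cand$width == best$width && cand$hi > best$hi) ||
          (cand$width == best$width && cand$hi == best$hi &&
           cand$lo < best$lo)) {
        best <- cand
      }
    }
  }
  best
}

#' Estimate the limit of detection
#'
#' Classical 3-sigma LOD. When at least two blank runs have detectable
#' (non-missing, positive) areas, the LOD signal is
#' `mean(blank) + multiplier * sd(blank)` converted to concentration through
#' the inverse of the fitted calibration curve (`used_spiked = FALSE`).
#' When blanks report no detectable signal — the usual situation on
#' sensitive instruments — the spiked-in fallback is used:
#' `LOD = multiplier * sd(lowest detectable calibration point) / slope`
#' (`used_spiked = TRUE`).
#'
#' @param blank_areas Numeric vector of pre-curve blank-run areas.
#' @param lowest_point_areas Numeric vector of replicate areas at the lowest
#'   calibration point with detectable signal.
#' @param fit An `mrm_curve_fit` from [fit_curve()], or `NULL`.
#' @param multiplier The sigma multiplier (default 3).
#' @return A list with `value` (concentration units of the dilution map; `NA`
#'   when not estimable) and `used_spiked` (logical).
#' @export
estimate_lod <- function(blank_areas, lowest_point_areas, fit,
                         multiplier = 3) {
  if (is.null(fit) || !is.finite(fit$slope) || fit$slope <= 0) {
    warning("LOD not estimable: calibration slope missing or non-positive",
            call. = FALSE)
    return(list(value = NA_real_, used_spiked = NA))
  }
  blanks <- blank_areas[.detectable(blank_areas)]
  if (length(blanks) >= 2L) {
    signal <- mean(blanks) + multiplier * stats::sd(blanks)
    return(list(value = max(0, (signal - fit$intercept) / fit$slope),
                used_spiked = FALSE))
  }
  low <- lowest_point_areas[!is.na(lowest_point_areas)]
  if (length(low) >= 2L) {
    return(list(value = multiplier * stats::sd(low) / fit$slope,
                used_spiked = TRUE))
  }
  list(value = NA_real_, used_spiked = NA)
}

#' Estimate the lower limit of quantification calibration point
#'
#' The LLOQ calibration point is the lowest point at which all replicates
#' are detectable and the replicate CV is at or below `cv_threshold`, with
#' every higher point up to the ULOQ also satisfying both conditions. When
#' no point qualifies the LLOQ is not estimable (`NA`) — a legal outcome
#' that the report renders as `"NA"`.
#'
#' @param groups Named list mapping calibration point to replicate areas, as
#'   from [group_by_design()].
#' @param dilution Parsed dilution map.
#' @param cv_threshold Replicate CV bound in percent (default 20).
#' @param uloq The ULOQ calibration point bounding the scan (default: the
#'   highest designed point).
#' @return The LLOQ calibration point (integer) or `NA`.
#' @export
estimate_lloq <- function(groups, dilution, cv_threshold = 20,
                          uloq = max(as.integer(names(groups)))) {
  if (is.na(uloq)) return(NA_integer_)
  s <- .point_stats(groups, dilution)
  s <- s[s$point <= uloq, , drop = FALSE]
  s <- s[order(s$point), , drop = FALSE]
  ok <- s$n > 0L & s$n_detect == s$n & !is.na(s$cv) & s$cv <= cv_threshold
  # zero-variance replicate sets have sd = 0 hence cv = 0, but a single
  # detectable replicate yields cv NA and fails
  for (i in seq_len(nrow(s))) {
    if (all(ok[i:nrow(s)])) return(s$point[i])
  }
  NA_integer_
}

#' Estimate the upper limit of quantification calibration point
#'
#' The ULOQ is the highest calibration point retained in the widest
#' contiguous point window whose own OLS fit keeps every member point's
#' back-calculated accuracy within `accuracy_tolerance` percent of nominal
#' and every member point's replicate CV at or below `cv_threshold`.
#' Windows must span at least three points; ties between equally wide
#' windows prefer the higher top point, then the lower bottom point.
#'
#' @inheritParams estimate_lloq
#' @param accuracy_tolerance Back-calculated accuracy bound in percent
#'   (default 20).
#' @param weighting Regression weighting passed to [fit_curve()].
#' @return The ULOQ calibration point (integer) or `NA` when no window
#'   passes.
#' @export
estimate_uloq <- function(groups, dilution, cv_threshold = 20,
                          accuracy_tolerance = 20, weighting = "none") {
  control <- list(lloq_cv_threshold = cv_threshold,
                  accuracy_tolerance = accuracy_tolerance,
                  weighting = weighting)
  s <- .point_stats(groups, dilution)
  obs <- .calibration_obs(groups, dilution)
  lr <- .find_linear_range(s, obs, control)
  if (is.null(lr)) NA_integer_ else max(lr$points)
}

# Long observation table (point, conc, area) over all calibration runs.
.calibration_obs <- function(groups, dilution) {
  pts <- as.integer(names(groups))
  conc <- dilution$theoretical_concentration[
    match(pts, dilution$calibration_point)]
  do.call(rbind, lapply(seq_along(pts), function(i) {
    data.frame(point = pts[i], conc = conc[i], area = groups[[i]])
  }))
}

#' Assess carry-over
#'
#' Carry-over is the residual signal in blank runs acquired immediately
#' after the highest-concentration calibration runs, expressed as a percent
#' of the mean high-point signal. The result is additionally flagged when
#' the mean post-high blank signal exceeds 20 % of the signal at the LLOQ.
#'
#' @param blank_after_high_areas Areas of blank runs acquired after the
#'   highest calibration point (may be empty).
#' @param high_point_areas Replicate areas at the highest calibration point.
#' @param lloq_area Mean area at the LLOQ calibration point, or `NA`.
#' @return A list with `percent` (`NA` when no post-high blanks exist) and
#'   `flag` (logical or `NA`).
#' @export
assess_carryover <- function(blank_after_high_areas, high_point_areas,
                             lloq_area = NA_real_) {
  bp <- blank_after_high_areas[!is.na(blank_after_high_areas)]
  if (length(bp) == 0L) return(list(percent = NA_real_, flag = NA))
  high <- high_point_areas[!is.na(high_point_areas)]
  if (length(high) == 0L || mean(high) <= 0) {
    return(list(percent = NA_real_, flag = NA))
  }
  pct <- 100 * mean(bp) / mean(high)
  flag <- if (is.na(lloq_area)) NA else mean(bp) > 0.2 * lloq_area
  list(percent = pct, flag = flag)
}

# One response-curve report row for one measurement set.
.rc_row <- function(set, dilution, control) {
  groups <- group_by_design(set, "response_curve")
  s <- .point_stats(groups$calibration, dilution)
  obs <- .calibration_obs(groups$calibration, dilution)
  lr <- .find_linear_range(s, obs, control)

  if (!is.null(lr)) {
    fit <- lr$fit
    uloq <- max(lr$points)
    lloq <- estimate_lloq(groups$calibration, dilution,
                          control$lloq_cv_threshold, uloq)
  } else {
    fit <- tryCatch(fit_curve(obs$conc, obs$area, control$weighting),
                    error = function(e) NULL)
    uloq <- NA_integer_
    lloq <- NA_integer_
  }

  lowest_detect <- s[s$n_detect >= 2L, , drop = FALSE]
  lowest_areas <- if (nrow(lowest_detect)) {
    groups$calibration[[as.character(min(lowest_detect$point))]]
  } else numeric(0)
  lod <- if (is.null(fit)) {
    list(value = NA_real_, used_spiked = NA)
  } else {
    estimate_lod(groups$blanks_pre, lowest_areas, fit,
                 control$lod_multiplier)
  }

  lloq_area <- if (!is.na(lloq)) s$mean[s$point == lloq] else NA_real_
  top <- max(s$point)
  co <- assess_carryover(groups$blanks_post,
                         groups$calibration[[as.character(top)]],
                         lloq_area)

  list(
    row = data.frame(
      Peptide = set$key$peptide_sequence,
      Transition = transition_label(set$key),
      `LOD.value` = lod$value,
      `LOD.usedSpiked` = lod$used_spiked,
      `LLOQ.CaliPoint` = lloq,
      `ULOQ.CaliPoint` = uloq,
      `Curve.Slope` = if (is.null(fit)) NA_real_ else fit$slope,
      `Curve.Intercept` = if (is.null(fit)) NA_real_ else fit$intercept,
      `Curve.Rsquared` = if (is.null(fit)) NA_real_ else fit$r_squared,
      `Curve.SlopeStdErr(%)` = if (is.null(fit)) NA_real_ else fit$slope_se_pct,
      `Carryover.percent` = co$percent,
      `Carryover.flag` = co$flag,
      check.names = FALSE, stringsAsFactors = FALSE
    ),
    fit = fit
  )
}

#' Compute the response-curve report
#'
#' Runs the full response-curve characterization for every transition of
#' every peptide in the assay, and for each peptide's summed-transition
#' series: limit of detection (with spiked-in fallback), LLOQ and ULOQ
#' calibration points from the contiguous linear-range search, the
#' calibration regression (slope, intercept, R^2, slope standard error in
#' percent) and carry-over.
#'
#' @param assay An `mrm_assay` with a dilution map.
#' @param control Analysis parameters from [mrm_control()].
#' @return An object of class `mrm_response_curve`. `as.data.frame()`
#'   extracts the report table (one row per transition plus one summed row
#'   per peptide); `coef()` returns the fitted slopes and intercepts;
#'   `plot()` draws per-peptide calibration panels.
#' @examples
#' sim <- simulate_response_curve(simulation_config(seed = 7, n_peptides = 2))
#' assay <- mrm_assay(sim$export, sim$metadata, sim$dilution)
#' rc <- response_curve(assay)
#' summary(rc)
#' @export
response_curve <- function(assay, control = mrm_control()) {
  stopifnot(inherits(assay, "mrm_assay"))
  if (is.null(assay$dilution)) {
    stop("response_curve: the assay has no dilution map", call. = FALSE)
  }
  rows <- list()
  fits <- list()
  for (i in seq_len(nrow(assay$peptides))) {
    sets <- .peptide_sets(assay, assay$peptides$peptide_sequence[i],
                          assay$peptides$precursor_charge[i])
    all_sets <- c(sets, list(sum_transitions(sets)))
    for (s in all_sets) {
      res <- .rc_row(s, assay$dilution, control)
      id <- .set_id(s$key)
      rows[[id]] <- res$row
      fits[[id]] <- res$fit
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, fits = fits, control = control,
                 dilution = assay$dilution, assay = assay),
            class = "mrm_response_curve")
}

#' @export
as.data.frame.mrm_response_curve <- function(x, ...) x$results

#' @export
print.mrm_response_curve <- function(x, ...) {
  df <- x$results
  cat("Response-curve report:", nrow(df), "rows (",
      sum(df$Transition != "summed"), "transitions,",
      sum(df$Transition == "summed"), "summed )\n", sep = " ")
  print(utils::head(df, 10), digits = 6)
  if (nrow(df) > 10) cat("  ...", nrow(df) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.mrm_response_curve <- function(object, ...) {
  df <- object$results
  out <- list(
    n_peptides = length(unique(df$Peptide)),
    n_rows = nrow(df),
    lod_range = range(df$`LOD.value`, na.rm = TRUE),
    r_squared_range = range(df$`Curve.Rsquared`, na.rm = TRUE),
    slope_se_pct_range = range(df$`Curve.SlopeStdErr(%)`, na.rm = TRUE),
    lloq_estimable = sum(!is.na(df$`LLOQ.CaliPoint`)),
    lloq_not_estimable = sum(is.na(df$`LLOQ.CaliPoint`))
  )
  class(out) <- "summary.mrm_response_curve"
  out
}

#' @export
print.summary.mrm_response_curve <- function(x, ...) {
  cat("Response-curve summary\n")
  cat(sprintf("  peptides: %d, report rows: %d\n", x$n_peptides, x$n_rows))
  cat(sprintf("  LOD range: %.6g - %.6g\n", x$lod_range[1], x$lod_range[2]))
  cat(sprintf("  R^2 range: %.6g - %.6g\n",
              x$r_squared_range[1], x$r_squared_range[2]))
  cat(sprintf("  SlopeStdErr(%%) range: %.4f - %.4f\n",
              x$slope_se_pct_range[1], x$slope_se_pct_range[2]))
  cat(sprintf("  LLOQ estimable for %d rows, not estimable for %d\n",
              x$lloq_estimable, x$lloq_not_estimable))
  invisible(x)
}

#' @export
coef.mrm_response_curve <- function(object, ...) {
  df <- object$results
  m <- cbind(slope = df$`Curve.Slope`, intercept = df$`Curve.Intercept`)
  rownames(m) <- paste(df$Peptide, df$Transition, sep = "|")
  m
}
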