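# Figures: per-peptide response-curve and repeatability panels, and the
# eight-panel global overview.

#' Plot per-peptide response curves
#'
#' Draws one panel per monitored transition plus one for the summed
#' transition: replicate peak areas against theoretical concentration on
#' log-log axes with the fitted calibration line.
#'
#' @param x An `mrm_response_curve` object.
#' @param peptide Peptide sequence to plot (default: the first peptide).
#' @param ... Ignored.
#' @return Invisibly, `x`.
#' @export
plot.mrm_response_curve <- function(x, peptide = NULL, ...) {
  assay <- x$assay
  if (is.null(peptide)) peptide <- assay$peptides$peptide_sequence[1L]
  i <- match(peptide, assay$peptides$peptide_sequence)
  if (is.na(i)) stop("unknown peptide: ", peptide, call. = FALSE)
  sets <- .peptide_sets(assay, peptide, assay$peptides$precursor_charge[i])
  all_sets <- c(sets, list(sum_transitions(sets)))

  old <- graphics::par(mfrow = grDevices::n2mfrow(length(all_sets)),
                       mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(old))
  for (s in all_sets) {
    g <- group_by_design(s, "response_curve")
    obs <- .calibration_obs(g$calibration, x$dilution)
    obs <- obs[!is.na(obs$area) & obs$area > 0 & obs$conc > 0, , drop = FALSE]
    lab <- transition_label(s$key)
    if (!nrow(obs)) {
      graphics::plot.new()
      graphics::title(main = paste(peptide, lab, "(no detectable signal)"))
      next
    }
    graphics::plot(obs$conc, obs$area, log = "xy",
                   xlab = "theoretical concentration",
                   ylab = "peak area", pch = 19, col = "grey30",
                   main = paste(peptide, "-", lab))
    fit <- x$fits[[paste(peptide, lab, sep = "|")]]
    if (!is.null(fit) && is.finite(fit$slope) && fit$slope > 0) {
      cc <- exp(seq(log(min(obs$conc)), log(max(obs$conc)),
                    length.out = 100))
      yy <- fit$intercept + fit$slope * cc
      keep <- yy > 0
      graphics::lines(cc[keep], yy[keep], col = "firebrick", lwd = 2)
    }
  }
  invisible(x)
}

#' Plot per-peptide repeatability profiles
#'
#' For the peptide's summed transition, plots the per-day median of the
#' replicate measurements at the low, medium and high concentration levels
#' against acquisition day (one panel per level).
#'
#' @param x An `mrm_repeatability` object.
#' @param peptide Peptide sequence to plot (default: the first peptide).
#' @param ... Ignored.
#' @return Invisibly, `x`.
#' @export
plot.mrm_repeatability <- function(x, peptide = NULL, ...) {
  assay <- x$assay
  if (is.null(peptide)) peptide <- assay$peptides$peptide_sequence[1L]
  i <- match(peptide, assay$peptides$peptide_sequence)
  if (is.na(i)) stop("unknown peptide: ", peptide, call. = FALSE)
  sets <- .peptide_sets(assay, peptide, assay$peptides$precursor_charge[i])
  summed <- sum_transitions(sets)
  groups <- group_by_design(summed, "repeatability")$levels

  lv <- intersect(.conc_levels, names(groups))
  old <- graphics::par(mfrow = c(1, length(lv)), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(old))
  for (l in lv) {
    med <- .day_medians(groups[[l]])
    days <- as.integer(names(groups[[l]]))
    graphics::plot(days, med, type = "b", pch = 19, col = "grey20",
                   xlab = "day", ylab = "median peak area (replicates)",
                   main = paste(peptide, "- summed,", l))
  }
  invisible(x)
}

#' Global assay-performance overview
#'
#' Draws the eight-panel overview of assay performance across all assayed
#' transitions: the LOD distribution (log10), the LLOQ calibration-point
#' distribution, the calibration R^2 and slope-standard-error
#' distributions, per-level boxplots of the intra-, inter- and total CV,
#' and the distribution of maximum transition-ratio deviations.
#'
#' @param rc An `mrm_response_curve` object.
#' @param rep An `mrm_repeatability` object.
#' @param file Optional PNG path; when given the figure is written there.
#' @return Invisibly, `NULL`.
#' @export
mrm_overview <- function(rc, rep, file = NULL) {
  stopifnot(inherits(rc, "mrm_response_curve"),
            inherits(rep, "mrm_repeatability"))
  if (!is.null(file)) {
    grDevices::png(file, width = 1600, height = 900, res = 110)
    on.exit(grDevices::dev.off())
  }
  rcd <- rc$results
  rpd <- rep$results
  old <- graphics::par(mfrow = c(2, 4), mar = c(4, 4, 2.5, 1))
  # restore par before any registered dev.off(), or the restore would
  # reopen a default device
  on.exit(graphics::par(old), add = TRUE, after = FALSE)

  hist_or_empty <- function(x, main, xlab) {
    x <- x[is.finite(x)]
    if (length(x)) graphics::hist(x, main = main, xlab = xlab,
                                  col = "grey80", border = "grey40")
    else {
      graphics::plot.new()
      graphics::title(main = paste(main, "(no data)"))
    }
  }
  hist_or_empty(log10(rcd$`LOD.value`[rcd$`LOD.value` > 0]),
                "LOD distribution", "log10 LOD")
  lloq <- table(factor(rcd$`LLOQ.CaliPoint`,
                       levels = sort(unique(rc$dilution$calibration_point))))
  graphics::barplot(lloq, main = "LLOQ calibration point",
                    xlab = "calibration point", col = "grey80")
  hist_or_empty(rcd$`Curve.Rsquared`, "Calibration R^2", "R^2")
  hist_or_empty(rcd$`Curve.SlopeStdErr(%)`, "Slope standard error",
                "SE(slope) % of slope")

  cv_panel <- function(prefix, main) {
    cols <- paste0(prefix, ".", .conc_levels)
    vals <- lapply(cols, function(cn) {
      v <- rpd[[cn]]
      v[is.finite(v)]
    })
    names(vals) <- .conc_levels
    graphics::boxplot(vals, main = main, ylab = "CV (%)", col = "grey80")
  }
  cv_panel("intraCV", "Intra-assay CV by level")
  cv_panel("interCV", "Inter-assay CV by level")
  cv_panel("totalCV", "Total CV by level")
  hist_or_empty(rpd$`PVSpec.maxDeviation`,
                "Transition-ratio deviation", "max deviation (%)")
  invisible(NULL)
}

# All figures for mrm_run(visualize = TRUE).
.write_figures <- function(results, out) {
  paths <- character(0)
  assay <- results$assay
  if (!is.null(results$response_curve)) {
    for (pep in assay$peptides$peptide_sequence) {
      p <- file.path(out, paste0("response_curve_", pep, ".png"))
      grDevices::png(p, width = 1200, height = 900, res = 110)
      plot(results$response_curve, peptide = pep)
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  }
  if (!is.null(results$repeatability)) {
    for (pep in assay$peptides$peptide_sequence) {
      p <- file.path(out, paste0("repeatability_", pep, ".png"))
      grDevices::png(p, width = 1200, height = 450, res = 110)
      plot(results$repeatability, peptide = pep)
      grDevices::dev.off()
      paths <- c(paths, p)
    }
  }
  if (!is.null(results$response_curve) && !is.null(results$repeatability)) {
    p <- file.path(out, "overview.png")
    mrm_overview(results$response_curve, results$repeatability, file = p)
    paths <- c(paths, p)
  }
  paths
}
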