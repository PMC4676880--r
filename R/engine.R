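# Engine configuration and the end-to-end run driver.

#' Analysis control parameters
#'
#' Collects the tunable thresholds of the characterization engine. All
#' thresholds are percentages and must be positive.
#'
#' @param lod_multiplier Sigma multiplier in the LOD estimator (default 3,
#'   the classical 3-sigma convention).
#' @param lloq_cv_threshold Replicate CV bound for LLOQ qualification and
#'   the linear-range search, percent (default 20).
#' @param accuracy_tolerance Back-calculated accuracy bound of the
#'   linear-range search, percent of nominal (default 20).
#' @param specificity_threshold Maximum tolerated transition-ratio
#'   deviation, percent (default 30).
#' @param validation_cv_threshold Total-CV bound validating an LLOQ
#'   concentration level in the repeatability experiment, percent
#'   (default 20).
#' @param ratio_denominator Transition-ratio denominator: `"sum"` of all
#'   monitored transitions (default; ratios are relative fractions) or
#'   `"max_transition"`.
#' @param weighting Calibration-regression weighting: `"none"` (default),
#'   `"inv_x"` or `"inv_x2"`.
#' @return An object of class `mrm_control`.
#' @export
mrm_control <- function(lod_multiplier = 3,
                        lloq_cv_threshold = 20,
                        accuracy_tolerance = 20,
                        specificity_threshold = 30,
                        validation_cv_threshold = 20,
                        ratio_denominator = c("sum", "max_transition"),
                        weighting = c("none", "inv_x", "inv_x2")) {
  ratio_denominator <- match.arg(ratio_denominator)
  weighting <- match.arg(weighting)
  vals <- c(lod_multiplier, lloq_cv_threshold, accuracy_tolerance,
            specificity_threshold, validation_cv_threshold)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("mrm_control: all thresholds must be positive", call. = FALSE)
  }
  structure(list(lod_multiplier = lod_multiplier,
                 lloq_cv_threshold = lloq_cv_threshold,
                 accuracy_tolerance = accuracy_tolerance,
                 specificity_threshold = specificity_threshold,
                 validation_cv_threshold = validation_cv_threshold,
                 ratio_denominator = ratio_denominator,
                 weighting = weighting),
            class = "mrm_control")
}

#' @export
print.mrm_control <- function(x, ...) {
  cat("MRM analysis control\n")
  cat(sprintf("  LOD multiplier: %g | LLOQ CV <= %g %% | accuracy +/- %g %%\n",
              x$lod_multiplier, x$lloq_cv_threshold, x$accuracy_tolerance))
  cat(sprintf("  specificity <= %g %% | validation total CV <= %g %%\n",
              x$specificity_threshold, x$validation_cv_threshold))
  cat(sprintf("  ratio denominator: %s | regression weighting: %s\n",
              x$ratio_denominator, x$weighting))
  invisible(x)
}

#' Read a flat key=value engine configuration file
#'
#' Parses a plain-text configuration file of `key = value` lines (`#`
#' comments and blank lines ignored) into an [mrm_control()] object plus
#' any non-threshold keys (`mode`, `visualize`, `output_dir`). Keys given
#' explicitly to [mrm_run()] override file values.
#'
#' @param path Path to the configuration file.
#' @return A list with elements `control` (an `mrm_control`) and `extra`
#'   (named list of any other recognised keys).
#' @export
read_engine_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, function(x) trimws(x[1L]), "")
  vals <- vapply(kv, function(x) trimws(paste(x[-1L], collapse = "=")), "")
  names(vals) <- keys

  ctl_args <- list()
  num_keys <- c("lod_multiplier", "lloq_cv_threshold", "accuracy_tolerance",
                "specificity_threshold", "validation_cv_threshold")
  for (k in intersect(num_keys, keys)) ctl_args[[k]] <- as.numeric(vals[[k]])
  for (k in intersect(c("ratio_denominator", "weighting"), keys)) {
    ctl_args[[k]] <- vals[[k]]
  }
  extra <- as.list(vals[setdiff(keys, c(num_keys, "ratio_denominator",
                                        "weighting"))])
  if ("visualize" %in% names(extra)) {
    extra$visualize <- toupper(extra$visualize) %in% c("TRUE", "1", "YES")
  }
  list(control = do.call(mrm_control, ctl_args), extra = extra)
}

#' Run the characterization engine end to end
#'
#' Parses the input files, assembles the assay, computes the requested
#' reports and writes them as tab-delimited files
#' (`response_curve_report.tsv`, `repeatability_report.tsv`) into the
#' output directory. With `visualize = TRUE`, per-peptide response-curve
#' and repeatability figures and an eight-panel global overview are written
#' as PNG files alongside the reports.
#'
#' @param skyline,metadata,dilution Paths to the three input files (or
#'   pre-parsed data frames). `dilution` may be `NULL` in pure
#'   repeatability mode.
#' @param mode `"both"` (default), `"response_curve"` or `"repeatability"`.
#' @param out Output directory (created if necessary).
#' @param control An [mrm_control()]; overrides `config_file` values.
#' @param config_file Optional flat key=value configuration file read with
#'   [read_engine_config()]; explicit arguments win on conflict.
#' @param visualize Write figures as well as reports.
#' @param column_map Optional input column renaming (see
#'   [parse_skyline_export()]).
#' @return Invisibly, a list with the result objects and the written file
#'   paths.
#' @export
mrm_run <- function(skyline, metadata, dilution = NULL,
                    mode = c("both", "response_curve", "repeatability"),
                    out = ".", control = NULL, config_file = NULL,
                    visualize = FALSE, column_map = NULL) {
  mode_given <- !missing(mode)
  mode <- match.arg(mode)
  if (!is.null(config_file)) {
    cfg <- read_engine_config(config_file)
    if (is.null(control)) control <- cfg$control
    if (!mode_given && !is.null(cfg$extra$mode)) {
      mode <- match.arg(cfg$extra$mode,
                        c("both", "response_curve", "repeatability"))
    }
    if (missing(visualize) && !is.null(cfg$extra$visualize)) {
      visualize <- cfg$extra$visualize
    }
  }
  if (is.null(control)) control <- mrm_control()
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out)) stop("mrm_run: cannot create output directory ", out,
                             call. = FALSE)

  assay <- mrm_assay(skyline, metadata, dilution, column_map)
  results <- list(assay = assay, control = control, paths = list())

  if (mode %in% c("both", "response_curve")) {
    rc <- response_curve(assay, control)
    p <- file.path(out, "response_curve_report.tsv")
    write_report(rc, p)
    message("wrote ", p, " (", nrow(rc$results), " rows)")
    results$response_curve <- rc
    results$paths$response_curve <- p
  }
  if (mode %in% c("both", "repeatability")) {
    rp <- repeatability(assay, control)
    p <- file.path(out, "repeatability_report.tsv")
    write_report(rp, p)
    message("wrote ", p, " (", nrow(rp$results), " rows)")
    results$repeatability <- rp
    results$paths$repeatability <- p
  }
  if (visualize) {
    results$paths$figures <- .write_figures(results, out)
  }
  invisible(results)
}
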