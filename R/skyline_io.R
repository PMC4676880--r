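# Readers for the three tab-delimited inputs (Skyline transition-results
# export, run metadata, dilution map) and the tab-delimited report writer.

# Canonical Skyline transition-results column names. Header matching is
# case-insensitive and tolerant of space/underscore/dot separators; a
# user-supplied column_map may rename any of them.
.sky_export_cols <- c(
  peptide_sequence = "Peptide Sequence",
  precursor_charge = "Precursor Charge",
  fragment_ion     = "Fragment Ion",
  product_charge   = "Product Charge",
  replicate_name   = "Replicate Name",
  peak_area        = "Area"
)

.metadata_cols <- c(
  replicate_name      = "Replicate Name",
  sample_type         = "Sample Type",
  day                 = "Day",
  replicate_index     = "Replicate",
  concentration_level = "Concentration Level",
  calibration_point   = "Calibration Point"
)

.dilution_cols <- c(
  calibration_point         = "Calibration Point",
  theoretical_concentration = "Concentration"
)

# Read a tab-delimited file as character cells, keeping the raw header.
.read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    stop("format error: empty file: ", path, call. = FALSE)
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  body <- lines[-1L]
  keep <- nzchar(trimws(body))
  skipped <- which(!keep)
  for (ln in skipped) {
    message("skipping empty line ", ln + 1L, " in ", basename(path))
  }
  body <- body[keep]
  cells <- if (length(body)) strsplit(body, "\t", fixed = TRUE) else list()
  list(header = trimws(header), cells = cells,
       line_numbers = which(keep) + 1L)
}

.field <- function(cells, idx) {
  vapply(cells, function(r) if (idx <= length(r)) r[[idx]] else "", "")
}

.require_columns <- function(header, canonical, map, what) {
  idx <- vapply(names(canonical), function(f) {
    .find_column(header, canonical[[f]], map, f)
  }, integer(1))
  if (anyNA(idx)) {
    miss <- canonical[names(idx)[is.na(idx)]]
    stop("format error in ", what, ": missing required column(s): ",
         paste(sQuote(miss), collapse = ", "), call. = FALSE)
  }
  idx
}

#' Parse a Skyline transition-results export
#'
#' Reads a tab-delimited Skyline transition-results export into a data frame
#' with one row per (transition, run) measurement. The six required columns
#' are matched case-insensitively and tolerantly of space/underscore
#' variants against the canonical Skyline names (`"Peptide Sequence"`,
#' `"Precursor Charge"`, `"Fragment Ion"`, `"Product Charge"`,
#' `"Replicate Name"`, `"Area"`); report templates with different headers
#' can be read by supplying `column_map`.
#'
#' Missing or non-numeric area cells (`""`, `"#N/A"`, `"NA"`, `"NaN"`)
#' become `NA`, never zero. Row order is preserved and no data line is
#' silently dropped; skipped blank lines are reported via [message()] with
#' their line number.
#'
#' @param path Path to the tab-delimited export file (UTF-8, header line
#'   mandatory).
#' @param column_map Optional named character vector or list mapping any of
#'   the internal field names (`peptide_sequence`, `precursor_charge`,
#'   `fragment_ion`, `product_charge`, `replicate_name`, `peak_area`) to the
#'   header actually used in the file.
#' @return A data frame with columns `peptide_sequence`, `precursor_charge`,
#'   `fragment_ion`, `product_charge`, `replicate_name`, `peak_area`.
#' @seealso [parse_metadata()], [parse_dilution_map()], [mrm_assay()]
#' @export
parse_skyline_export <- function(path, column_map = NULL) {
  raw <- .read_tsv_raw(path)
  idx <- .require_columns(raw$header, .sky_export_cols, column_map,
                          "Skyline export")
  out <- data.frame(
    peptide_sequence = trimws(.field(raw$cells, idx[["peptide_sequence"]])),
    precursor_charge = .parse_int(.field(raw$cells, idx[["precursor_charge"]])),
    fragment_ion     = trimws(.field(raw$cells, idx[["fragment_ion"]])),
    product_charge   = .parse_int(.field(raw$cells, idx[["product_charge"]])),
    replicate_name   = trimws(.field(raw$cells, idx[["replicate_name"]])),
    peak_area        = .parse_area(.field(raw$cells, idx[["peak_area"]])),
    stringsAsFactors = FALSE
  )
  bad_seq <- !.valid_sequence(out$peptide_sequence)
  if (any(bad_seq)) {
    stop("format error in Skyline export: invalid peptide sequence at line(s) ",
         paste(raw$line_numbers[bad_seq], collapse = ", "), call. = FALSE)
  }
  bad_charge <- is.na(out$precursor_charge) | out$precursor_charge < 1L |
    is.na(out$product_charge) | out$product_charge < 1L
  if (any(bad_charge)) {
    stop("format error in Skyline export: invalid charge at line(s) ",
         paste(raw$line_numbers[bad_charge], collapse = ", "), call. = FALSE)
  }
  neg <- !is.na(out$peak_area) & out$peak_area < 0
  if (any(neg)) {
    stop("format error in Skyline export: negative peak area at line(s) ",
         paste(raw$line_numbers[neg], collapse = ", "), call. = FALSE)
  }
  out
}

#' Parse the experiment-metadata file
#'
#' Reads the run-annotation table that maps each mass-spectrometry run
#' (replicate name) to its experiment-design coordinates: sample type
#' (`blank`, `calibration`, or `qc`), acquisition day, replicate index,
#' calibration point (calibration runs only) and concentration level
#' (`low`/`medium`/`high`, QC runs only). Row order is taken as acquisition
#' order, which downstream code uses to distinguish pre-curve blanks from
#' blanks acquired after the highest calibration point (carry-over blanks).
#'
#' @param path Path to the tab-delimited metadata file. Expected columns
#'   (tolerantly matched): `Replicate Name`, `Sample Type`, `Day`,
#'   `Replicate`, `Concentration Level`, `Calibration Point`.
#' @param column_map Optional header renaming as in
#'   [parse_skyline_export()], keyed by `replicate_name`, `sample_type`,
#'   `day`, `replicate_index`, `concentration_level`, `calibration_point`.
#' @return A data frame with one validated row per run, in file order, plus
#'   a `run_order` column recording acquisition rank.
#' @export
parse_metadata <- function(path, column_map = NULL) {
  raw <- .read_tsv_raw(path)
  idx <- .require_columns(raw$header, .metadata_cols, column_map, "metadata")
  out <- data.frame(
    replicate_name      = trimws(.field(raw$cells, idx[["replicate_name"]])),
    sample_type         = tolower(trimws(.field(raw$cells, idx[["sample_type"]]))),
    day                 = .parse_int(.field(raw$cells, idx[["day"]])),
    replicate_index     = .parse_int(.field(raw$cells, idx[["replicate_index"]])),
    concentration_level = tolower(trimws(.field(raw$cells, idx[["concentration_level"]]))),
    calibration_point   = .parse_int(.field(raw$cells, idx[["calibration_point"]])),
    stringsAsFactors = FALSE
  )
  out$concentration_level[out$concentration_level %in% .na_spellings] <- NA_character_
  out$run_order <- seq_len(nrow(out))

  dup <- duplicated(out$replicate_name)
  if (any(dup)) {
    stop("metadata error: duplicate replicate name(s): ",
         paste(unique(out$replicate_name[dup]), collapse = ", "),
         call. = FALSE)
  }
  bad_type <- !(out$sample_type %in% c("blank", "calibration", "qc"))
  if (any(bad_type)) {
    stop("metadata error: unknown sample type(s): ",
         paste(unique(out$sample_type[bad_type]), collapse = ", "),
         " (expected blank/calibration/qc)", call. = FALSE)
  }
  bad_level <- !is.na(out$concentration_level) &
    !(out$concentration_level %in% .conc_levels)
  if (any(bad_level)) {
    stop("metadata error: unknown concentration level(s): ",
         paste(unique(out$concentration_level[bad_level]), collapse = ", "),
         call. = FALSE)
  }
  # Conditional-presence invariants per sample type.
  cal <- out$sample_type == "calibration"
  qc <- out$sample_type == "qc"
  blank <- out$sample_type == "blank"
  viol <- (cal & (is.na(out$calibration_point) | !is.na(out$concentration_level))) |
    (qc & (is.na(out$concentration_level) | !is.na(out$calibration_point))) |
    (blank & (!is.na(out$calibration_point) | !is.na(out$concentration_level)))
  if (any(viol)) {
    stop("metadata error: sample-type/annotation mismatch for run(s): ",
         paste(out$replicate_name[viol], collapse = ", "),
         " (calibration runs need a calibration point, qc runs a ",
         "concentration level, blank runs neither)", call. = FALSE)
  }
  if (any(is.na(out$replicate_index) | out$replicate_index < 1L)) {
    stop("metadata error: replicate index must be a positive integer",
         call. = FALSE)
  }
  out
}

#' Parse the serial-dilution map
#'
#' Reads the calibration-point-to-concentration table for a response-curve
#' experiment. Concentrations are in whatever units the file provides
#' (e.g. fmol/uL) and must increase strictly with calibration point.
#'
#' @param path Path to the tab-delimited dilution file. Expected columns
#'   (tolerantly matched): `Calibration Point`, `Concentration`.
#' @param column_map Optional header renaming keyed by `calibration_point`,
#'   `theoretical_concentration`.
#' @return A data frame with columns `calibration_point` and
#'   `theoretical_concentration`, sorted by calibration point.
#' @export
parse_dilution_map <- function(path, column_map = NULL) {
  raw <- .read_tsv_raw(path)
  idx <- .require_columns(raw$header, .dilution_cols, column_map,
                          "dilution map")
  out <- data.frame(
    calibration_point = .parse_int(.field(raw$cells, idx[["calibration_point"]])),
    theoretical_concentration =
      .parse_area(.field(raw$cells, idx[["theoretical_concentration"]])),
    stringsAsFactors = FALSE
  )
  if (anyNA(out$calibration_point) || anyNA(out$theoretical_concentration)) {
    stop("dilution map error: missing calibration point or concentration",
         call. = FALSE)
  }
  if (anyDuplicated(out$calibration_point)) {
    stop("dilution map error: duplicate calibration point(s)", call. = FALSE)
  }
  if (any(out$theoretical_concentration < 0)) {
    stop("dilution map error: negative concentration", call. = FALSE)
  }
  out <- out[order(out$calibration_point), , drop = FALSE]
  if (any(diff(out$theoretical_concentration) <= 0)) {
    stop("dilution map error: concentrations must increase strictly with ",
         "calibration point", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

# Column classes driving report formatting: CVs and percentages print with
# 4 decimal places, other reals with 6 significant figures.
.pct_col <- function(nm) {
  grepl("^(intraCV|interCV|totalCV)", nm) |
    nm %in% c("Curve.SlopeStdErr(%)", "Carryover.percent",
              "PVSpec.maxDeviation", "totalCV.Me")
}

.format_report_cell <- function(x, pct) {
  if (is.na(x)) return("NA")
  if (is.logical(x)) return(if (x) "TRUE" else "FALSE")
  if (is.character(x)) return(x)
  if (is.integer(x)) return(format(x))
  if (pct) sprintf("%.4f", x) else format(signif(x, 6))
}

#' Write a performance report
#'
#' Writes a response-curve or repeatability result table to a tab-delimited
#' file: one header line with the exact report column names, one row per
#' (peptide, transition) including the summed-transition rows, missing or
#' not-applicable cells rendered as `"NA"`. Coefficients of variation and
#' percentages are printed with 4 decimal places, other real values with 6
#' significant figures.
#'
#' @param rows A result table: an `mrm_response_curve` or
#'   `mrm_repeatability` object, or the data frame extracted from one with
#'   [as.data.frame()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @seealso [read_report()] for the inverse operation.
#' @export
write_report <- function(rows, path) {
  df <- as.data.frame(rows)
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write report: ",
                                           conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    pct <- .pct_col(names(df))
    lines <- vapply(seq_len(nrow(df)), function(i) {
      paste(vapply(seq_along(df), function(j) {
        .format_report_cell(df[[j]][i], pct[j])
      }, ""), collapse = "\t")
    }, "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read back a written performance report
#'
#' Inverse of [write_report()]: reads a tab-delimited report file into a
#' data frame, mapping `"NA"` cells back to missing values and restoring
#' column types (logical for flag columns, integer for calibration-point
#' and day columns, numeric elsewhere).
#'
#' @param path Path to a report file produced by [write_report()].
#' @return A data frame with the report's columns.
#' @export
read_report <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, na.strings = "NA",
                          stringsAsFactors = FALSE)
  int_cols <- intersect(c("LLOQ.CaliPoint", "ULOQ.CaliPoint",
                          "PVSpec.dayAtMaxDev"), names(df))
  for (nm in int_cols) df[[nm]] <- as.integer(df[[nm]])
  lgl_cols <- intersect(c("LOD.usedSpiked", "Carryover.flag",
                          "PVSpec.specific"), names(df))
  for (nm in lgl_cols) df[[nm]] <- as.logical(df[[nm]])
  df
}
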