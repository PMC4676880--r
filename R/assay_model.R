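# Assembly of parsed rows into per-transition measurement sets, the
# summed-transition series, and design-aware grouping.

#' Transition display label
#'
#' Renders a transition key as the conventional
#' `"{precursor charge}.{fragment ion}.{product charge}"` label
#' (e.g. `"2.y4.1"`); summed-transition keys render as `"summed"`.
#'
#' @param key A transition key as stored in a measurement set (a list with
#'   fields `peptide_sequence`, `precursor_charge`, `fragment_ion`,
#'   `product_charge`, `is_summed`).
#' @return A character scalar.
#' @export
transition_label <- function(key) {
  if (isTRUE(key$is_summed)) return("summed")
  paste(key$precursor_charge, key$fragment_ion, key$product_charge, sep = ".")
}

.set_id <- function(key) {
  paste(key$peptide_sequence, transition_label(key), sep = "|")
}

.new_measurement_set <- function(key, data) {
  rownames(data) <- NULL
  structure(list(key = key, data = data), class = "mrm_measurement_set")
}

#' @export
print.mrm_measurement_set <- function(x, ...) {
  cat("Measurement set:", x$key$peptide_sequence,
      transition_label(x$key), "-", nrow(x$data), "runs\n")
  invisible(x)
}

#' Assemble an assay object from export and metadata
#'
#' Joins a Skyline-style transition-level export with the run metadata into
#' an `mrm_assay`: one measurement set per distinct transition
#' (peptide sequence, precursor charge, fragment ion, product charge), each
#' holding that transition's peak area and design annotation for every run
#' it was exported in. Every run named in the export must have exactly one
#' metadata row; runs annotated in the metadata but absent from the export
#' only raise a warning.
#'
#' @param export A parsed export data frame ([parse_skyline_export()]) or a
#'   path to the export file.
#' @param metadata A parsed metadata data frame ([parse_metadata()]) or a
#'   path to the metadata file.
#' @param dilution Optional parsed dilution map ([parse_dilution_map()]) or
#'   path; required later for response-curve analysis.
#' @param column_map Optional column renaming forwarded to the parsers when
#'   paths are given.
#' @return An object of class `mrm_assay`: a list with elements `sets`
#'   (named list of measurement sets), `peptides` (data frame of distinct
#'   peptide/precursor-charge pairs), `metadata` and `dilution`.
#' @examples
#' sim <- simulate_response_curve(simulation_config(seed = 1, n_peptides = 2))
#' assay <- mrm_assay(sim$export, sim$metadata, sim$dilution)
#' assay
#' @export
mrm_assay <- function(export, metadata, dilution = NULL, column_map = NULL) {
  if (is.character(export)) export <- parse_skyline_export(export, column_map)
  if (is.character(metadata)) metadata <- parse_metadata(metadata, column_map)
  if (is.character(dilution)) dilution <- parse_dilution_map(dilution, column_map)

  orphan <- setdiff(unique(export$replicate_name), metadata$replicate_name)
  if (length(orphan)) {
    stop("assembly error: export run(s) with no metadata row: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  unused <- setdiff(metadata$replicate_name, unique(export$replicate_name))
  if (length(unused)) {
    warning("metadata run(s) absent from export: ",
            paste(unused, collapse = ", "), call. = FALSE)
  }

  ann_cols <- c("sample_type", "day", "replicate_index",
                "concentration_level", "calibration_point", "run_order")
  m <- match(export$replicate_name, metadata$replicate_name)
  merged <- cbind(export, metadata[m, ann_cols, drop = FALSE])

  id <- paste(merged$peptide_sequence, merged$precursor_charge,
              merged$fragment_ion, merged$product_charge, sep = "|")
  split_idx <- split(seq_len(nrow(merged)), factor(id, levels = unique(id)))
  sets <- lapply(split_idx, function(ix) {
    first <- ix[1L]
    key <- list(
      peptide_sequence = merged$peptide_sequence[first],
      precursor_charge = merged$precursor_charge[first],
      fragment_ion = merged$fragment_ion[first],
      product_charge = merged$product_charge[first],
      is_summed = FALSE
    )
    dat <- merged[ix, c("replicate_name", "peak_area", ann_cols)]
    if (anyDuplicated(dat$replicate_name)) {
      stop("assembly error: transition ", .set_id(key),
           " measured more than once in run(s): ",
           paste(unique(dat$replicate_name[duplicated(dat$replicate_name)]),
                 collapse = ", "), call. = FALSE)
    }
    .new_measurement_set(key, dat)
  })
  names(sets) <- vapply(sets, function(s) .set_id(s$key), "")

  pep <- unique(merged[, c("peptide_sequence", "precursor_charge")])
  rownames(pep) <- NULL
  structure(list(sets = sets, peptides = pep, metadata = metadata,
                 dilution = dilution),
            class = "mrm_assay")
}

#' @export
print.mrm_assay <- function(x, ...) {
  cat("MRM assay data:", nrow(x$peptides), "peptide(s),",
      length(x$sets), "transition(s),",
      nrow(x$metadata), "annotated run(s)\n")
  tab <- table(x$metadata$sample_type)
  cat("  runs by sample type:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  if (!is.null(x$dilution)) {
    cat("  dilution map:", nrow(x$dilution), "calibration points spanning",
        min(x$dilution$theoretical_concentration), "-",
        max(x$dilution$theoretical_concentration), "\n")
  }
  invisible(x)
}

# Measurement sets belonging to one peptide (sequence + precursor charge).
.peptide_sets <- function(assay, peptide_sequence, precursor_charge) {
  keep <- vapply(assay$sets, function(s) {
    s$key$peptide_sequence == peptide_sequence &&
      s$key$precursor_charge == precursor_charge
  }, logical(1))
  assay$sets[keep]
}

#' Sum the transitions of one peptide
#'
#' Builds the summed-transition series for a peptide: per run, the sum of
#' the non-missing transition peak areas (missing areas are treated as
#' absent, not zero); a run in which every transition is missing yields a
#' missing summed value. The number of contributing transitions per run is
#' recorded in an `n_contributing` column.
#'
#' @param sets A list of measurement sets sharing one peptide sequence and
#'   precursor charge and covering the same runs.
#' @return A measurement set whose key has `fragment_ion = "summed"` and
#'   `is_summed = TRUE`.
#' @export
sum_transitions <- function(sets) {
  if (length(sets) == 0L) stop("sum_transitions: no measurement sets")
  pep <- unique(vapply(sets, function(s) s$key$peptide_sequence, ""))
  chg <- unique(vapply(sets, function(s) s$key$precursor_charge, 0L))
  if (length(pep) != 1L || length(chg) != 1L) {
    stop("sum_transitions: sets span different peptides or precursor charges: ",
         paste(pep, collapse = ", "), call. = FALSE)
  }
  runs <- sets[[1L]]$data$replicate_name
  for (s in sets[-1L]) {
    if (!setequal(runs, s$data$replicate_name)) {
      stop("sum_transitions: sets do not cover the same runs", call. = FALSE)
    }
  }
  areas <- vapply(sets, function(s) {
    s$data$peak_area[match(runs, s$data$replicate_name)]
  }, numeric(length(runs)))
  areas <- matrix(areas, nrow = length(runs))
  n_contrib <- rowSums(!is.na(areas))
  summed <- rowSums(areas, na.rm = TRUE)
  summed[n_contrib == 0L] <- NA_real_

  dat <- sets[[1L]]$data
  dat$peak_area <- summed
  dat$n_contributing <- n_contrib
  key <- list(peptide_sequence = pep, precursor_charge = chg,
              fragment_ion = "summed", product_charge = NA_integer_,
              is_summed = TRUE)
  .new_measurement_set(key, dat)
}

#' Group a measurement set by experiment design
#'
#' Splits one transition's measurements according to the experiment mode.
#' In `response_curve` mode the result maps each calibration point to its
#' replicate areas and separates blank runs into pre-curve blanks and
#' blanks acquired after the highest calibration point (carry-over blanks,
#' identified by metadata acquisition order). In `repeatability` mode the
#' result maps each (concentration level, day) cell to its replicate areas.
#'
#' @param set A measurement set from [mrm_assay()] or [sum_transitions()].
#' @param mode `"response_curve"` or `"repeatability"`.
#' @return For `response_curve`: a list with `calibration` (list of numeric
#'   vectors named by calibration point, ascending), `blanks_pre`,
#'   `blanks_post`. For `repeatability`: a list with `levels` (per
#'   concentration level, a list of numeric vectors named by day) and the
#'   per-cell replicate detectability.
#' @export
group_by_design <- function(set, mode = c("response_curve", "repeatability")) {
  mode <- match.arg(mode)
  d <- set$data
  if (mode == "response_curve") {
    cal <- d[d$sample_type == "calibration", , drop = FALSE]
    if (!nrow(cal)) {
      stop("group_by_design: no calibration runs for ", .set_id(set$key),
           call. = FALSE)
    }
    pts <- sort(unique(cal$calibration_point))
    groups <- lapply(pts, function(p) cal$peak_area[cal$calibration_point == p])
    names(groups) <- pts
    blanks <- d[d$sample_type == "blank", , drop = FALSE]
    top <- max(cal$calibration_point)
    last_high <- max(cal$run_order[cal$calibration_point == top])
    post <- blanks$run_order > last_high
    list(calibration = groups,
         blanks_pre = blanks$peak_area[!post],
         blanks_post = blanks$peak_area[post])
  } else {
    qc <- d[d$sample_type == "qc", , drop = FALSE]
    if (!nrow(qc)) {
      stop("group_by_design: no qc runs for ", .set_id(set$key),
           call. = FALSE)
    }
    lv <- intersect(.conc_levels, unique(qc$concentration_level))
    levels <- lapply(lv, function(l) {
      sub <- qc[qc$concentration_level == l, , drop = FALSE]
      days <- sort(unique(sub$day))
      g <- lapply(days, function(dd) sub$peak_area[sub$day == dd])
      names(g) <- days
      g
    })
    names(levels) <- lv
    list(levels = levels)
  }
}
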