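# Mini-validation of repeatability: intra-/inter-/total CV by one-way
# random-effects variance decomposition, the validated LLOQ level, and
# partial validation of specificity via transition-ratio stability.

#' Decompose replicate variance into intra-, inter- and total CV
#'
#' One-way random-effects (method-of-moments) decomposition of replicate
#' peak areas grouped by acquisition day. The within-day variance is the
#' pooled within-day mean square; the between-day variance is
#' `max(0, (MS_between - MS_within) / n0)` with
#' `n0 = (N - sum(n_d^2)/N) / (D - 1)`, the standard unbalanced-design
#' average group size. A negative moment estimate of the between-day
#' variance is clamped to zero. Coefficients of variation are each variance
#' component's square root over the grand mean, in percent; the total CV
#' combines both components.
#'
#' Days are retained only if at least two detectable replicates remain;
#' dropped days are reported with a warning. At least two retained days are
#' required.
#'
#' @param day_groups A list of numeric vectors of replicate areas, one per
#'   day (named by day).
#' @return A list with `intra_cv`, `inter_cv`, `total_cv` (percent),
#'   `grand_mean`, `n_days`, `n_total`, and `clamped` (`TRUE` when the
#'   between-day moment estimate was negative), or all-`NA` values when not
#'   estimable.
#' @examples
#' cv_components(list(`1` = c(10, 12), `2` = c(14, 16)))
#' @export
cv_components <- function(day_groups) {
  not_est <- list(intra_cv = NA_real_, inter_cv = NA_real_,
                  total_cv = NA_real_, grand_mean = NA_real_,
                  n_days = 0L, n_total = 0L, clamped = FALSE)
  kept <- lapply(day_groups, function(x) x[.detectable(x)])
  dropped <- names(kept)[vapply(kept, length, 0L) < 2L]
  if (length(dropped) && length(dropped) < length(kept)) {
    warning("cv_components: dropping day(s) with <2 detectable replicates: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  kept <- kept[vapply(kept, length, 0L) >= 2L]
  D <- length(kept)
  if (D < 2L) return(not_est)

  y <- unlist(kept, use.names = FALSE)
  n_d <- vapply(kept, length, 0L)
  N <- length(y)
  grand <- mean(y)
  if (grand <= 0) return(not_est)

  day_means <- vapply(kept, mean, 0)
  ms_within <- sum(vapply(kept, function(g) sum((g - mean(g))^2), 0)) / (N - D)
  ms_between <- sum(n_d * (day_means - grand)^2) / (D - 1)
  n0 <- (N - sum(n_d^2) / N) / (D - 1)
  sigma2_b_raw <- (ms_between - ms_within) / n0
  clamped <- sigma2_b_raw < 0
  sigma2_b <- max(0, sigma2_b_raw)

  list(intra_cv = 100 * sqrt(ms_within) / grand,
       inter_cv = 100 * sqrt(sigma2_b) / grand,
       total_cv = 100 * sqrt(ms_within + sigma2_b) / grand,
       grand_mean = grand, n_days = D, n_total = N, clamped = clamped)
}

# Median of detectable replicate areas per day; NA for empty days.
.day_medians <- function(day_groups) {
  vapply(day_groups, function(x) {
    d <- x[.detectable(x)]
    if (length(d)) stats::median(d) else NA_real_
  }, 0)
}

#' Determine the validated LLOQ concentration level
#'
#' Scans the QC concentration levels in increasing order (low < medium <
#' high) for the lowest level whose total CV is at or below the validation
#' threshold and whose replicates are all detectable on all days. The
#' reported `totalCV.Me` is the median-based total CV at that level: the CV
#' of the per-day medians of replicate measurements
#' (`100 * sd(day medians) / mean(day medians)`).
#'
#' @param level_results Named list (by level) of [cv_components()] results.
#' @param level_groups Named list (by level) of day-grouped replicate areas,
#'   as in [group_by_design()] repeatability mode.
#' @param threshold Total CV validation bound in percent (default 20).
#' @return A list with `level` (`"low"`, `"medium"`, `"high"` or `NA` when
#'   no level validates) and `total_cv_me` (percent or `NA`).
#' @export
validated_lloq <- function(level_results, level_groups, threshold = 20) {
  for (lv in intersect(.conc_levels, names(level_results))) {
    res <- level_results[[lv]]
    if (is.na(res$total_cv) || res$total_cv > threshold) next
    groups <- level_groups[[lv]]
    all_detect <- all(vapply(groups, function(x) {
      length(x) > 0L && all(.detectable(x))
    }, logical(1)))
    if (!all_detect) next
    med <- .day_medians(groups)
    med <- med[!is.na(med)]
    cv_me <- if (length(med) >= 2L && mean(med) > 0) {
      100 * stats::sd(med) / mean(med)
    } else NA_real_
    return(list(level = lv, total_cv_me = cv_me))
  }
  list(level = NA_character_, total_cv_me = NA_real_)
}

#' Partial validation of specificity via transition-ratio stability
#'
#' For each sample above the lower limit of quantification, the transition
#' ratio of each monitored transition is its peak area over the summed peak
#' area of all the peptide's transitions in that sample (or, optionally,
#' over the most intense transition's area). A transition is deemed
#' specific to its peptide when no sample's ratio deviates more than the
#' threshold (default 30 %) from that transition's mean ratio across the
#' qualifying samples.
#'
#' @param transition_sets List of the peptide's individual-transition
#'   measurement sets (at least two).
#' @param qualifying_runs Character vector of replicate names above the
#'   LLOQ filter.
#' @param threshold Maximum tolerated deviation in percent (default 30).
#' @param denominator `"sum"` (default) or `"max_transition"`.
#' @return A data frame with one row per transition and columns
#'   `max_deviation` (percent), `mean_at_max_dev` (that transition's mean
#'   ratio), `day_at_max_dev`, `conc_level_at_max_dev` (annotations of the
#'   maximizing sample), and `specific` (logical).
#' @export
specificity_deviation <- function(transition_sets, qualifying_runs,
                                  threshold = 30,
                                  denominator = c("sum", "max_transition")) {
  denominator <- match.arg(denominator)
  if (length(transition_sets) < 2L) {
    stop("specificity_deviation: need at least two transitions",
         call. = FALSE)
  }
  labels <- vapply(transition_sets, function(s) transition_label(s$key), "")
  na_row <- data.frame(transition = labels,
                       max_deviation = NA_real_,
                       mean_at_max_dev = NA_real_,
                       day_at_max_dev = NA_integer_,
                       conc_level_at_max_dev = NA_character_,
                       specific = NA, stringsAsFactors = FALSE)
  if (length(qualifying_runs) == 0L) {
    warning("specificity_deviation: no samples above the LLOQ filter",
            call. = FALSE)
    return(na_row)
  }
  ref <- transition_sets[[1L]]$data
  ann <- ref[match(qualifying_runs, ref$replicate_name), , drop = FALSE]
  areas <- vapply(transition_sets, function(s) {
    s$data$peak_area[match(qualifying_runs, s$data$replicate_name)]
  }, numeric(length(qualifying_runs)))
  areas <- matrix(areas, nrow = length(qualifying_runs))

  denom <- if (denominator == "sum") {
    rowSums(areas, na.rm = TRUE)
  } else {
    apply(areas, 1L, function(r) if (all(is.na(r))) NA_real_ else
      max(r, na.rm = TRUE))
  }
  denom[denom <= 0] <- NA_real_
  ratios <- areas / denom

  out <- na_row
  for (t in seq_along(transition_sets)) {
    r <- ratios[, t]
    usable <- !is.na(r)
    if (!any(usable)) next
    mean_r <- mean(r[usable])
    if (!is.finite(mean_r) || mean_r <= 0) {
      warning("specificity_deviation: zero mean transition ratio for ",
              labels[t], call. = FALSE)
      next
    }
    dev <- 100 * abs(r - mean_r) / mean_r
    imax <- which.max(dev)
    out$max_deviation[t] <- dev[imax]
    out$mean_at_max_dev[t] <- mean_r
    out$day_at_max_dev[t] <- ann$day[imax]
    out$conc_level_at_max_dev[t] <- ann$concentration_level[imax]
    out$specific[t] <- dev[imax] <= threshold
  }
  out
}

# One repeatability report row (without PVSpec fields, added by the driver).
.rep_cv_fields <- function(set, control) {
  groups <- group_by_design(set, "repeatability")$levels
  level_results <- lapply(groups, cv_components)
  fields <- list()
  for (lv in .conc_levels) {
    res <- if (lv %in% names(level_results)) level_results[[lv]] else
      list(intra_cv = NA_real_, inter_cv = NA_real_, total_cv = NA_real_)
    fields[[paste0("intraCV.", lv)]] <- res$intra_cv
    fields[[paste0("interCV.", lv)]] <- res$inter_cv
    fields[[paste0("totalCV.", lv)]] <- res$total_cv
  }
  vl <- validated_lloq(level_results, groups,
                       control$validation_cv_threshold)
  fields[["ValidatedLLOQ.concLevel"]] <- vl$level
  fields[["totalCV.Me"]] <- vl$total_cv_me
  list(fields = fields, validated_level = vl$level, groups = groups)
}

#' Compute the mini-validation-of-repeatability report
#'
#' For every transition of every peptide and for each peptide's
#' summed-transition series, computes the intra-assay, inter-assay and
#' total coefficient of variation at each QC concentration level (low,
#' medium, high), the validated LLOQ concentration level with its
#' median-based total CV (`totalCV.Me`), and the partial validation of
#' specificity (PVSpec) fields from transition-ratio stability across
#' samples above the LLOQ.
#'
#' Samples qualify for the specificity check when their concentration level
#' is at or above the peptide's validated LLOQ level, determined on the
#' summed-transition series; if no level validates, all QC samples qualify
#' and a warning is issued. Summed-transition rows carry `NA` for all
#' PVSpec fields, which are defined only for individual transitions.
#'
#' @inheritParams response_curve
#' @return An object of class `mrm_repeatability`; `as.data.frame()`
#'   extracts the report table, `plot()` draws the per-peptide day-median
#'   profiles.
#' @examples
#' sim <- simulate_repeatability(simulation_config(seed = 7, n_peptides = 2))
#' assay <- mrm_assay(sim$export, sim$metadata)
#' rep <- repeatability(assay)
#' head(as.data.frame(rep))
#' @export
repeatability <- function(assay, control = mrm_control()) {
  stopifnot(inherits(assay, "mrm_assay"))
  rows <- list()
  for (i in seq_len(nrow(assay$peptides))) {
    pep <- assay$peptides$peptide_sequence[i]
    chg <- assay$peptides$precursor_charge[i]
    sets <- .peptide_sets(assay, pep, chg)
    summed <- sum_transitions(sets)

    summed_cv <- .rep_cv_fields(summed, control)
    qc <- summed$data[summed$data$sample_type == "qc", , drop = FALSE]
    vlevel <- summed_cv$validated_level
    if (is.na(vlevel)) {
      warning("no validated LLOQ level for peptide ", pep,
              "; all qc samples enter the specificity check", call. = FALSE)
      qualifying <- qc$replicate_name
    } else {
      keep_lv <- .conc_levels[match(vlevel, .conc_levels):length(.conc_levels)]
      qualifying <- qc$replicate_name[qc$concentration_level %in% keep_lv]
    }
    pv <- if (length(sets) >= 2L) {
      specificity_deviation(sets, qualifying,
                            control$specificity_threshold,
                            control$ratio_denominator)
    } else NULL

    for (t in seq_along(sets)) {
      cvf <- .rep_cv_fields(sets[[t]], control)
      lab <- transition_label(sets[[t]]$key)
      pvrow <- if (!is.null(pv)) pv[pv$transition == lab, , drop = FALSE] else
        data.frame(max_deviation = NA_real_, mean_at_max_dev = NA_real_,
                   day_at_max_dev = NA_integer_,
                   conc_level_at_max_dev = NA_character_, specific = NA)
      rows[[paste(pep, lab, sep = "|")]] <- data.frame(
        Peptide = pep, Transition = lab,
        cvf$fields,
        `PVSpec.maxDeviation` = pvrow$max_deviation[1L],
        `PVSpec.meanAtMaxDev` = pvrow$mean_at_max_dev[1L],
        `PVSpec.dayAtMaxDev` = pvrow$day_at_max_dev[1L],
        `PVSpec.concLevelAtMaxDev` = pvrow$conc_level_at_max_dev[1L],
        `PVSpec.specific` = pvrow$specific[1L],
        check.names = FALSE, stringsAsFactors = FALSE
      )
    }
    # summed row: PVSpec fields are transition-specific, hence NA
    rows[[paste(pep, "summed", sep = "|")]] <- data.frame(
      Peptide = pep, Transition = "summed",
      summed_cv$fields,
      `PVSpec.maxDeviation` = NA_real_,
      `PVSpec.meanAtMaxDev` = NA_real_,
      `PVSpec.dayAtMaxDev` = NA_integer_,
      `PVSpec.concLevelAtMaxDev` = NA_character_,
      `PVSpec.specific` = NA,
      check.names = FALSE, stringsAsFactors = FALSE
    )
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  structure(list(results = results, control = control, assay = assay),
            class = "mrm_repeatability")
}

#' @export
as.data.frame.mrm_repeatability <- function(x, ...) x$results

#' @export
print.mrm_repeatability <- function(x, ...) {
  df <- x$results
  cat("Repeatability report:", nrow(df), "rows (",
      sum(df$Transition != "summed"), "transitions,",
      sum(df$Transition == "summed"), "summed )\n", sep = " ")
  print(utils::head(df, 10), digits = 6)
  if (nrow(df) > 10) cat("  ...", nrow(df) - 10, "more rows\n")
  invisible(x)
}

#' @export
summary.mrm_repeatability <- function(object, ...) {
  df <- object$results
  trans <- df[df$Transition != "summed", , drop = FALSE]
  out <- list(
    n_peptides = length(unique(df$Peptide)),
    n_rows = nrow(df),
    total_cv_range = range(unlist(df[, grep("^totalCV\\.(low|medium|high)$",
                                            names(df))]), na.rm = TRUE),
    min_total_cv_me = suppressWarnings(min(df$`totalCV.Me`, na.rm = TRUE)),
    validated = table(factor(df$ValidatedLLOQ.concLevel,
                             levels = .conc_levels), useNA = "ifany"),
    n_specific = sum(trans$`PVSpec.specific`, na.rm = TRUE),
    n_nonspecific = sum(!trans$`PVSpec.specific`, na.rm = TRUE)
  )
  class(out) <- "summary.mrm_repeatability"
  out
}

#' @export
print.summary.mrm_repeatability <- function(x, ...) {
  cat("Repeatability summary\n")
  cat(sprintf("  peptides: %d, report rows: %d\n", x$n_peptides, x$n_rows))
  cat(sprintf("  total CV range: %.4f - %.4f %%\n",
              x$total_cv_range[1], x$total_cv_range[2]))
  cat(sprintf("  lowest totalCV.Me at a validated LLOQ: %.4f %%\n",
              x$min_total_cv_me))
  cat("  validated LLOQ levels:\n")
  print(x$validated)
  cat(sprintf("  transitions specific: %d, non-specific: %d\n",
              x$n_specific, x$n_nonspecific))
  invisible(x)
}
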