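# Internal helpers shared across modules.

# Missing-value spellings accepted on input; output always uses "NA".
.na_spellings <- c("", "#N/A", "NA", "NaN")

# Ordered QC concentration levels.
.conc_levels <- c("low", "medium", "high")

# An area is detectable iff non-missing and strictly positive.
.detectable <- function(x) !is.na(x) & x > 0

# Case-insensitive, separator-tolerant header normalisation.
.norm_name <- function(x) gsub("[ _.()%/-]+", "", tolower(x))

# Locate one required column in a header; `map` optionally renames it.
# Returns the column index or NA.
.find_column <- function(header, canonical, map = NULL, field = NULL) {
  wanted <- canonical
  if (!is.null(map) && !is.null(field) && field %in% names(map)) {
    wanted <- map[[field]]
  }
  idx <- which(.norm_name(header) == .norm_name(wanted))
  if (length(idx) == 0L) NA_integer_ else idx[1L]
}

# Coefficient of variation in percent over detectable values; NA if the
# mean is non-positive or fewer than two values remain.
.cv_pct <- function(x) {
  x <- x[.detectable(x)]
  if (length(x) < 2L) return(NA_real_)
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  100 * stats::sd(x) / m
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 1 && x == floor(x)
}

# Parse a numeric field tolerating the accepted missing spellings;
# non-numeric text also maps to NA (never to zero).
.parse_area <- function(x) {
  x <- trimws(x)
  out <- suppressWarnings(as.numeric(x))
  out[x %in% .na_spellings] <- NA_real_
  out
}

.parse_int <- function(x) {
  x <- trimws(x)
  out <- suppressWarnings(as.integer(x))
  out[x %in% .na_spellings] <- NA_integer_
  out
}

# Sequence sanity: plain amino acids or a Skyline-style modified sequence
# (e.g. "C[+57]PEPTIDER"); modified strings are used verbatim as keys.
.valid_sequence <- function(x) {
  grepl("^[A-Z][A-Za-z0-9().+\\[\\]-]*$", x, perl = TRUE)
}
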