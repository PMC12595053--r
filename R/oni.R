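# Ocean-index series handling: parsing, ONI-style smoothing, phase labels.

# NOAA 3-month season codes mapped to their centre month
SEASON_CODES <- c(DJF = 1L, JFM = 2L, FMA = 3L, MAM = 4L, AMJ = 5L, MJJ = 6L,
                  JJA = 7L, JAS = 8L, ASO = 9L, SON = 10L, OND = 11L, NDJ = 12L)

#' Monthly ocean-index series
#'
#' Container for a gap-free monthly sea-surface-temperature anomaly index
#' (degrees C), e.g. the Oceanic Nino Index. The `smoothed` flag records
#' whether the 3-month running mean has already been applied, so that the
#' smoothing step cannot be applied twice by accident.
#'
#' @param values numeric vector of monthly index values (degrees C anomaly).
#' @param start integer `(year, month)` of the first value.
#' @param smoothed logical; has [running_mean3()] been applied?
#' @return An object of class `index_series`.
#' @export
index_series <- function(values, start = c(1992L, 1L), smoothed = FALSE) {
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop2("index series must be finite and gap-free")
  stopifnot(length(start) == 2L, start[2] >= 1, start[2] <= 12)
  structure(list(values = values, start = as.integer(start),
                 smoothed = isTRUE(smoothed)),
            class = "index_series")
}

#' @export
length.index_series <- function(x) length(x$values)

#' @export
print.index_series <- function(x, ...) {
  mo <- month_seq(x$start, length(x$values))
  cat(sprintf("<index_series> %d months, %d-%02d to %d-%02d, %s\n",
              length(x$values), mo$year[1], mo$month[1],
              tail(mo$year, 1), tail(mo$month, 1),
              if (x$smoothed) "smoothed (3-month running mean)" else "raw"))
  cat(sprintf("  range [%.2f, %.2f] degC\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' Parse an ONI-style index CSV
#'
#' Reads either of the two common NOAA layouts: numeric `year, month, value`
#' columns, or a season code plus year (`DJF 1998` style) where the 3-month
#' season label is assigned to its centre month (DJF -> January). Rows may be
#' in any order; the result is sorted. A gap in the monthly sequence is a hard
#' error naming the missing months.
#'
#' @param path path to a CSV file.
#' @param smoothed logical; mark the parsed series as already smoothed
#'   (official ONI releases are 3-month running means).
#' @return An [index_series()].
#' @export
parse_index_csv <- function(path, smoothed = FALSE) {
  if (!file.exists(path)) stop2("index file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  names(df) <- tolower(names(df))
  val_col <- intersect(c("value", "anom", "oni", "index"), names(df))[1]
  if (is.na(val_col)) stop2("no value column (value/anom/oni/index) in %s", path)
  vals <- suppressWarnings(as.numeric(df[[val_col]]))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop2("unparseable index value in row %d of %s: '%s'",
          bad, path, as.character(df[[val_col]][bad]))
  }
  if ("month" %in% names(df) && is.numeric(df$month)) {
    year <- as.integer(df$year)
    month <- as.integer(df$month)
  } else {
    seas_col <- intersect(c("seas", "season", "month"), names(df))[1]
    if (is.na(seas_col) || !"year" %in% names(df))
      stop2("need either numeric year+month or season-code+year columns in %s", path)
    code <- toupper(trimws(as.character(df[[seas_col]])))
    month <- unname(SEASON_CODES[code])
    if (anyNA(month)) {
      bad <- which(is.na(month))[1]
      stop2("unknown season code in row %d of %s: '%s'", bad, path, code[bad])
    }
    year <- as.integer(df$year)
  }
  if (anyNA(year) || any(month < 1 | month > 12))
    stop2("invalid year/month values in %s", path)
  k <- year * 12L + (month - 1L)
  o <- order(k)
  k <- k[o]; vals <- vals[o]; year <- year[o]; month <- month[o]
  if (anyDuplicated(k)) stop2("duplicate months in %s", path)
  expected <- seq(k[1], k[length(k)])
  if (length(expected) != length(k)) {
    miss <- setdiff(expected, k)
    stop2("gap in monthly series (%s missing): %s", path,
          paste(sprintf("%d-%02d", miss %/% 12L, miss %% 12L + 1L),
                collapse = ", "))
  }
  index_series(vals, start = c(year[1], month[1]), smoothed = smoothed)
}

#' 3-month running mean of an index series
#'
#' Centred 3-month mean, the smoothing that defines the Oceanic Nino Index.
#' The first and last months use the available 2-month partial window so the
#' series keeps its full length and stays aligned with monthly data cubes.
#' Applying it twice is an error (the `smoothed` flag is enforced).
#'
#' @param series an [index_series()].
#' @return The smoothed [index_series()] with `smoothed = TRUE`.
#' @export
running_mean3 <- function(series) {
  stopifnot(inherits(series, "index_series"))
  if (series$smoothed)
    stop2("series is already smoothed; the 3-month running mean is applied once")
  index_series(running_mean3_vec(series$values), start = series$start,
               smoothed = TRUE)
}

#' Classify months into ENSO phases
#'
#' Labels each month `elnino` when the smoothed index is at or above
#' `+threshold`, `lanina` at or below `-threshold`, and `neutral` otherwise.
#' The boundary is inclusive: exactly +0.5 degC is El Nino.
#'
#' @param series a smoothed [index_series()].
#' @param threshold positive phase threshold in degrees C (default 0.5).
#' @param require_smoothed logical; insist that the ONI smoothing has been
#'   applied (default TRUE, matching the index definition).
#' @return An object of class `phase_labels`: factor vector with levels
#'   `elnino`, `lanina`, `neutral`, plus the series start.
#' @export
classify_phases <- function(series, threshold = 0.5, require_smoothed = TRUE) {
  stopifnot(inherits(series, "index_series"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop2("threshold must be a single positive number")
  if (require_smoothed && !series$smoothed)
    stop2("phases are classified on the smoothed index; call running_mean3() first")
  v <- series$values
  lab <- ifelse(v >= threshold, "elnino", ifelse(v <= -threshold, "lanina", "neutral"))
  structure(list(labels = factor(lab, levels = c("elnino", "lanina", "neutral")),
                 start = series$start, threshold = threshold),
            class = "phase_labels")
}

#' @export
length.phase_labels <- function(x) length(x$labels)

#' @export
print.phase_labels <- function(x, ...) {
  tb <- table(x$labels)
  cat(sprintf("<phase_labels> %d months (threshold +/-%.2f degC): %s\n",
              length(x$labels), x$threshold,
              paste(sprintf("%s %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}

#' Extract ENSO episodes from phase labels
#'
#' Maximal consecutive runs of one non-neutral phase with length at least
#' `min_length` months (the NOAA convention uses five consecutive overlapping
#' seasons). The catalog is for reporting only; phase-conditional correlations
#' use the per-month labels, not episodes.
#'
#' @param labels a [classify_phases()] result.
#' @param min_length minimum run length in months (default 5).
#' @return A data.frame with columns `phase`, `start_year`, `start_month`,
#'   `end_year`, `end_month`, `length`.
#' @export
extract_episodes <- function(labels, min_length = 5L) {
  stopifnot(inherits(labels, "phase_labels"))
  lab <- as.character(labels$labels)
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "neutral" & r$lengths >= min_length
  mo <- month_seq(labels$start, length(lab))
  data.frame(
    phase = r$values[keep],
    start_year = mo$year[starts[keep]], start_month = mo$month[starts[keep]],
    end_year = mo$year[ends[keep]], end_month = mo$month[ends[keep]],
    length = r$lengths[keep],
    stringsAsFactors = FALSE
  )
}

#' Month indices carrying a phase label
#'
#' @param labels a [classify_phases()] result.
#' @param phase `"elnino"` or `"lanina"`.
#' @return Integer vector of month positions (1-based) with that label.
#' @export
phase_months <- function(labels, phase) {
  stopifnot(inherits(labels, "phase_labels"))
  phase <- match.arg(phase, c("elnino", "lanina"))
  which(labels$labels == phase)
}
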