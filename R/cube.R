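# climate_cube: a monthly raster stack with mask, geotransform and
# processing-provenance flags.

#' Monthly gridded climate cube
#'
#' A stack of monthly fields for one variable, stored as a numeric array with
#' dimensions `(rows, cols, time)`. Cells excluded by `mask` (or NA in the
#' data) are missing. `flags` track the preprocessing provenance
#' (`anomalized`, `detrended`, `smoothed`): the pipeline stages check and set
#' them so stages cannot run out of order.
#'
#' @param data numeric array `rows x cols x time`.
#' @param variable variable name (e.g. `"tmax"`, `"gpp_sun"`).
#' @param units physical units string.
#' @param start integer `(year, month)` of the first time slice.
#' @param mask logical matrix `rows x cols`, TRUE where the cell is valid;
#'   NULL means all valid.
#' @param geo list with `origin` (x, y of the upper-left corner), `px`
#'   (pixel width, height; north-up so height is negative), `crs` tag.
#' @param flags named logical list of provenance flags.
#' @return An object of class `climate_cube`.
#' @export
climate_cube <- function(data, variable, units = "", start = c(1992L, 1L),
                         mask = NULL, geo = NULL,
                         flags = list(anomalized = FALSE, detrended = FALSE,
                                      smoothed = FALSE)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop2("data must be a rows x cols x time array")
  stopifnot(length(start) == 2L, start[2] >= 1, start[2] <= 12)
  d <- dim(data)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!is.logical(mask) || !all(dim(mask) == d[1:2]))
    stop2("mask must be a %d x %d logical matrix", d[1], d[2])
  if (is.null(geo))
    geo <- list(origin = c(0, 0), px = c(1, -1), crs = "synthetic")
  bad <- !is.finite(data[rep(mask, d[3])]) & !is.na(data[rep(mask, d[3])])
  if (any(bad)) stop2("non-finite (non-NA) values inside the mask")
  structure(list(data = data, variable = variable, units = units,
                 start = as.integer(start), mask = mask, geo = geo,
                 flags = flags),
            class = "climate_cube")
}

#' @export
dim.climate_cube <- function(x) dim(x$data)

#' Number of time steps of a cube
#' @param cube a [climate_cube()].
#' @return Integer month count.
#' @export
n_months <- function(cube) dim(cube$data)[3]

#' Per-pixel time series matrix
#'
#' Flattens a cube into a `time x pixel` matrix (pixels in column-major grid
#' order); masked-out pixels become all-NA columns.
#'
#' @param cube a [climate_cube()].
#' @return Numeric matrix, `n_months x (rows*cols)`.
#' @export
cube_matrix <- function(cube) {
  d <- dim(cube$data)
  m <- t(matrix(cube$data, d[1] * d[2], d[3]))
  m[, !as.vector(cube$mask)] <- NA_real_
  m
}

# inverse of cube_matrix for a same-shaped result
matrix_to_cube <- function(m, template, flags = template$flags) {
  d <- dim(template$data)
  a <- array(t(m), dim = d)
  climate_cube(a, variable = template$variable, units = template$units,
               start = template$start, mask = template$mask,
               geo = template$geo, flags = flags)
}

#' @export
print.climate_cube <- function(x, ...) {
  d <- dim(x$data)
  fl <- names(Filter(isTRUE, x$flags))
  cat(sprintf("<climate_cube> '%s' [%s] %d x %d grid, %d months from %d-%02d\n",
              x$variable, x$units, d[1], d[2], d[3], x$start[1], x$start[2]))
  cat(sprintf("  mask: %d/%d valid pixels; flags: %s\n",
              sum(x$mask), d[1] * d[2],
              if (length(fl)) paste(fl, collapse = ", ") else "raw"))
  invisible(x)
}

check_same_grid <- function(a, b, what = "grids") {
  da <- if (inherits(a, "climate_cube")) dim(a$data)[1:2] else dim(a)
  db <- if (inherits(b, "climate_cube")) dim(b$data)[1:2] else dim(b)
  if (!all(da == db))
    stop2("%s do not share a grid: %dx%d vs %dx%d", what, da[1], da[2], db[1], db[2])
  invisible(TRUE)
}
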