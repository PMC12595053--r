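# Preprocessing: monthly climatology, anomalies, per-pixel detrending,
# 3-month smoothing, and the deforestation / suitability analysis mask.
# Stage order (anomalize -> detrend -> smooth) is enforced via cube flags.

#' Per-pixel monthly climatology
#'
#' Calendar-month means per pixel over whole years, missing-aware.
#'
#' @param cube a [climate_cube()] spanning a whole number of years.
#' @return Numeric array `rows x cols x 12` of monthly means.
#' @export
monthly_climatology <- function(cube) {
  stopifnot(inherits(cube, "climate_cube"))
  n <- n_months(cube)
  if (n %% 12L != 0L)
    stop2("climatology needs whole years; cube has %d months", n)
  mo <- ((cube$start[2] - 1L) + seq_len(n) - 1L) %% 12L + 1L
  d <- dim(cube$data)
  out <- array(NA_real_, c(d[1], d[2], 12L))
  for (m in 1:12) {
    out[, , m] <- apply(cube$data[, , mo == m, drop = FALSE], c(1, 2),
                        function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
  }
  out[array(!cube$mask, dim = c(d[1], d[2], 12L))] <- NA_real_
  out
}

#' Convert a cube to monthly anomalies
#'
#' Subtracts the calendar-month climatological mean from every field, the
#' standard anomaly definition for monthly data. `overall_mean = TRUE`
#' instead subtracts a single per-pixel long-term mean.
#'
#' @param cube a raw [climate_cube()].
#' @param climatology optional precomputed [monthly_climatology()] array;
#'   computed from `cube` when missing.
#' @param overall_mean subtract one overall mean instead of monthly means.
#' @return The anomaly [climate_cube()] with `anomalized = TRUE`.
#' @export
to_anomalies <- function(cube, climatology = NULL, overall_mean = FALSE) {
  stopifnot(inherits(cube, "climate_cube"))
  if (isTRUE(cube$flags$anomalized)) stop2("cube is already anomalized")
  d <- dim(cube$data)
  if (overall_mean) {
    mu <- apply(cube$data, c(1, 2), mean, na.rm = TRUE)
    out <- cube$data - array(mu, dim = d)
  } else {
    if (is.null(climatology)) climatology <- monthly_climatology(cube)
    if (!all(dim(climatology) == c(d[1], d[2], 12L)))
      stop2("climatology must be a %d x %d x 12 array", d[1], d[2])
    mo <- ((cube$start[2] - 1L) + seq_len(d[3]) - 1L) %% 12L + 1L
    out <- cube$data - climatology[, , mo, drop = FALSE]
  }
  fl <- cube$flags; fl$anomalized <- TRUE
  climate_cube(out, variable = cube$variable, units = cube$units,
               start = cube$start, mask = cube$mask, geo = cube$geo,
               flags = fl)
}

#' Remove the per-pixel linear trend
#'
#' Ordinary least-squares line over time fitted and removed independently at
#' each pixel, to suppress spurious correlations between trending series.
#' Pixels with fewer than 3 valid months become missing.
#'
#' @param anom an anomalized [climate_cube()].
#' @return The detrended cube with `detrended = TRUE`.
#' @export
detrend_linear <- function(anom) {
  stopifnot(inherits(anom, "climate_cube"))
  if (!isTRUE(anom$flags$anomalized))
    stop2("detrend_linear() expects an anomalized cube (call to_anomalies() first)")
  if (isTRUE(anom$flags$detrended)) stop2("cube is already detrended")
  m <- cube_matrix(anom)               # time x pixel
  n <- nrow(m)
  X <- cbind(1, seq_len(n))
  complete <- !colSums(is.na(m))
  res <- matrix(NA_real_, n, ncol(m))
  if (any(complete))
    res[, complete] <- lm.fit(X, m[, complete, drop = FALSE])$residuals
  for (j in which(!complete)) {
    ok <- !is.na(m[, j])
    if (sum(ok) < 3L) next                       # too few points -> missing
    fit <- lm.fit(X[ok, , drop = FALSE], m[ok, j])
    res[ok, j] <- fit$residuals
  }
  fl <- anom$flags; fl$detrended <- TRUE
  matrix_to_cube(res, anom, flags = fl)
}

#' 3-month running mean of a cube
#'
#' Applies the same centred 3-month mean (2-month partial edge windows) as
#' [running_mean3()] to every pixel's series. A smoothed value is missing
#' whenever any member of its window is missing.
#'
#' @param anom a detrended anomaly [climate_cube()].
#' @param require_detrended set FALSE to smooth a merely anomalized cube
#'   (diagnostic use).
#' @return The smoothed cube with `smoothed = TRUE`.
#' @export
running_mean3_cube <- function(anom, require_detrended = TRUE) {
  stopifnot(inherits(anom, "climate_cube"))
  if (require_detrended && !isTRUE(anom$flags$detrended))
    stop2("running_mean3_cube() expects a detrended cube (order: anomalies -> detrend -> smooth)")
  if (isTRUE(anom$flags$smoothed)) stop2("cube is already smoothed")
  m <- cube_matrix(anom)
  n <- nrow(m)
  if (n < 3L) stop2("need at least 3 months to smooth")
  up <- m[c(1L, 1L:(n - 1L)), , drop = FALSE]
  dn <- m[c(2L:n, n), , drop = FALSE]
  out <- (up + m + dn) / 3
  out[1L, ] <- (m[1L, ] + m[2L, ]) / 2
  out[n, ] <- (m[n - 1L, ] + m[n, ]) / 2
  fl <- anom$flags; fl$smoothed <- TRUE
  matrix_to_cube(out, anom, flags = fl)
}

#' Aggregate a fine forest-loss raster into an analysis-scale filter
#'
#' Upscales a binary loss raster to the coarse analysis grid. Under the
#' default `"any"` rule a coarse cell is excluded (FALSE) as soon as one fine
#' loss pixel falls inside it — the conservative filter removing all
#' potentially compromised pixels. `rule = "fraction"` excludes a cell only
#' when the loss fraction strictly exceeds `tau`.
#'
#' @param loss_fine logical matrix of fine-resolution loss pixels (TRUE =
#'   loss); dimensions must be integer multiples of `target_shape`.
#' @param target_shape integer `(rows, cols)` of the analysis grid.
#' @param rule `"any"` or `"fraction"`.
#' @param tau loss-fraction threshold for `rule = "fraction"`.
#' @return Logical `rows x cols` matrix, TRUE where the cell is retained.
#' @export
deforestation_filter <- function(loss_fine, target_shape,
                                 rule = c("any", "fraction"), tau = 0.25) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(loss_fine), length(target_shape) == 2L)
  nr <- target_shape[1]; nc <- target_shape[2]
  fr <- nrow(loss_fine); fc <- ncol(loss_fine)
  if (fr %% nr != 0L || fc %% nc != 0L)
    stop2("fine raster %dx%d is not an integer multiple of target %dx%d",
          fr, fc, nr, nc)
  ky <- fr %/% nr; kx <- fc %/% nc
  ii <- (seq_len(fr) - 1L) %/% ky + 1L
  jj <- (seq_len(fc) - 1L) %/% kx + 1L
  frac <- matrix(0, nr, nc)
  cnt <- tapply(as.numeric(loss_fine),
                list(row = ii[row(loss_fine)], col = jj[col(loss_fine)]), sum)
  frac[] <- cnt / (ky * kx)
  if (rule == "any") frac == 0 else frac <= tau
}

#' Combine suitability and forest-retention masks
#'
#' Logical AND of the crop-suitability mask and the deforestation filter.
#' An empty result is allowed; downstream stages report an empty domain
#' rather than failing.
#'
#' @param suitability logical matrix (TRUE = suitable).
#' @param forest_retained logical matrix (TRUE = retained), same shape.
#' @return Logical matrix.
#' @export
combine_masks <- function(suitability, forest_retained) {
  stopifnot(is.matrix(suitability), is.matrix(forest_retained))
  if (!all(dim(suitability) == dim(forest_retained)))
    stop2("mask shapes differ: %dx%d vs %dx%d",
          nrow(suitability), ncol(suitability),
          nrow(forest_retained), ncol(forest_retained))
  suitability & forest_retained
}

#' Standard anomaly preprocessing chain
#'
#' Convenience wrapper running anomalize -> detrend -> smooth in the enforced
#' order.
#'
#' @param cube a raw [climate_cube()].
#' @param smooth apply the final 3-month running mean (default TRUE).
#' @return A processed [climate_cube()].
#' @export
preprocess_cube <- function(cube, smooth = TRUE) {
  out <- detrend_linear(to_anomalies(cube))
  if (smooth) out <- running_mean3_cube(out)
  out
}
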