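# Synthetic teleconnection generator: an ONI-like AR(1) index plus gridded
# monthly fields built as climatology + trend + beta * lagged index + noise,
# with the ground truth returned alongside.

#' Simulation configuration
#'
#' Describes one synthetic monthly cube tied to an ocean index. Defaults give
#' a 29-year (348-month) record on a modest grid with an ENSO-like index:
#' AR(1) coefficient 0.9 and innovation sd 0.25 degC yield a stationary sd of
#' ~0.57 degC, so multi-month episodes beyond +/-0.5 degC occur regularly as
#' in the observed record.
#'
#' @param n_months number of months (default 348 = 12 x 29).
#' @param grid_shape integer `(rows, cols)`.
#' @param ar1_coeff AR(1) coefficient of the index, in `[0, 1)`.
#' @param index_noise_sd sd of the index innovations (degrees C).
#' @param beta_field per-pixel teleconnection slope (field units per degC);
#'   scalar or `rows x cols` matrix.
#' @param lag_field per-pixel integer response lag in months, in `[-3, 3]`;
#'   positive lag means the field responds AFTER the index (the field at
#'   month `t` follows the index at `t - lag`). Scalar or matrix.
#' @param trend_slope linear trend in field units per month.
#' @param seasonal_amplitude amplitude of the sinusoidal 12-month
#'   climatology (field units); ignored when `climatology` is given.
#' @param climatology optional explicit 12-value monthly climatology.
#' @param noise_sd sd of the per-pixel Gaussian noise (field units).
#' @param start integer `(year, month)` of the first month.
#' @param seed root seed; per-component substreams are derived from it with
#'   [derive_seed()], so outputs are bit-identical for identical configs.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_months = 348L, grid_shape = c(20L, 20L),
                       ar1_coeff = 0.9, index_noise_sd = 0.25,
                       beta_field = 0.5, lag_field = 0L,
                       trend_slope = 0.002, seasonal_amplitude = 1,
                       climatology = NULL, noise_sd = 0.5,
                       start = c(1992L, 1L), seed = 1L) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop2("%s must be a single finite number", nm)
  }
  num1(n_months, "n_months"); num1(ar1_coeff, "ar1_coeff")
  num1(index_noise_sd, "index_noise_sd"); num1(trend_slope, "trend_slope")
  num1(seasonal_amplitude, "seasonal_amplitude"); num1(noise_sd, "noise_sd")
  num1(seed, "seed")
  if (n_months < 24L) stop2("n_months must be >= 24")
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1))
  if (ar1_coeff < 0 || ar1_coeff >= 1) stop2("ar1_coeff must be in [0, 1)")
  if (index_noise_sd < 0 || noise_sd < 0) stop2("noise sds must be >= 0")
  grid_shape <- as.integer(grid_shape)
  as_field <- function(x, nm) {
    if (is.matrix(x)) {
      if (!all(dim(x) == grid_shape))
        stop2("%s must match grid_shape %dx%d", nm, grid_shape[1], grid_shape[2])
      x
    } else {
      num1(x, nm)
      matrix(x, grid_shape[1], grid_shape[2])
    }
  }
  beta_field <- as_field(beta_field, "beta_field")
  lag_field <- as_field(lag_field, "lag_field")
  if (any(lag_field != round(lag_field)) || any(abs(lag_field) > 3))
    stop2("lag_field must hold integer lags in [-3, 3]")
  if (!is.null(climatology) && length(climatology) != 12L)
    stop2("climatology must have 12 values")
  structure(list(n_months = as.integer(n_months), grid_shape = grid_shape,
                 ar1_coeff = ar1_coeff, index_noise_sd = index_noise_sd,
                 beta_field = beta_field, lag_field = lag_field,
                 trend_slope = trend_slope,
                 seasonal_amplitude = seasonal_amplitude,
                 climatology = climatology, noise_sd = noise_sd,
                 start = as.integer(start), seed = as.integer(seed)),
            class = "sim_config")
}

# the default 12-value climatology: a sinusoid, so the monthly-anomaly step
# is non-trivial
config_climatology <- function(config) {
  config$climatology %||%
    (config$seasonal_amplitude * sin(2 * pi * (0:11) / 12))
}

#' Simulate an ONI-like monthly index
#'
#' AR(1) series `x_t = phi * x_(t-1) + e_t`, `e_t ~ N(0, index_noise_sd^2)`,
#' started at 0. Returned raw (unsmoothed); apply [running_mean3()] before
#' [classify_phases()], as for the real index.
#'
#' @param config a [sim_config()].
#' @return An [index_series()] with `smoothed = FALSE`.
#' @export
simulate_index <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_months
  x <- numeric(n)
  if (config$index_noise_sd > 0) {
    eps <- with_seed(derive_seed(config$seed, "index"),
                     rnorm(n, 0, config$index_noise_sd))
    for (t in seq_len(n)) x[t] <- config$ar1_coeff * (if (t > 1) x[t - 1] else 0) + eps[t]
  }
  index_series(x, start = config$start, smoothed = FALSE)
}

#' Simulate a teleconnected monthly cube
#'
#' Builds, per pixel `(i, j)` and month `t`:
#' `climatology(month) + trend_slope * t + beta[i,j] * index[t - lag[i,j]] +
#' noise`. Lagged index positions falling outside the series contribute 0.
#' The ground truth (beta field, lag field, signal mask, phase months of the
#' driving index) is returned for downstream verification.
#'
#' @param config a [sim_config()].
#' @param index the driving [index_series()] (raw), length `n_months`.
#' @param variable_name name for the simulated variable.
#' @return List with elements `cube` (a [climate_cube()]) and `truth`
#'   (class `sim_truth`).
#' @export
simulate_cube <- function(config, index, variable_name = "var") {
  stopifnot(inherits(config, "sim_config"), inherits(index, "index_series"))
  if (length(index) != config$n_months)
    stop2("index length %d != n_months %d", length(index), config$n_months)
  nr <- config$grid_shape[1]; nc <- config$grid_shape[2]
  n <- config$n_months
  clim <- config_climatology(config)
  mo <- ((config$start[2] - 1L) + seq_len(n) - 1L) %% 12L + 1L
  base_t <- clim[mo] + config$trend_slope * seq_len(n)

  # index shifted by each distinct lag, zero-padded outside the record
  idx0 <- index$values
  shift_idx <- function(lag) {
    tt <- seq_len(n) - lag
    out <- numeric(n)
    ok <- tt >= 1 & tt <= n
    out[ok] <- idx0[tt[ok]]
    out
  }
  lags <- sort(unique(as.vector(config$lag_field)))
  shifted <- vapply(lags, shift_idx, numeric(n))  # n x n_lags

  npix <- nr * nc
  beta <- as.vector(config$beta_field)
  lag_pos <- match(as.vector(config$lag_field), lags)
  # time x pixel matrix of the teleconnection term
  tele <- shifted[, lag_pos, drop = FALSE] * rep(beta, each = n)
  m <- matrix(base_t, n, npix) + tele
  if (config$noise_sd > 0) {
    noise <- with_seed(derive_seed(config$seed, paste0("cube:", variable_name)),
                       rnorm(n * npix, 0, config$noise_sd))
    m <- m + matrix(noise, n, npix)
  }
  cube <- climate_cube(array(t(m), dim = c(nr, nc, n)),
                       variable = variable_name, units = "sim",
                       start = config$start)
  ph <- classify_phases(running_mean3(index))
  truth <- structure(list(beta_field = config$beta_field,
                          lag_field = config$lag_field,
                          signal_mask = config$beta_field != 0,
                          event_months = list(
                            elnino = phase_months(ph, "elnino"),
                            lanina = phase_months(ph, "lanina"))),
                     class = "sim_truth")
  list(cube = cube, truth = truth)
}

#' Simulate a paired sun/shade productivity cube set
#'
#' Two cubes driven by the same index but with independent beta and lag
#' fields, emulating sunlit-leaf and shaded-leaf gross primary productivity.
#' Block-structured beta signs in the two configs construct any cell of the
#' sun/shade sensitivity typology.
#'
#' @param config_sun,config_shade [sim_config()]s sharing `grid_shape` and
#'   `n_months`.
#' @param index the shared driving [index_series()].
#' @return List with `sun` and `shade`, each a `list(cube, truth)`.
#' @export
simulate_gpp_pair <- function(config_sun, config_shade, index) {
  stopifnot(inherits(config_sun, "sim_config"),
            inherits(config_shade, "sim_config"))
  if (!all(config_sun$grid_shape == config_shade$grid_shape))
    stop2("sun and shade configs must share grid_shape")
  if (config_sun$n_months != config_shade$n_months)
    stop2("sun and shade configs must share n_months")
  list(sun = simulate_cube(config_sun, index, "gpp_sun"),
       shade = simulate_cube(config_shade, index, "gpp_shade"))
}

#' Simulate suitability and forest-loss masks
#'
#' Stand-ins for a crop-suitability mask at the analysis resolution and a
#' finer-resolution binary forest-loss raster to be aggregated by
#' [deforestation_filter()].
#'
#' @param grid_shape integer `(rows, cols)` of the analysis grid.
#' @param suitable_fraction expected fraction of suitable cells, in `[0,1]`.
#' @param loss_fraction expected fraction of fine loss pixels, in `[0,1]`.
#' @param fine_factor integer >= 1; the loss raster is `fine_factor` times
#'   finer in each dimension.
#' @param seed root seed.
#' @return List with `suitability` (logical `rows x cols` matrix, TRUE =
#'   suitable) and `loss` (logical fine-resolution matrix, TRUE = loss).
#' @export
simulate_masks <- function(grid_shape, suitable_fraction = 0.8,
                           loss_fraction = 0.05, fine_factor = 4L,
                           seed = 1L) {
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 1))
  if (suitable_fraction < 0 || suitable_fraction > 1 ||
      loss_fraction < 0 || loss_fraction > 1)
    stop2("fractions must lie in [0, 1]")
  if (fine_factor < 1 || fine_factor != round(fine_factor))
    stop2("fine_factor must be an integer >= 1")
  nr <- grid_shape[1]; nc <- grid_shape[2]
  suit <- with_seed(derive_seed(seed, "mask:suitability"),
                    matrix(runif(nr * nc) < suitable_fraction, nr, nc))
  fr <- nr * fine_factor; fc <- nc * fine_factor
  loss <- with_seed(derive_seed(seed, "mask:loss"),
                    matrix(runif(fr * fc) < loss_fraction, fr, fc))
  list(suitability = suit, loss = loss)
}
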