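# Phase-conditional, optionally lagged per-pixel Pearson correlation maps
# with t-based two-sided significance.

lag1_acf <- function(v) {
  n <- length(v)
  v <- v - mean(v)
  s <- sum(v^2)
  if (s == 0) return(0)
  sum(v[-1] * v[-n]) / s
}

#' Pearson correlation with t-based p-value
#'
#' Sample product-moment correlation with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))`. Zero-variance input gives an
#' undefined (NA) result, not zero; fewer than `min_n` pairs likewise flags
#' the result undefined rather than raising an error. Optionally applies a
#' Bretherton-style effective-sample-size correction for serially correlated
#' (e.g. 3-month-smoothed) series: `n_eff = n * (1 - a1x*a1y) / (1 + a1x*a1y)`
#' with the lag-1 autocorrelations `a1x`, `a1y`.
#'
#' @param x,y paired numeric vectors; NA pairs are dropped.
#' @param min_n minimum pairs for a defined result (default 8).
#' @param use_neff apply the effective-sample-size correction (default FALSE,
#'   the nominal test).
#' @return List with `r`, `p`, `n` (pairs used; `n_eff` added when corrected).
#' @export
pearson_cor <- function(x, y, min_n = 8L, use_neff = FALSE) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  out <- list(r = NA_real_, p = NA_real_, n = n)
  if (n < max(min_n, 3L)) return(out)
  xc <- x - mean(x); yc <- y - mean(y)
  sx <- sum(xc^2); sy <- sum(yc^2)
  if (sx == 0 || sy == 0) return(out)           # degenerate: undefined
  r <- sum(xc * yc) / sqrt(sx * sy)
  r <- max(-1, min(1, r))
  df_n <- n
  if (use_neff) {
    a <- lag1_acf(x) * lag1_acf(y)
    df_n <- n * (1 - a) / (1 + a)
    out$n_eff <- df_n
    if (df_n < 3) return(out)
  }
  out$r <- r
  if (abs(r) == 1) {
    out$p <- 0
  } else {
    tt <- r * sqrt((df_n - 2) / (1 - r^2))
    out$p <- 2 * pt(-abs(tt), df = df_n - 2)
  }
  out
}

#' Per-pixel phase-conditional lagged correlation map
#'
#' For every masked pixel, correlates the smoothed index at the months
#' carrying `phase` against the pixel's series `lag` months later (positive
#' lag: the field responds after the index). Phase months whose lagged
#' counterpart falls outside the record are dropped pixel-wise. Pixels with
#' fewer than `min_n` usable pairs, or zero variance, are undefined.
#'
#' @param cube a preprocessed anomaly [climate_cube()].
#' @param index the smoothed [index_series()].
#' @param labels [classify_phases()] labels aligned with the series.
#' @param phase `"elnino"` or `"lanina"`.
#' @param lag integer month offset (values beyond +/-3 are allowed with a
#'   warning).
#' @param mask optional logical analysis mask; defaults to the cube mask.
#' @param alpha significance level stored with the map (default 0.05).
#' @param min_n minimum pairs per pixel (default 8).
#' @param require_smoothed insist that cube and index are 3-month smoothed
#'   (default TRUE, the standard pipeline); set FALSE for diagnostics on
#'   unsmoothed series, e.g. significance-calibration checks.
#' @param use_neff effective-sample-size correction, see [pearson_cor()].
#' @return Object of class `correlation_map`: grids `r`, `p`, `n`, plus
#'   `variable`, `phase`, `lag`, `alpha`, `min_n` and a `status` field
#'   (`"ok"` or `"empty-domain"`).
#' @export
correlation_map <- function(cube, index, labels, phase, lag = 0L, mask = NULL,
                            alpha = 0.05, min_n = 8L,
                            require_smoothed = TRUE, use_neff = FALSE) {
  stopifnot(inherits(cube, "climate_cube"), inherits(index, "index_series"),
            inherits(labels, "phase_labels"))
  phase <- match.arg(phase, c("elnino", "lanina"))
  if (require_smoothed &&
      !(isTRUE(cube$flags$smoothed) && isTRUE(index$smoothed)))
    stop2("cube and index must both be 3-month smoothed (or set require_smoothed = FALSE)")
  if (length(index) != n_months(cube))
    stop2("index length %d != cube months %d", length(index), n_months(cube))
  if (length(labels) != length(index))
    stop2("labels length %d != index length %d", length(labels), length(index))
  if (abs(lag) > 3) warn2("|lag| = %d exceeds the usual -3..+3 window", abs(lag))
  d <- dim(cube$data)
  if (is.null(mask)) mask <- cube$mask
  check_same_grid(cube, mask, "cube and mask")

  empty <- function(status) {
    na <- matrix(NA_real_, d[1], d[2])
    structure(list(variable = cube$variable, phase = phase, lag = as.integer(lag),
                   r = na, p = na, n = matrix(0L, d[1], d[2]),
                   alpha = alpha, min_n = min_n, status = status,
                   geo = cube$geo),
              class = "correlation_map")
  }
  tm <- phase_months(labels, phase)
  tl <- tm + lag
  ok <- tl >= 1L & tl <= n_months(cube)
  tm <- tm[ok]; tl <- tl[ok]
  if (length(tm) == 0L) return(empty("empty-domain"))

  x <- index$values[tm]
  Y <- cube_matrix(cube)[tl, , drop = FALSE]     # months x pixels
  Y[, !as.vector(mask)] <- NA_real_
  nmon <- length(x)
  npix <- ncol(Y)
  rv <- rep(NA_real_, npix); pv <- rep(NA_real_, npix); nv <- integer(npix)

  complete <- !colSums(is.na(Y))
  nv[complete] <- nmon
  if (any(complete) && nmon >= max(min_n, 3L) && sd(x) > 0) {
    Yc <- Y[, complete, drop = FALSE]
    Yc <- sweep(Yc, 2L, colMeans(Yc))
    xc <- x - mean(x)
    sy <- colSums(Yc^2)
    r <- as.vector(crossprod(xc, Yc)) / sqrt(sum(xc^2) * sy)
    r[sy == 0] <- NA_real_
    r <- pmax(-1, pmin(1, r))
    df_n <- nmon
    if (use_neff) {
      a1x <- lag1_acf(x)
      a1y <- apply(Y[, complete, drop = FALSE], 2L, lag1_acf)
      af <- a1x * a1y
      df_n <- nmon * (1 - af) / (1 + af)
    }
    tt <- r * sqrt((df_n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tt), df = pmax(df_n - 2, .Machine$double.eps))
    p[abs(r) == 1] <- 0
    rv[complete] <- r
    pv[complete] <- p
  }
  partial <- which(!complete & as.vector(mask))
  for (j in partial) {
    res <- pearson_cor(x, Y[, j], min_n = min_n, use_neff = use_neff)
    rv[j] <- res$r; pv[j] <- res$p; nv[j] <- res$n
  }
  structure(list(variable = cube$variable, phase = phase, lag = as.integer(lag),
                 r = matrix(rv, d[1], d[2]), p = matrix(pv, d[1], d[2]),
                 n = matrix(nv, d[1], d[2]),
                 alpha = alpha, min_n = min_n,
                 status = if (all(is.na(rv))) "empty-domain" else "ok",
                 geo = cube$geo),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  nd <- sum(!is.na(x$r))
  cat(sprintf("<correlation_map> '%s' phase=%s lag=%+d [%s]\n",
              x$variable, x$phase, x$lag, x$status))
  if (nd > 0) {
    sig <- sum(x$p < x$alpha, na.rm = TRUE)
    cat(sprintf("  %d defined pixels, %d significant at p<%g (%.1f%%), median r %.3f\n",
                nd, sig, x$alpha, 100 * sig / nd, median(x$r, na.rm = TRUE)))
  }
  invisible(x)
}

#' Significance mask of a correlation map
#'
#' TRUE where the correlation is defined and `p < alpha` (strict inequality:
#' `p = 0.05` is excluded at the default level).
#'
#' @param cmap a [correlation_map()].
#' @param alpha significance level (defaults to the map's own alpha).
#' @return Logical matrix.
#' @export
significance_mask <- function(cmap, alpha = NULL) {
  stopifnot(inherits(cmap, "correlation_map"))
  alpha <- alpha %||% cmap$alpha
  out <- !is.na(cmap$r) & !is.na(cmap$p) & cmap$p < alpha
  out
}

#' Summary row for a correlation map
#'
#' @param cmap a [correlation_map()].
#' @return One-row data.frame: variable, phase, lag, pixel counts, percent
#'   significant, median r.
#' @export
summarize_cmap <- function(cmap) {
  nd <- sum(!is.na(cmap$r))
  sig <- sum(significance_mask(cmap))
  data.frame(variable = cmap$variable, phase = cmap$phase, lag = cmap$lag,
             n_defined = nd, n_significant = sig,
             pct_significant = if (nd > 0) 100 * sig / nd else NA_real_,
             median_r = if (nd > 0) median(cmap$r, na.rm = TRUE) else NA_real_,
             stringsAsFactors = FALSE)
}
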