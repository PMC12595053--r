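# Lag analysis: distribution of per-pixel r across lags -3..+3, median sign
# transition detection, and non-significant -> significant transition maps.

#' Correlation maps across the -3..+3 lag window
#'
#' Convenience wrapper computing one [correlation_map()] per lag.
#'
#' @param cube,index,labels,phase,mask,... passed to [correlation_map()].
#' @param lags integer lags (default -3:3).
#' @return Named list of correlation maps (`"lag-3"` ... `"lag+3"`).
#' @export
lag_correlation_maps <- function(cube, index, labels, phase, mask = NULL,
                                 lags = -3:3, ...) {
  maps <- lapply(lags, function(l)
    correlation_map(cube, index, labels, phase, lag = l, mask = mask, ...))
  names(maps) <- sprintf("lag%+d", lags)
  maps
}

#' Lag profile of pixel-wise correlations
#'
#' Boxplot-style summary (median, quartiles, 1.5*IQR whiskers, pixel count)
#' of the per-pixel r distribution over the masked domain, per lag. All
#' masked pixels with a defined r are included, not only significant ones.
#'
#' @param corr_maps list of [correlation_map()]s at consecutive lags (same
#'   grid and phase), e.g. from [lag_correlation_maps()].
#' @param mask optional logical analysis mask.
#' @return Object of class `lag_profile`: data.frame `summary` with one row
#'   per lag (`lag`, `median`, `q1`, `q3`, `lo`, `hi`, `count`), plus
#'   `phase` and `status`.
#' @export
lag_profiles <- function(corr_maps, mask = NULL) {
  stopifnot(is.list(corr_maps), length(corr_maps) >= 2L)
  phases <- unique(vapply(corr_maps, `[[`, "", "phase"))
  if (length(phases) != 1L) stop2("maps must share one phase")
  lags <- vapply(corr_maps, `[[`, 0L, "lag")
  if (any(diff(sort(lags)) != 1L)) stop2("lags must be consecutive, got %s",
                                         paste(sort(lags), collapse = ", "))
  rows <- lapply(corr_maps[order(lags)], function(cm) {
    r <- cm$r
    if (!is.null(mask)) r[!mask] <- NA_real_
    v <- r[!is.na(r)]
    if (length(v) == 0L)
      return(data.frame(lag = cm$lag, median = NA_real_, q1 = NA_real_,
                        q3 = NA_real_, lo = NA_real_, hi = NA_real_,
                        count = 0L))
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    data.frame(lag = cm$lag, median = q[2], q1 = q[1], q3 = q[3],
               lo = min(v[v >= q[1] - 1.5 * iqr]),
               hi = max(v[v <= q[3] + 1.5 * iqr]),
               count = length(v))
  })
  sm <- do.call(rbind, rows)
  structure(list(summary = sm, phase = phases,
                 status = if (all(sm$count == 0L)) "empty-domain" else "ok"),
            class = "lag_profile")
}

#' @export
print.lag_profile <- function(x, ...) {
  cat(sprintf("<lag_profile> phase=%s [%s]\n", x$phase, x$status))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Detect the median sign transition between consecutive lags
#'
#' Scans the per-lag medians for the earliest consecutive pair where the
#' median changes sign (crossing through or landing on exactly 0 counts).
#' When no sign change exists the conventional default pair `(-1, 0)` is
#' returned — the transition depicted when no clear change of direction is
#' observed.
#'
#' @param profile a [lag_profiles()] result.
#' @return Integer vector `c(a, a + 1)`; attribute `"detected"` is FALSE
#'   when the default pair was used.
#' @export
detect_transition <- function(profile) {
  stopifnot(inherits(profile, "lag_profile"))
  sm <- profile$summary
  if (anyNA(sm$median)) stop2("profile is incomplete (NA medians)")
  s <- sign(sm$median)
  chg <- which(s[-1] != s[-length(s)])
  if (length(chg) == 0L) {
    out <- c(-1L, 0L)
    attr(out, "detected") <- FALSE
  } else {
    out <- c(sm$lag[chg[1]], sm$lag[chg[1] + 1L])
    attr(out, "detected") <- TRUE
  }
  out
}

#' Map pixels shifting from non-significant to significant across a lag pair
#'
#' Classifies pixels that are non-significant at lag `a` and significant at
#' lag `b = a + 1` by their productivity direction at lag `b`: during El
#' Nino a positive r is `increase`, during La Nina a negative r is
#' `increase`; the opposite signs are `decrease`. All other pixels are
#' `none`.
#'
#' @param cmap_a,cmap_b [correlation_map()]s at consecutive lags, same grid
#'   and phase.
#' @param alpha significance level (default 0.05).
#' @param mask optional logical analysis mask.
#' @return Object of class `transition_map`: `class` (character matrix of
#'   `increase`/`decrease`/`none`), `lag_pair`, `phase`.
#' @export
transition_map <- function(cmap_a, cmap_b, alpha = 0.05, mask = NULL) {
  stopifnot(inherits(cmap_a, "correlation_map"),
            inherits(cmap_b, "correlation_map"))
  if (!identical(cmap_a$phase, cmap_b$phase))
    stop2("maps must share a phase")
  if (cmap_b$lag - cmap_a$lag != 1L)
    stop2("lags must be consecutive (a, a+1), got %d and %d",
          cmap_a$lag, cmap_b$lag)
  check_same_grid(cmap_a$r, cmap_b$r, "lag maps")
  sig_a <- significance_mask(cmap_a, alpha)
  sig_b <- significance_mask(cmap_b, alpha)
  newsig <- !sig_a & sig_b & !is.na(cmap_a$r)
  if (!is.null(mask)) newsig <- newsig & mask
  cls <- matrix("none", nrow(cmap_a$r), ncol(cmap_a$r))
  pos <- newsig & cmap_b$r > 0
  neg <- newsig & cmap_b$r < 0
  if (cmap_a$phase == "elnino") {
    cls[pos] <- "increase"; cls[neg] <- "decrease"
  } else {
    cls[neg] <- "increase"; cls[pos] <- "decrease"
  }
  structure(list(class = cls, lag_pair = c(cmap_a$lag, cmap_b$lag),
                 phase = cmap_a$phase),
            class = "transition_map")
}

#' @export
print.transition_map <- function(x, ...) {
  tb <- table(factor(x$class, levels = c("increase", "decrease", "none")))
  cat(sprintf("<transition_map> phase=%s lags (%+d -> %+d): %s\n",
              x$phase, x$lag_pair[1], x$lag_pair[2],
              paste(sprintf("%s %d", names(tb), tb), collapse = ", ")))
  invisible(x)
}
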