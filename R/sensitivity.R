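# Sun/shade productivity sensitivity: correlation signs -> productivity
# direction values -> four-class typology with area percentages.

SENSITIVITY_LEVELS <- c("both_increase", "both_decrease",
                        "sun_decrease_only", "shade_decrease_only", "none")

#' Productivity direction from a GPP correlation map
#'
#' Converts significant ONI-GPP correlations into productivity-direction
#' values: +1 (increased productivity) or -1 (decreased productivity), 0
#' where non-significant or undefined. Under El Nino a positive correlation
#' means productivity rises with the warm phase (+1); under La Nina a
#' positive correlation means productivity falls as the index drops (-1), so
#' the sign is flipped.
#'
#' @param cmap a [correlation_map()] of a GPP layer.
#' @param phase phase the direction is evaluated for; must match the map.
#' @param alpha significance level (defaults to the map's alpha).
#' @return Integer matrix of -1/0/+1.
#' @export
productivity_direction <- function(cmap, phase = cmap$phase, alpha = NULL) {
  stopifnot(inherits(cmap, "correlation_map"))
  phase <- match.arg(phase, c("elnino", "lanina"))
  if (!identical(phase, cmap$phase))
    stop2("phase mismatch: map is '%s', requested '%s'", cmap$phase, phase)
  sig <- significance_mask(cmap, alpha)
  dir <- matrix(0L, nrow(cmap$r), ncol(cmap$r))
  s <- sign(cmap$r[sig])
  dir[sig] <- as.integer(if (phase == "elnino") s else -s)
  dir
}

#' Sun/shade sensitivity typology
#'
#' Combines the sunlit-leaf and shaded-leaf direction grids into the
#' four-class typology: `both_increase` (+1, +1), `both_decrease` (-1, -1),
#' `sun_decrease_only` (sun -1, shade not decreased), `shade_decrease_only`
#' (shade -1, sun not decreased). Pixels with no decrease and no joint
#' increase (including one-sided +1 responses) are `none`.
#'
#' @param sun_dir,shade_dir direction grids from [productivity_direction()].
#' @param phase phase label stored with the map.
#' @return Object of class `sensitivity_map`: `category` (factor matrix
#'   values via integer codes), `sun_dir`, `shade_dir`, `phase`, `levels`.
#' @export
sensitivity_typology <- function(sun_dir, shade_dir, phase = "elnino") {
  stopifnot(is.matrix(sun_dir), is.matrix(shade_dir))
  check_same_grid(sun_dir, shade_dir, "sun and shade grids")
  vals <- c(sun_dir, shade_dir)
  if (!all(vals %in% c(-1L, 0L, 1L)))
    stop2("direction grids must hold values in {-1, 0, +1}")
  cat_ <- matrix("none", nrow(sun_dir), ncol(sun_dir))
  cat_[sun_dir == -1L & shade_dir == -1L] <- "both_decrease"
  cat_[sun_dir == -1L & shade_dir >= 0L] <- "sun_decrease_only"
  cat_[shade_dir == -1L & sun_dir >= 0L] <- "shade_decrease_only"
  cat_[sun_dir == 1L & shade_dir == 1L] <- "both_increase"
  structure(list(category = cat_, sun_dir = sun_dir, shade_dir = shade_dir,
                 phase = phase, levels = SENSITIVITY_LEVELS),
            class = "sensitivity_map")
}

#' @export
print.sensitivity_map <- function(x, ...) {
  tb <- table(factor(x$category, levels = x$levels))
  cat(sprintf("<sensitivity_map> phase=%s, %d pixels\n", x$phase,
              length(x$category)))
  print(tb)
  invisible(x)
}

#' Area percentages per sensitivity category
#'
#' Percentage of masked pixels in each typology category. The denominator is
#' all masked (suitability) pixels, so the four signal categories need not
#' sum to 100; together with `none` they do.
#'
#' @param smap a [sensitivity_typology()] result.
#' @param mask logical analysis mask.
#' @return data.frame with `category`, `n_pixels`, `percent`.
#' @export
area_percentages <- function(smap, mask) {
  stopifnot(inherits(smap, "sensitivity_map"), is.matrix(mask))
  check_same_grid(smap$category, mask, "typology and mask")
  if (!any(mask)) stop2("empty mask: no pixels to tabulate")
  cats <- factor(smap$category[mask], levels = smap$levels)
  tb <- table(cats)
  data.frame(category = names(tb), n_pixels = as.integer(tb),
             percent = 100 * as.integer(tb) / sum(mask),
             stringsAsFactors = FALSE)
}
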