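# Entropy Weight Method: per-variable weights from the spatial entropy of
# significant teleconnection magnitudes, and the per-pixel exposure index.

#' Assemble EWM inputs from correlation maps
#'
#' Builds the `m variables x n pixels` exposure-signal matrix from one
#' correlation map per climate variable. A pixel enters the domain when it is
#' inside `mask` and at least one variable is significant there (union rule;
#' `retention = "intersection"` requires all variables significant).
#' Entries are `|r|` where significant, 0 otherwise; the sign of each
#' significant correlation is kept in a separate direction table (the
#' stress-direction bookkeeping), never folded into the magnitude.
#'
#' @param corr_maps named list of [correlation_map()]s sharing phase, lag and
#'   grid (typically the six climate variables).
#' @param mask logical analysis mask.
#' @param retention `"union"` (default) or `"intersection"`.
#' @return Object of class `ewm_inputs`: `X` (m x n), `direction` (m x n of
#'   -1/0/+1), `variables`, `pixels` (linear indices into the grid), `phase`,
#'   `grid_dim`, `status`.
#' @export
ewm_build_inputs <- function(corr_maps, mask,
                             retention = c("union", "intersection")) {
  retention <- match.arg(retention)
  stopifnot(is.list(corr_maps), length(corr_maps) >= 1L)
  if (!all(vapply(corr_maps, inherits, TRUE, "correlation_map")))
    stop2("corr_maps must be correlation_map objects")
  phases <- unique(vapply(corr_maps, `[[`, "", "phase"))
  if (length(phases) != 1L)
    stop2("all correlation maps must share one phase, got: %s",
          paste(phases, collapse = ", "))
  lags <- unique(vapply(corr_maps, `[[`, 0L, "lag"))
  if (length(lags) != 1L) stop2("all correlation maps must share one lag")
  gd <- dim(corr_maps[[1]]$r)
  for (cm in corr_maps) check_same_grid(cm$r, mask, "map and mask")
  vars <- names(corr_maps) %||% vapply(corr_maps, `[[`, "", "variable")
  sig <- vapply(corr_maps, significance_mask,
                matrix(TRUE, gd[1], gd[2]))           # rows x cols x m
  sig <- matrix(sig, prod(gd), length(corr_maps))     # pixels x m
  inmask <- as.vector(mask)
  keep <- inmask & (if (retention == "union") rowSums(sig) > 0
                    else rowSums(sig) == ncol(sig))
  pixels <- which(keep)
  if (length(pixels) == 0L) {
    return(structure(list(X = matrix(0, length(corr_maps), 0),
                          direction = matrix(0L, length(corr_maps), 0),
                          variables = vars, pixels = integer(0),
                          phase = phases, grid_dim = gd,
                          status = "empty-domain"),
                     class = "ewm_inputs"))
  }
  m <- length(corr_maps)
  X <- matrix(0, m, length(pixels), dimnames = list(vars, NULL))
  dir <- matrix(0L, m, length(pixels), dimnames = list(vars, NULL))
  for (i in seq_len(m)) {
    rvec <- as.vector(corr_maps[[i]]$r)[pixels]
    svec <- sig[pixels, i]
    X[i, svec] <- abs(rvec[svec])
    dir[i, svec] <- as.integer(sign(rvec[svec]))
  }
  structure(list(X = X, direction = dir, variables = vars, pixels = pixels,
                 phase = phases, grid_dim = gd, status = "ok"),
            class = "ewm_inputs")
}

#' Row-normalize an exposure-signal matrix
#'
#' `P[i, j] = X[i, j] / sum_j X[i, j]`, so each variable's pixel values sum
#' to 1. All-zero variable rows cannot be normalized and are dropped with a
#' warning.
#'
#' @param X non-negative `m x n` matrix.
#' @return The normalized matrix `P` (possibly with fewer rows).
#' @export
ewm_normalize <- function(X) {
  stopifnot(is.matrix(X))
  if (any(X < 0) || any(!is.finite(X))) stop2("X must be finite and non-negative")
  rs <- rowSums(X)
  if (any(rs == 0)) {
    warn2("dropping %d all-zero variable row(s): %s", sum(rs == 0),
          paste(rownames(X)[rs == 0] %||% which(rs == 0), collapse = ", "))
    X <- X[rs > 0, , drop = FALSE]
    rs <- rs[rs > 0]
  }
  X / rs
}

#' Shannon entropy of normalized variable rows
#'
#' `E[i] = -k * sum_j P[i, j] * ln(P[i, j])` with `k = 1 / ln(n)`, so a
#' uniform row has entropy 1 and a single-mass row entropy 0. Terms with
#' `P = 0` contribute 0.
#'
#' @param P row-normalized matrix from [ewm_normalize()].
#' @param n number of pixels; defaults to `ncol(P)`. Must be >= 2.
#' @return Numeric vector of entropies in `[0, 1]`.
#' @export
ewm_entropy <- function(P, n = ncol(P)) {
  stopifnot(is.matrix(P))
  if (n < 2) stop2("entropy needs n >= 2 pixels (k = 1/ln(n) undefined)")
  if (any(abs(rowSums(P) - 1) > 1e-8))
    stop2("rows of P must sum to 1; run ewm_normalize() first")
  k <- 1 / log(n)
  plogp <- P * log(P)
  plogp[P == 0] <- 0           # 0 * ln 0 := 0
  E <- -k * rowSums(plogp)
  pmin(pmax(E, 0), 1)
}

#' Diversification and weights from entropies
#'
#' `d[i] = 1 - E[i]`; `w[i] = d[i] / sum(d)`. Lower entropy (more spatial
#' variability) yields a higher weight. All entropies equal to 1 carry no
#' information and raise an error.
#'
#' @param E entropies in `[0, 1]`.
#' @return List with `d` (diversification) and `w` (weights summing to 1).
#' @export
ewm_weights <- function(E) {
  if (any(E < -1e-9) || any(E > 1 + 1e-9)) stop2("entropies must lie in [0, 1]")
  d <- 1 - E
  if (sum(d) <= 0)
    stop2(paste("all entropies are 1: the variables are spatially uniform and",
                "carry no weighting information; supply at least one variable",
                "with spatial structure"))
  list(d = d, w = d / sum(d))
}

#' Per-pixel exposure index
#'
#' `exposure[j] = sum_i w[i] * X_scaled[i, j]`. With weights summing to 1 and
#' `X_scaled` rows in `[0, 1]`, the index lies in `[0, 1]`.
#'
#' @param w normalized weights (length m).
#' @param X_scaled `m x n` matrix with rows scaled to `[0, 1]`.
#' @return Numeric vector of length n.
#' @export
exposure_index <- function(w, X_scaled) {
  stopifnot(is.matrix(X_scaled))
  if (length(w) != nrow(X_scaled))
    stop2("length(w) = %d != nrow(X_scaled) = %d", length(w), nrow(X_scaled))
  if (abs(sum(w) - 1) > 1e-8) stop2("weights must sum to 1")
  if (any(X_scaled < -1e-12) || any(X_scaled > 1 + 1e-12))
    stop2("X_scaled rows must lie in [0, 1]")
  as.vector(crossprod(X_scaled, w))
}

# per-variable min-max scaling to [0, 1] over the domain
minmax_rows <- function(X) {
  t(apply(X, 1L, function(v) {
    rng <- range(v)
    if (diff(rng) == 0) rep(0, length(v)) else (v - rng[1]) / diff(rng)
  }))
}

#' Entropy-Weight-Method exposure pipeline
#'
#' Composition of [ewm_build_inputs()], [ewm_normalize()], [ewm_entropy()],
#' [ewm_weights()] and [exposure_index()] for one phase. The index uses
#' per-variable min-max-scaled `|r|`, so exposure lies in `[0, 1]`; the
#' correlation signs stay in the direction table for map colouring.
#'
#' @param corr_maps named list of same-phase [correlation_map()]s.
#' @param mask logical analysis mask.
#' @param retention pixel retention rule, see [ewm_build_inputs()].
#' @return Object of class `ewm_result`: `P`, `E`, `d`, `w`, `k`, `n_pixels`,
#'   `exposure` (grid matrix, NA off-domain), `inputs`, `status`.
#' @export
ewm_pipeline <- function(corr_maps, mask, retention = "union") {
  inp <- ewm_build_inputs(corr_maps, mask, retention = retention)
  if (inp$status == "empty-domain" || length(inp$pixels) < 2L) {
    status <- if (inp$status == "empty-domain") "empty-domain" else "degenerate-domain"
    if (status == "degenerate-domain")
      stop2("EWM needs at least 2 domain pixels, got %d", length(inp$pixels))
    return(structure(list(P = NULL, E = NULL, d = NULL, w = NULL, k = NA_real_,
                          n_pixels = 0L,
                          exposure = matrix(NA_real_, inp$grid_dim[1], inp$grid_dim[2]),
                          inputs = inp, status = status),
                     class = "ewm_result"))
  }
  P <- ewm_normalize(inp$X)
  kept <- rownames(P) %||% seq_len(nrow(P))
  E <- ewm_entropy(P)
  dw <- ewm_weights(E)
  Xs <- minmax_rows(inp$X[kept, , drop = FALSE])
  expo <- exposure_index(dw$w, Xs)
  grid <- matrix(NA_real_, inp$grid_dim[1], inp$grid_dim[2])
  grid[inp$pixels] <- expo
  structure(list(P = P, E = stats::setNames(E, kept),
                 d = stats::setNames(dw$d, kept),
                 w = stats::setNames(dw$w, kept),
                 k = 1 / log(ncol(P)), n_pixels = ncol(P),
                 exposure = grid, inputs = inp, status = "ok"),
            class = "ewm_result")
}

#' @export
print.ewm_result <- function(x, ...) {
  cat(sprintf("<ewm_result> [%s] %d domain pixels\n", x$status, x$n_pixels))
  if (x$status == "ok") {
    tab <- data.frame(entropy = round(x$E, 4), weight = round(x$w, 4))
    print(tab)
    cat(sprintf("  exposure range [%.3f, %.3f]\n",
                min(x$exposure, na.rm = TRUE), max(x$exposure, na.rm = TRUE)))
  }
  invisible(x)
}

#' Published entropy/weight reference table
#'
#' The per-variable entropies and weights for the four crop x ENSO-phase
#' blocks (coffee and cacao potential zones under El Nino and La Nina),
#' as shipped in `inst/extdata/ewm_reference_table.csv`. The weights can be
#' recomputed from the entropies with [ewm_weights()]; see
#' [check_reference_weights()].
#'
#' @return data.frame with columns `crop`, `phase`, `variable`, `entropy`,
#'   `weight`.
#' @export
ewm_reference_table <- function() {
  path <- system.file("extdata", "ewm_reference_table.csv",
                      package = "ensotele", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recompute reference weights from reference entropies
#'
#' For each crop x phase block, runs the published entropies through
#' [ewm_weights()] and compares with the published weights. Because the
#' published entropies are rounded to 4 decimals, recomputed weights can
#' differ from the published ones in the 4th decimal (observed max deviation
#' ~6e-5).
#'
#' @param table a reference table as from [ewm_reference_table()].
#' @return data.frame with recomputed weights and deviations per row;
#'   attribute `max_abs_dev` holds the largest absolute deviation.
#' @export
check_reference_weights <- function(table = ewm_reference_table()) {
  need <- c("crop", "phase", "variable", "entropy", "weight")
  if (!all(need %in% names(table)))
    stop2("table must have columns %s", paste(need, collapse = ", "))
  out <- do.call(rbind, lapply(split(table, paste(table$crop, table$phase)),
    function(blk) {
      blk$weight_recomputed <- ewm_weights(blk$entropy)$w
      blk$deviation <- blk$weight_recomputed - blk$weight
      blk
    }))
  rownames(out) <- NULL
  attr(out, "max_abs_dev") <- max(abs(out$deviation))
  out
}
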