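#' @keywords internal
"_PACKAGE"

#' @importFrom stats pt lm.fit median quantile rnorm runif sd cor
#' @importFrom utils read.csv head tail packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(sprintf(...), call. = FALSE)
warn2 <- function(...) warning(sprintf(...), call. = FALSE)

#' Derive a deterministic component seed from a root seed
#'
#' One root seed drives the whole simulation; each component (index, each
#' variable's noise field, masks, ...) draws from its own substream whose seed
#' is a deterministic hash of the root seed and the component label. Adding a
#' new component therefore never perturbs the streams of existing ones.
#'
#' @param seed integer root seed.
#' @param component character label of the consuming component.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(component), length(component) == 1L)
  m <- 2147483647  # 2^31 - 1, keeps the result a valid 32-bit R integer
  h <- as.numeric(seed) %% m
  for (ch in utf8ToInt(component)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# run expr with a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# month arithmetic on (year, month) pairs, month in 1..12
month_seq <- function(start, n) {
  stopifnot(length(start) == 2L, start[2] >= 1, start[2] <= 12)
  k <- (start[1] * 12L + (start[2] - 1L)) + seq_len(n) - 1L
  data.frame(year = k %/% 12L, month = k %% 12L + 1L)
}

# centered 3-point running mean with 2-point partial windows at the edges;
# NA if any window member is NA (missing data propagate)
running_mean3_vec <- function(x) {
  n <- length(x)
  if (n < 3L) stop2("running mean requires at least 3 values, got %d", n)
  out <- (x[c(1L, 1L:(n - 1L))] + x + x[c(2L:n, n)]) / 3
  out[1L] <- (x[1L] + x[2L]) / 2
  out[n] <- (x[n - 1L] + x[n]) / 2
  out
}
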