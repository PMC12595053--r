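# Shared fixtures built in code.

# a tiny config with known structure; any sim_config argument can override
tiny_config <- function(...) {
  args <- utils::modifyList(list(n_months = 48L, grid_shape = c(4L, 4L),
                                 seed = 42L),
                            list(...))
  do.call(sim_config, args)
}

# deterministic index with prescribed values (bypasses the AR(1) generator)
fixed_index <- function(values, start = c(1992L, 1L), smoothed = FALSE) {
  index_series(values, start = start, smoothed = smoothed)
}

# labels built directly from a vector of "elnino"/"lanina"/"neutral"
fixed_labels <- function(labs, start = c(1992L, 1L), threshold = 0.5) {
  structure(list(labels = factor(labs, levels = c("elnino", "lanina", "neutral")),
                 start = as.integer(start), threshold = threshold),
            class = "phase_labels")
}

# a correlation_map with prescribed r/p grids (for typology and lag tests)
fake_cmap <- function(r, p, phase = "elnino", lag = 0L, alpha = 0.05,
                      variable = "test") {
  stopifnot(all(dim(r) == dim(p)))
  n <- matrix(100L, nrow(r), ncol(r))
  n[is.na(r)] <- 0L
  structure(list(variable = variable, phase = phase, lag = as.integer(lag),
                 r = r, p = p, n = n, alpha = alpha, min_n = 8L,
                 status = "ok",
                 geo = list(origin = c(0, 0), px = c(1, -1), crs = "synthetic")),
            class = "correlation_map")
}

# loop-based oracle for the centred running mean with partial edge windows
running_mean3_vec_ref <- function(x) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- max(1, i - 1):min(n, i + 1)
    out[i] <- mean(x[w])
  }
  out
}

# write a temporary index CSV and return its path (cleaned with the caller)
write_temp_index <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE)
  path
}
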