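# Pearson kernel and phase-conditional lagged correlation maps.

test_that("pearson_cor matches hand values and cor.test", {
  # hand evaluation of the product-moment formula
  h <- pearson_cor(c(1, 2, 3, 4), c(1, 3, 2, 4), min_n = 3L)
  expect_identical(h$r, 0.8)
  # perfect proportionality
  x <- c(0.3, 1.1, -0.4, 2, 0.7, -1, 0.1, 0.5)
  expect_equal(pearson_cor(x, 2 * x)$r, 1)
  expect_equal(pearson_cor(x, -x)$r, -1)
  # agreement with the independent implementation on random pairs
  set.seed(101)
  for (i in 1:25) {
    n <- sample(8:60, 1)
    a <- rnorm(n); b <- rnorm(n)
    ref <- cor.test(a, b)
    got <- pearson_cor(a, b)
    expect_lt(abs(got$r - unname(ref$estimate)), 1e-12)
    expect_lt(abs(got$p - ref$p.value), 1e-12)
    expect_equal(got$n, n)
  }
})

test_that("degenerate and short inputs are undefined, not errors", {
  expect_true(is.na(pearson_cor(rep(1, 10), rnorm(10))$r))   # zero variance
  expect_true(is.na(pearson_cor(rnorm(10), rep(2, 10))$r))
  short <- pearson_cor(1:5, c(2, 1, 4, 3, 5), min_n = 8L)
  expect_true(is.na(short$r))
  expect_equal(short$n, 5L)
  # NA pairs dropped before counting
  x <- c(1:9, NA); y <- c(NA, 2:10)
  expect_equal(pearson_cor(x, y, min_n = 3L)$n, 8L)
})

test_that("effective-sample-size correction weakens smoothed significance", {
  set.seed(7)
  x <- running_mean3_vec_ref(rnorm(200))
  y <- running_mean3_vec_ref(rnorm(200))
  nominal <- pearson_cor(x, y)
  corrected <- pearson_cor(x, y, use_neff = TRUE)
  expect_equal(nominal$r, corrected$r)
  expect_lt(corrected$n_eff, nominal$n)     # smoothing costs degrees of freedom
  expect_gte(corrected$p, nominal$p)
})

test_that("correlation maps recover noise-free teleconnections", {
  beta <- matrix(0, 4, 4); beta[1, 2] <- 1.5; beta[4, 4] <- -2
  cfg <- tiny_config(n_months = 120L, beta_field = beta, noise_sd = 0,
                     trend_slope = 0)
  raw <- simulate_index(cfg)
  cube <- preprocess_cube(simulate_cube(cfg, raw, "v")$cube)
  idx <- running_mean3(raw)
  labels <- classify_phases(idx)

  # a noise-free field is beta times the index passed through the same
  # linear preprocessing chain; against that processed index r is exactly
  # sign(beta)
  idx_cube <- climate_cube(array(raw$values, c(1, 1, 120)), "oni")
  idx_proc <- preprocess_cube(idx_cube)$data[1, 1, ]
  expect_gt(pearson_cor(idx_proc, cube$data[1, 2, ], min_n = 3)$r, 1 - 1e-9)
  expect_lt(pearson_cor(idx_proc, cube$data[4, 4, ], min_n = 3)$r, -1 + 1e-9)

  # against the ONI-convention index (smoothed only) the sign and near-unit
  # magnitude survive phase filtering
  for (ph in c("elnino", "lanina")) {
    if (length(phase_months(labels, ph)) < 8) next
    cm <- correlation_map(cube, idx, labels, ph, lag = 0L)
    expect_gt(cm$r[1, 2], 0.9)
    expect_lt(cm$r[4, 4], -0.9)
    # beta = 0 pixels have no variance after noise-free preprocessing
    expect_true(is.na(cm$r[2, 2]))
  }
})

test_that("lagged pairing drops out-of-range months and honours the lag sign", {
  lagf <- matrix(2L, 4, 4)
  cfg <- tiny_config(n_months = 120L, beta_field = 1, lag_field = lagf,
                     noise_sd = 0.1)
  raw <- simulate_index(cfg)
  cube <- preprocess_cube(simulate_cube(cfg, raw, "v")$cube)
  idx <- running_mean3(raw)
  labels <- classify_phases(idx)
  ph <- if (length(phase_months(labels, "elnino")) >=
            length(phase_months(labels, "lanina"))) "elnino" else "lanina"
  cm0 <- correlation_map(cube, idx, labels, ph, lag = 0L)
  cm2 <- correlation_map(cube, idx, labels, ph, lag = 2L)
  # constructed +2 response: stronger at the matching evaluation lag
  expect_gt(abs(cm2$r[2, 2]), abs(cm0$r[2, 2]))
  # months whose lagged counterpart leaves the record are dropped
  n_ph <- length(phase_months(labels, ph))
  expect_lte(max(cm2$n), n_ph)
  expect_warning(correlation_map(cube, idx, labels, ph, lag = 4L), "usual")
})

test_that("mask exclusion and smoothing provenance are enforced", {
  cfg <- tiny_config()
  raw <- simulate_index(cfg)
  cube <- preprocess_cube(simulate_cube(cfg, raw, "v")$cube)
  idx <- running_mean3(raw)
  labels <- classify_phases(idx)
  mask <- matrix(TRUE, 4, 4); mask[3, 3] <- FALSE
  cm <- correlation_map(cube, idx, labels, "elnino", mask = mask)
  expect_true(is.na(cm$r[3, 3]))
  expect_equal(cm$n[3, 3], 0L)
  # unsmoothed inputs are rejected unless explicitly allowed
  unsm <- detrend_linear(to_anomalies(simulate_cube(cfg, raw, "v")$cube))
  expect_error(correlation_map(unsm, idx, labels, "elnino"), "smoothed")
  cm2 <- correlation_map(unsm, running_mean3(raw), labels, "elnino",
                         require_smoothed = FALSE)
  expect_s3_class(cm2, "correlation_map")
})

test_that("significance mask uses strict p < alpha", {
  r <- matrix(c(0.5, 0.5, NA, 0.2), 2, 2)
  p <- matrix(c(0.049, 0.05, NA, 0.2), 2, 2)
  cm <- fake_cmap(r, p)
  sig <- significance_mask(cm)
  expect_true(sig[1, 1])     # p = 0.049 included
  expect_false(sig[2, 1])    # p = 0.05 excluded (strict)
  expect_false(sig[1, 2])    # undefined excluded
  # alpha = 1 recovers the definedness mask
  expect_equal(significance_mask(cm, alpha = 1), !is.na(r))
  # all-undefined map -> all-false
  cm_na <- fake_cmap(matrix(NA_real_, 2, 2), matrix(NA_real_, 2, 2))
  expect_false(any(significance_mask(cm_na)))
})

test_that("vectorised map agrees with the scalar kernel pixel by pixel", {
  cfg <- sim_config(n_months = 96L, grid_shape = c(5L, 5L),
                    beta_field = matrix(rnorm(25, 0, 0.6), 5, 5),
                    noise_sd = 0.4, seed = 13L)
  raw <- simulate_index(cfg)
  cube <- preprocess_cube(simulate_cube(cfg, raw, "v")$cube)
  idx <- running_mean3(raw)
  labels <- classify_phases(idx)
  ph <- if (length(phase_months(labels, "elnino")) >= 8) "elnino" else "lanina"
  cm <- correlation_map(cube, idx, labels, ph, lag = 1L)
  tm <- phase_months(labels, ph)
  tl <- tm + 1L
  keep <- tl <= n_months(cube)
  x <- idx$values[tm[keep]]
  for (i in 1:5) for (j in 1:5) {
    ref <- pearson_cor(x, cube$data[i, j, tl[keep]])
    expect_equal(cm$r[i, j], ref$r, tolerance = 1e-12)
    expect_equal(cm$p[i, j], ref$p, tolerance = 1e-12)
  }
})
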