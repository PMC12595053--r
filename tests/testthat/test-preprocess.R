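# Anomaly preprocessing chain and mask construction.

test_that("monthly climatology averages calendar months, missing-aware", {
  # two years with January values 1 and 3 at one pixel -> January mean 2
  a <- array(0, c(2, 2, 24))
  a[1, 1, 1] <- 1; a[1, 1, 13] <- 3
  cube <- climate_cube(a, "v")
  clim <- monthly_climatology(cube)
  expect_equal(clim[1, 1, 1], 2)
  expect_equal(clim[2, 2, 1], 0)
  # one repeated year equals that year; constant cube -> constant fields
  one <- array(rep(sin(1:12), each = 4), c(2, 2, 12))
  expect_equal(monthly_climatology(climate_cube(one, "v"))[1, 1, ], sin(1:12))
  cc <- climate_cube(array(7, c(2, 2, 24)), "v")
  expect_true(all(monthly_climatology(cc) == 7))
  # partial years rejected
  expect_error(monthly_climatology(climate_cube(array(0, c(2, 2, 25)), "v")),
               "whole years")
})

test_that("anomalies subtract the monthly climatology and set provenance", {
  cfg <- tiny_config(noise_sd = 0, trend_slope = 0, beta_field = 0.5)
  idx <- simulate_index(cfg)
  cube <- simulate_cube(cfg, idx, "v")$cube
  anom <- to_anomalies(cube)
  expect_true(anom$flags$anomalized)
  # per-pixel monthly means of anomalies are ~0 (invariant), and the
  # climatology of the anomalies is ~0
  clim2 <- monthly_climatology(anom)
  expect_lt(max(abs(clim2)), 1e-9)
  # a cube equal to its own climatology gives all-zero anomalies
  rep_clim <- climate_cube(array(rep(sin(1:12), each = 4), c(2, 2, 48)), "v")
  expect_lt(max(abs(to_anomalies(rep_clim)$data)), 1e-12)
  # noise-free reconstruction: after anomaly + detrend the pixel equals
  # beta times the index passed through the same linear chain, exactly
  sm <- detrend_linear(anom)
  idx_proc <- detrend_linear(to_anomalies(
    climate_cube(array(idx$values, c(1, 1, 48)), "oni")))$data[1, 1, ]
  expect_equal(sm$data[1, 1, ], 0.5 * idx_proc, tolerance = 1e-10)
  expect_error(to_anomalies(anom), "already anomalized")
})

test_that("detrending matches a least-squares oracle and flags order", {
  cfg <- tiny_config(noise_sd = 0.3, trend_slope = 0.02)
  cube <- simulate_cube(cfg, simulate_index(cfg), "v")$cube
  anom <- to_anomalies(cube)
  det <- detrend_linear(anom)
  expect_true(det$flags$detrended)
  # oracle: per-pixel lm() residuals
  t <- seq_len(n_months(cube))
  for (px in list(c(1, 1), c(3, 4))) {
    y <- anom$data[px[1], px[2], ]
    expect_equal(det$data[px[1], px[2], ],
                 unname(residuals(lm(y ~ t))), tolerance = 1e-10)
  }
  # residual OLS slope ~ 0; pure line -> ~0 residuals
  y <- det$data[2, 2, ]
  expect_lt(abs(coef(lm(y ~ t))[2]), 1e-10)
  line <- climate_cube(array(rep(2 + 0.1 * t, each = 4), c(2, 2, 48)), "v",
                       flags = list(anomalized = TRUE, detrended = FALSE,
                                    smoothed = FALSE))
  expect_lt(max(abs(detrend_linear(line)$data)), 1e-9)
  # stage order enforced
  expect_error(detrend_linear(cube), "anomalized")
  expect_error(running_mean3_cube(anom), "detrended")
})

test_that("pixels with < 3 valid months become missing when detrending", {
  a <- array(rnorm(2 * 2 * 48), c(2, 2, 48))
  a[1, 1, 3:48] <- NA           # only 2 valid points
  cube <- climate_cube(a, "v", flags = list(anomalized = TRUE,
                                            detrended = FALSE, smoothed = FALSE))
  det <- detrend_linear(cube)
  expect_true(all(is.na(det$data[1, 1, ])))
  expect_false(anyNA(det$data[2, 2, ]))
})

test_that("cube smoothing matches the series convention and propagates NA", {
  cfg <- tiny_config()
  det <- detrend_linear(to_anomalies(simulate_cube(cfg, simulate_index(cfg), "v")$cube))
  sm <- running_mean3_cube(det)
  expect_true(sm$flags$smoothed)
  expect_equal(sm$data[2, 2, ], running_mean3_vec_ref(det$data[2, 2, ]))
  # NA in any window member -> NA out
  d2 <- det; d2$data[1, 1, 10] <- NA
  sm2 <- running_mean3_cube(d2)
  expect_true(all(is.na(sm2$data[1, 1, 9:11])))
  expect_false(anyNA(sm2$data[1, 1, c(8, 12)]))
  expect_error(running_mean3_cube(sm), "already smoothed")
})

test_that("deforestation filter aggregates fine loss correctly", {
  # single fine loss pixel excludes exactly its coarse cell under "any"
  loss <- matrix(FALSE, 8, 8)
  loss[3, 6] <- TRUE            # coarse cell (2, 3) at factor 2... -> (2,3)
  keep <- deforestation_filter(loss, c(4, 4), rule = "any")
  expect_false(keep[2, 3])
  expect_equal(sum(!keep), 1L)
  # fraction rule: 3 of 16 = 0.1875 <= 0.25 -> retained
  loss2 <- matrix(FALSE, 4, 4); loss2[c(1, 2, 3)] <- TRUE
  expect_true(deforestation_filter(loss2, c(1, 1), rule = "fraction", tau = 0.25))
  # but 5/16 > 0.25 -> excluded
  loss3 <- matrix(FALSE, 4, 4); loss3[1:5] <- TRUE
  expect_false(deforestation_filter(loss3, c(1, 1), rule = "fraction", tau = 0.25))
  expect_error(deforestation_filter(matrix(FALSE, 7, 8), c(4, 4)),
               "integer multiple")
})

test_that("mask combination is a logical AND with empty-domain tolerance", {
  a <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE), 2, 3)
  b <- matrix(c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE), 2, 3)
  expect_equal(combine_masks(a, b), a & b)
  expect_true(all(combine_masks(matrix(TRUE, 2, 2), matrix(TRUE, 2, 2))))
  # disjoint masks -> empty mask; downstream reports empty domain, no crash
  empty <- combine_masks(matrix(c(TRUE, FALSE), 4, 4),
                         matrix(c(FALSE, TRUE), 4, 4))
  expect_false(any(empty))
  cfg <- tiny_config()
  idx <- running_mean3(simulate_index(cfg))
  labels <- classify_phases(idx)
  cube <- preprocess_cube(simulate_cube(cfg, simulate_index(cfg), "v")$cube)
  cm <- correlation_map(cube, idx, labels, "elnino", mask = empty)
  expect_equal(cm$status, "empty-domain")
  expect_error(combine_masks(a, matrix(TRUE, 3, 2)), "shapes differ")
})
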