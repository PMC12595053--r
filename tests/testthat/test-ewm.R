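# Entropy Weight Method: normalization, entropy, weights, exposure index.

test_that("row normalization divides by the row sum", {
  expect_equal(ewm_normalize(matrix(c(1, 1, 1, 1), 1)), matrix(0.25, 1, 4))
  expect_equal(ewm_normalize(matrix(c(2, 0, 0), 1)), matrix(c(1, 0, 0), 1))
  expect_equal(ewm_normalize(matrix(c(1, 3), 1)), matrix(c(0.25, 0.75), 1))
  # all-zero rows are dropped with a warning
  X <- rbind(a = c(1, 1), b = c(0, 0))
  expect_warning(P <- ewm_normalize(X), "all-zero")
  expect_equal(rownames(P), "a")
  expect_error(ewm_normalize(matrix(c(-1, 2), 1)), "non-negative")
})

test_that("entropy hits its closed-form values", {
  # uniform row -> 1; single mass -> 0; half/half over 4 -> ln2/ln4 = 0.5
  expect_equal(ewm_entropy(matrix(1 / 7, 1, 7)), 1)
  expect_equal(ewm_entropy(matrix(c(1, 0, 0, 0, 0), 1)), 0)
  expect_equal(ewm_entropy(matrix(c(0.5, 0.5, 0, 0), 1)), 0.5)
  expect_error(ewm_entropy(matrix(1, 1, 1)), "n >= 2")
  expect_error(ewm_entropy(matrix(c(0.5, 0.4), 1)), "sum to 1")
})

test_that("weights normalize the diversification degrees", {
  dw <- ewm_weights(c(0.9, 0.8))
  expect_equal(dw$d, c(0.1, 0.2))
  expect_equal(dw$w, c(1 / 3, 2 / 3))
  # equal entropies -> equal weights
  expect_equal(ewm_weights(rep(0.7, 6))$w, rep(1 / 6, 6))
  expect_error(ewm_weights(c(1, 1, 1)), "no weighting information|spatially uniform")
  expect_error(ewm_weights(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("published entropy blocks reproduce the published weights", {
  tab <- ewm_reference_table()
  expect_equal(nrow(tab), 24L)
  # the coffee El Nino block, checked value by value at 4 dp
  blk <- tab[tab$crop == "coffee" & tab$phase == "elnino", ]
  w <- ewm_weights(blk$entropy)$w
  expect_equal(round(w[blk$variable == "vpd"], 4), 0.1940)
  expect_equal(round(w[blk$variable == "tmin"], 4), 0.1340)
  expect_equal(round(w[blk$variable == "tmax"], 4), 0.1529)
  # the published entropies are rounded to 4 dp, so recomputed weights can
  # sit up to one unit off in the 4th decimal; all 24 agree within 1e-4
  res <- check_reference_weights()
  expect_lte(attr(res, "max_abs_dev"), 1e-4)
})

test_that("EWM invariants hold on random matrices", {
  set.seed(31)
  for (i in 1:50) {
    m <- sample(2:8, 1); n <- sample(3:40, 1)
    X <- matrix(rexp(m * n), m, n)
    P <- ewm_normalize(X)
    expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
    E <- ewm_entropy(P)
    expect_true(all(E >= 0 & E <= 1))
    if (any(E < 1)) {
      w <- ewm_weights(E)$w
      expect_lt(abs(sum(w) - 1), 1e-12)
      expect_true(all(w >= 0))
    }
  }
})

test_that("entropy is permutation-invariant and stable under duplication", {
  set.seed(5)
  X <- matrix(rexp(3 * 10), 3, 10)
  P <- ewm_normalize(X)
  E <- ewm_entropy(P)
  perm <- sample(10)
  expect_equal(ewm_entropy(P[, perm]), E)
  # duplicating every pixel (mass split evenly over 2n) leaves weights
  # unchanged even though entropies rescale with k = 1/ln(n)
  P2 <- cbind(P / 2, P / 2)
  w1 <- ewm_weights(E)$w
  # weights from duplicated matrix: compare through the pipeline formula
  w2 <- ewm_weights(ewm_entropy(P2))$w
  expect_equal(w2, w1, tolerance = 1e-9)
})

test_that("concentrating mass never increases entropy", {
  # mean-preserving spread: move mass eps from a small entry to a large one
  set.seed(8)
  for (i in 1:20) {
    p <- as.vector(ewm_normalize(matrix(rexp(12), 1)))
    lo <- which.min(p); hi <- which.max(p)
    eps <- p[lo] * 0.5
    q <- p; q[lo] <- q[lo] - eps; q[hi] <- q[hi] + eps
    expect_lte(ewm_entropy(matrix(q, 1)), ewm_entropy(matrix(p, 1)) + 1e-12)
  }
})

test_that("input assembly applies the union retention rule and |r| signal", {
  r1 <- matrix(c(0.8, NA, -0.6, 0.1), 2, 2)
  p1 <- matrix(c(0.001, NA, 0.01, 0.9), 2, 2)
  r2 <- matrix(c(0.2, 0.7, 0.3, 0.2), 2, 2)
  p2 <- matrix(c(0.5, 0.001, 0.6, 0.7), 2, 2)
  maps <- list(a = fake_cmap(r1, p1), b = fake_cmap(r2, p2))
  mask <- matrix(TRUE, 2, 2)
  inp <- ewm_build_inputs(maps, mask)
  # union: pixels 1 (a sig), 2 (b sig), 3 (a sig); pixel 4 nowhere significant
  expect_equal(inp$pixels, c(1L, 2L, 3L))
  expect_equal(inp$X["a", ], c(0.8, 0, 0.6))      # |r| where significant
  expect_equal(inp$X["b", ], c(0, 0.7, 0))
  expect_equal(inp$direction["a", ], c(1L, 0L, -1L))
  # intersection keeps only pixels significant in every variable
  int <- ewm_build_inputs(maps, mask, retention = "intersection")
  expect_length(int$pixels, 0L)
  expect_equal(int$status, "empty-domain")
  # one variable significant at one pixel with r = -0.6 -> single 0.6 entry
  # only the significant pixel enters the union domain: X is the single 0.6
  lone <- ewm_build_inputs(list(a = fake_cmap(matrix(c(-0.6, 0.1), 1),
                                              matrix(c(0.01, 0.8), 1))),
                           matrix(TRUE, 1, 2))
  expect_equal(as.vector(lone$X), 0.6)
  expect_equal(as.vector(lone$direction), -1L)
  # phase disagreement rejected
  expect_error(ewm_build_inputs(list(fake_cmap(r1, p1),
                                     fake_cmap(r2, p2, phase = "lanina")),
                                mask), "phase")
})

test_that("exposure index is the weighted scaled signal in [0, 1]", {
  expect_equal(exposure_index(c(0.25, 0.75), matrix(c(0.4, 0.8), 2, 1)), 0.7)
  # w = (1, 0) recovers the first variable's scaled signal
  Xs <- rbind(c(0.1, 0.9, 0.3), c(0.5, 0.2, 0.8))
  expect_equal(exposure_index(c(1, 0), Xs), Xs[1, ])
  # constant signal c gives exposure c
  expect_equal(exposure_index(c(0.3, 0.7), matrix(0.4, 2, 5)), rep(0.4, 5))
  expect_error(exposure_index(c(0.5, 0.6), Xs), "sum to 1")
  expect_error(exposure_index(c(1, 0), Xs * 2), "\\[0, 1\\]")
})

test_that("the EWM pipeline favours spatially patchy variables", {
  # one patchy variable among five uniform ones takes the largest weight
  n <- 40
  mk <- function(r, p) fake_cmap(matrix(r, 1), matrix(p, 1))
  uni_r <- rep(0.5, n); uni_p <- rep(0.001, n)
  patchy_r <- c(rep(0.9, 4), rep(0.05, n - 4))
  patchy_p <- c(rep(1e-4, 4), rep(0.5, n - 4))
  maps <- c(lapply(1:5, function(i) mk(uni_r, uni_p)),
            list(mk(patchy_r, patchy_p)))
  names(maps) <- c(paste0("u", 1:5), "patchy")
  res <- ewm_pipeline(maps, matrix(TRUE, 1, n))
  expect_equal(res$status, "ok")
  expect_equal(names(which.max(res$w)), "patchy")
  # oracle recomputation of the whole chain
  P <- ewm_normalize(res$inputs$X)
  E <- -1 / log(ncol(P)) * rowSums(ifelse(P > 0, P * log(P), 0))
  w <- (1 - E) / sum(1 - E)
  expect_equal(unname(res$w), unname(w), tolerance = 1e-12)
  # exposure bounded in [0, 1] over the domain
  expect_true(all(res$exposure[!is.na(res$exposure)] >= 0 &
                  res$exposure[!is.na(res$exposure)] <= 1))
})

test_that("degenerate EWM domains are reported, not crashed", {
  r <- matrix(0.1, 1, 5); p <- matrix(0.9, 1, 5)     # nothing significant
  res <- ewm_pipeline(list(a = fake_cmap(r, p)), matrix(TRUE, 1, 5))
  expect_equal(res$status, "empty-domain")
  expect_true(all(is.na(res$exposure)))
  # a single-pixel domain is rejected (k = 1/ln(n) needs n >= 2)
  r1 <- matrix(c(0.9, 0.1), 1); p1 <- matrix(c(0.001, 0.9), 1)
  expect_error(ewm_pipeline(list(a = fake_cmap(r1, p1)), matrix(TRUE, 1, 2)),
               "at least 2")
})
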