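# The second-difference CSD operator, its exact inverse, and the
# template/nCSD/modulation statistics built on it.

test_that("csd_params validates step, conductivity and spacing", {
  p <- csd_params()
  expect_equal(p$k, 2L)
  expect_error(csd_params(h = 0.15), "integer multiple")
  expect_error(csd_params(sigma = 0), "sigma")
  expect_error(csd_params(spacing = -1), "spacing")
})

test_that("compute_csd annihilates constant and affine depth profiles", {
  # dyadic coefficients and integer depth index: exact floating-point zero
  i <- seq_len(24)
  phi_const <- matrix(2.5, 24, 5)
  phi_affine <- matrix(rep(2 + 3 * i, 4), 24)
  for (phi in list(phi_const, phi_affine)) {
    v <- compute_csd(phi)$values
    expect_identical(unique(as.numeric(v[!is.na(v)])), 0)
  }
  # generic (non-dyadic) affine profile in physical units
  x <- (i - 1) * 0.1
  v <- compute_csd(matrix(rep(0.3 + 1.7 * x, 3), 24))$values
  expect_lt(max(abs(v), na.rm = TRUE), 1e-12)
})

test_that("quadratic potential gives the closed-form CSD exactly", {
  # phi(x) = x^2 (mV, x in mm): second difference is exact for quadratics,
  # CSD = -sigma * 2 = -0.8 at every valid channel
  x <- (0:23) * 0.1
  csd <- compute_csd(matrix(rep(x^2, 3), 24), csd_params(h = 0.2, sigma = 0.4))
  vals <- csd$values[csd$valid, ]
  expect_equal(unique(round(as.numeric(vals), 12)), -0.8)
  expect_true(all(abs(vals + 0.8) < 1e-12))
})

test_that("compute_csd is linear and masks channels near the probe ends", {
  set.seed(42)
  a <- matrix(rnorm(24 * 10), 24)
  b <- matrix(rnorm(24 * 10), 24)
  va <- compute_csd(a)$values
  vb <- compute_csd(b)$values
  vab <- compute_csd(2 * a - 3 * b)$values
  expect_equal(vab, 2 * va - 3 * vb, tolerance = 1e-12)
  csd <- compute_csd(a)
  expect_equal(which(!csd$valid), c(1L, 2L, 23L, 24L))
  expect_true(all(is.na(csd$values[!csd$valid, ])))
  expect_error(compute_csd(a[1:4, ]), "at least 5 channels")
})

test_that("lfp_from_csd -> compute_csd roundtrips exactly at interior channels", {
  set.seed(7)
  for (rep in 1:20) {
    C <- matrix(rnorm(24 * 50), 24)
    p <- csd_params()
    rt <- compute_csd(lfp_from_csd(C, p), p)
    err <- max(abs(rt$values[rt$valid, ] - C[rt$valid, ])) / max(abs(C))
    expect_lt(err, 1e-10)
  }
  # also with the single-channel step
  p1 <- csd_params(h = 0.1)
  C <- matrix(rnorm(24 * 5), 24)
  rt <- compute_csd(lfp_from_csd(C, p1), p1)
  expect_lt(max(abs(rt$values[rt$valid, ] - C[rt$valid, ])), 1e-10)
})

test_that("lfp_from_csd zero/linearity properties and input checks", {
  z <- lfp_from_csd(matrix(0, 24, 6))
  expect_identical(unique(as.numeric(z)), 0)
  C <- matrix(rnorm(24 * 6), 24)
  expect_equal(lfp_from_csd(2 * C), 2 * lfp_from_csd(C), tolerance = 1e-12)
  expect_error(lfp_from_csd(matrix(Inf, 24, 2)), "finite")
})

test_that("make_template averages the window and normalizes to the strongest sink", {
  time <- seq(0, 90, by = 10)
  # single sink of -5 at channel 10, constant in time
  v <- matrix(0, 16, length(time))
  v[10, ] <- -5
  tpl <- make_template(v, time, window = c(0, 90))
  expect_equal(tpl$weights[10], -1)
  expect_equal(tpl$weights[-10], rep(0, 15))
  # generic profile: template = window mean / |min(window mean)|
  set.seed(3)
  v2 <- matrix(rnorm(16 * length(time)), 16)
  pbar <- rowMeans(v2[, time >= 20 & time <= 70])
  tpl2 <- make_template(v2, time, window = c(20, 70))
  expect_equal(tpl2$weights, pbar / abs(min(pbar)))
  expect_equal(max(abs(tpl2$weights)), 1)
  expect_error(make_template(matrix(0, 16, 10), seq(0, 90, by = 10),
                             window = c(0, 90)),
               "all zero")
})

test_that("ncsd_timecourse equals the per-time inner product", {
  set.seed(9)
  csd <- matrix(rnorm(5 * 7), 5)
  w <- rnorm(5)
  brute <- vapply(1:7, function(j) sum(w * csd[, j]), numeric(1))
  expect_equal(ncsd_timecourse(csd, w), brute)
  # orthogonal template -> all-zero time course
  csd0 <- matrix(c(1, -1, 0, 0, 0), 5, 4)
  w_orth <- c(1, 1, 0, 0, 0)
  expect_equal(ncsd_timecourse(csd0, w_orth), rep(0, 4))
  # column equal to template -> sum of squared weights
  csd1 <- matrix(w, 5, 3)
  expect_equal(ncsd_timecourse(csd1, w), rep(sum(w^2), 3))
  expect_error(ncsd_timecourse(csd, c(w, 1)), "do not match")
})

test_that("abs_csd_modulation averages per-channel absolute differences", {
  time <- 0:9 * 100
  a <- matrix(rnorm(10 * 10), 10)
  expect_equal(abs_csd_modulation(a, a, time, c(0, 900)), 0)
  # +d on half the channels, -d on the other half: no cancellation
  d <- 0.37
  b <- a + rep(c(d, -d), each = 5)
  expect_equal(abs_csd_modulation(b, a, time, c(0, 900)), d)
  expect_error(abs_csd_modulation(a, a[1:5, ], time, c(0, 900)), "shape")
})

test_that("normalize_csd scales by the reference stimulus-period maximum", {
  time <- seq(-50, 300, by = 10)
  set.seed(5)
  v <- matrix(rnorm(12 * length(time)), 12)
  ref <- 4 * v
  out <- normalize_csd(v, ref, time, window = c(0, 150))
  m <- max(abs(ref[, time >= 0 & time <= 150]))
  expect_equal(out, v / m, ignore_attr = TRUE)
})
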