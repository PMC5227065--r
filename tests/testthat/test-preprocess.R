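# MUA envelope extraction, LFP conditioning, SNR-based channel QC and
# bad-channel interpolation.

test_that("mua_envelope demodulates an amplitude-modulated carrier", {
  fs <- 24400
  t <- seq(0, 1, by = 1 / fs)
  modulator <- abs(sin(2 * pi * 5 * t))
  wb <- sin(2 * pi * 1000 * t) * modulator
  env <- mua_envelope(wb, fs)
  expect_equal(attr(env, "fs"), 763)
  mod_rs <- approx(t, modulator, xout = (seq_along(env) - 1) / 763)$y
  expect_gt(cor(env, mod_rs), 0.95)
})

test_that("mua_envelope is nonnegative, zero on zero, linear in scale", {
  fs <- 24400
  t <- seq(0, 0.5, by = 1 / fs)
  expect_true(all(mua_envelope(numeric(length(t)), fs) == 0))
  wb <- sin(2 * pi * 900 * t) * (1 + 0.5 * sin(2 * pi * 3 * t))
  env <- mua_envelope(wb, fs)
  expect_true(all(env >= 0))
  expect_equal(mua_envelope(3 * wb, fs), 3 * env, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("mua_envelope rejects sub-passband tones and too-low rates", {
  fs <- 24400
  t <- seq(0, 0.5, by = 1 / fs)
  tone <- sin(2 * pi * 100 * t)   # below the 500 Hz corner
  env <- mua_envelope(tone, fs)
  expect_lt(max(env), 0.02)
  expect_error(mua_envelope(tone, fs_wb = 8000), "too low")
})

test_that("condition_lfp passes DC, attenuates the stopband, resamples to 763 Hz", {
  dc <- condition_lfp(rep(2, 4000), 2000)
  expect_equal(attr(dc, "fs"), 763)
  expect_true(all(abs(dc - 2) < 0.01))
  t <- seq(0, 1, by = 1 / 2000)
  tone <- sin(2 * pi * 300 * t)
  out <- condition_lfp(tone, 2000)
  # forward-backward 4th-order filter: strong squared-magnitude attenuation
  expect_lt(max(abs(out[100:600])), 0.1)
  expect_gt(max(abs(out[100:600])), 0.001)
  expect_equal(length(out), length(seq(0, 1, by = 1 / 763)))
  # preamp hook defaults to identity but is honoured
  out2 <- condition_lfp(tone, 2000, preamp_correction = function(x) 2 * x)
  expect_equal(out2, 2 * out, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("compute_snr matches the peak-over-baseline-SD construction", {
  time <- seq(-200, 400, by = 4)
  n_tr <- 8; n_ch <- 3
  set.seed(14)
  mua <- array(0, c(n_tr, n_ch, length(time)))
  s <- 0.05
  for (tr in 1:n_tr) for (ch in 1:n_ch)
    mua[tr, ch, ] <- rnorm(length(time), mean = 1, sd = s * sqrt(n_tr))
  # channel 1: injected evoked peak of amplitude A; channels 2-3 flat
  A <- 0.9
  peak_shape <- exp(-((time - 70)^2) / (2 * 8^2))
  for (tr in 1:n_tr) mua[tr, 1, ] <- mua[tr, 1, ] + A * peak_shape
  qc <- compute_snr(mua, time)
  base_sd <- sd(colMeans(mua[, 1, time >= -150 & time <= 0]))
  expect_equal(qc$snr[1], A / base_sd, tolerance = 0.15)
  expect_false(qc$excluded[1])
  expect_lt(qc$snr[2], 3)           # flat channel: excluded at the 3 cutoff
  expect_true(all(qc$excluded[2:3]))
  expect_error(compute_snr(mua[1, , , drop = FALSE], time), "2 trials")
  mua0 <- mua; mua0[, 2, ] <- 1
  expect_error(compute_snr(mua0, time), "zero pre-stimulus variance")
})

test_that("interpolate_bad_channels is the identity without exclusions and idempotent", {
  set.seed(2)
  lfp <- matrix(rnorm(10 * 40), 10)
  none <- rep(FALSE, 10)
  expect_identical(interpolate_bad_channels(lfp, none), lfp)
  excl <- none; excl[c(4, 9)] <- TRUE
  out <- interpolate_bad_channels(lfp, excl)
  expect_equal(out[4, ], (lfp[3, ] + lfp[5, ]) / 2)
  expect_equal(out[9, ], (lfp[8, ] + lfp[10, ]) / 2)
  expect_identical(interpolate_bad_channels(out, excl), out)
  # edge channel: nearest-neighbour extension
  excl1 <- none; excl1[1] <- TRUE
  expect_equal(interpolate_bad_channels(lfp, excl1)[1, ], lfp[2, ])
  # non-adjacent good neighbours: inverse-distance weights
  excl2 <- none; excl2[4:5] <- TRUE
  out2 <- interpolate_bad_channels(lfp, excl2)
  expect_equal(out2[4, ], (2 * lfp[3, ] + lfp[6, ]) / 3)
  expect_equal(out2[5, ], (lfp[3, ] + 2 * lfp[6, ]) / 3)
})

test_that("interpolate_bad_channels refuses degenerate exclusion patterns", {
  lfp <- matrix(rnorm(10 * 5), 10)
  excl <- rep(FALSE, 10); excl[1:2] <- TRUE
  expect_error(interpolate_bad_channels(lfp, excl), "edge channels")
  excl2 <- rep(c(TRUE, FALSE), 5)
  expect_error(interpolate_bad_channels(lfp, excl2), "50%")
  # works on trial x channel x time arrays too
  arr <- array(rnorm(2 * 10 * 5), c(2, 10, 5))
  excl3 <- rep(FALSE, 10); excl3[6] <- TRUE
  out <- interpolate_bad_channels(arr, excl3)
  expect_equal(out[, 6, ], (arr[, 5, ] + arr[, 7, ]) / 2)
})
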