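# Response normalization, latency fitting, modulation profiles, band
# power and RF geometry.

test_that("analysis_windows validates window order", {
  w <- analysis_windows()
  expect_equal(w$modulation, c(200, 750))
  expect_equal(w$baseline, c(-150, 0))
  expect_error(analysis_windows(peak = c(90, 50)), "peak")
})

make_norm_fixture <- function(n_tr = 12, seed = 31) {
  set.seed(seed)
  time <- seq(-200, 400, by = 4)
  n_ch <- 4
  shape <- 0.5 + exp(-((time - 70)^2) / (2 * 10^2))
  mua <- array(rnorm(n_tr * n_ch * length(time), sd = 0.01),
               c(n_tr, n_ch, length(time)))
  for (tr in seq_len(n_tr)) for (ch in seq_len(n_ch))
    mua[tr, ch, ] <- mua[tr, ch, ] + shape * ch
  trials <- data.frame(condition = rep(c("target_rf", "distractor_rf"),
                                       length.out = n_tr))
  list(mua = mua, time = time, trials = trials)
}

test_that("normalize_mua subtracts baseline and scales the reference peak to 1", {
  f <- make_norm_fixture()
  norm <- normalize_mua(f$mua, f$time, f$trials)
  ref <- f$trials$condition == "distractor_rf"
  ref_avg <- colMeans(norm$mua[ref, , , drop = FALSE], dims = 1)
  pk <- f$time >= 50 & f$time <= 90
  for (ch in 1:4) expect_equal(max(ref_avg[ch, pk]), 1, tolerance = 1e-9)
  # response identically at baseline level -> normalized to ~0
  base_cols <- f$time >= -150 & f$time <= 0
  expect_lt(max(abs(colMeans(norm$mua[, , base_cols], dims = 1))), 0.02)
})

test_that("normalize_mua is shift-invariant and scale-equivariant", {
  f <- make_norm_fixture()
  n0 <- normalize_mua(f$mua, f$time, f$trials)
  n_shift <- normalize_mua(f$mua + 5, f$time, f$trials)
  expect_equal(n_shift$mua, n0$mua, tolerance = 1e-9)
  n_scale <- normalize_mua(f$mua * 3, f$time, f$trials)
  expect_equal(n_scale$mua, n0$mua, tolerance = 1e-9)
  expect_error(normalize_mua(f$mua, f$time,
                             data.frame(condition = rep("x", 12))),
               "not present")
  # a channel with no evoked response in the reference gets flagged
  f2 <- make_norm_fixture()
  f2$mua[, 2, ] <- 0.5
  expect_warning(norm2 <- normalize_mua(f2$mua, f2$time, f2$trials),
                 "flagged")
  expect_true(norm2$flagged[2])
  expect_true(all(is.na(norm2$mua[, 2, ])))
})

test_that("fit_latency matches the cumulative-Gaussian closed form", {
  tt <- seq(-50, 200, by = 1000 / 763)
  y <- 2 * pnorm((tt - 60) / 5)
  f <- fit_latency(y, tt)
  expect_lt(abs(f$latency - (60 + 5 * qnorm(0.33))), 1000 / 763)
  expect_lt(f$rss, 1e-6)
})

test_that("fit_latency is invariant to offset and preserves simulator ordering", {
  tt <- seq(-50, 250, by = 1000 / 763)
  y <- 1.5 * pnorm((tt - 80) / 8) + 0.8 * exp(-((tt - 90)^2) / (2 * 12^2))
  f0 <- fit_latency(y, tt)
  f1 <- fit_latency(y + 3, tt)
  expect_equal(f0$latency, f1$latency, tolerance = 0.2)
  expect_error(fit_latency(rep(1, 100), seq_len(100)), "no rise")
  # layered session: fitted latencies preserve the ground-truth ordering
  q <- quick_session(n_trials = 30L, seed = 12L)
  avg <- colMeans(q$ses$recording$mua, dims = 1)
  lats <- vapply(c(layer4 = 10L, deep = 4L, superficial = 17L),
                 function(ch) fit_latency(avg[ch, ], q$cfg$time_mua)$latency,
                 numeric(1))
  expect_lt(lats["layer4"], lats["deep"])
  expect_lt(lats["deep"], lats["superficial"])
})

test_that("modulation_profile is zero for identical conditions and validates input", {
  f <- make_norm_fixture()
  al <- alignment_result(2L, 4L)
  norm <- normalize_mua(f$mua, f$time, f$trials)
  # same condition twice -> exact zeros
  prof <- modulation_profile(norm$mua, f$time, f$trials,
                             conditions = c("target_rf", "target_rf"),
                             window = c(100, 300), alignment = al)
  expect_equal(prof$per_channel$modulation, rep(0, 4))
  expect_error(modulation_profile(norm$mua, f$time, f$trials,
                                  conditions = c("target_rf", "missing"),
                                  window = c(100, 300), alignment = al),
               "not present")
})

test_that("band_power separates tones, is additive, and scales with bandwidth", {
  fs <- 763
  t <- seq(0, 1, by = 1 / fs)
  tone50 <- sin(2 * pi * 50 * t)
  expect_gt(band_power(tone50, fs, c(30, 90)),
            1e4 * band_power(tone50, fs, c(5, 15)))
  # a unit tone carries its variance (0.5) into its band, and power adds
  # over disjoint bands for a deterministic two-tone signal
  expect_equal(band_power(tone50, fs, c(30, 90)), 0.5, tolerance = 0.05)
  two <- sin(2 * pi * 10 * t) + sin(2 * pi * 60 * t)
  expect_equal(band_power(two, fs, c(5, 15)) + band_power(two, fs, c(30, 90)),
               band_power(two, fs, c(5, 90)), tolerance = 0.02)
  # white noise: power proportional to bandwidth (equal-width bands agree)
  set.seed(6)
  wn <- matrix(rnorm(300 * length(t)), 300)
  b1 <- mean(band_power(wn, fs, c(30, 90)))
  b2 <- mean(band_power(wn, fs, c(120, 180)))
  expect_lt(abs(b1 / b2 - 1), 0.1)
  # double-width band has double power
  b3 <- mean(band_power(wn, fs, c(30, 150)))
  expect_lt(abs(b3 / (2 * b1) - 1), 0.1)
  expect_error(band_power(tone50, fs, c(300, 500)), "Nyquist")
})

make_sweeps <- function(width = 1.4, height = 1.4, center = c(3, 1),
                        latency = 0) {
  # boxcar RF: response 1 while the bar centre is inside the RF box
  lapply((0:7) * 45, function(ang) {
    u <- c(cos(ang * pi / 180), sin(ang * pi / 180))
    v <- 2 * u                        # 2 deg/s sweep
    p0 <- center - 6 * u              # start 6 deg before the RF centre
    time <- seq(0, 6, by = 0.002)
    pos <- outer(time, v) + matrix(p0, length(time), 2, byrow = TRUE)
    inside <- abs(pos[, 1] - center[1]) <= width / 2 &
      abs(pos[, 2] - center[2]) <= height / 2
    resp <- rep(0, length(time))
    resp[inside] <- 1
    if (latency > 0) {
      k <- round(latency / 0.002)
      resp <- c(rep(0, k), resp)[seq_along(resp)]
    }
    list(response = resp, time = time, angle = ang, pos0 = p0, velocity = v)
  })
}

test_that("rf_from_bar recovers a boxcar RF exactly without latency", {
  rf <- rf_from_bar(make_sweeps())
  expect_equal(rf$width, 1.4, tolerance = 0.02)
  expect_equal(rf$height, 1.4, tolerance = 0.02)
  expect_equal(rf$center, c(3, 1), tolerance = 0.02)
  expect_equal(rf$eccentricity, sqrt(10), tolerance = 0.02)
})

test_that("equal latency in opposing sweeps cancels in the RF centre", {
  rf0 <- rf_from_bar(make_sweeps())
  rf1 <- rf_from_bar(make_sweeps(latency = 0.25))
  expect_equal(rf1$center, rf0$center, tolerance = 0.02)
  expect_error(rf_from_bar(make_sweeps()[1:6]), "missing sweep")
})
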