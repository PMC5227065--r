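# The synthetic laminar-column generator: presets, schedules,
# determinism, and the statistical structure of simulated sessions.

test_that("presets encode the laminar modulation structure", {
  cfg <- quick_config()
  gt_att <- make_ground_truth(cfg, "attention_like")
  m <- gt_att$modulation_amplitude
  expect_gt(m["superficial"], m["layer4"])
  expect_gt(m["deep"], m["layer4"])
  cfg_mem <- quick_config(task = "memory")
  gt_mem <- make_ground_truth(cfg_mem, "memory_like")
  expect_true(all(gt_mem$modulation_amplitude <
                    gt_att$modulation_amplitude))
  expect_true(all(gt_mem$modulation_amplitude >= 0))
  gt_null <- make_ground_truth(cfg_mem, "null")
  expect_true(all(gt_null$modulation_amplitude == 0))
  expect_true(all(gt_null$modulation_by_channel == 0))
})

test_that("unknown presets and inconsistent schedules are rejected", {
  cfg <- quick_config()
  expect_error(make_ground_truth(cfg, "bogus"), "valid presets are")
  expect_error(make_ground_truth(cfg, "memory_like"), "requires task")
  expect_error(sim_config("memory", t_end = 100), "inconsistent")
  expect_error(sim_config("attention", conditions = "nope"), "unknown condition")
  s <- sim_config("mask")$schedule
  expect_equal(s$stim_off, 150)
  expect_equal(s$mask_off - s$mask_on, 50)
  expect_equal(s$mask_on, 400)
})

test_that("latencies are earliest in layers 4C and 6", {
  cfg <- quick_config()
  gt <- make_ground_truth(cfg, "attention_like")
  l4 <- gt$layer_latencies[gt$compartment == "layer4"]
  l6 <- gt$layer_latencies[gt$rel_depth < -0.55]
  others <- gt$layer_latencies[gt$compartment %in% c("deep", "superficial")]
  expect_true(all(l4 < min(others)))
  expect_true(all(l6 < min(others)))
  expect_true(all(others - min(l4) >= 5 & others - min(l4) <= 15))
})

test_that("identical ground truth, config and seed give identical sessions", {
  q1 <- quick_session(n_trials = 3L, signals = "mua", seed = 21L)
  q2 <- quick_session(n_trials = 3L, signals = "mua", seed = 21L)
  expect_identical(q1$ses, q2$ses)
  q3 <- simulate_session(q1$gt, q1$cfg, signals = "mua", seed = 22L)
  expect_false(identical(q1$ses$recording$mua, q3$recording$mua))
})

test_that("null preset gives no target/distractor difference at any channel", {
  q <- quick_session(preset = "null", task = "memory", n_trials = 100L,
                     seed = 5L)
  cfg <- q$cfg
  cols <- win_between <- which(cfg$time_mua >= 200 & cfg$time_mua <= 750)
  mua <- q$ses$recording$mua
  tgt <- q$ses$trials$condition == "target_rf"
  tstats <- vapply(seq_len(cfg$n_channels), function(ch) {
    a <- rowMeans(mua[tgt, ch, cols])
    b <- rowMeans(mua[!tgt, ch, cols])
    (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
  }, numeric(1))
  expect_lt(max(abs(tstats)), 4)
})

test_that("adjacent-curve conditions give only a weak, delayed transient", {
  q <- quick_session(n_trials = 20L, seed = 8L,
                     conditions = c("target_rf", "distractor_rf",
                                    "target_adj", "distractor_adj"))
  cfg <- q$cfg
  mua <- q$ses$recording$mua
  avg <- function(cond) colMeans(mua[q$ses$trials$condition == cond, , ,
                                     drop = FALSE], dims = 1)
  rf <- avg("distractor_rf"); adj <- avg("target_adj")
  base_cols <- which(cfg$time_mua < 0)
  evoked <- function(m) max(colMeans(m)) - mean(m[, base_cols])
  expect_lt(evoked(adj), 0.35 * evoked(rf))
  # delayed: adjacent peak later than RF peak
  expect_gt(cfg$time_mua[which.max(colMeans(adj))],
            cfg$time_mua[which.max(colMeans(rf))])
  # no sustained modulation between adjacent conditions
  cols <- which(cfg$time_mua >= 200 & cfg$time_mua <= 750)
  d <- mean(avg("target_adj")[, cols]) - mean(avg("distractor_adj")[, cols])
  expect_lt(abs(d), 0.02)
})

test_that("the forward-modelled LFP embeds the true CSD recoverable by the operator", {
  q <- quick_session(n_trials = 2L, signals = "lfp", seed = 3L)
  gt <- q$gt
  # noiseless profile roundtrip, all conditions
  for (cnd in dimnames(gt$csd_profile)[[3]]) {
    rt <- compute_csd(gt$lfp_profile[, , cnd], gt$params)
    expect_lt(max(abs(rt$values[rt$valid, ] - gt$csd_profile[rt$valid, , cnd])),
              1e-9)
  }
})

test_that("mask-task ground truth nulls and restores the modulation window", {
  cfg <- quick_config(task = "mask")
  gt <- make_ground_truth(cfg, "mask_like")
  tmua <- cfg$time_mua
  diff_tc <- gt$mua_profile[15, , "target_rf"] -
    gt$mua_profile[15, , "distractor_rf"]
  expect_true(all(diff_tc[tmua >= 450 & tmua <= 550] == 0))
  m <- gt$modulation_by_channel[15]
  expect_true(all(abs(diff_tc[tmua >= 650 & tmua <= 750] - m) < 1e-12))
  expect_true(all(abs(diff_tc[tmua >= 200 & tmua <= 400] - m) < 1e-12))
})
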