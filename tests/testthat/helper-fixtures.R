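# Shared fixtures: small, fast simulation configurations.  All fixtures
# are built in code at test time.

quick_config <- function(task = "attention", n_trials = 10L, fs = 250,
                         seed = 1L,
                         conditions = c("target_rf", "distractor_rf")) {
  sim_config(task = task, n_trials_per_condition = n_trials,
             fs_lfp = fs, fs_mua = fs, conditions = conditions, seed = seed)
}

quick_session <- function(preset = "attention_like", task = "attention",
                          n_trials = 10L, seed = 1L, signals = "mua",
                          conditions = c("target_rf", "distractor_rf")) {
  cfg <- quick_config(task = task, n_trials = n_trials, seed = seed,
                      conditions = conditions)
  gt <- make_ground_truth(cfg, preset)
  list(cfg = cfg, gt = gt,
       ses = simulate_session(gt, cfg, signals = signals))
}

# A fixation trace with a constant-velocity excursion whose central-
# difference speed exceeds the 5 x SD threshold on exactly `n_above`
# samples: a ramp of (n_above + 1) equal position increments produces
# n_above full-height interior speed samples flanked by two half-height
# edges, and the half-height edges stay below 5 x SD of the whole trace.
trace_with_excursion <- function(n = 300, n_above = 6, seed = 1,
                                 noise_sd = 0.005, step = 0.2) {
  set.seed(seed)
  x <- rnorm(n, sd = noise_sd)
  y <- rnorm(n, sd = noise_sd)
  i0 <- 150
  m <- n_above + 1
  ramp <- c(seq_len(m) * step, rep(m * step, n - i0 - m))
  x[(i0 + 1):n] <- x[(i0 + 1):n] + ramp
  list(x = x, y = y)
}
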