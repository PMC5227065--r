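#' Simulation configuration for a synthetic laminar-column session
#'
#' Encodes the geometry, sampling rates and per-task epoch schedule of a
#' simulated penetration.  Defaults follow the recorded preparation: a
#' 24-contact probe with 0.1 mm spacing, LFP and MUA envelope on a 763 Hz
#' time base, eye traces at 250 Hz, about 100 trials per condition, and the
#' task timelines: in the attention task the stimulus stays on until the
#' cue at 750 ms; in the memory-type tasks it disappears at 150 ms; in the
#' mask and capacity tasks a 50 ms mask appears 400 ms after stimulus onset
#' (250 ms after offset); in the capacity task the identity cue arrives
#' only at 700 ms and the trial runs to 1200 ms.
#'
#' @param task One of `"attention"`, `"memory"`, `"mask"`, `"capacity"`.
#' @param n_channels Number of probe contacts (24).
#' @param spacing_mm Contact spacing in mm (0.1).
#' @param fs_lfp,fs_mua,fs_eye Sampling rates in Hz (763, 763, 250).
#' @param n_trials_per_condition Trials per condition (default 100).
#' @param conditions Condition labels; the receptive field holds the target
#'   curve, the distractor curve, or lies next to one of them.
#' @param t_start Recording start in ms relative to stimulus onset.
#' @param t_end Optional override of the task's default trial end (ms).
#' @param seed Integer RNG seed for [simulate_session()].
#' @return `lam_sim_config` list with the schedule attached.
#' @export
sim_config <- function(task = c("attention", "memory", "mask", "capacity"),
                       n_channels = 24L, spacing_mm = 0.1,
                       fs_lfp = 763, fs_mua = 763, fs_eye = 250,
                       n_trials_per_condition = 100L,
                       conditions = c("target_rf", "distractor_rf",
                                      "target_adj", "distractor_adj"),
                       t_start = -200, t_end = NULL, seed = 1L) {
  task <- match.arg(task)
  if (spacing_mm <= 0) stop("`spacing_mm` must be > 0")
  if (any(c(fs_lfp, fs_mua, fs_eye) <= 0)) stop("sampling rates must be > 0")
  if (n_trials_per_condition < 1) stop("`n_trials_per_condition` must be >= 1")
  known <- c("target_rf", "distractor_rf", "target_adj", "distractor_adj")
  if (!all(conditions %in% known))
    stop("unknown condition(s): ", paste(setdiff(conditions, known), collapse = ", "))
  schedule <- switch(task,
    attention = list(stim_on = 0, stim_off = 750, mask_on = NA_real_,
                     mask_off = NA_real_, cue = 750, t_end = 750),
    memory    = list(stim_on = 0, stim_off = 150, mask_on = NA_real_,
                     mask_off = NA_real_, cue = 750, t_end = 750),
    mask      = list(stim_on = 0, stim_off = 150, mask_on = 400,
                     mask_off = 450, cue = 750, t_end = 750),
    capacity  = list(stim_on = 0, stim_off = 150, mask_on = 400,
                     mask_off = 450, cue = 700, t_end = 1200))
  if (!is.null(t_end)) {
    if (t_end <= max(0, schedule$cue, schedule$mask_off, na.rm = TRUE))
      stop("`t_end` is inconsistent with the task schedule")
    schedule$t_end <- t_end
  }
  if (t_start >= schedule$stim_on) stop("`t_start` must precede stimulus onset")
  cfg <- list(task = task, n_channels = as.integer(n_channels),
              spacing_mm = spacing_mm, fs_lfp = fs_lfp, fs_mua = fs_mua,
              fs_eye = fs_eye,
              n_trials_per_condition = as.integer(n_trials_per_condition),
              conditions = conditions, t_start = t_start,
              schedule = schedule, seed = as.integer(seed))
  cfg$time_lfp <- seq(t_start, schedule$t_end, by = 1000 / fs_lfp)
  cfg$time_mua <- seq(t_start, schedule$t_end, by = 1000 / fs_mua)
  cfg$time_eye <- seq(t_start, schedule$t_end, by = 1000 / fs_eye)
  structure(cfg, class = "lam_sim_config")
}

# Temporal modulation window w(t) in [0, 1] for the target-minus-distractor
# effect, per task.  Attention/memory: ramps on after the feedforward
# response and is fully established when the 200-750 ms analysis window
# opens, so the configured amplitude is the window-mean sustained gain.
# Mask: abolished during the mask response (exactly zero over 450-550 ms)
# and restored by 650 ms.  Capacity: present only after the late cue,
# full over 900-1150 ms.
modulation_window <- function(t, task) {
  up <- ramp01(t, 170, 200)
  switch(task,
    attention = up,
    memory    = up,
    mask      = up * (1 - ramp01(t, 410, 445)) + ramp01(t, 600, 645),
    capacity  = ramp01(t, 855, 895),
    stop("unknown task: ", task))
}

known_presets <- c("attention_like", "memory_like", "mask_like",
                   "capacity_like", "null")

preset_modulation <- function(preset) {
  switch(preset,
    attention_like = c(superficial = 0.30, layer4 = 0.10, deep = 0.30),
    memory_like    = c(superficial = 0.15, layer4 = 0.05, deep = 0.15),
    mask_like      = c(superficial = 0.15, layer4 = 0.05, deep = 0.15),
    capacity_like  = c(superficial = 0.15, layer4 = 0.05, deep = 0.15),
    null           = c(superficial = 0, layer4 = 0, deep = 0))
}

preset_task <- function(preset) {
  switch(preset,
    attention_like = "attention", memory_like = "memory",
    mask_like = "mask", capacity_like = "capacity", null = "memory")
}

#' Ground truth for a simulated laminar column
#'
#' Builds the deterministic structure a simulated session is drawn from:
#' per-channel response latencies (earliest in layers 4C and 6, the
#' superficial and deep layers 5-15 ms later), per-compartment sustained
#' modulation amplitudes (fractions of the peak response; stronger in the
#' superficial and deep compartments than in layer 4, and weaker for the
#' memory-type presets than for attention), the true CSD profile per
#' condition (an early layer-4C sink with deep sources, later sustained
#' sinks, and a modulation pattern with sinks in the superficial layers and
#' layer 5), and the noiseless LFP profiles obtained by inverting the CSD
#' operator.
#'
#' @param config A [sim_config()].
#' @param preset One of `"attention_like"`, `"memory_like"`, `"mask_like"`,
#'   `"capacity_like"`, `"null"`.  The `"null"` preset has zero modulation
#'   everywhere.
#' @param boundary_channel True index of the channel just below the 4C/5
#'   boundary (default 8, the "eighth contact from the tip" placement).
#' @param noise_sd List of additive noise SDs: `lfp` (LFP units), `mua`
#'   (units of the peak response) and `eye` (degrees).
#' @param params [csd_params()] used both to forward-model the LFP and by
#'   downstream CSD analysis.
#' @param modulation Optional named vector overriding the preset's
#'   per-compartment modulation amplitudes.
#' @param off_gain Amplitude of the stimulus off-response in the
#'   memory-type tasks (fraction of peak; not constrained by data, exposed
#'   as a free parameter).
#' @return `lam_ground_truth`.
#' @export
make_ground_truth <- function(config, preset,
                              boundary_channel = 8L,
                              noise_sd = list(lfp = 0.02, mua = 0.1, eye = 0.05),
                              params = csd_params(),
                              modulation = NULL,
                              off_gain = 0.3) {
  if (!inherits(config, "lam_sim_config")) stop("`config` must be a sim_config()")
  if (!is.character(preset) || length(preset) != 1L || !preset %in% known_presets)
    stop("unknown preset; valid presets are: ",
         paste(known_presets, collapse = ", "))
  if (preset != "null" && preset_task(preset) != config$task)
    stop(sprintf("preset '%s' requires task '%s' (config has '%s')",
                 preset, preset_task(preset), config$task))
  n <- config$n_channels
  b <- as.integer(boundary_channel)
  if (b < 2L || b > n - 2L) stop("`boundary_channel` must lie within the probe")
  stopifnot(all(unlist(noise_sd) >= 0))
  mod_amp <- modulation %||% preset_modulation(preset)
  stopifnot(all(mod_amp >= 0),
            all(c("superficial", "layer4", "deep") %in% names(mod_amp)))

  align <- alignment_result(b, n, config$spacing_mm)
  comp <- align$compartment
  rel <- align$rel_depth

  # Latencies (ms): layer 4C and layer 6 earliest, then deep, then
  # superficial; unassigned above the superficial band latest.
  lat <- rep(48, n)
  lat[comp == "layer4"] <- 35
  lat[comp == "unassigned" & rel < -0.55] <- 35   # layer 6, below the deep band
  lat[comp == "deep"] <- 42
  lat[comp == "superficial"] <- 45

  # Per-channel modulation amplitude: compartment value, nearest assigned
  # channel's value for unassigned channels.
  m_ch <- numeric(n)
  assigned <- which(comp != "unassigned")
  for (i in seq_len(n)) {
    j <- if (comp[i] == "unassigned") assigned[which.min(abs(assigned - i))] else i
    m_ch[i] <- unname(mod_amp[comp[j]])
  }

  t_mua <- config$time_mua
  t_lfp <- config$time_lfp
  sched <- config$schedule
  task <- config$task
  w_mua <- modulation_window(t_mua, task)
  w_lfp <- modulation_window(t_lfp, task)

  # --- MUA rate profiles -------------------------------------------------
  sustain_shape <- function(t) {
    s <- 0.35 * ramp01(t, 60, 120)
    if (sched$stim_off < sched$t_end) {   # stimulus disappears: decay + floor
      decay <- pmin(1, exp(-(pmax(t - (sched$stim_off + 60), 0)) / 250))
      s <- pmax(0.35 * ramp01(t, 60, 120) * decay, 0.08 * ramp01(t, 60, 120))
    }
    s
  }
  off_resp <- if (sched$stim_off < sched$t_end)
    off_gain * gauss_bump(t_mua, sched$stim_off + 60, 15) else 0
  mask_resp <- if (is.finite(sched$mask_on))
    1.1 * gauss_bump(t_mua, sched$mask_on + 50, 18) else 0

  conds <- c("target_rf", "distractor_rf", "target_adj", "distractor_adj")
  mua_profile <- array(0, c(n, length(t_mua), length(conds)),
                       dimnames = list(NULL, NULL, conds))
  peak_cols <- win_idx(t_mua, c(50, 90))
  baseline_rate <- 0.2
  for (i in seq_len(n)) {
    transient <- gauss_bump(t_mua, lat[i] + 15, 12)
    drive <- transient + sustain_shape(t_mua) + off_resp + mask_resp
    drive <- drive / max(drive[peak_cols])     # peak response == 1 by design
    adj <- 0.2 * gauss_bump(t_mua, lat[i] + 35, 14)
    mua_profile[i, , "distractor_rf"] <- baseline_rate + drive
    mua_profile[i, , "target_rf"] <- baseline_rate + drive + m_ch[i] * w_mua
    mua_profile[i, , "target_adj"] <- baseline_rate + adj
    mua_profile[i, , "distractor_adj"] <- baseline_rate + adj
  }

  # --- CSD profiles ------------------------------------------------------
  gch <- function(c0, w) gauss_bump(seq_len(n), c0, w)
  # early feedforward: layer-4C sink above the boundary, deep source below
  E1 <- -1.0 * gch(b + 3, 1.5) + 0.9 * gch(b - 2.5, 1.8)
  p1 <- gauss_bump(t_lfp, 42, 9)
  # sustained stimulus-driven pattern: sinks straddling superficial/upper
  # layer 4 and in the deep layers, with compensating sources
  E2 <- -0.5 * gch(b + 6.5, 2.2) - 0.4 * gch(b - 2.5, 1.6) +
    0.45 * gch(b + 2, 1.2) + 0.3 * gch(b - 5.5, 1.5)
  p2 <- ramp01(t_lfp, 80, 140) * (sustain_shape(t_lfp) / 0.35)
  # top-down modulation: sinks in the superficial layers and layer 5
  M <- -0.8 * gch(b + 9, 2.0) - 0.7 * gch(b - 1.5, 1.2) +
    0.5 * gch(b + 4.5, 1.5) + 0.3 * gch(b - 4.5, 1.5)
  g_mod <- 2 * mean(mod_amp)

  evoked <- outer(E1, p1) + outer(E2, p2)
  evoked_adj <- 0.2 * outer(E1, gauss_bump(t_lfp, 62, 9))
  csd_profile <- array(0, c(n, length(t_lfp), length(conds)),
                       dimnames = list(NULL, NULL, conds))
  csd_profile[, , "distractor_rf"] <- evoked
  csd_profile[, , "target_rf"] <- evoked + g_mod * outer(M, w_lfp)
  csd_profile[, , "target_adj"] <- evoked_adj
  csd_profile[, , "distractor_adj"] <- evoked_adj

  lfp_profile <- array(0, dim(csd_profile), dimnames = dimnames(csd_profile))
  for (cnd in conds)
    lfp_profile[, , cnd] <- lfp_from_csd(csd_profile[, , cnd], params)

  structure(list(preset = preset, task = task,
                 boundary_channel = b,
                 rel_depth = rel, compartment = comp,
                 layer_latencies = lat,
                 modulation_amplitude = mod_amp,
                 modulation_by_channel = m_ch,
                 csd_profile = csd_profile,
                 lfp_profile = lfp_profile,
                 mua_profile = mua_profile,
                 noise_sd = noise_sd,
                 params = params,
                 off_gain = off_gain,
                 seed = config$seed,
                 time_lfp = t_lfp, time_mua = t_mua),
            class = "lam_ground_truth")
}

#' Forward-model an LFP depth profile from a known CSD
#'
#' Exact discrete inverse of [compute_csd()]: returns potentials `phi`
#' such that applying the three-point second-difference CSD operator with
#' the same conductivity and step recovers the input CSD exactly at
#' interior channels.  For a step of `k` channels the second difference
#' couples `k` independent channel chains; integration constants are fixed
#' by assigning `boundary_values[1]` to the deepest `k` channels and
#' `boundary_values[2]` to the next `k` (both default 0).  The operator is
#' linear, so zero CSD with zero boundary values gives an identically zero
#' (affine-in-depth) potential.
#'
#' @param csd_true Channel x time matrix of true CSD values (negative =
#'   sink), or a vector treated as one time point.
#' @param params [csd_params()]; must match the parameters used downstream
#'   for an exact roundtrip.
#' @param boundary_values Length-2 numeric: potentials anchoring the two
#'   integration constants per chain.
#' @return Channel x time matrix of potentials.
#' @export
lfp_from_csd <- function(csd_true, params = csd_params(),
                         boundary_values = c(0, 0)) {
  if (is.vector(csd_true)) csd_true <- matrix(csd_true, ncol = 1)
  if (!all(is.finite(csd_true))) stop("`csd_true` must be finite")
  stopifnot(length(boundary_values) == 2L)
  k <- params$k
  n <- nrow(csd_true)
  if (n < 2L * k + 1L) stop("too few channels for the requested step")
  step <- params$h^2 / params$sigma
  phi <- matrix(0, n, ncol(csd_true))
  phi[seq_len(k), ] <- boundary_values[1]
  phi[k + seq_len(k), ] <- boundary_values[2]
  for (p in (k + 1L):(n - k)) {
    # CSD(p) = -sigma*(phi[p+k] - 2 phi[p] + phi[p-k])/h^2  =>  solve for phi[p+k]
    phi[p + k, ] <- 2 * phi[p, ] - phi[p - k, ] - csd_true[p, ] * step
  }
  phi
}

#' Simulate one session (penetration) from a ground truth
#'
#' Draws a trial-structured recording from the deterministic profiles in
#' `gt`: LFP = forward-modelled potential + white Gaussian noise
#' (independent across channels), MUA = rate envelope + Gaussian noise
#' truncated at zero, eye traces = fixational jitter around a small
#' constant bias towards the lower-left.  Identical `(gt, config)` produce
#' byte-identical output (the RNG is seeded from `config$seed`).
#'
#' @param gt A [make_ground_truth()] result built from the same `config`.
#' @param config The [sim_config()] used to build `gt`.
#' @param signals Which signals to generate (subset of
#'   `c("lfp", "mua", "eye")`); skipping unused signals speeds up large
#'   simulation studies.
#' @param penetration_id Identifier stored with the recording.
#' @param seed Optional RNG seed overriding `config$seed`, so one ground
#'   truth/config pair can generate many independent penetrations.
#' @return List with `recording` (class `lam_recording`) and `trials`
#'   (data frame: trial, task, condition, correct).
#' @export
simulate_session <- function(gt, config, signals = c("lfp", "mua", "eye"),
                             penetration_id = "pen01", seed = NULL) {
  if (!inherits(gt, "lam_ground_truth")) stop("`gt` must be a ground truth object")
  if (!inherits(config, "lam_sim_config")) stop("`config` must be a sim_config()")
  if (!identical(gt$task, config$task) ||
      !identical(length(gt$time_mua), length(config$time_mua)) ||
      !identical(length(gt$time_lfp), length(config$time_lfp)))
    stop("`gt` was built from a different, inconsistent config/schedule")
  signals <- match.arg(signals, several.ok = TRUE)
  seed <- as.integer(seed %||% config$seed)
  set.seed(seed)
  conds <- config$conditions
  n_tr <- length(conds) * config$n_trials_per_condition
  condition <- sample(rep(conds, each = config$n_trials_per_condition))
  correct <- runif(n_tr) < 0.95
  n <- config$n_channels

  rec <- list(fs_lfp = config$fs_lfp, fs_mua = config$fs_mua,
              time_lfp = config$time_lfp, time_mua = config$time_mua,
              channel_depths = (seq_len(n) - 1L) * config$spacing_mm,
              penetration_id = penetration_id,
              task = config$task, schedule = config$schedule,
              seed = seed)

  if ("lfp" %in% signals) {
    Tn <- length(config$time_lfp)
    lfp <- array(0, c(n_tr, n, Tn))
    noise <- array(rnorm(n_tr * n * Tn, sd = gt$noise_sd$lfp), c(n_tr, n, Tn))
    for (tr in seq_len(n_tr))
      lfp[tr, , ] <- gt$lfp_profile[, , condition[tr]] + noise[tr, , ]
    rec$lfp <- lfp
  }
  if ("mua" %in% signals) {
    Tn <- length(config$time_mua)
    mua <- array(0, c(n_tr, n, Tn))
    noise <- array(rnorm(n_tr * n * Tn, sd = gt$noise_sd$mua), c(n_tr, n, Tn))
    for (tr in seq_len(n_tr))
      mua[tr, , ] <- pmax(gt$mua_profile[, , condition[tr]] + noise[tr, , ], 0)
    rec$mua <- mua
  }
  if ("eye" %in% signals) {
    Te <- length(config$time_eye)
    rec$eye <- list(
      x = matrix(rnorm(n_tr * Te, mean = -0.02, sd = gt$noise_sd$eye), n_tr, Te),
      y = matrix(rnorm(n_tr * Te, mean = -0.02, sd = gt$noise_sd$eye), n_tr, Te),
      fs = config$fs_eye, time = config$time_eye)
  }
  class(rec) <- "lam_recording"
  trials <- data.frame(trial = seq_len(n_tr), task = config$task,
                       condition = condition, correct = correct,
                       stringsAsFactors = FALSE)
  list(recording = rec, trials = trials)
}

#' @export
print.lam_recording <- function(x, ...) {
  sig <- intersect(c("lfp", "mua", "eye"), names(x))
  cat(sprintf("<lam_recording> %s task, penetration %s; signals: %s\n",
              x$task, x$penetration_id, paste(sig, collapse = ", ")))
  if (!is.null(x$lfp))
    cat(sprintf("  lfp: %d trials x %d channels x %d samples @ %g Hz\n",
                dim(x$lfp)[1], dim(x$lfp)[2], dim(x$lfp)[3], x$fs_lfp))
  if (!is.null(x$mua))
    cat(sprintf("  mua: %d trials x %d channels x %d samples @ %g Hz\n",
                dim(x$mua)[1], dim(x$mua)[2], dim(x$mua)[3], x$fs_mua))
  invisible(x)
}
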