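# Simulation experiments that validate the pipeline against its own
# ground truth: boundary recovery, modulation parameter recovery, type-I
# error calibration under the null preset, decoder validation against the
# Gaussian closed form, and the mask-task scenario.  These run the real
# simulate -> analyse path at reduced problem sizes chosen for desk-scale
# runtimes (sizes are arguments, defaults documented in the vignette).

# A small, fast session configuration used by the Monte-Carlo studies:
# 250 Hz envelope/LFP time base and a handful of trials per condition.
calib_config <- function(task = "memory", n_trials = 4L, fs = 250,
                         seed = 1L,
                         conditions = c("target_rf", "distractor_rf"),
                         t_end = NULL) {
  sim_config(task = task, n_trials_per_condition = n_trials,
             fs_lfp = fs, fs_mua = fs, conditions = conditions,
             t_end = t_end, seed = seed)
}

#' Boundary-recovery experiment
#'
#' Simulates full-field-response sessions with known 4C/5 boundary
#' channels, runs [compute_csd()] + [find_reversal()] on the
#' trial-averaged LFP and reports how often the recovered boundary lies
#' within +/- 1 channel of the truth.
#'
#' @param n_sessions Number of sessions (default 50).
#' @param boundary_range Range the true boundary is drawn from.
#' @param seed RNG seed.
#' @param n_trials Trials per condition per session.
#' @return List: `recovery_rate`, `errors` (recovered minus true),
#'   `boundaries`.
#' @export
boundary_recovery_experiment <- function(n_sessions = 50L,
                                         boundary_range = c(6L, 18L),
                                         seed = 1L, n_trials = 10L) {
  set.seed(seed)
  truth <- sample(boundary_range[1]:boundary_range[2], n_sessions,
                  replace = TRUE)
  errors <- integer(n_sessions)
  for (s in seq_len(n_sessions)) {
    cfg <- calib_config(task = "attention", n_trials = n_trials,
                        seed = seed + s,
                        conditions = c("target_rf", "distractor_rf"))
    gt <- make_ground_truth(cfg, "attention_like",
                            boundary_channel = truth[s])
    ses <- simulate_session(gt, cfg, signals = "lfp")
    avg <- apply(ses$recording$lfp, c(2, 3), mean)
    rev <- find_reversal(compute_csd(avg, gt$params), cfg$time_lfp)
    errors[s] <- rev$boundary_channel - truth[s]
  }
  list(recovery_rate = mean(abs(errors) <= 1), errors = errors,
       boundaries = truth)
}

#' Modulation parameter-recovery experiment
#'
#' Simulates penetrations with known per-compartment modulation
#' amplitudes, runs the normalization + modulation-profile path and
#' compares recovered compartment means with the truth; also runs the
#' compartment ANOVA with post-hoc tests.
#'
#' @param n_penetrations Number of penetrations (default 24).
#' @param modulation Named true amplitudes (fractions of peak).
#' @param seed RNG seed.
#' @param n_trials Trials per condition (default 60; the recorded
#'   sessions used blocks of about 100).
#' @param fs Envelope sampling rate for the experiment.
#' @return List: `recovered` (per-penetration matrix), `means`, `se`,
#'   `truth`, `anova`, `within_3se`.
#' @export
modulation_recovery_experiment <- function(n_penetrations = 24L,
                                           modulation = c(superficial = 0.30,
                                                          layer4 = 0.10,
                                                          deep = 0.30),
                                           seed = 1L, n_trials = 60L,
                                           fs = 250) {
  comp <- matrix(NA_real_, n_penetrations, 3,
                 dimnames = list(NULL, c("deep", "layer4", "superficial")))
  cfg <- calib_config(task = "attention", n_trials = n_trials, fs = fs,
                      seed = seed)
  gt <- make_ground_truth(cfg, "attention_like", modulation = modulation)
  align <- alignment_result(gt$boundary_channel, cfg$n_channels)
  for (i in seq_len(n_penetrations)) {
    ses <- simulate_session(gt, cfg, signals = "mua", seed = seed + i)
    norm <- normalize_mua(ses$recording$mua, cfg$time_mua, ses$trials)
    prof <- modulation_profile(norm$mua, cfg$time_mua, ses$trials,
                               alignment = align)
    comp[i, ] <- prof$compartment_means
  }
  means <- colMeans(comp)
  se <- apply(comp, 2, sd) / sqrt(n_penetrations)
  truth <- modulation[colnames(comp)]
  list(recovered = comp, means = means, se = se, truth = truth,
       anova = compartment_anova(comp),
       within_3se = abs(means - truth) <= 3 * se)
}

#' Type-I error calibration of the penetration-level tests
#'
#' Under the `null` preset (zero modulation everywhere), repeatedly
#' simulates sets of penetrations through the simulate -> normalize ->
#' profile path and applies the paired signed-rank test (target vs
#' distractor penetration means) and the compartment RM-ANOVA, reporting
#' the empirical rejection rates at `alpha`.
#'
#' @param n_sims Number of Monte-Carlo simulations (default 1000).
#' @param n_penetrations Penetrations per simulation (default 24).
#' @param alpha Nominal level (default 0.05).
#' @param seed RNG seed.
#' @param n_trials Trials per condition per penetration.
#' @return List: `paired_rate`, `anova_rate`, their Monte-Carlo standard
#'   errors and the per-simulation p-values.
#' @export
null_type1_experiment <- function(n_sims = 1000L, n_penetrations = 24L,
                                  alpha = 0.05, seed = 1L, n_trials = 4L) {
  p_paired <- numeric(n_sims)
  p_anova <- numeric(n_sims)
  cfg <- calib_config(n_trials = n_trials, seed = seed)
  gt <- make_ground_truth(cfg, "null")
  align <- alignment_result(gt$boundary_channel, cfg$n_channels)
  base <- 0L
  for (s in seq_len(n_sims)) {
    tgt <- dst <- numeric(n_penetrations)
    comp <- matrix(NA_real_, n_penetrations, 3,
                   dimnames = list(NULL, c("deep", "layer4", "superficial")))
    for (i in seq_len(n_penetrations)) {
      ses <- simulate_session(gt, cfg, signals = "mua", seed = seed + base + i)
      norm <- normalize_mua(ses$recording$mua, cfg$time_mua, ses$trials)
      prof <- modulation_profile(norm$mua, cfg$time_mua, ses$trials,
                                 alignment = align)
      comp[i, ] <- prof$compartment_means
      cols <- win_idx(cfg$time_mua, c(200, 750))
      tgt[i] <- mean(norm$mua[ses$trials$condition == "target_rf", , cols])
      dst[i] <- mean(norm$mua[ses$trials$condition == "distractor_rf", , cols])
    }
    base <- base + n_penetrations
    p_paired[s] <- paired_test(tgt, dst)$p.value
    p_anova[s] <- compartment_anova(comp, posthoc = FALSE)$p.value
  }
  mc_se <- sqrt(alpha * (1 - alpha) / n_sims)
  list(paired_rate = mean(p_paired < alpha),
       anova_rate = mean(p_anova < alpha),
       mc_se = mc_se, alpha = alpha,
       p_paired = p_paired, p_anova = p_anova)
}

#' Family-wise error calibration of the cluster permutation test
#'
#' Under the `null` preset, simulates per-penetration CSD difference maps
#' (target minus distractor, pure noise), runs
#' [cluster_permutation()] and reports the empirical family-wise error:
#' the fraction of simulations with any cluster p-value at or below
#' `alpha`.
#'
#' @param n_sims Simulations (default 1000).
#' @param n_penetrations Penetrations per simulation (default 12).
#' @param n_perm Sign-flip permutations per test (default 199).
#' @param n_time_bins Difference maps are averaged down to this many time
#'   bins before clustering.
#' @param alpha Nominal level.
#' @param seed RNG seed.
#' @param n_trials Trials per condition per penetration.
#' @return List: `fwer`, `mc_se`, per-simulation minimum p-values.
#' @export
cluster_fwer_experiment <- function(n_sims = 1000L, n_penetrations = 12L,
                                    n_perm = 199L, n_time_bins = 24L,
                                    alpha = 0.05, seed = 1L, n_trials = 4L) {
  min_p <- numeric(n_sims)
  cfg <- calib_config(n_trials = n_trials, seed = seed)
  gt <- make_ground_truth(cfg, "null")
  base <- 0L
  for (s in seq_len(n_sims)) {
    maps <- vector("list", n_penetrations)
    for (i in seq_len(n_penetrations)) {
      ses <- simulate_session(gt, cfg, signals = "lfp", seed = seed + base + i)
      csds <- condition_csds(ses$recording, ses$trials,
                             c("target_rf", "distractor_rf"),
                             params = gt$params)
      d <- csds$target_rf$values - csds$distractor_rf$values
      d <- d[csds$target_rf$valid, , drop = FALSE]
      maps[[i]] <- bin_columns(d, n_time_bins)
    }
    base <- base + n_penetrations
    res <- cluster_permutation(maps, n_perm = n_perm, seed = seed + s)
    min_p[s] <- if (nrow(res$clusters)) min(res$clusters$p.value) else 1
  }
  list(fwer = mean(min_p <= alpha),
       mc_se = sqrt(alpha * (1 - alpha) / n_sims),
       alpha = alpha, min_p = min_p)
}

# Average matrix columns down to nb bins.
bin_columns <- function(x, nb) {
  n <- ncol(x)
  nb <- min(nb, n)
  grp <- cut(seq_len(n), nb, labels = FALSE)
  out <- matrix(0, nrow(x), nb)
  for (b in seq_len(nb)) out[, b] <- rowMeans(x[, grp == b, drop = FALSE])
  out
}

#' Shuffle-control calibration of the profile-consistency analysis
#'
#' Simulates penetrations with a consistent laminar modulation profile,
#' verifies that the within-task consistency is high, and that the
#' channel-shuffle control destroys it (mean r compatible with 0).
#'
#' @param n_penetrations Penetrations (default 8).
#' @param n_shuffle Shuffle replicates (the total shuffled correlations
#'   are `n_shuffle * N(N-1)/2`).
#' @param seed RNG seed.
#' @param n_trials Trials per condition.
#' @return List: `consistent` (unshuffled result), `shuffled` result,
#'   `shuffle_within_2se`.
#' @export
shuffle_control_experiment <- function(n_penetrations = 8L, n_shuffle = 36L,
                                       seed = 1L, n_trials = 20L) {
  profs <- NULL
  cfg <- calib_config(task = "attention", n_trials = n_trials, seed = seed)
  gt <- make_ground_truth(cfg, "attention_like")
  align <- alignment_result(gt$boundary_channel, cfg$n_channels)
  for (i in seq_len(n_penetrations)) {
    ses <- simulate_session(gt, cfg, signals = "mua", seed = seed + i)
    norm <- normalize_mua(ses$recording$mua, cfg$time_mua, ses$trials)
    prof <- modulation_profile(norm$mua, cfg$time_mua, ses$trials,
                               alignment = align)
    profs <- cbind(profs, prof$per_channel$modulation)
  }
  consistent <- profile_consistency(profs)
  shuffled <- profile_consistency(profs, shuffle = TRUE,
                                  n_shuffle = n_shuffle, seed = seed)
  se <- sd(shuffled$r) / sqrt(length(shuffled$r))
  list(consistent = consistent, shuffled = shuffled,
       shuffle_se = se,
       shuffle_within_2se = abs(shuffled$mean_r) <= 2 * se)
}

#' Decoder validation against the Gaussian closed form
#'
#' Two multivariate Gaussian classes with equal identity covariance and
#' Mahalanobis separation d' have an optimal ROC area of Phi(d'/sqrt(2));
#' this experiment checks the cross-validated SVM/ROC accuracy against
#' that closed form, and against chance for permuted labels.
#'
#' @param dprimes Separations to test.
#' @param n_trials Trials per experiment (split evenly).
#' @param n_dims Feature dimensionality (24 recording sites).
#' @param seed RNG seed.
#' @return Data frame: dprime, expected, observed accuracy; plus the
#'   permuted-label accuracy as attribute `"chance"`.
#' @export
decoder_validation <- function(dprimes = c(0, 1, 2), n_trials = 1000L,
                               n_dims = 24L, seed = 1L) {
  set.seed(seed)
  out <- data.frame(dprime = dprimes, expected = pnorm(dprimes / sqrt(2)),
                    observed = NA_real_)
  chance <- NA_real_
  for (j in seq_along(dprimes)) {
    d <- dprimes[j]
    n2 <- n_trials %/% 2
    delta <- rep(d / sqrt(n_dims), n_dims)   # |delta| = d under identity cov
    xa <- matrix(rnorm(n2 * n_dims), n2)
    xb <- matrix(rnorm(n2 * n_dims), n2, byrow = FALSE) +
      matrix(delta, n2, n_dims, byrow = TRUE)
    x <- rbind(xa, xb)
    labels <- factor(rep(c("distractor", "target"), each = n2))
    out$observed[j] <- decode_session(x, labels,
                                      seed = seed + j)$mean_accuracy
    if (d == max(dprimes)) {
      perm <- sample(labels)
      chance <- decode_session(x, perm, seed = seed + 100L)$mean_accuracy
    }
  }
  attr(out, "chance") <- chance
  out
}

#' Mask-task scenario: modulation abolished, then restored
#'
#' Simulates mask-task penetrations (50 ms mask 400 ms after stimulus
#' onset), where the true modulation is zero during the mask response and
#' restored afterwards, and tests the modulation during 450-550 ms
#' (expected non-significant) and 650-750 ms (expected significant).
#'
#' @param n_penetrations Penetrations (default 12).
#' @param seed RNG seed.
#' @param n_trials Trials per condition.
#' @return List: `p_during`, `p_after`, per-penetration means.
#' @export
mask_scenario_experiment <- function(n_penetrations = 12L, seed = 1L,
                                     n_trials = 30L) {
  w <- analysis_windows()
  during <- matrix(NA_real_, n_penetrations, 2)
  after <- matrix(NA_real_, n_penetrations, 2)
  cfg <- calib_config(task = "mask", n_trials = n_trials, seed = seed)
  gt <- make_ground_truth(cfg, "mask_like")
  for (i in seq_len(n_penetrations)) {
    ses <- simulate_session(gt, cfg, signals = "mua", seed = seed + i)
    norm <- normalize_mua(ses$recording$mua, cfg$time_mua, ses$trials)
    for (win in c("mask_during", "mask_after")) {
      cols <- win_idx(cfg$time_mua, w[[win]])
      m <- vapply(c("target_rf", "distractor_rf"), function(cc)
        mean(norm$mua[ses$trials$condition == cc, , cols]), numeric(1))
      if (win == "mask_during") during[i, ] <- m else after[i, ] <- m
    }
  }
  list(p_during = paired_test(during[, 1], during[, 2])$p.value,
       p_after = paired_test(after[, 1], after[, 2])$p.value,
       during = during, after = after)
}
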