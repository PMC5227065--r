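# Microsaccade screening of 250 Hz eye traces and condition-balance
# checks on eye position.

#' Detect microsaccades in an eye trace
#'
#' Eye speed is the magnitude of the central-difference velocity of the
#' (x, y) position (one-sided at the ends, no smoothing).  A microsaccade
#' is a run of at least `min_samples` consecutive samples whose speed
#' exceeds `threshold_mult` times the speed SD; by default the SD is
#' computed over the whole trial (pass `sd_samples` to restrict it to a
#' fixation epoch).  Trials with at least one event are flagged for
#' exclusion.
#'
#' @param x,y Position traces in degrees (equal length, >= 20 samples).
#' @param fs Sampling rate in Hz (default 250).
#' @param threshold_mult Speed threshold in SD units (default 5).
#' @param min_samples Minimum run length (default 5).
#' @param sd_samples Optional index vector over which the speed SD is
#'   estimated (default: all samples).
#' @return `lam_saccades`: `events` data frame (start, end, peak_speed),
#'   `excluded` flag, `threshold` (deg/s), `speed` trace.
#' @export
detect_microsaccades <- function(x, y, fs = 250, threshold_mult = 5,
                                 min_samples = 5L, sd_samples = NULL) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  n <- length(x)
  if (n < 20) stop("need at least 20 samples")
  vx <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) * fs
  vy <- c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1]) * fs
  speed <- sqrt(vx^2 + vy^2)
  sd_idx <- sd_samples %||% seq_len(n)
  s <- sd(speed[sd_idx])
  events <- data.frame(start = integer(0), end = integer(0),
                       peak_speed = numeric(0))
  if (s == 0) {
    warning("zero speed variance; no events detectable")
  } else {
    thr <- threshold_mult * s
    above <- speed > thr
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values & r$lengths >= min_samples
    if (any(keep)) {
      events <- data.frame(
        start = starts[keep], end = ends[keep],
        peak_speed = mapply(function(a, b) max(speed[a:b]),
                            starts[keep], ends[keep]))
    }
  }
  structure(list(events = events, excluded = nrow(events) > 0,
                 threshold = if (s > 0) threshold_mult * s else NA_real_,
                 speed = speed, fs = fs),
            class = "lam_saccades")
}

#' Screen all trials of a session for microsaccades
#'
#' @param eye Eye component of a `lam_recording` (`x`, `y` trial x sample
#'   matrices, `fs`).
#' @param ... Passed to [detect_microsaccades()].
#' @return Logical vector: trial excluded.
#' @export
screen_trials <- function(eye, ...) {
  vapply(seq_len(nrow(eye$x)), function(tr)
    detect_microsaccades(eye$x[tr, ], eye$y[tr, ], fs = eye$fs, ...)$excluded,
    logical(1))
}

#' Check that eye position is balanced across conditions
#'
#' Per condition, the mean and SD of the x and y eye position over the
#' analysis window; every condition pair is compared on each of the four
#' per-trial summaries with rank-sum tests, Bonferroni-corrected over all
#' comparisons.  A global fixation bias common to all conditions does not
#' produce between-condition differences.
#'
#' @param eye Eye component of a recording (`x`, `y`, `fs`, `time`).
#' @param trials Trial table with `condition`.
#' @param window Optional analysis window in ms.
#' @param alpha Flagging level (default 0.05).
#' @return List: `summary` (per-condition means/SDs), `tests` (pairwise
#'   p-values, Bonferroni-corrected), `balanced` (no corrected p below
#'   `alpha`).
#' @export
position_balance_check <- function(eye, trials, window = NULL, alpha = 0.05) {
  conds <- unique(trials$condition)
  if (length(conds) < 2) stop("need at least 2 conditions")
  cols <- if (!is.null(window)) win_idx(eye$time, window) else
    seq_len(ncol(eye$x))
  per_trial <- data.frame(
    condition = trials$condition,
    mean_x = rowMeans(eye$x[, cols, drop = FALSE]),
    mean_y = rowMeans(eye$y[, cols, drop = FALSE]),
    sd_x = apply(eye$x[, cols, drop = FALSE], 1, sd),
    sd_y = apply(eye$y[, cols, drop = FALSE], 1, sd))
  summ <- do.call(rbind, lapply(conds, function(cc) {
    s <- per_trial[per_trial$condition == cc, -1]
    data.frame(condition = cc, t(colMeans(s)))
  }))
  prs <- combn(length(conds), 2)
  measures <- c("mean_x", "mean_y", "sd_x", "sd_y")
  n_comp <- ncol(prs) * length(measures)
  tests <- do.call(rbind, lapply(seq_len(ncol(prs)), function(j) {
    a <- per_trial[per_trial$condition == conds[prs[1, j]], ]
    b <- per_trial[per_trial$condition == conds[prs[2, j]], ]
    do.call(rbind, lapply(measures, function(mm) {
      p <- wilcox.test(a[[mm]], b[[mm]])$p.value
      data.frame(a = conds[prs[1, j]], b = conds[prs[2, j]], measure = mm,
                 p.value = min(1, p * n_comp))
    }))
  }))
  list(summary = summ, tests = tests,
       balanced = all(tests$p.value >= alpha))
}
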