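#' Standard analysis windows
#'
#' The windows used throughout the laminar analysis, all in ms relative to
#' stimulus onset: spontaneous baseline (-150-0), evoked peak (50-90),
#' sustained modulation (200-750), during-mask (450-550), after-mask
#' (650-750) and the late capacity-task window (900-1150).
#'
#' @param baseline,peak,modulation,mask_during,mask_after,capacity_late
#'   Length-2 numeric windows (ms).
#' @return `lam_windows` list.
#' @export
analysis_windows <- function(baseline = c(-150, 0), peak = c(50, 90),
                             modulation = c(200, 750),
                             mask_during = c(450, 550),
                             mask_after = c(650, 750),
                             capacity_late = c(900, 1150)) {
  w <- list(baseline = baseline, peak = peak, modulation = modulation,
            mask_during = mask_during, mask_after = mask_after,
            capacity_late = capacity_late)
  for (nm in names(w)) {
    if (length(w[[nm]]) != 2L || w[[nm]][1] >= w[[nm]][2])
      stop("window `", nm, "` must be c(start, end) with start < end")
  }
  structure(w, class = "lam_windows")
}

#' Normalize MUA per recording site
#'
#' Per channel: subtract the spontaneous activity (mean over the baseline
#' window across all trials) and divide by the peak response of the site
#' in the reference (distractor) condition, i.e. the maximum of the
#' baseline-subtracted trial-averaged response in the 50-90 ms peak
#' window.  After normalization the reference condition's trial average
#' attains 1 at its peak sample.  Channels whose reference peak is not
#' positive are flagged and set to `NA`.
#'
#' @param mua Trial x channel x time array.
#' @param time Time base in ms.
#' @param trials Trial table with a `condition` column (row i = trial i).
#' @param windows [analysis_windows()].
#' @param reference_condition Condition supplying the peak (default
#'   `"distractor_rf"`).
#' @return List: `mua` (normalized array, `NA` on flagged channels),
#'   `baseline`, `peak` (per channel), `flagged` (logical).
#' @export
normalize_mua <- function(mua, time, trials, windows = analysis_windows(),
                          reference_condition = "distractor_rf") {
  stopifnot(length(dim(mua)) == 3L, dim(mua)[3] == length(time),
            nrow(trials) == dim(mua)[1])
  if (!reference_condition %in% trials$condition)
    stop("reference condition '", reference_condition, "' not present")
  base_cols <- win_idx(time, windows$baseline)
  peak_cols <- win_idx(time, windows$peak)
  n_tr <- dim(mua)[1]; n_ch <- dim(mua)[2]
  bm <- colMeans(mua[, , base_cols, drop = FALSE], dims = 1)  # ch x t
  baseline <- rowMeans(bm)
  ref <- trials$condition == reference_condition
  ref_avg <- colMeans(mua[ref, , , drop = FALSE], dims = 1)   # ch x t
  peak <- apply(ref_avg[, peak_cols, drop = FALSE] - baseline, 1, max)
  flagged <- peak <= 0
  if (any(flagged))
    warning(sum(flagged), " channel(s) flagged: nonpositive reference peak")
  denom <- ifelse(flagged, NA_real_, peak)
  # recycle per-channel constants over the trial x channel x time layout
  out <- (mua - rep(baseline, each = n_tr)) / rep(denom, each = n_tr)
  list(mua = out, baseline = baseline, peak = peak, flagged = flagged)
}

#' Visual response latency from a Gaussian + cumulative-Gaussian fit
#'
#' Fits the sum of a Gaussian and a cumulative Gaussian (plus offset) to a
#' trial-averaged response by bounded least squares and defines the
#' latency as the earliest time at which the fitted curve reaches 33% of
#' its maximum above the fitted offset.  Initialization: the
#' cumulative-Gaussian mean starts at the half-peak crossing of the raw
#' trace and the Gaussian mean at the raw peak.
#'
#' @param response Trial-averaged response (numeric vector).
#' @param time Time base in ms.
#' @param frac Criterion fraction of the maximum (default 0.33).
#' @return `lam_latency`: fitted `par`, `latency` (ms), `fitted` values
#'   and residual sum of squares `rss`.
#' @export
fit_latency <- function(response, time, frac = 0.33) {
  stopifnot(length(response) == length(time), length(response) > 10)
  y <- as.numeric(response)
  rng <- range(time)
  y0_init <- if (any(time < 0)) mean(y[time < 0]) else min(y)
  amp <- max(y) - y0_init
  if (amp <= 0) stop("response contains no rise above its initial level")
  peak_t <- time[which.max(y)]
  half_idx <- which(y >= y0_init + 0.5 * amp)[1]
  half_t <- time[max(half_idx, 1)]
  df <- data.frame(t = time, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ y0 + Ag * exp(-((t - mg)^2) / (2 * sg^2)) + Ac * pnorm((t - mc) / sc),
      data = df,
      start = list(y0 = y0_init, Ag = amp / 2, mg = peak_t, sg = 10,
                   Ac = amp / 2, mc = half_t, sc = 10),
      lower = c(y0 = -Inf, Ag = 0, mg = rng[1], sg = 0.5,
                Ac = 0, mc = rng[1], sc = 0.5),
      upper = c(y0 = Inf, Ag = 2 * amp, mg = rng[2], sg = diff(rng),
                Ac = 2 * amp, mc = rng[2], sc = diff(rng)),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("latency fit did not converge: ",
                             conditionMessage(e), call. = FALSE))
  p <- as.list(coef(fit))
  tt <- seq(rng[1], rng[2], by = 0.05)
  curve <- p$Ag * exp(-((tt - p$mg)^2) / (2 * p$sg^2)) +
    p$Ac * pnorm((tt - p$mc) / p$sc)
  ymax <- max(curve)
  if (ymax <= 0) stop("fitted curve has no positive excursion above offset")
  crit <- frac * ymax
  above <- which(curve >= crit)
  i <- above[1]
  latency <- if (i == 1) tt[1] else {
    # linear interpolation between the straddling fine-grid points
    tt[i - 1] + (crit - curve[i - 1]) / (curve[i] - curve[i - 1]) * 0.05
  }
  structure(list(par = p, latency = latency, frac = frac,
                 fitted = p$y0 + approx(tt, curve, xout = time)$y,
                 rss = sum(resid(fit)^2)),
            class = "lam_latency")
}

#' @export
print.lam_latency <- function(x, ...) {
  cat(sprintf("<lam_latency> %.2f ms (%.0f%% of fitted maximum; rss = %.3g)\n",
              x$latency, 100 * x$frac, x$rss))
  invisible(x)
}

#' Laminar modulation profile between two conditions
#'
#' Per-channel difference of window-averaged normalized MUA between a
#' condition pair (target minus distractor), with per-compartment means
#' attached via the penetration's alignment.
#'
#' @param norm_mua Normalized trial x channel x time array (from
#'   [normalize_mua()]).
#' @param time Time base in ms.
#' @param trials Trial table with `condition`.
#' @param conditions Length-2 character: `c(target, reference)`.
#' @param window Analysis window in ms (default the 200-750 ms modulation
#'   period).
#' @param alignment [alignment_result()] for the penetration.
#' @param penetration_id Stored with the result.
#' @return `lam_modprofile`: `per_channel` data frame (channel, rel_depth,
#'   compartment, modulation) and `compartment_means`.
#' @export
modulation_profile <- function(norm_mua, time, trials,
                               conditions = c("target_rf", "distractor_rf"),
                               window = c(200, 750), alignment,
                               penetration_id = NA_character_) {
  stopifnot(length(conditions) == 2L)
  missing_cond <- setdiff(conditions, unique(trials$condition))
  if (length(missing_cond))
    stop("condition(s) not present: ", paste(missing_cond, collapse = ", "))
  cols <- win_idx(time, window)
  chan_mean <- function(cond) {
    sel <- trials$condition == cond
    rowMeans(colMeans(norm_mua[sel, , cols, drop = FALSE], dims = 1))
  }
  d <- chan_mean(conditions[1]) - chan_mean(conditions[2])
  per_channel <- data.frame(channel = seq_along(d),
                            rel_depth = alignment$rel_depth,
                            compartment = alignment$compartment,
                            modulation = d,
                            stringsAsFactors = FALSE)
  comp <- c("deep", "layer4", "superficial")
  cm <- vapply(comp, function(cc)
    mean(d[alignment$compartment == cc], na.rm = TRUE), numeric(1))
  structure(list(per_channel = per_channel, compartment_means = cm,
                 window = window, conditions = conditions,
                 penetration_id = penetration_id),
            class = "lam_modprofile")
}

# Hann-window Welch PSD (density, units^2/Hz); standard 50%-overlap
# segment averaging built on stats::fft since no installed package
# provides a Welch estimator.
welch_psd <- function(x, fs, seg_len = min(length(x), 256L), overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  U <- sum(w^2)
  nf <- floor(seg_len / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- fft(seg)[seq_len(nf)]
    acc <- acc + (Mod(X)^2) / (fs * U)
  }
  psd <- acc / length(starts)
  # one-sided density: double everything except DC (and Nyquist if present)
  psd[-1] <- 2 * psd[-1]
  if (seg_len %% 2 == 0) psd[nf] <- psd[nf] / 2
  list(freq = (seq_len(nf) - 1L) * fs / seg_len, psd = psd)
}

#' Band power of the LFP per trial
#'
#' Mean spectral power in a frequency band, estimated by a Hann-window
#' Welch periodogram over the analysis window.  Standard bands: gamma
#' 30-90 Hz, alpha 5-15 Hz.
#'
#' @param lfp Trials x time matrix (one channel) or numeric vector.
#' @param fs Sampling rate in Hz.
#' @param band Length-2 frequency band in Hz; must lie below Nyquist.
#' @param time,window Optional time base (ms) and analysis window; when
#'   given, only samples inside the window enter the estimate.
#' @param seg_len Welch segment length in samples.
#' @return Numeric vector of band power (signal units^2), one per trial.
#' @export
band_power <- function(lfp, fs, band, time = NULL, window = NULL,
                       seg_len = 256L) {
  if (is.vector(lfp)) lfp <- matrix(lfp, nrow = 1)
  if (band[1] >= band[2] || band[2] > fs / 2)
    stop("`band` must be increasing and lie below the Nyquist frequency")
  if (!is.null(time) && !is.null(window)) {
    stopifnot(length(time) == ncol(lfp))
    lfp <- lfp[, win_idx(time, window), drop = FALSE]
  }
  apply(lfp, 1, function(x) {
    sp <- welch_psd(x, fs, seg_len = min(seg_len, length(x)))
    sel <- sp$freq >= band[1] & sp$freq <= band[2]
    df <- sp$freq[2] - sp$freq[1]
    sum(sp$psd[sel]) * df
  })
}

#' Receptive field geometry from moving-bar sweeps
#'
#' Maps response onset and offset times during slow bar sweeps in eight
#' movement directions to screen positions.  Each RF border is estimated
#' as the midpoint of the positions obtained from the two opposing sweep
#' directions, so a response latency that is equal in opposing directions
#' cancels.  The RF center is the least-squares point consistent with the
#' per-axis centers; width and height are the extents along the horizontal
#' and vertical sweep axes.
#'
#' @param sweeps List of 8 sweeps, each a list with `response` (numeric),
#'   `time` (s), `angle` (movement direction, degrees), `pos0` (bar
#'   position at time 0, length-2) and `velocity` (deg/s, length-2).
#' @param threshold Fraction of the peak (above baseline) defining
#'   response onset/offset (default 0.5).
#' @return List: `center` (x, y in deg), `width`, `height`,
#'   `extent_by_axis`, `eccentricity`.
#' @export
rf_from_bar <- function(sweeps, threshold = 0.5) {
  angs <- vapply(sweeps, function(s) s$angle %% 360, numeric(1))
  need <- (seq_len(8) - 1) * 45
  if (!all(need %in% round(angs)))
    stop("missing sweep direction(s): ",
         paste(setdiff(need, round(angs)), collapse = ", "), " deg")
  edge_times <- function(s) {
    y <- s$response
    base <- min(y)
    crit <- base + threshold * (max(y) - base)
    on <- which(y >= crit)
    if (!length(on)) stop("no response in sweep at ", s$angle, " deg")
    c(s$time[on[1]], s$time[on[length(on)]])
  }
  pos_at <- function(s, t) s$pos0 + s$velocity * t
  axes <- list()
  for (a in c(0, 45, 90, 135)) {
    f <- sweeps[[which(round(angs) == a)[1]]]
    r <- sweeps[[which(round(angs) == (a + 180) %% 360)[1]]]
    u <- f$velocity / sqrt(sum(f$velocity^2))
    tf <- edge_times(f); tr <- edge_times(r)
    # entry of the forward sweep and exit of the reverse sweep both
    # estimate the low border along u (latency shifts cancel at midpoint)
    low <- (sum(pos_at(f, tf[1]) * u) + sum(pos_at(r, tr[2]) * u)) / 2
    high <- (sum(pos_at(f, tf[2]) * u) + sum(pos_at(r, tr[1]) * u)) / 2
    axes[[as.character(a)]] <- list(u = u, low = low, high = high,
                                    center = (low + high) / 2,
                                    extent = high - low)
  }
  U <- do.call(rbind, lapply(axes, `[[`, "u"))
  cvec <- vapply(axes, `[[`, numeric(1), "center")
  center <- as.numeric(qr.solve(U, cvec))
  list(center = center,
       width = axes[["0"]]$extent,
       height = axes[["90"]]$extent,
       extent_by_axis = vapply(axes, `[[`, numeric(1), "extent"),
       eccentricity = sqrt(sum(center^2)))
}
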