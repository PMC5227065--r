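# Signal conditioning: wideband -> MUA envelope, raw -> analysis LFP,
# channel quality control.  All filters are zero-phase 4th-order
# Butterworth applied forward-backward (signal::filtfilt); the corner
# frequencies are fixed by the recording protocol, the design is a package
# choice that avoids latency bias in downstream latency fits.

# Zero-phase Butterworth with odd-reflection padding at both ends, which
# suppresses the start-up transients of plain forward-backward filtering.
butter_filtfilt <- function(x, fs, cutoff, type) {
  bf <- signal::butter(4, cutoff / (fs / 2), type = type)
  n <- length(x)
  # pad by a few periods of the lowest corner frequency
  np <- min(n - 1L, as.integer(ceiling(3 * fs / min(cutoff))))
  head_pad <- 2 * x[1] - x[(np + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - np)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(np + 1L):(np + n)]
}

resample_linear <- function(x, fs_in, fs_out) {
  n <- length(x)
  t_in <- (seq_len(n) - 1) / fs_in
  t_out <- seq(0, t_in[n], by = 1 / fs_out)
  approx(t_in, x, xout = t_out)$y
}

apply_rows <- function(x, f) {
  if (is.matrix(x)) t(apply(x, 1, f)) else f(x)
}

#' Multi-unit activity envelope from the wideband signal
#'
#' Band-pass filters the wideband extracellular signal (500 Hz - 5 kHz),
#' full-wave rectifies it and low-pass filters the result (200 Hz),
#' yielding a nonnegative envelope of aggregate spiking near the contact.
#' The envelope is resampled to `fs_out` (default 763 Hz, sharing the LFP
#' time base).  Zero-phase filtering keeps response latencies unbiased;
#' residual filter undershoot after rectification is clipped at zero.
#'
#' @param wideband Numeric vector, or channel x time matrix, of wideband
#'   signal (V).
#' @param fs_wb Wideband sampling rate in Hz; must exceed twice the 5 kHz
#'   corner.
#' @param fs_out Output sampling rate of the envelope (Hz).
#' @param band Pass band of the spiking-band filter (Hz).
#' @param lp_cutoff Envelope smoothing cutoff (Hz).
#' @return Envelope with the same orientation as the input, attribute
#'   `"fs"` set to `fs_out`.
#' @export
mua_envelope <- function(wideband, fs_wb, fs_out = 763,
                         band = c(500, 5000), lp_cutoff = 200) {
  if (fs_wb <= 2 * band[2])
    stop(sprintf("fs_wb = %g Hz is too low for the %g Hz band edge", fs_wb, band[2]))
  env <- apply_rows(wideband, function(x) {
    y <- butter_filtfilt(x, fs_wb, band, "pass")
    y <- abs(y)
    y <- butter_filtfilt(y, fs_wb, lp_cutoff, "low")
    pmax(resample_linear(y, fs_wb, fs_out), 0)
  })
  attr(env, "fs") <- fs_out
  env
}

#' Condition a raw signal into the analysis LFP
#'
#' Low-pass filters below 200 Hz and resamples to the 763 Hz LFP time
#' base.  An optional preamplifier amplitude/phase correction hook is
#' applied first; it defaults to the identity.
#'
#' @param raw Numeric vector or channel x time matrix.
#' @param fs Input sampling rate (Hz), at least `fs_out`.
#' @param fs_out Output sampling rate (default 763 Hz).
#' @param cutoff Low-pass corner (Hz).
#' @param preamp_correction Function applied to each channel before
#'   filtering (identity by default).
#' @return LFP with attribute `"fs"` set to `fs_out`.
#' @export
condition_lfp <- function(raw, fs, fs_out = 763, cutoff = 200,
                          preamp_correction = identity) {
  if (fs < fs_out) stop("`fs` must be at least the output rate")
  out <- apply_rows(raw, function(x) {
    x <- preamp_correction(x)
    y <- butter_filtfilt(x, fs, cutoff, "low")
    resample_linear(y, fs, fs_out)
  })
  attr(out, "fs") <- fs_out
  out
}

#' Channel signal-to-noise ratio and exclusion
#'
#' SNR per channel = height of the peak of the trial-averaged
#' stimulus-evoked response (baseline-subtracted maximum in the peak
#' search window) divided by the SD of the trial-averaged activity in the
#' pre-stimulus period.  Channels with SNR below the threshold (default 3)
#' are excluded.
#'
#' @param mua Trial x channel x time array of MUA envelopes.
#' @param time Time base in ms relative to stimulus onset.
#' @param baseline_window Pre-stimulus window in ms (default -150-0).
#' @param peak_window Peak search window in ms (default 50-90).
#' @param threshold Exclusion threshold (default 3).
#' @return `lam_qc` data frame: channel, snr, excluded.
#' @export
compute_snr <- function(mua, time, baseline_window = c(-150, 0),
                        peak_window = c(50, 90), threshold = 3) {
  stopifnot(length(dim(mua)) == 3L, dim(mua)[3] == length(time))
  if (dim(mua)[1] < 2L) stop("need at least 2 trials to compute SNR")
  base_cols <- win_idx(time, baseline_window)
  peak_cols <- win_idx(time, peak_window)
  if (!length(base_cols) || !length(peak_cols))
    stop("baseline/peak windows must lie within the trial")
  avg <- colMeans(mua, dims = 1)                # channel x time
  base_mean <- rowMeans(avg[, base_cols, drop = FALSE])
  base_sd <- apply(avg[, base_cols, drop = FALSE], 1, sd)
  if (any(base_sd == 0))
    stop("zero pre-stimulus variance on channel(s) ",
         paste(which(base_sd == 0), collapse = ", "), "; degenerate input")
  peak <- apply(avg[, peak_cols, drop = FALSE], 1, max) - base_mean
  snr <- peak / base_sd
  structure(data.frame(channel = seq_len(dim(mua)[2]), snr = snr,
                       excluded = snr < threshold),
            class = c("lam_qc", "data.frame"), threshold = threshold)
}

#' Replace excluded channels by depth interpolation
#'
#' Excluded channels are replaced by linear interpolation (in depth)
#' between the nearest good neighbours, which avoids second-difference
#' artifacts in the CSD.  Excluded channels at the probe ends are filled
#' by nearest-neighbour extension; if the two outermost channels at either
#' end are both excluded the interpolation is refused.  The operation is
#' idempotent.
#'
#' @param lfp Channel x time matrix or trial x channel x time array.
#' @param excluded Logical vector, one flag per channel.
#' @return Object of the same shape with excluded channels replaced.
#' @export
interpolate_bad_channels <- function(lfp, excluded) {
  n <- if (is.matrix(lfp)) nrow(lfp) else dim(lfp)[2]
  stopifnot(length(excluded) == n, is.logical(excluded))
  if (!any(excluded)) return(lfp)
  if (mean(excluded) >= 0.5) stop("50% or more channels excluded; refusing to interpolate")
  if ((excluded[1] && excluded[2]) || (excluded[n] && excluded[n - 1]))
    stop("two consecutive excluded edge channels; cannot interpolate")
  good <- which(!excluded)
  fill_row <- function(get_row) {
    for (i in which(excluded)) {
      lo <- good[good < i]
      hi <- good[good > i]
      if (!length(lo)) {
        val <- get_row(min(hi), NULL, 0)
      } else if (!length(hi)) {
        val <- get_row(max(lo), NULL, 0)
      } else {
        l <- max(lo); h <- min(hi)
        wl <- (h - i) / (h - l)
        val <- get_row(l, h, wl)
      }
      assign_row(i, val)
    }
  }
  if (is.matrix(lfp)) {
    assign_row <- function(i, v) lfp[i, ] <<- v
    get_row <- function(l, h, wl)
      if (is.null(h)) lfp[l, ] else wl * lfp[l, ] + (1 - wl) * lfp[h, ]
  } else {
    assign_row <- function(i, v) lfp[, i, ] <<- v
    get_row <- function(l, h, wl)
      if (is.null(h)) lfp[, l, ] else wl * lfp[, l, ] + (1 - wl) * lfp[, h, ]
  }
  fill_row(get_row)
  lfp
}
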