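#' CSD computation parameters
#'
#' Parameters of the one-dimensional current-source density estimator:
#' the spatial derivative step `h`, the tissue conductivity `sigma`
#' and the electrode spacing.  `h` must be an integer multiple of the
#' spacing; with 0.1 mm contacts and the default `h = 0.2` mm the second
#' difference uses neighbours two channels away.
#'
#' @param h Derivative step in mm (default 0.2).
#' @param sigma Conductivity of cortical tissue in S/m (default 0.4).
#' @param spacing Electrode spacing in mm (default 0.1).
#' @return An object of class `lam_csd_params`.
#' @export
csd_params <- function(h = 0.2, sigma = 0.4, spacing = 0.1) {
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0")
  if (!is.numeric(spacing) || spacing <= 0) stop("`spacing` must be > 0")
  if (!is.numeric(h) || h <= 0) stop("`h` must be > 0")
  k <- h / spacing
  if (abs(k - round(k)) > 1e-8)
    stop("`h` must be an integer multiple of the electrode spacing")
  structure(list(h = h, sigma = sigma, spacing = spacing,
                 k = as.integer(round(k))),
            class = "lam_csd_params")
}

#' One-dimensional current-source density from a laminar LFP profile
#'
#' Three-point second spatial difference of the potential along the probe,
#' scaled by minus the conductivity over the squared step:
#' \deqn{CSD(x) = -\sigma \, [\phi(x+h) - 2\phi(x) + \phi(x-h)] / h^2.}
#' Negative values are current sinks (current flowing towards the
#' electrode), positive values sources.  Channels within `h` of either
#' probe end have no estimate and are masked invalid rather than
#' zero-padded, to avoid fabricating sinks at the boundaries.
#'
#' @param lfp Numeric matrix, channel x time (channel 1 = deepest contact).
#'   Units are whatever `phi` is recorded in; with mV and mm the CSD comes
#'   out in mV S / mm^2 / m (arbitrary but consistent units).
#' @param params A [csd_params()] object.
#' @return An object of class `lam_csd` with elements `values`
#'   (channel x time, `NA` at invalid channels), `valid` (logical mask),
#'   `params` and the sign convention.
#' @export
compute_csd <- function(lfp, params = csd_params()) {
  if (!is.matrix(lfp) || !is.numeric(lfp)) stop("`lfp` must be a numeric matrix")
  k <- params$k
  n <- nrow(lfp)
  if (n < 2L * k + 1L)
    stop(sprintf("need at least %d channels for h = %g mm (got %d)",
                 2L * k + 1L, params$h, n))
  idx <- (k + 1L):(n - k)
  values <- matrix(NA_real_, n, ncol(lfp),
                   dimnames = dimnames(lfp))
  values[idx, ] <- -(params$sigma / params$h^2) *
    (lfp[idx + k, , drop = FALSE] - 2 * lfp[idx, , drop = FALSE] +
       lfp[idx - k, , drop = FALSE])
  structure(list(values = values,
                 valid = seq_len(n) %in% idx,
                 params = params,
                 sign_convention = "negative = sink"),
            class = "lam_csd")
}

#' @export
print.lam_csd <- function(x, ...) {
  cat(sprintf("<lam_csd> %d channels x %d time points (%d valid channels), h = %g mm, sigma = %g S/m\n",
              nrow(x$values), ncol(x$values), sum(x$valid),
              x$params$h, x$params$sigma))
  invisible(x)
}

as_csd_values <- function(csd) {
  if (inherits(csd, "lam_csd")) csd$values else csd
}

#' Laminar CSD template
#'
#' The laminar template is the per-channel time-average of the CSD over the
#' modulation window, normalized so that the channel with the strongest
#' sink has weight -1 (sinks are negative).
#'
#' @param csd A `lam_csd` object or channel x time matrix (NA rows allowed).
#' @param time Time base in ms, one value per column.
#' @param window Length-2 window in ms (default the 200-750 ms modulation
#'   period).
#' @return `lam_template`: `weights` per channel (NA at invalid channels),
#'   `channels` (indices with weights) and the normalization constant.
#' @export
make_template <- function(csd, time, window = c(200, 750)) {
  values <- as_csd_values(csd)
  stopifnot(ncol(values) == length(time))
  cols <- win_idx(time, window)
  if (!length(cols)) stop("`window` contains no time samples")
  profile <- rowMeans(values[, cols, drop = FALSE])
  ok <- !is.na(profile)
  if (!any(ok) || all(profile[ok] == 0))
    stop("window-averaged CSD profile is all zero; cannot form a template")
  strongest_sink <- min(profile[ok])
  if (strongest_sink >= 0)
    stop("no current sink (negative CSD) in the window average")
  weights <- profile / abs(strongest_sink)
  structure(list(weights = weights,
                 channels = which(ok),
                 normalization = abs(strongest_sink),
                 window = window),
            class = "lam_template")
}

#' nCSD time course: template expression over time
#'
#' Inner product of the laminar template with the momentary CSD, giving one
#' value per time point that tracks how strongly the template pattern is
#' expressed.
#'
#' @param csd A `lam_csd` object or channel x time matrix.
#' @param template A [make_template()] result, or a plain numeric weight
#'   vector over the same channels.
#' @return Numeric vector, one value per time point.
#' @export
ncsd_timecourse <- function(csd, template) {
  values <- as_csd_values(csd)
  if (inherits(template, "lam_template")) {
    ch <- template$channels
    w <- template$weights[ch]
  } else {
    w <- as.numeric(template)
    ch <- which(!is.na(w))
    w <- w[ch]
  }
  if (max(ch) > nrow(values))
    stop("template channels do not match the CSD matrix")
  sub <- values[ch, , drop = FALSE]
  if (anyNA(sub))
    stop("template channels include channels without a CSD estimate")
  as.numeric(crossprod(w, sub))
}

#' Absolute CSD modulation between two conditions
#'
#' Mean over valid channels of the absolute value of the per-channel
#' time-averaged difference between two conditions.  The absolute value is
#' taken per channel before averaging across channels, so sinks and sources
#' of the modulation pattern do not cancel.
#'
#' @param csd_a,csd_b `lam_csd` objects or matrices of identical shape.
#' @param time Time base in ms.
#' @param window Analysis window in ms.
#' @return A scalar.
#' @export
abs_csd_modulation <- function(csd_a, csd_b, time, window = c(200, 750)) {
  a <- as_csd_values(csd_a)
  b <- as_csd_values(csd_b)
  if (!identical(dim(a), dim(b))) stop("condition CSD matrices differ in shape")
  stopifnot(ncol(a) == length(time))
  cols <- win_idx(time, window)
  d <- rowMeans(a[, cols, drop = FALSE] - b[, cols, drop = FALSE])
  mean(abs(d[!is.na(d)]))
}

#' Normalize a CSD matrix per penetration
#'
#' Divides by the maximum absolute CSD across channels during the stimulus
#' period of a reference condition (the target-curve condition in the
#' standard analysis), so penetrations share a common scale before
#' averaging.
#'
#' @param csd `lam_csd` or matrix to normalize.
#' @param reference `lam_csd` or matrix supplying the normalization
#'   constant (default: `csd` itself).
#' @param time Time base in ms.
#' @param window Stimulus period in ms used for the maximum.
#' @return Object of the same type as `csd`, rescaled; the constant is
#'   attached as attribute `"normalization"`.
#' @export
normalize_csd <- function(csd, reference = csd, time, window = c(0, 150)) {
  ref <- as_csd_values(reference)
  stopifnot(ncol(ref) == length(time))
  cols <- win_idx(time, window)
  m <- max(abs(ref[, cols]), na.rm = TRUE)
  if (!is.finite(m) || m == 0) stop("reference CSD is zero in the stimulus period")
  if (inherits(csd, "lam_csd")) {
    csd$values <- csd$values / m
    attr(csd, "normalization") <- m
    csd
  } else {
    structure(csd / m, normalization = m)
  }
}
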