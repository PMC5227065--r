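# Internal helpers shared across modules.

# Indices of `time` (ms) falling inside a closed window c(t0, t1).
win_idx <- function(time, window) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  which(time >= window[1] & time <= window[2])
}

# Linear ramp from 0 at t0 to 1 at t1 (clamped).
ramp01 <- function(t, t0, t1) pmin(1, pmax(0, (t - t0) / (t1 - t0)))

# Gaussian bump, unit peak.
gauss_bump <- function(t, mu, sd) exp(-((t - mu)^2) / (2 * sd^2))

# Tiny polynomial hash of a deparsed R object; used to stamp reports so
# that reruns with an identical configuration are recognizable.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 536870909
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
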