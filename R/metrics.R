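#' Dominant oscillation frequency of a trace
#'
#' Magnitude spectrum of the detrended (mean-removed), Hann-windowed,
#' zero-padded trace; returns the frequency of the largest peak above
#' 0 Hz. A flat trace is reported as 0 Hz with zero peak power.
#'
#' @param trace numeric vector sampled every `dt` ms.
#' @param dt sampling interval (ms).
#' @param fmin,fmax search band (Hz); the default excludes slow drift and
#'   anything above 200 Hz.
#' @return a list with fields `freq_hz`, `peak_power`, `window_ms`,
#'   `resolution_hz` and `detrended` (always `TRUE`).
#' @export
dominant_frequency <- function(trace, dt, fmin = 5, fmax = 200) {
  n <- length(trace)
  if (n * dt < 100) stop("trace must cover at least 100 ms")
  if (any(!is.finite(trace))) stop("non-finite trace")
  x <- trace - mean(trace)
  if (sd(x) < 1e-9)
    return(list(freq_hz = 0, peak_power = 0, window_ms = n * dt,
                resolution_hz = 1000 / (n * dt), detrended = TRUE))
  w <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  pad <- 2^ceiling(log2(n * 8))
  sp <- Mod(fft(c(x * w, rep(0, pad - n))))^2
  f <- seq(0, pad - 1) / (pad * dt / 1000)
  keep <- f >= fmin & f <= fmax
  i <- which.max(sp[keep])
  list(freq_hz = f[keep][i], peak_power = sp[keep][i],
       window_ms = n * dt, resolution_hz = 1000 / (n * dt),
       detrended = TRUE)
}

#' Phase lag between two oscillatory traces
#'
#' Lag of the cross-correlation maximum, in ms, wrapped into
#' `(-period/2, period/2]` of the dominant rhythm. Positive lag means
#' `b` follows `a`. Non-oscillatory input (spectral peak below the power
#' floor) yields `NA` with a warning.
#'
#' @param trace_a,trace_b numeric vectors on the same time base.
#' @param dt sampling interval (ms).
#' @param max_lag_ms largest lag searched.
#' @return lag in ms, or `NA` if either trace is non-oscillatory.
#' @export
phase_lag <- function(trace_a, trace_b, dt, max_lag_ms = 20) {
  fa <- dominant_frequency(trace_a, dt)
  fb <- dominant_frequency(trace_b, dt)
  if (fa$freq_hz == 0 || fb$freq_hz == 0) {
    warning("non-oscillatory trace: lag undefined")
    return(NA_real_)
  }
  a <- trace_a - mean(trace_a)
  b <- trace_b - mean(trace_b)
  kmax <- round(max_lag_ms / dt)
  n <- length(a)
  lags <- seq(-kmax, kmax)
  cc <- vapply(lags, function(k) {
    if (k >= 0) sum(a[1:(n - k)] * b[(1 + k):n])
    else sum(a[(1 - k):n] * b[1:(n + k)])
    }, numeric(1))
  i <- which.max(cc)
  lag <- lags[i] * dt
  # parabolic interpolation of the correlation peak for sub-sample precision
  if (i > 1 && i < length(cc)) {
    denom <- cc[i - 1] - 2 * cc[i] + cc[i + 1]
    if (denom < 0) lag <- lag + dt * 0.5 * (cc[i - 1] - cc[i + 1]) / denom
  }
  period <- 1000 / fa$freq_hz
  # wrap into (-period/2, period/2]
  lag <- lag - period * ceiling(lag / period - 0.5)
  lag
}

#' Mean activity trace of the retrieved object representation
#'
#' Averages the excitatory activity of the units that form the final
#' bubble in each area (membership taken from the trailing window-maximum
#' map), then averages across areas. This is the signal whose spectral
#' peak defines the network's binding rhythm.
#'
#' @param sim a `bilex_sim` with recorded features.
#' @param threshold bubble membership threshold.
#' @return a list with `trace` (one value per recorded sample), `n_units`
#'   (bubble members per area) and `members` (per-area index sets).
#' @export
object_activity_trace <- function(sim,
                                  threshold = sim$network$dec$bubble_threshold) {
  geom <- sim$network$geometry
  M <- geom$side
  traces <- list()
  nun <- integer(0)
  members <- list()
  for (a in seq_len(geom$n_areas)) {
    wm <- feature_window_max(sim, a)
    sel <- which(t(wm) >= threshold)  # t(): back to row-major unit order
    if (length(sel) == 0) next
    idx <- (a - 1) * M * M + sel
    traces[[length(traces) + 1]] <-
      rowMeans(sim$feature_ex[, idx, drop = FALSE])
    nun <- c(nun, length(sel))
    members[[length(members) + 1]] <- idx
  }
  if (length(traces) == 0)
    return(list(trace = rep(0, nrow(sim$feature_ex)), n_units = integer(0),
                members = list()))
  list(trace = Reduce(`+`, traces) / length(traces), n_units = nun,
       members = members)
}
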