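# Afterdepolarization (ADP) detection at the current threshold.
#
# After the first AP's AHP trough, the membrane either recovers
# monotonically (no ADP) or rises through a local maximum before dipping to a
# local minimum (ADP). The post-ADP minimum is located on a heavily smoothed
# copy of the trace (8-pole Bessel low-pass, 50 Hz cutoff, causal) as the
# point where the smoothed slope first turns from negative to positive; the
# ADP's integrated amplitude is the mean of the positive part of the raw
# trace after subtracting the straight line from the AHP trough to that
# minimum.

# Reverse Bessel polynomial coefficients (ascending powers of s)
bessel_poly <- function(n) {
  th0 <- 1; th1 <- c(1, 1)
  if (n == 0) return(th0)
  if (n == 1) return(th1)
  for (k in 2:n) {
    a <- (2 * k - 1) * c(th1, 0)
    b <- c(0, 0, th0)
    th <- a + c(b, numeric(length(a) - length(b)))
    th0 <- th1; th1 <- th
  }
  th1
}

# analog prototype poles of an order-n Bessel low-pass, -3 dB at 1 rad/s
bessel_poles <- function(n) {
  coef <- bessel_poly(n)
  p <- polyroot(coef)
  # scale so |H(jw)| = 1/sqrt(2) at w = 1
  hmag2 <- function(w) {
    s <- complex(real = 0, imaginary = w)
    num <- coef[1]
    den <- sum(coef * s^(seq_along(coef) - 1))
    Mod(num / den)^2
  }
  w3 <- stats::uniroot(function(w) hmag2(w) - 0.5, c(1e-3, 10))$root
  p / w3
}

#' Causal Bessel low-pass filter
#'
#' Digital realization (bilinear transform, cascaded biquads) of an 8-pole
#' Bessel low-pass, applied forward only, matching an acquisition-style
#' hardware filter.
#'
#' @param x Numeric signal.
#' @param sampling_rate Sampling rate, Hz.
#' @param fc Cutoff frequency, Hz.
#' @param order Filter order (even).
#' @return Filtered signal, same length as `x`.
#' @export
bessel_lowpass <- function(x, sampling_rate, fc = 50, order = 8) {
  if (order %% 2 != 0) abort("`order` must be even")
  wc <- 2 * sampling_rate * tan(pi * fc / sampling_rate)  # pre-warped cutoff
  p <- bessel_poles(order) * wc
  p <- p[order(Im(p))]
  pairs <- p[Im(p) > 0]
  c2 <- 2 * sampling_rate
  x0 <- x[1]
  y <- x - x0
  for (pp in pairs) {
    zp <- (c2 + pp) / (c2 - pp)
    a <- c(1, -2 * Re(zp), Mod(zp)^2)
    k <- sum(a) / 4
    b <- k * c(1, 2, 1)
    y <- as.numeric(signal::filter(b, a, y))
  }
  y + x0
}

# sign-change points of a slope sign sequence, with hysteresis: sign phases
# shorter than `min_run` samples are absorbed into the preceding phase so
# micro-wiggles around zero slope do not register as turns
slope_phases <- function(sgn, min_run) {
  r <- rle(sgn)
  val <- logical(0); len <- integer(0); pend <- 0L
  for (i in seq_along(r$values)) {
    li <- r$lengths[i] + pend; pend <- 0L
    if (li < min_run && length(val)) {
      len[length(len)] <- len[length(len)] + li
    } else if (li < min_run) {
      pend <- li
    } else if (length(val) && val[length(val)] == r$values[i]) {
      len[length(len)] <- len[length(len)] + li
    } else {
      val <- c(val, r$values[i]); len <- c(len, li)
    }
  }
  ends <- cumsum(len)
  k <- seq_len(length(val) - 1L)
  list(up = ends[k][!val[k]], dn = ends[k][val[k]])
}

# group delay (samples) of the causal Bessel smoother, from the centroid of
# its impulse response
bessel_delay <- function(sampling_rate, fc = 50, order = 8) {
  n <- round(6 * sampling_rate / fc)
  h <- diff(bessel_lowpass(c(0, rep(1, n)), sampling_rate, fc, order))
  round(sum((seq_along(h) - 1) * h) / sum(h))
}

#' Detect an afterdepolarization after the first action potential
#'
#' @param voltage Numeric trace (mV), typically the sweep at the current
#'   threshold.
#' @param sampling_rate Sampling rate, Hz.
#' @param events Event tibble from [detect_aps()] for this trace; only the
#'   first event is used.
#' @param window Optional analysis window in seconds.
#' @param fc Cutoff of the smoothing filter, Hz.
#' @param min_bump Minimum residual height (mV) for a local maximum to count
#'   as an ADP.
#' @return A one-row tibble: `present` (logical) and `integrated_amplitude`
#'   (mV, mean positive residual; 0 when absent).
#' @export
detect_adp <- function(voltage, sampling_rate, events, window = NULL,
                       fc = 50, min_bump = 0.05) {
  absent <- tibble(present = FALSE, integrated_amplitude = 0)
  if (is.null(events) || nrow(events) == 0L) return(absent)
  win <- window_index(length(voltage), sampling_rate, window)
  trough <- events$ahp_idx[1]
  seg_end <- if (nrow(events) > 1L) events$threshold_idx[2] - 1L else win[2]
  if (is.na(trough) || seg_end - trough < 3L) return(absent)
  f <- bessel_lowpass(voltage, sampling_rate, fc = fc)
  lag <- bessel_delay(sampling_rate, fc)
  sf <- diff(f[trough:seg_end])
  ph <- slope_phases(sf >= 0, min_run = round(0.004 * sampling_rate))
  up <- ph$up                                       # slope turns neg -> pos
  dn <- ph$dn                                       # slope turns pos -> neg
  up <- up[up > round(0.001 * sampling_rate)]
  if (length(up) == 0L) return(absent)
  # the causal filter delays the trace by `lag`; the first upward turn is
  # the delayed image of the AHP trough itself. An ADP shows up as a
  # subsequent local maximum (pos -> neg turn) followed by the post-ADP
  # local minimum (the next neg -> pos turn); both are mapped back onto the
  # raw trace by subtracting the filter delay.
  peak_img <- dn[dn > up[1]][1]
  if (is.na(peak_img)) return(absent)
  min_img <- up[up > peak_img][1]
  if (is.na(min_img)) return(absent)
  t_peak <- min(trough + max(peak_img - lag, 1L), seg_end - 1L)
  t_min <- min(trough + max(min_img - lag, peak_img - lag + 1L) +
                 round(0.002 * sampling_rate), seg_end)
  if (t_min <= t_peak + 1L) return(absent)
  rng <- t_peak:t_min
  local_min <- rng[which.min(voltage[rng])]
  if (local_min - trough < 3L) return(absent)
  # a genuine ADP peak must stand above the post-ADP minimum; comparing
  # against the minimum (not the chord) keeps a concave monotonic recovery
  # from counting as a bump
  if (max(voltage[t_peak:local_min]) - voltage[local_min] < min_bump)
    return(absent)
  idx <- trough:local_min
  base <- seq(voltage[trough], voltage[local_min], length.out = length(idx))
  resid <- voltage[idx] - base
  pos <- resid[resid > 0]
  tibble(present = TRUE,
         integrated_amplitude = if (length(pos)) mean(pos) else 0)
}
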