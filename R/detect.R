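# Action-potential detection and per-spike waveform analysis.
#
# Threshold = first sample of a suprathreshold excursion where dV/dt exceeds
# 10 mV/ms, after at least 1 ms below that rate (debounce). Spikes that do
# not overshoot 0 mV are rejected. All derivative work uses central
# differences on the raw trace.

dvdt_mv_ms <- function(v, sampling_rate) {
  dt_ms <- 1000 / sampling_rate
  n <- length(v)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt_ms)
  if (n >= 2) {
    d[1] <- (v[2] - v[1]) / dt_ms
    d[n] <- (v[n] - v[n - 1]) / dt_ms
  }
  d
}

window_index <- function(n, sampling_rate, window) {
  if (is.null(window)) return(c(1L, n))
  i0 <- max(1L, floor(window[1] * sampling_rate) + 1L)
  i1 <- min(n, floor(window[2] * sampling_rate))
  if (i1 <= i0) abort("window lies outside the trace")
  c(i0, i1)
}

#' Detect action potentials in a voltage trace
#'
#' @param voltage Numeric vector, membrane potential in mV.
#' @param sampling_rate Sampling rate, Hz.
#' @param window Optional `c(start, end)` in seconds restricting the search
#'   (typically the stimulus window).
#' @param dvdt_threshold Spike-threshold criterion on dV/dt, mV/ms.
#' @param debounce_ms Minimum time below the dV/dt criterion before a new
#'   threshold crossing is accepted.
#' @param min_peak Overshoot criterion: events whose peak does not exceed
#'   this potential (mV) are rejected.
#' @param analyze Also fill waveform and AHP descriptors
#'   (see [ap_waveform()], [ahp_features()]).
#' @return A tibble with one row per accepted action potential: threshold
#'   index/time/potential, peak index/time/potential and amplitude, plus
#'   waveform and AHP columns when `analyze = TRUE`. Times are in ms from the
#'   start of the trace. Zero rows when nothing fires.
#' @export
detect_aps <- function(voltage, sampling_rate, window = NULL,
                       dvdt_threshold = 10, debounce_ms = 1,
                       min_peak = 0, analyze = TRUE) {
  n <- length(voltage)
  dt_ms <- 1000 / sampling_rate
  win <- window_index(n, sampling_rate, window)
  d <- dvdt_mv_ms(voltage, sampling_rate)
  above <- d > dvdt_threshold
  above[seq_len(n) < win[1] | seq_len(n) > win[2]] <- FALSE
  if (!any(above)) return(empty_ap_tibble(analyze))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_on <- which(r$values)
  deb <- max(1L, round(debounce_ms / dt_ms))
  thr_idx <- integer()
  last_end <- -Inf
  for (k in run_on) {
    if (starts[k] - last_end > deb) thr_idx <- c(thr_idx, starts[k])
    last_end <- ends[k]
  }
  bounds <- c(thr_idx, win[2] + 1L)
  cap <- round(10 / dt_ms)  # peak search cap: +10 ms
  ev <- purrr::map_dfr(seq_along(thr_idx), function(i) {
    k <- thr_idx[i]
    span_end <- min(bounds[i + 1L] - 1L, k + cap, win[2])
    seg <- voltage[k:span_end]
    pk <- k + which.max(seg) - 1L
    tibble(threshold_idx = k,
           threshold_time_ms = (k - 1L) * dt_ms,
           threshold_v = voltage[k],
           peak_idx = pk,
           peak_time_ms = (pk - 1L) * dt_ms,
           peak_v = voltage[pk],
           next_bound = bounds[i + 1L])
  })
  ev <- ev[ev$peak_v > min_peak, , drop = FALSE]
  if (nrow(ev) == 0L) return(empty_ap_tibble(analyze))
  ev$amplitude <- ev$peak_v - ev$threshold_v
  if (analyze) {
    ev <- ahp_features(ev, voltage, sampling_rate, window = window)
    ev <- ap_waveform(ev, voltage, sampling_rate)
  }
  ev$next_bound <- NULL
  ev
}

empty_ap_tibble <- function(analyze = TRUE) {
  out <- tibble(threshold_idx = integer(), threshold_time_ms = numeric(),
                threshold_v = numeric(), peak_idx = integer(),
                peak_time_ms = numeric(), peak_v = numeric(),
                amplitude = numeric())
  if (analyze)
    out <- dplyr::mutate(out, ahp_idx = integer(), ahp_v = numeric(),
                         ahp_latency_ms = numeric(), half_width_ms = numeric(),
                         max_rise = numeric(), max_decay = numeric(),
                         thr_amp_ratio = numeric(), rise_hw_ratio = numeric(),
                         rise_decay_ratio = numeric())
  out
}

#' Afterhyperpolarization descriptors per action potential
#'
#' The AHP trough is the minimum between an AP's peak and the next AP's
#' threshold crossing (or the end of the analysis window). `ahp_v` is
#' threshold-referenced (trough minus threshold potential, negative for a
#' genuine AHP; non-negative values indicate no AHP and are reported as-is);
#' `ahp_latency_ms` runs from the AP peak to the trough.
#'
#' @param events Event tibble from [detect_aps()].
#' @param voltage,sampling_rate The trace the events came from.
#' @param window Optional analysis window in seconds.
#' @return `events` with `ahp_idx`, `ahp_v`, `ahp_latency_ms` columns.
#' @export
ahp_features <- function(events, voltage, sampling_rate, window = NULL) {
  if (nrow(events) == 0L) return(events)
  win <- window_index(length(voltage), sampling_rate, window)
  dt_ms <- 1000 / sampling_rate
  ends <- c(events$threshold_idx[-1], win[2])
  res <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    from <- events$peak_idx[i]
    to <- max(ends[i], from + 1L)
    seg <- voltage[from:to]
    tr <- from + which.min(seg) - 1L
    tibble(ahp_idx = tr,
           ahp_v = voltage[tr] - events$threshold_v[i],
           ahp_latency_ms = (tr - from) * dt_ms)
  })
  dplyr::bind_cols(events[setdiff(names(events),
                                  c("ahp_idx", "ahp_v", "ahp_latency_ms"))], res)
}

#' Action-potential waveform descriptors
#'
#' Fills half-width (time between half-amplitude crossings, half level =
#' threshold + amplitude/2, linear interpolation between samples), maximum
#' rise and decay rates of dV/dt (rise between threshold and peak; decay
#' between threshold crossing and the AHP trough, capped at +10 ms), and the
#' derived ratios threshold/amplitude, max rise/half-width and
#' max rise/|max decay|.
#'
#' @param events Event tibble from [detect_aps()] (after [ahp_features()]).
#' @param voltage,sampling_rate The trace the events came from.
#' @return `events` with waveform columns added; `half_width_ms` is `NA` when
#'   the falling half-amplitude crossing is not found before the next AP.
#' @export
ap_waveform <- function(events, voltage, sampling_rate) {
  if (nrow(events) == 0L) return(events)
  dt_ms <- 1000 / sampling_rate
  d <- dvdt_mv_ms(voltage, sampling_rate)
  cap <- round(10 / dt_ms)
  res <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
    k <- events$threshold_idx[i]; pk <- events$peak_idx[i]
    trough <- if ("ahp_idx" %in% names(events)) events$ahp_idx[i] else
      min(pk + cap, length(voltage))
    dec_end <- min(trough, k + cap)
    max_rise <- max(d[k:pk])
    max_decay <- min(d[pk:max(dec_end, pk + 1L)])
    half <- events$threshold_v[i] + events$amplitude[i] / 2
    up <- crossing_time(voltage, k, pk, half, rising = TRUE, dt_ms)
    dn <- crossing_time(voltage, pk, trough, half, rising = FALSE, dt_ms)
    hw <- if (is.na(up) || is.na(dn)) NA_real_ else dn - up
    tibble(half_width_ms = hw, max_rise = max_rise, max_decay = max_decay,
           thr_amp_ratio = events$threshold_v[i] / events$amplitude[i],
           rise_hw_ratio = if (is.na(hw)) NA_real_ else max_rise / hw,
           rise_decay_ratio = abs(max_rise / max_decay))
  })
  dplyr::bind_cols(events[setdiff(names(events), names(res))], res)
}

# linearly interpolated time (ms from trace start) where v crosses `level`
crossing_time <- function(v, from, to, level, rising, dt_ms) {
  if (to <= from) return(NA_real_)
  seg <- v[from:to]
  hit <- if (rising) which(seg[-1] >= level & seg[-length(seg)] < level)
         else which(seg[-1] <= level & seg[-length(seg)] > level)
  if (length(hit) == 0L) return(NA_real_)
  i <- hit[1]
  v0 <- seg[i]; v1 <- seg[i + 1]
  frac <- if (v1 == v0) 0 else (level - v0) / (v1 - v0)
  (from + i - 2L + frac) * dt_ms
}
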