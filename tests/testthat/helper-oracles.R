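# Independent oracles and fixture builders, kept deliberately naive:
# plain-loop implementations that the vectorized/library-backed code under
# test is checked against.

# --- trace fixtures ---------------------------------------------------------

# trace with analytic raised-cosine spikes stamped at known times; the
# inter-spike level sits between the AHP trough and threshold (a depolarized
# plateau, as during a current step), so the trough is the true minimum
make_spike_trace <- function(spike_times_s, rate = 50000, duration_s = 1.2,
                             baseline = -42, threshold = -35, peak = 40,
                             trough_drop = 12, rise_ms = 0.6, decay_ms = 3) {
  n <- round(duration_s * rate)
  v <- rep(baseline, n)
  dt_ms <- 1000 / rate
  for (ts in spike_times_s) {
    i0 <- round(ts * rate) + 1L
    # linear run-up from the plateau to threshold over 5 ms (slope well
    # below the 10 mV/ms detection criterion)
    ramp_n <- round(5 / dt_ms)
    ramp <- seq(baseline, threshold, length.out = ramp_n)
    v[(i0 - ramp_n):(i0 - 1L)] <- ramp
    tr <- seq(dt_ms, rise_ms, by = dt_ms)
    td <- seq(dt_ms, decay_ms, by = dt_ms)
    spike <- c(threshold,
               threshold + (peak - threshold) * (1 - cos(pi * tr / rise_ms)) / 2,
               (threshold - trough_drop) +
                 (peak - threshold + trough_drop) * (1 + cos(pi * td / decay_ms)) / 2)
    v[i0:(i0 + length(spike) - 1L)] <- spike
    # relax back to baseline
    rec_n <- round(30 / dt_ms)
    rec <- (threshold - trough_drop) +
      (baseline - threshold + trough_drop) * (1 - exp(-(1:rec_n) * dt_ms / 10))
    j <- i0 + length(spike)
    v[j:(j + rec_n - 1L)] <- rec
  }
  v
}

# piecewise-linear (triangular) spike with closed-form half-width
make_triangle_trace <- function(rate = 50000, baseline = -70,
                                threshold = -35, peak = 40,
                                rise_ms = 1, decay_ms = 2) {
  dt_ms <- 1000 / rate
  n <- round(0.4 * rate)
  v <- rep(baseline, n)
  i0 <- round(0.15 * rate)
  ramp_n <- round(5 / dt_ms)
  v[(i0 - ramp_n):(i0 - 1L)] <- seq(baseline, threshold, length.out = ramp_n)
  up <- seq(threshold, peak, length.out = round(rise_ms / dt_ms) + 1L)
  dn <- seq(peak, baseline, length.out = round(decay_ms / dt_ms) + 1L)[-1]
  v[i0:(i0 + length(up) + length(dn) - 1L)] <- c(up, dn)
  list(v = v, i0 = i0, rise_ms = rise_ms, decay_ms = decay_ms,
       threshold = threshold, peak = peak, baseline = baseline)
}

# fake AP event tibble from peak times (ms) and amplitudes, for train stats
fake_events <- function(peak_times_ms, amplitudes = rep(75, length(peak_times_ms)),
                        latency0_ms = 5) {
  tibble::tibble(
    threshold_time_ms = peak_times_ms - 0.5,
    threshold_v = -35,
    peak_time_ms = peak_times_ms,
    peak_v = amplitudes - 35,
    amplitude = amplitudes
  )
}

# multi-sweep set from per-sweep spike-time lists; flat subthreshold sweeps
# follow V = rmp + rm * I / 1000 during the stimulus
make_fake_sweepset <- function(spikes_per_sweep, current_pa, rate = 10000,
                               rmp = -70, rm = 200) {
  volts <- purrr::map2(spikes_per_sweep, current_pa, function(sp, amp) {
    if (length(sp) == 0) {
      n <- round(1.2 * rate)
      v <- rep(rmp, n)
      idx <- (round(0.1 * rate) + 1L):round(1.1 * rate)
      v[idx] <- rmp + rm * amp / 1000
      v
    } else {
      make_spike_trace(sp, rate = rate)
    }
  })
  sweepset(volts, current_pa, rate, stim_onset = 0.1, stim_duration = 1.0,
           cell_id = "fake")
}

# --- clustering oracles -----------------------------------------------------

# naive O(n^3) agglomerative clustering via Lance-Williams updates
naive_agglomerative <- function(d, method = c("average", "ward")) {
  method <- match.arg(method)
  dm <- as.matrix(d)
  if (method == "ward") dm <- dm^2
  n <- nrow(dm)
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(n - 1)
  members <- as.list(seq_len(n))
  merges <- list()
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_along(active)) for (j in seq_len(i - 1)) {
      dij <- dm[active[i], active[j]]
      if (dij < bestd) { bestd <- dij; best <- c(active[j], active[i]) }
    }
    a <- best[1]; b <- best[2]
    heights[step] <- if (method == "ward") sqrt(bestd) else bestd
    for (k in setdiff(active, c(a, b))) {
      dm[a, k] <- dm[k, a] <- if (method == "average") {
        (sizes[a] * dm[a, k] + sizes[b] * dm[b, k]) / (sizes[a] + sizes[b])
      } else {
        ((sizes[a] + sizes[k]) * dm[a, k] + (sizes[b] + sizes[k]) * dm[b, k] -
           sizes[k] * dm[a, b]) / (sizes[a] + sizes[b] + sizes[k])
      }
    }
    sizes[a] <- sizes[a] + sizes[b]
    members[[a]] <- c(members[[a]], members[[b]])
    merges[[step]] <- members[[a]]
    active <- setdiff(active, b)
  }
  list(heights = heights, merges = merges)
}

# partition of 1..n implied by the first k naive merges
naive_cut <- function(oracle, n, k) {
  cl <- seq_len(n)
  for (step in seq_len(n - k)) {
    grp <- oracle$merges[[step]]
    cl[cl %in% cl[grp]] <- min(cl[grp])
  }
  as.integer(factor(cl))
}

same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# plain-loop silhouette widths
naive_silhouette <- function(cl, d) {
  dm <- as.matrix(d)
  n <- length(cl)
  vapply(seq_len(n), function(i) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0) return(0)  # singleton
    a <- mean(dm[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(g)
      mean(dm[i, cl == g]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

# --- misc oracles -----------------------------------------------------------

trapezoid <- function(y, dx = 1) dx * (sum(y) - (y[1] + y[length(y)]) / 2)

# least-squares slope/intercept via explicit normal equations
normal_eq_fit <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(intercept = intercept, slope = slope)
}

# --- shared simulated cells (expensive; built once per test run) ------------

.sim_cache <- new.env(parent = emptyenv())

sim_features_all <- function() {
  if (is.null(.sim_cache$fx)) {
    .sim_cache$fx <- purrr::map_dfr(names(sim_presets()), function(st)
      dplyr::mutate(extract_features(simulate_sweepset(st, seed = 20), 38),
                    label = st))
  }
  .sim_cache$fx
}
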