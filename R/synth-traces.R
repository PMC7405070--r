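# Spiking-trace simulator: an adaptive integrate-and-fire model whose firing
# rate is controlled by a fast spike-triggered adaptation current (the AHP
# conductance analogue: jump b_f, decay tau_wf), with a slow adaptation
# current (b_s, tau_ws) for late frequency adaptation and saturation, an
# optional depolarizing after-current (d, tau_d; source of doublet firing and
# the ADP), a relaxing threshold offset for delayed-onset phenotypes and
# Ornstein-Uhlenbeck current noise for irregular firing. Emitted spikes are
# rendered with subtype-specific waveform templates (raised-cosine rise and
# decay, threshold-referenced AHP trough, amplitude decrement along the
# train).
#
# In the adaptation-dominated regime the interspike interval is
# approximately tau_wf * log((g_fire + b_f)/g_fire) with
# g_fire = Rm * (I - 0.95 ct)/1000 / ahp (the conductance level at which the
# shunted equilibrium potential recrosses threshold), which is how the
# per-subtype parameters were derived from the published initial
# instantaneous frequencies, ISI ratios and AP counts.

#' Simulator presets for the eight claustral subtypes
#'
#' Each preset anchors the passive properties (resting level, input
#' resistance, current threshold) at the published subtype medians and sets
#' the dynamical parameters (fast/slow adaptation, after-current, onset
#' delay, noise) to reproduce the subtype's firing phenotype: minimal early
#' frequency adaptation with amplitude decrement (PN1), high-threshold firing
#' with strong adaptation (PN2), doublet firing with an ADP (PN3, PN4),
#' delayed onset (PN5), fast regular spiking (PV), regular moderately
#' adapting firing (SST) and irregular firing (VIP).
#'
#' @return Named list of parameter lists.
#' @export
sim_presets <- function() {
  p <- function(el, rm, ct, tau, tau_wf, b_f, tau_ws = 1500, b_s = 1,
                d = 0, tau_d = 6, theta0 = 0, tau_theta = 40,
                sigma = 0, tau_n = 5, refrac = 4, amp = 75, rise = 0.6,
                ahp = 12, decay = 3.5, w2 = 0.9, wlate = 0.8, ktau = 4) {
    list(el = el, rm = rm, ct = ct, tau = tau, tau_wf = tau_wf, b_f = b_f,
         tau_ws = tau_ws, b_s = b_s, d = d, tau_d = tau_d, theta0 = theta0,
         tau_theta = tau_theta, sigma = sigma, tau_n = tau_n, refrac = refrac,
         amp = amp, rise = rise, ahp = ahp, decay = decay, w2 = w2,
         wlate = wlate, ktau = ktau)
  }
  list(
    PN1 = p(el = -73.9, rm = 248, ct = 100, tau = 20, tau_wf = 41, b_f = 4.34,
            b_s = 1, sigma = 1.5, amp = 81.6, rise = 0.62, ahp = 12,
            decay = 3.7, w2 = 0.88, wlate = 0.64, ktau = 5),
    PN2 = p(el = -74.8, rm = 151, ct = 220, tau = 16, tau_wf = 109, b_f = 2.73,
            b_s = 1, d = 8, tau_d = 12, sigma = 4, amp = 71.5, rise = 0.59, ahp = 14.5,
            decay = 3.55, w2 = 0.77, wlate = 0.73),
    PN3 = p(el = -71.5, rm = 219, ct = 120, tau = 18, tau_wf = 90, b_f = 3.12,
            b_s = 1.5, d = 55, tau_d = 18, sigma = 3, amp = 77.2, rise = 0.56,
            ahp = 10.2, decay = 3.1, w2 = 0.71, wlate = 0.85),
    PN4 = p(el = -70.5, rm = 238, ct = 100, tau = 20, tau_wf = 134, b_f = 2.57,
            b_s = 1.5, d = 30, tau_d = 15, sigma = 4, amp = 73.9, rise = 0.68,
            ahp = 10.8, decay = 3.9, w2 = 0.71, wlate = 0.86),
    PN5 = p(el = -68.7, rm = 399, ct = 40, tau = 25, tau_wf = 132, b_f = 1.86,
            b_s = 0.8, d = 15, tau_d = 15, theta0 = 5, tau_theta = 40,
            sigma = 3, amp = 74.2, rise = 0.71, ahp = 11.7, decay = 4.0,
            w2 = 0.85, wlate = 0.88),
    PV  = p(el = -67.2, rm = 157, ct = 160, tau = 8, tau_wf = 10, b_f = 3.06,
            tau_ws = 1200, b_s = 1, sigma = 0.8, refrac = 10.5, amp = 68.3, rise = 0.41,
            ahp = 22.4, decay = 1.06, w2 = 0.95, wlate = 0.88, ktau = 15),
    SST = p(el = -63.0, rm = 389, ct = 40, tau = 15, tau_wf = 40, b_f = 1.88,
            b_s = 0.6, sigma = 1.5, refrac = 24, amp = 70.6, rise = 0.60, ahp = 20,
            decay = 2.16, w2 = 0.96, wlate = 0.88, ktau = 10),
    VIP = p(el = -59.8, rm = 616, ct = 20, tau = 18, tau_wf = 79, b_f = 1.45,
            b_s = 0.8, sigma = 3.5, tau_n = 20, refrac = 45, amp = 72.4, rise = 0.74,
            ahp = 13.4, decay = 2.98, w2 = 0.92, wlate = 0.79)
  )
}

resolve_preset <- function(proto) {
  if (is.character(proto)) {
    presets <- sim_presets()
    if (!proto %in% names(presets))
      abort(paste0("unknown subtype preset: ", proto))
    presets[[proto]]
  } else proto
}

# spike waveform template, sampled at dt from the threshold crossing:
# raised-cosine rise to the peak, raised-cosine decay to the AHP trough
spike_template <- function(vthr, peak, trough, rise_ms, decay_ms, dt_ms) {
  tr <- seq(dt_ms, rise_ms, by = dt_ms)
  td <- seq(dt_ms, decay_ms, by = dt_ms)
  c(vthr + (peak - vthr) * (1 - cos(pi * tr / rise_ms)) / 2,
    trough + (peak - trough) * (1 + cos(pi * td / decay_ms)) / 2)
}

#' Simulate one voltage trace
#'
#' Integrates the adaptive integrate-and-fire model (exponential-Euler
#' update) over a sweep containing a 1-s current step.
#'
#' @param proto Preset name (see [sim_presets()]) or parameter list.
#' @param current_pa Injected current during the step, pA.
#' @param seed Random seed for the noise process.
#' @param dt_ms Integration/sampling step, ms (0.02 ms = 50 kHz).
#' @param duration_s Total sweep duration, seconds.
#' @param stim_onset,stim_duration Stimulus window, seconds.
#' @return Numeric voltage trace (mV).
#' @export
simulate_trace <- function(proto, current_pa, seed = 1, dt_ms = 0.02,
                           duration_s = 1.2, stim_onset = 0.1,
                           stim_duration = 1.0) {
  pr <- resolve_preset(proto)
  if (pr$tau <= 0 || pr$tau_wf <= 0 || pr$tau_ws <= 0 || pr$tau_d <= 0 ||
      pr$rm <= 0)
    abort("unstable simulator parameters")
  n <- round(duration_s * 1000 / dt_ms)
  i_on <- floor(stim_onset * 1000 / dt_ms) + 1L
  i_off <- floor((stim_onset + stim_duration) * 1000 / dt_ms)
  vt <- pr$el + pr$rm * 0.95 * pr$ct / 1000
  e_ahp <- vt - pr$ahp
  dwf <- exp(-dt_ms / pr$tau_wf)
  dws <- exp(-dt_ms / pr$tau_ws)
  da <- exp(-dt_ms / pr$tau_d)
  dn <- exp(-dt_ms / pr$tau_n)
  set.seed(seed)
  noise <- if (pr$sigma > 0)
    stats::rnorm(n) * pr$sigma * sqrt(1 - dn^2) else numeric(n)
  out <- numeric(n)
  v <- pr$el; wf <- 0; ws <- 0; a <- 0; eta <- 0
  k <- 0L  # spikes so far
  refrac_until <- 0L
  i <- 1L
  while (i <= n) {
    stim <- i >= i_on && i <= i_off
    inj <- if (stim) current_pa else 0
    eta <- eta * dn + noise[i]
    drive <- pr$el + pr$rm * (inj - ws + a + eta) / 1000
    veq <- (drive + wf * e_ahp) / (1 + wf)
    v <- veq + (v - veq) * exp(-dt_ms * (1 + wf) / pr$tau)
    wf <- wf * dwf; ws <- ws * dws; a <- a * da
    theta <- if (stim && pr$theta0 > 0)
      pr$theta0 * exp(-(i - i_on) * dt_ms / pr$tau_theta) else 0
    if (stim && i > refrac_until && v >= vt + theta) {
      k <- k + 1L
      wk <- if (k == 1L) 1 else
        pr$wlate + (pr$w2 - pr$wlate) * exp(-(k - 2) / pr$ktau)
      peak <- vt + pr$amp * wk
      trough <- vt - pr$ahp
      tpl <- spike_template(vt, peak, trough, pr$rise, pr$decay, dt_ms)
      j <- min(n, i + length(tpl))
      out[i] <- vt
      out[(i + 1L):j] <- tpl[seq_len(j - i)]
      elapsed <- (j - i) * dt_ms
      wf <- (wf + pr$b_f) * exp(-elapsed / pr$tau_wf)
      ws <- (ws + pr$b_s) * exp(-elapsed / pr$tau_ws)
      a <- (a + pr$d) * exp(-elapsed / pr$tau_d)
      eta <- eta * exp(-elapsed / pr$tau_n)
      v <- trough
      refrac_until <- j + round(pr$refrac / dt_ms)
      i <- j + 1L
      if (!is.finite(v)) abort("simulator diverged")
    } else {
      out[i] <- v
      i <- i + 1L
    }
  }
  out
}

#' Simulate a full current ladder for one cell
#'
#' @param proto Preset name or parameter list.
#' @param ladder Current amplitudes (pA); defaults to -60 pA upward in 20-pA
#'   steps to about 3.2x the preset's current threshold (at least 160 pA
#'   beyond it, so low-threshold cells reach their maximal firing range).
#' @param seed Random seed; each sweep uses a sweep-specific derived seed.
#' @param cell_id Cell identifier.
#' @param temperature Bath temperature attached to the recording, degC.
#' @param dt_ms Integration step, ms.
#' @return A [sweepset()].
#' @export
simulate_sweepset <- function(proto, ladder = NULL, seed = 1,
                              cell_id = NULL, temperature = 24,
                              dt_ms = 0.02) {
  pr <- resolve_preset(proto)
  name <- if (is.character(proto)) proto else "synthetic"
  ladder <- ladder %||% seq(-60, 20 * ceiling(max(3.2 * pr$ct, pr$ct + 160) / 20), by = 20)
  volts <- lapply(seq_along(ladder), function(i)
    simulate_trace(pr, ladder[i], seed = seed * 1000L + i, dt_ms = dt_ms))
  sweepset(volts, ladder, sampling_rate = 1000 / dt_ms,
           stim_onset = 0.1, stim_duration = 1.0,
           cell_id = cell_id %||% paste0(name, "_sim", seed),
           temperature = temperature)
}
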