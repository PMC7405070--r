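# Composition of the canonical feature sets from a sweep family.

#' Passive membrane properties from subthreshold sweeps
#'
#' The membrane (input) resistance is the slope of the least-squares fit of
#' steady-state membrane potential against injected current over the
#' subthreshold sweeps; the resting membrane potential is the fitted value at
#' zero current. Steady state is the mean over the last fifth of the stimulus
#' window.
#'
#' @param s A [sweepset()].
#' @param steady_frac Final fraction of the stimulus window averaged for the
#'   steady-state potential.
#' @return One-row tibble: `rmp` (mV), `rm` (MOhm).
#' @export
passive_properties <- function(s, steady_frac = 0.2) {
  counts <- sweep_ap_counts(s)
  sub <- which(counts == 0L)
  if (length(sub) < 2L) abort("need at least 2 subthreshold sweeps for a V-I fit")
  idx <- stim_index(s)
  tail_idx <- idx[idx > idx[length(idx)] - steady_frac * length(idx)]
  vss <- vapply(sub, function(i) mean(s$voltages[[i]][tail_idx]), numeric(1))
  fit <- stats::lm(vss ~ s$current_pa[sub])
  tibble(rmp = unname(stats::coef(fit)[1]),
         rm = unname(stats::coef(fit)[2]) * 1000)  # mV/pA -> MOhm
}

sweep_ap_counts <- function(s) {
  win <- c(s$stim_onset, s$stim_onset + s$stim_duration)
  vapply(s$voltages, function(v)
    nrow(detect_aps(v, s$sampling_rate, window = win, analyze = FALSE)),
    integer(1))
}

#' Current threshold and reference sweeps
#'
#' The current threshold (ct) is the lowest injected current eliciting at
#' least one accepted AP. The 2xct sweep is the sweep whose amplitude is
#' nearest to twice the threshold (ties to the lower amplitude); the
#' maximum-activity sweep is the one with the most APs (ties to the lowest
#' amplitude).
#'
#' @param s A [sweepset()].
#' @param counts Optional precomputed per-sweep AP counts.
#' @return One-row tibble: `ct` (pA), `sweep_ct`, `sweep_2xct`, `sweep_max`
#'   (sweep indices), `saturated` (is the AP count non-increasing over the two
#'   highest amplitudes?).
#' @export
current_threshold <- function(s, counts = NULL) {
  counts <- counts %||% sweep_ap_counts(s)
  supra <- which(counts > 0L)
  if (length(supra) == 0L) abort("no current threshold: no sweep fires")
  sweep_ct <- supra[which.min(s$current_pa[supra])]
  ct <- s$current_pa[sweep_ct]
  d2 <- abs(s$current_pa - 2 * ct)
  cand <- which(d2 == min(d2))
  sweep_2xct <- cand[which.min(s$current_pa[cand])]
  mx <- which(counts == max(counts))
  sweep_max <- mx[which.min(s$current_pa[mx])]
  nsw <- length(counts)
  saturated <- nsw >= 2 && counts[nsw] <= counts[nsw - 1]
  tibble(ct = ct, sweep_ct = sweep_ct, sweep_2xct = sweep_2xct,
         sweep_max = sweep_max, saturated = saturated)
}

# per-level feature block: first-AP waveform descriptors + train statistics
level_block <- function(events, onset_ms) {
  ts <- train_statistics(events, stim_onset_ms = onset_ms)
  first <- events[1, ]
  list(
    n_ap = ts$n_ap, latency = ts$latency_first_ap_ms,
    ahp_v = first$ahp_v, ahp_lat = first$ahp_latency_ms,
    rise = first$max_rise, decay = first$max_decay,
    hw = first$half_width_ms, thr = first$threshold_v, amp = first$amplitude,
    rise_decay = first$rise_decay_ratio, thr_amp = first$thr_amp_ratio,
    rise_hw = first$rise_hw_ratio,
    r12 = ts$amp_ratio_1_2, r23 = ts$amp_ratio_2_3, r1l = ts$amp_ratio_1_last3,
    f0 = ts$initial_inst_freq, adapt = ts$max_adaptation,
    isi_ratio = ts$isi_ratio,
    m2 = ts$mean_first2_isi, s2 = ts$sd_first2_isi,
    disi = ts$delta_isi_1_2, df = ts$delta_f_1_2,
    cv2 = ts$cv2_all, cv2x1 = ts$cv2_excl1, cv2x2 = ts$cv2_excl2
  )
}

#' Extract the canonical feature set from a sweep set
#'
#' Composes AP detection, waveform/AHP/ADP analysis, train statistics, the
#' V-I fit and the cross-sweep adaptation measures at the required stimulus
#' levels (ct, 2xct and, for the 63-property set, the maximum-activity
#' level). Property names and units follow [property_registry()].
#' Maximum-activity features are reported only when firing saturates (AP
#' count non-increasing over the two highest currents); unmeasurable
#' features are `NA`, never silently zero.
#'
#' @param s A [sweepset()].
#' @param set Which property set to extract, 38 or 63.
#' @return A one-row tibble: `cell_id` plus one column per canonical
#'   property.
#' @export
extract_features <- function(s, set = 38) {
  set <- as.character(set[[1]])
  if (!set %in% c("38", "63")) abort("`set` must be 38 or 63")
  win <- c(s$stim_onset, s$stim_onset + s$stim_duration)
  onset_ms <- s$stim_onset * 1000
  rate <- s$sampling_rate
  events <- lapply(s$voltages, detect_aps, sampling_rate = rate, window = win)
  counts <- vapply(events, nrow, integer(1))
  ctinfo <- current_threshold(s, counts = counts)
  pp <- passive_properties(s)

  ev_ct <- events[[ctinfo$sweep_ct]]
  ev_2x <- events[[ctinfo$sweep_2xct]]
  ev_mx <- events[[ctinfo$sweep_max]]
  b_ct <- level_block(ev_ct, onset_ms)
  b_2x <- level_block(ev_2x, onset_ms)
  b_mx <- level_block(ev_mx, onset_ms)

  out <- stats::setNames(rep(NA_real_, as.integer(set)),
                         canonical_properties(set))
  if (set == "38") {
    adp <- detect_adp(s$voltages[[ctinfo$sweep_ct]], rate, ev_ct, window = win)
    sweep_stats <- tibble(current_pa = s$current_pa, n_ap = counts,
                          initial_inst_freq = vapply(events, function(e)
                            if (nrow(e) >= 2) 1000 / diff(e$peak_time_ms)[1]
                            else NA_real_, numeric(1)))
    ia <- initial_adaptation(sweep_stats, ctinfo$ct)
    out[1:16] <- c(pp$rmp, pp$rm, ctinfo$ct,
                   as.numeric(adp$present), adp$integrated_amplitude,
                   ia$max_change, ia$peak_level_rel,
                   ia$max_change_v2, ia$peak_level_rel_v2,
                   b_ct$ahp_v, b_ct$ahp_lat, b_ct$rise, b_ct$decay,
                   b_ct$hw, b_ct$thr, b_ct$amp)
    out[17:38] <- c(b_2x$n_ap, b_2x$latency, b_2x$ahp_v, b_2x$ahp_lat,
                    b_2x$rise, b_2x$decay, b_2x$hw, b_2x$thr, b_2x$amp,
                    b_2x$r12, b_2x$r23, b_2x$r1l, b_2x$f0, b_2x$adapt,
                    b_2x$isi_ratio, b_2x$m2, b_2x$s2, b_2x$disi, b_2x$df,
                    b_2x$cv2, b_2x$cv2x1, b_2x$cv2x2)
  } else {
    fill25 <- function(b) c(b$n_ap, b$latency, b$ahp_v, b$ahp_lat, b$rise,
                            b$decay, b$hw, b$thr, b$amp, b$rise_decay,
                            b$thr_amp, b$rise_hw, b$r12, b$r23, b$r1l,
                            b$f0, b$adapt, b$isi_ratio, b$m2, b$s2,
                            b$disi, b$df, b$cv2, b$cv2x1, b$cv2x2)
    out[1:3] <- c(pp$rmp, pp$rm, ctinfo$ct)
    out[4:13] <- c(b_ct$ahp_v, b_ct$ahp_lat, b_ct$rise, b_ct$decay, b_ct$hw,
                   b_ct$thr, b_ct$amp, b_ct$rise_decay, b_ct$thr_amp,
                   b_ct$rise_hw)
    out[14:38] <- fill25(b_2x)
    if (isTRUE(ctinfo$saturated)) out[39:63] <- fill25(b_mx)
  }
  dplyr::bind_cols(tibble(cell_id = s$cell_id),
                   as_tibble(as.list(out), .name_repair = "minimal"))
}
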