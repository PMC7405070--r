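# Spike-train statistics: adaptation, burstiness, Cv2 variability.

#' Spike-train statistics for one sweep
#'
#' Interspike intervals (ISIs) run between consecutive AP peaks; the
#' instantaneous frequency is the reciprocal of the ISI (Hz). Frequency
#' adaptation is the initial first-pair instantaneous frequency minus the
#' mean instantaneous frequency of the last three APs (the frequencies of the
#' last three inter-AP intervals when at least four ISIs exist, otherwise the
#' last two); the ISI ratio is final/initial. Cv2 for an ISI pair is
#' `2|ISI[i+1] - ISI[i]| / (ISI[i+1] + ISI[i])`; `cv2_all` averages over all
#' consecutive pairs, `cv2_excl1`/`cv2_excl2` drop the first one/two ISIs
#' first. Adaptation statistics require at least five APs; statistics whose
#' requirements are not met are `NA`, never silently zero.
#'
#' @param events Event tibble from [detect_aps()].
#' @param stim_onset_ms Stimulus onset in ms from trace start; latency to the
#'   first AP is measured from here to the first threshold crossing.
#' @return A one-row tibble of train statistics (`n_ap`,
#'   `latency_first_ap_ms`, `initial_inst_freq`, `max_adaptation`,
#'   `isi_ratio`, `mean_first2_isi`, `sd_first2_isi`, `delta_isi_1_2`,
#'   `delta_f_1_2`, `cv2_all`, `cv2_excl1`, `cv2_excl2`, `amp_ratio_1_2`,
#'   `amp_ratio_2_3`, `amp_ratio_1_last3`, plus `isis` and `inst_freqs`
#'   list-columns).
#' @export
train_statistics <- function(events, stim_onset_ms = 0) {
  n <- nrow(events)
  isis <- if (n >= 2) diff(events$peak_time_ms) else numeric()
  inst <- 1000 / isis
  amp <- events$amplitude
  cv2_of <- function(x) {
    if (length(x) < 2) return(NA_real_)
    mean(2 * abs(diff(x)) / (x[-1] + x[-length(x)]))
  }
  ni <- length(isis)
  init <- if (ni >= 1) inst[1] else NA_real_
  final <- if (n >= 5) mean(utils::tail(inst, 3)) else NA_real_
  tibble(
    n_ap = n,
    latency_first_ap_ms = if (n >= 1)
      events$threshold_time_ms[1] - stim_onset_ms else NA_real_,
    initial_inst_freq = init,
    max_adaptation = if (n >= 5) init - final else NA_real_,
    isi_ratio = if (n >= 5) final / init else NA_real_,
    mean_first2_isi = if (ni >= 2) mean(isis[1:2]) else NA_real_,
    sd_first2_isi = if (ni >= 2) stats::sd(isis[1:2]) else NA_real_,
    delta_isi_1_2 = if (ni >= 2) isis[2] - isis[1] else NA_real_,
    delta_f_1_2 = if (ni >= 2) inst[2] - inst[1] else NA_real_,
    cv2_all = cv2_of(isis),
    cv2_excl1 = if (ni >= 3) cv2_of(isis[-1]) else NA_real_,
    cv2_excl2 = if (ni >= 4) cv2_of(isis[-(1:2)]) else NA_real_,
    amp_ratio_1_2 = if (n >= 2) amp[1] / amp[2] else NA_real_,
    amp_ratio_2_3 = if (n >= 3) amp[2] / amp[3] else NA_real_,
    amp_ratio_1_last3 = if (n >= 4) amp[1] / mean(utils::tail(amp, 3)) else NA_real_,
    isis = list(isis),
    inst_freqs = list(inst)
  )
}

#' Cross-sweep initial-adaptation change
#'
#' The maximum, over consecutive suprathreshold sweeps, of the change in
#' first-pair instantaneous frequency divided by the current difference
#' (Hz/pA), with the current level where the maximum occurred expressed
#' relative to the current threshold. The second variant ignores the
#' current-threshold sweep (and, by construction, any sweep with fewer than
#' two APs, for which no pair frequency exists).
#'
#' @param sweep_stats Tibble with one row per sweep: `current_pa`, `n_ap`,
#'   `initial_inst_freq`.
#' @param ct Current threshold, pA.
#' @return One-row tibble: `max_change`, `peak_level_rel`, `max_change_v2`,
#'   `peak_level_rel_v2`; `NA` when fewer than two eligible sweeps exist.
#' @export
initial_adaptation <- function(sweep_stats, ct) {
  eligible <- sweep_stats[sweep_stats$n_ap >= 2 &
                            sweep_stats$current_pa >= ct &
                            !is.na(sweep_stats$initial_inst_freq), ]
  eligible <- eligible[order(eligible$current_pa), ]
  pair_max <- function(df) {
    if (nrow(df) < 2) return(c(NA_real_, NA_real_))
    dfreq <- diff(df$initial_inst_freq)
    dcur <- diff(df$current_pa)
    change <- dfreq / dcur
    k <- which.max(change)
    c(change[k], df$current_pa[k + 1] / ct)
  }
  v1 <- pair_max(eligible)
  v2 <- pair_max(eligible[eligible$current_pa > ct, ])
  tibble(max_change = v1[1], peak_level_rel = v1[2],
         max_change_v2 = v2[1], peak_level_rel_v2 = v2[2])
}
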