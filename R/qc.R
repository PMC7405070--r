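# Recording quality control: the exclusion rules applied before any feature
# enters clustering or classification.

#' Quality-control check for a recording
#'
#' Applies the recording exclusion rules: access resistance above 30 MOhm,
#' Ra/Rm ratio above 20%, resting potential less negative than -50 mV or
#' drifting by more than 5 mV across the sweep family, action potentials
#' failing to overshoot 0 mV, and (for interneuron maximum-activity features)
#' firing frequency that does not saturate at the highest current.
#'
#' @param rmp Resting membrane potential (mV).
#' @param ra Access resistance (MOhm).
#' @param rm Membrane resistance (MOhm).
#' @param ap_peaks Peak potentials (mV) of the accepted action potentials;
#'   empty or `NULL` skips the overshoot rule.
#' @param saturated Logical; did the AP count saturate at the highest current?
#'   `NA` skips the rule (it only gates maximum-activity features).
#' @param rmp_drift Absolute baseline drift between first and last sweep (mV);
#'   `NA` skips the stability rule.
#' @param ra_limit,ra_rm_limit,rmp_limit,drift_limit Rule thresholds.
#' @return A one-row tibble of class `qc_report`: `passed` plus one logical
#'   column per rule and a `reasons` list-column of failed rule identifiers
#'   (`ra_exceeds`, `ra_rm_ratio`, `rmp_unstable_or_high`, `no_overshoot`,
#'   `no_saturation`). `passed` is `TRUE` iff `reasons` is empty.
#' @export
#' @examples
#' qc_check(rmp = -72, ra = 18.9, rm = 227)
qc_check <- function(rmp = NA_real_, ra = NA_real_, rm = NA_real_,
                     ap_peaks = NULL, saturated = NA,
                     rmp_drift = NA_real_,
                     ra_limit = 30, ra_rm_limit = 0.20, rmp_limit = -50,
                     drift_limit = 5) {
  reasons <- character()
  if (!is.na(ra) && ra > ra_limit) reasons <- c(reasons, "ra_exceeds")
  if (!is.na(ra) && !is.na(rm) && ra / rm > ra_rm_limit)
    reasons <- c(reasons, "ra_rm_ratio")
  if ((!is.na(rmp) && rmp > rmp_limit) ||
      (!is.na(rmp_drift) && abs(rmp_drift) > drift_limit))
    reasons <- c(reasons, "rmp_unstable_or_high")
  if (length(ap_peaks) > 0 && any(ap_peaks <= 0, na.rm = TRUE))
    reasons <- c(reasons, "no_overshoot")
  if (!is.na(saturated) && !isTRUE(saturated))
    reasons <- c(reasons, "no_saturation")
  out <- tibble(passed = length(reasons) == 0L, reasons = list(reasons))
  class(out) <- c("qc_report", class(out))
  out
}
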