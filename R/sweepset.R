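# SweepSet: one cell's family of current-step recordings.

#' Construct a sweep set
#'
#' A `sweepset` bundles a cell's family of current-step recordings: one
#' voltage trace per injected current level, all sampled at the same rate,
#' with a common stimulus window (default: 1-s step starting 0.1 s into the
#' sweep).
#'
#' @param voltages List of numeric vectors, membrane potential in mV, one per
#'   sweep. All sweeps must have the same length.
#' @param current_pa Numeric vector of injected current amplitudes (pA), one
#'   per sweep.
#' @param sampling_rate Sampling rate in Hz.
#' @param stim_onset Stimulus onset within the sweep, seconds.
#' @param stim_duration Stimulus duration, seconds. A warning is issued when
#'   this differs from 1 s by more than one sample unless
#'   `check_stimulus = FALSE`.
#' @param cell_id Cell identifier.
#' @param temperature Bath temperature, degrees Celsius.
#' @param access_resistance Pipette access resistance Ra (MOhm), optional.
#' @param check_stimulus Enforce the 1-s stimulus convention.
#' @return An object of class `sweepset`.
#' @export
sweepset <- function(voltages, current_pa, sampling_rate,
                     stim_onset = 0.1, stim_duration = 1.0,
                     cell_id = "cell", temperature = NA_real_,
                     access_resistance = NA_real_, check_stimulus = TRUE) {
  if (!is.list(voltages) || length(voltages) == 0L)
    abort("`voltages` must be a non-empty list of numeric traces")
  lens <- lengths(voltages)
  if (length(unique(lens)) != 1L)
    abort("all sweeps must have the same length")
  if (length(current_pa) != length(voltages))
    abort("`current_pa` must have one amplitude per sweep")
  if (anyNA(current_pa)) abort("current amplitudes must not be missing")
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive")
  n <- lens[[1]]
  if (stim_onset < 0 || (stim_onset + stim_duration) * sampling_rate > n + 1e-6)
    abort("stimulus window must lie within the sweep")
  if (check_stimulus && abs(stim_duration - 1.0) > 1 / sampling_rate + 1e-12)
    warn("stimulus duration differs from the 1-s convention")
  ord <- order(current_pa)
  structure(
    list(cell_id = as.character(cell_id),
         voltages = lapply(voltages[ord], as.numeric),
         current_pa = as.numeric(current_pa[ord]),
         sampling_rate = as.numeric(sampling_rate),
         stim_onset = as.numeric(stim_onset),
         stim_duration = as.numeric(stim_duration),
         temperature = as.numeric(temperature),
         access_resistance = as.numeric(access_resistance)),
    class = "sweepset")
}

#' @export
print.sweepset <- function(x, ...) {
  cat(sprintf("<sweepset> cell '%s': %d sweeps x %d samples @ %g kHz\n",
              x$cell_id, length(x$voltages), length(x$voltages[[1]]),
              x$sampling_rate / 1000))
  cat(sprintf("  currents: %s pA\n", paste(x$current_pa, collapse = ", ")))
  cat(sprintf("  stimulus: %g-%g s; temperature: %s degC\n",
              x$stim_onset, x$stim_onset + x$stim_duration,
              format(x$temperature)))
  invisible(x)
}

#' @export
length.sweepset <- function(x) length(x$voltages)

#' Tidy a sweep set into a long tibble
#'
#' @param x A `sweepset`.
#' @param ... Unused.
#' @return A tibble with columns `cell_id`, `sweep`, `current_pa`, `time_s`,
#'   `voltage_mv`.
#' @export
as_tibble.sweepset <- function(x, ...) {
  n <- length(x$voltages[[1]])
  t <- (seq_len(n) - 1L) / x$sampling_rate
  purrr::map2_dfr(seq_along(x$voltages), x$current_pa, function(i, amp) {
    tibble(cell_id = x$cell_id, sweep = i, current_pa = amp,
           time_s = t, voltage_mv = x$voltages[[i]])
  })
}

# index of samples inside the stimulus window
stim_index <- function(s) {
  i0 <- floor(s$stim_onset * s$sampling_rate) + 1L
  i1 <- min(floor((s$stim_onset + s$stim_duration) * s$sampling_rate),
            length(s$voltages[[1]]))
  i0:i1
}

#' Plot a sweep set
#'
#' @param object A `sweepset`.
#' @param ... Unused.
#' @return A ggplot object: voltage traces stacked by injected current.
#' @export
autoplot.sweepset <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$voltage_mv,
                                   group = .data$sweep,
                                   colour = factor(.data$current_pa))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "membrane potential (mV)",
                  colour = "current (pA)",
                  title = object$cell_id) +
    ggplot2::theme_minimal()
}
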