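# Plain-text sweep and feature-table formats.
#
# Sweep CSV dialect: one column `time_s`, one column per sweep named
# `I_<pA>` (e.g. `I_-60`, `I_120`), UTF-8, '.' decimal separator.

#' Read a sweep CSV file
#'
#' @param path File in the sweep CSV dialect (`time_s` plus `I_<pA>` columns).
#' @param stim_onset,stim_duration Stimulus window (seconds); the file format
#'   carries no protocol metadata, so the 0.1-s onset / 1-s duration
#'   convention is assumed unless overridden.
#' @param cell_id Cell identifier; defaults to the file name.
#' @param temperature Bath temperature (degrees Celsius).
#' @return A [sweepset()].
#' @export
read_sweep_csv <- function(path, stim_onset = 0.1, stim_duration = 1.0,
                           cell_id = NULL, temperature = NA_real_) {
  df <- ct_read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  if (!"time_s" %in% names(df)) abort("sweep CSV must have a `time_s` column")
  icols <- grep("^I_", names(df), value = TRUE)
  if (length(icols) == 0L) abort("sweep CSV must have at least one `I_<pA>` column")
  amps <- as.numeric(sub("^I_", "", icols))
  if (anyNA(amps)) abort("sweep column names must encode the current in pA, e.g. `I_-60`")
  dt <- diff(df$time_s)
  if (any(abs(dt - dt[1]) > 1e-9)) abort("`time_s` must be uniformly sampled")
  sweepset(voltages = lapply(icols, function(cn) df[[cn]]),
           current_pa = amps,
           sampling_rate = 1 / dt[1],
           stim_onset = stim_onset, stim_duration = stim_duration,
           cell_id = cell_id %||% sub("\\.[^.]*$", "", basename(path)),
           temperature = temperature)
}

#' Write a sweep set to the sweep CSV dialect
#'
#' @param s A [sweepset()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(s, path) {
  n <- length(s$voltages[[1]])
  df <- c(list(time_s = (seq_len(n) - 1L) / s$sampling_rate),
          stats::setNames(s$voltages, paste0("I_", format(s$current_pa,
                                                          trim = TRUE,
                                                          scientific = FALSE))))
  readr::write_csv(as_tibble(df), path)
  invisible(path)
}

#' Read a feature table CSV
#'
#' Columns are matched against the canonical property registry, including the
#' accepted spelling variants of the source tables. A `cell_id` column is
#' carried through when present.
#'
#' @param path CSV file with one row per cell.
#' @param set Which property set the header should be matched against
#'   (38 or 63).
#' @param unknown What to do with unrecognized columns: `"warn"` keeps the
#'   recognized columns and warns, `"error"` aborts.
#' @return A tibble with `cell_id` plus canonical property columns; missing
#'   values are preserved as `NA`.
#' @export
read_feature_csv <- function(path, set = 38, unknown = c("warn", "error")) {
  unknown <- match.arg(unknown)
  df <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                        locale = readr::locale(encoding = "UTF-8"),
                        name_repair = "minimal")
  if (anyDuplicated(names(df))) abort("duplicated column names in feature CSV")
  id <- df[["cell_id"]] %||% paste0("cell", seq_len(nrow(df)))
  feat <- df[, setdiff(names(df), "cell_id"), drop = FALSE]
  canon <- resolve_property_names(names(feat), set = set)
  if (all(is.na(canon))) abort("no recognizable feature columns for this property set")
  if (anyNA(canon)) {
    bad <- names(feat)[is.na(canon)]
    msg <- paste0("unrecognized feature columns dropped: ",
                  paste(bad, collapse = ", "))
    if (unknown == "error") abort(msg) else warn(msg)
  }
  keep <- !is.na(canon)
  if (anyDuplicated(canon[keep])) abort("two columns resolve to the same canonical property")
  feat <- feat[, keep, drop = FALSE]
  names(feat) <- canon[keep]
  feat[] <- lapply(feat, as.numeric)
  dplyr::bind_cols(tibble(cell_id = as.character(id)), as_tibble(feat))
}

#' Write a feature table CSV
#'
#' @param features Tibble with `cell_id` and canonical property columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
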