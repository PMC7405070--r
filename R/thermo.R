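# Temperature sensitivity: Q10 coefficients and feature correction between
# recording temperatures.

#' Temperature coefficient Q10
#'
#' `Q10 = (P2 / P1) ^ (10 / (T2 - T1))`, the factor by which a property
#' changes per 10 degC rise. For negative-valued properties (AHP amplitudes,
#' decay rates) the ratio of magnitudes is used, since the expression is
#' undefined across sign changes; mixed-sign or zero inputs yield `NA`.
#'
#' @param p1,p2 Property values at temperatures `t1` and `t2`.
#' @param t1,t2 Temperatures, degrees Celsius (`t1 != t2`).
#' @return Q10 value(s); `NA` where undefined.
#' @export
#' @examples
#' q10(100, 200, 24, 34)  # exactly 2
q10 <- function(p1, p2, t1, t2) {
  if (any(t1 == t2)) abort("`t1` and `t2` must differ")
  out <- rep(NA_real_, length(p1))
  ok <- !is.na(p1) & !is.na(p2) & p1 != 0 & p2 != 0 & sign(p1) == sign(p2)
  out[ok] <- (abs(p2[ok]) / abs(p1[ok]))^(10 / (t2 - t1))
  out
}

#' Aggregate per-cell Q10 values into a Q10 table
#'
#' Per property, values outside the fence `[Q1 - 3 IQR, Q3 + 3 IQR]` are
#' discarded as outliers; the mean and SEM of the survivors are reported.
#'
#' @param per_cell Tibble with columns `property` and `q10` (one row per cell
#'   and property).
#' @param reference Reference temperature the table corrects to, degC.
#' @return A `q10_table` tibble: `property`, `mean_q10`, `sem`, `n`. A
#'   property whose values are all discarded (or all missing) is dropped.
#' @export
aggregate_q10 <- function(per_cell, reference = 24) {
  if (!all(c("property", "q10") %in% names(per_cell)))
    abort("`per_cell` needs columns `property` and `q10`")
  counts <- table(per_cell$property[!is.na(per_cell$q10)])
  if (any(counts < 3))
    abort("need at least 3 cells per property to aggregate Q10 values")
  out <- per_cell |>
    dplyr::filter(!is.na(.data$q10)) |>
    dplyr::group_by(.data$property) |>
    dplyr::group_modify(function(df, key) {
      q <- stats::quantile(df$q10, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      keep <- df$q10 >= q[1] - 3 * iqr & df$q10 <= q[2] + 3 * iqr
      x <- df$q10[keep]
      if (length(x) == 0L) return(tibble())
      tibble(mean_q10 = mean(x),
             sem = stats::sd(x) / sqrt(length(x)),
             n = length(x))
    }) |>
    dplyr::ungroup()
  attr(out, "reference") <- reference
  class(out) <- c("q10_table", class(out))
  out
}

#' The shipped claustral Q10 table
#'
#' Per-property mean and SEM of the temperature coefficients measured between
#' 24 degC and 30 degC, referenced to 24 degC.
#'
#' @return A `q10_table` tibble: `property`, `mean_q10`, `sem`.
#' @export
claustrum_q10_table <- function() {
  if (is.null(.registry_env$q10)) {
    q <- ct_read_csv(ct_extdata("q10_table.csv"),
                     col_types = readr::cols(property = readr::col_character(),
                                             mean_q10 = readr::col_double(),
                                             sem = readr::col_double()))
    attr(q, "reference") <- 24
    class(q) <- c("q10_table", class(q))
    .registry_env$q10 <- q
  }
  .registry_env$q10
}

q10_factor <- function(labels, set, q, delta_t) {
  keys <- q10_key_for(labels, set = set)
  hit <- match(keys, q$property)
  f <- rep(NA_real_, length(labels))
  f[!is.na(hit)] <- q$mean_q10[hit[!is.na(hit)]]^(delta_t / 10)
  f
}

scale_features <- function(features, factors, divide) {
  props <- setdiff(names(features), c("cell_id", "label"))
  uncovered <- props[is.na(factors)]
  if (length(uncovered))
    warn(paste0("no Q10 coefficient for ",
                length(uncovered), " properties; passed through unchanged"))
  for (i in seq_along(props)) {
    f <- factors[i]
    if (is.na(f)) next
    x <- features[[props[i]]]
    features[[props[i]]] <- sign(x) * (abs(x) * if (divide) 1 / f else f)
  }
  features
}

#' Correct features to the reference temperature
#'
#' Each covered property is divided by `Q10 ^ ((recorded_t - reference)/10)`,
#' on magnitudes with the sign restored (so negative-valued properties scale
#' like their magnitudes). Properties without a Q10 entry pass through with a
#' warning; missing values stay missing.
#'
#' @param features Feature tibble (`cell_id` plus canonical properties).
#' @param recorded_t Temperature the features were measured at, degC.
#' @param q A `q10_table`; defaults to the shipped claustral table.
#' @param set Property set the columns belong to (38 or 63).
#' @param reference Reference temperature, degC.
#' @return Feature tibble corrected to `reference`.
#' @export
correct_to_reference <- function(features, recorded_t,
                                 q = claustrum_q10_table(), set = 38,
                                 reference = attr(q, "reference") %||% 24) {
  props <- setdiff(names(features), c("cell_id", "label"))
  f <- q10_factor(props, set, q, recorded_t - reference)
  scale_features(features, f, divide = TRUE)
}

#' Shift features to another temperature
#'
#' The forward transform (multiplication by the Q10 factor), used to emulate
#' recordings at a warmer or cooler bath; [correct_to_reference()] is its
#' inverse.
#'
#' @inheritParams correct_to_reference
#' @param from,to Temperatures, degC.
#' @return Feature tibble shifted to temperature `to`.
#' @export
shift_to_temperature <- function(features, from = 24, to = 30,
                                 q = claustrum_q10_table(), set = 38) {
  props <- setdiff(names(features), c("cell_id", "label"))
  f <- q10_factor(props, set, q, to - from)
  scale_features(features, f, divide = FALSE)
}
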