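# Canonical property registry: printed labels, units, stimulus level tags,
# sampling family and physical bounds for the 38- and 63-property sets.

.registry_env <- new.env(parent = emptyenv())

ct_extdata <- function(file) {
  path <- system.file("extdata", file, package = "claustrotype")
  if (!nzchar(path)) abort(paste0("extdata file not found: ", file))
  path
}

ct_read_csv <- function(path, col_types) {
  readr::read_csv(path, col_types = col_types, progress = FALSE,
                  locale = readr::locale(encoding = "UTF-8"))
}

#' Canonical property registry
#'
#' The registry fixes the vocabulary of the package: every feature table and
#' feature vector uses these printed labels, with the stated units. The
#' 38-property set describes a cell at the current threshold (ct) and at twice
#' the threshold (2xct) plus cross-sweep adaptation measures; the 63-property
#' set adds the maximal-firing ("Max AP") level and waveform-ratio properties
#' and is used for interneuron work.
#'
#' @param set Which property set, `38` or `63`.
#' @return A tibble with one row per property: `index`, `label` (canonical
#'   printed name), `unit`, `level` (`base`, `ct`, `2xct`, `max` or `train`),
#'   `family` (sampling family used by the cohort generator), `lo`/`hi`
#'   (physical clipping bounds, `NA` when unbounded), `map63` (for the 38-set,
#'   the index of the matching 63-set property, `NA` when the property has no
#'   63-set counterpart) and `aliases` (list column of accepted spelling
#'   variants).
#' @export
#' @examples
#' property_registry(38)$label[1:3]
property_registry <- function(set = 38) {
  set <- as.character(set[[1]])
  if (!set %in% c("38", "63")) abort("`set` must be 38 or 63")
  if (is.null(.registry_env$registry)) {
    reg <- ct_read_csv(ct_extdata("property_registry.csv"),
                       col_types = readr::cols(
                         set = readr::col_character(),
                         index = readr::col_integer(),
                         label = readr::col_character(),
                         unit = readr::col_character(),
                         level = readr::col_character(),
                         family = readr::col_character(),
                         lo = readr::col_double(),
                         hi = readr::col_double(),
                         map63 = readr::col_integer(),
                         aliases = readr::col_character()
                       ))
    reg$aliases <- lapply(reg$aliases, function(a) {
      if (is.na(a) || !nzchar(a)) character() else strsplit(a, "|", fixed = TRUE)[[1]]
    })
    .registry_env$registry <- reg
  }
  .registry_env$registry[.registry_env$registry$set == set, ]
}

#' Canonical property labels
#'
#' @param set Which property set, `38` or `63`.
#' @return Character vector of canonical labels, in table order.
#' @export
canonical_properties <- function(set = 38) property_registry(set)$label

#' Resolve property names against the registry
#'
#' Maps printed labels (including accepted spelling variants from the source
#' tables) onto canonical registry labels.
#'
#' @param x Character vector of property names.
#' @param set Which property set, `38` or `63`.
#' @return Character vector of canonical labels, `NA` where unrecognized.
#' @export
resolve_property_names <- function(x, set = 38) {
  reg <- property_registry(set)
  out <- rep(NA_character_, length(x))
  out[x %in% reg$label] <- x[x %in% reg$label]
  alias_tab <- tidyr::unnest(reg[, c("label", "aliases")], "aliases")
  hit <- match(x, alias_tab$aliases)
  out[is.na(out) & !is.na(hit)] <- alias_tab$label[hit[is.na(out) & !is.na(hit)]]
  out
}

# q10 lookup key for a property label: 63-set labels are the reference
# vocabulary of the temperature table; 38-set labels map through `map63`
# where a counterpart exists, otherwise they stand for themselves.
q10_key_for <- function(labels, set = 38) {
  reg <- property_registry(set)
  idx <- match(labels, reg$label)
  keys <- labels
  if (set == 38 || identical(set, "38")) {
    reg63 <- property_registry(63)
    has_map <- !is.na(idx) & !is.na(reg$map63[idx])
    keys[has_map] <- reg63$label[match(reg$map63[idx[has_map]], reg63$index)]
  }
  keys
}
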