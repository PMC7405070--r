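# Synthetic feature-table cohorts sampled from the published subtype
# distributions, so clustering and classification can be exercised without
# raw recordings.

.in_subtype_n <- c(PV = 19, SST = 28, VIP = 30)

load_proto_csv <- function(file) {
  ct_read_csv(ct_extdata(file), col_types = readr::cols())
}

scale_floor <- function(scale, fallback, center) {
  out <- scale
  out[!is.finite(out) | out <= 0] <- fallback[!is.finite(out) | out <= 0]
  bad <- !is.finite(out) | out <= 0
  out[bad] <- pmax(0.02 * abs(center[bad]), 0.01)
  out
}

#' Subtype prototypes for the cohort sampler
#'
#' Per-subtype sampling parameters for each canonical property. PN subtypes
#' are centred on the published medians with scale `1.4826 x MAD` (the normal
#' MAD-to-SD factor); IN subtypes are centred on the published means with
#' scale `SEM x sqrt(n)` (n = 19 PV, 28 SST, 30 VIP). Where a printed
#' dispersion is zero the other printed dispersion (or 2% of the centre) is
#' used so every prototype has a positive scale. The six 38-set properties
#' not tabulated per IN subtype (ADP and cross-sweep adaptation measures)
#' inherit the IN population distribution for all three IN subtypes.
#'
#' @param set Property set, 38 or 63. The 63-property set exists for the IN
#'   subtypes only.
#' @return Tibble: `subtype`, `index`, `label`, `center`, `scale`, `family`,
#'   `lo`, `hi`.
#' @export
subtype_prototypes <- function(set = 38) {
  set <- as.character(set[[1]])
  reg <- property_registry(set)
  in63 <- load_proto_csv("prototypes_in_63.csv")
  in_rows <- function(labels63) {
    purrr::map_dfr(names(.in_subtype_n), function(st) {
      df <- in63[in63$subtype == st, ]
      df <- df[match(labels63, df$label), ]
      tibble(subtype = st, label63 = labels63,
             center = df$mean,
             scale = scale_floor(df$sem * sqrt(.in_subtype_n[[st]]),
                                 1.4826 * df$mad, df$mean))
    })
  }
  if (set == "63") {
    pro <- in_rows(reg$label)
    pro$label <- pro$label63
  } else {
    pn <- load_proto_csv("prototypes_pn.csv")
    pn_pro <- tibble(subtype = pn$subtype, label = pn$label,
                     center = pn$median,
                     scale = scale_floor(1.4826 * pn$mad, pn$sem, pn$median))
    reg63 <- property_registry(63)
    mapped <- !is.na(reg$map63)
    in_mapped <- in_rows(reg63$label[match(reg$map63[mapped], reg63$index)])
    in_mapped$label <- rep(reg$label[mapped], times = length(.in_subtype_n))
    popu <- load_proto_csv("population_38.csv")
    unm <- popu[match(reg$label[!mapped], popu$label), ]
    in_unmapped <- purrr::map_dfr(names(.in_subtype_n), function(st) {
      tibble(subtype = st, label = unm$label,
             center = unm$in_mean,
             scale = scale_floor(unm$in_sem * sqrt(152),
                                 1.4826 * unm$in_mad, unm$in_mean))
    })
    pro <- dplyr::bind_rows(pn_pro, in_mapped[, c("subtype", "label", "center", "scale")],
                            in_unmapped)
  }
  pro$label63 <- NULL
  ri <- match(pro$label, reg$label)
  pro$index <- reg$index[ri]
  pro$family <- reg$family[ri]
  pro$lo <- reg$lo[ri]
  pro$hi <- reg$hi[ri]
  dplyr::arrange(pro[, c("subtype", "index", "label", "center", "scale",
                         "family", "lo", "hi")],
                 .data$subtype, .data$index)
}

draw_property <- function(n, center, scale, family, lo, hi) {
  if (identical(family, "lognormal") && center > 0) {
    sigma2 <- log(1 + (scale / center)^2)
    x <- stats::rlnorm(n, meanlog = log(center) - sigma2 / 2,
                       sdlog = sqrt(sigma2))
  } else {
    x <- stats::rnorm(n, center, scale)
  }
  if (!is.na(lo)) x <- pmax(x, lo)
  if (!is.na(hi)) x <- pmin(x, hi)
  x
}

#' Default cohort sizes
#'
#' Cohort sizes matching the study proportions: 174 PNs (split evenly over
#' PN1-PN5) and 152 INs (19:28:30 PV:SST:VIP, scaled); the IN-subtype stage
#' uses the labeled-IN proportions scaled four-fold.
#'
#' @param stage `"population"` (all eight subtypes), `"pn"` or `"in"`.
#' @return Named integer vector of cells per subtype.
#' @export
cohort_counts <- function(stage = c("population", "pn", "in")) {
  stage <- match.arg(stage)
  pn <- c(PN1 = 35L, PN2 = 35L, PN3 = 35L, PN4 = 35L, PN5 = 34L)
  inn <- c(PV = 38L, SST = 55L, VIP = 59L)   # 152 in 19:28:30 proportion
  switch(stage,
         population = c(pn, inn),
         pn = pn,
         `in` = 4L * .in_subtype_n)
}

#' Sample a synthetic feature-table cohort
#'
#' Independent draws per property from the subtype prototypes (normal, or
#' log-normal for strictly positive heavy-tailed properties), clipped to
#' physical ranges. The same seed reproduces the table exactly.
#'
#' @param counts Named integer vector of cells per subtype (see
#'   [cohort_counts()]).
#' @param set Property set, 38 or 63.
#' @param seed Random seed (mandatory for reproducibility).
#' @return Tibble: `cell_id`, `label` (subtype), plus property columns in
#'   registry order.
#' @export
sample_cohort <- function(counts, set = 38, seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  pro <- subtype_prototypes(set)
  unknown <- setdiff(names(counts), unique(pro$subtype))
  if (length(unknown))
    abort(paste0("unknown subtype(s): ", paste(unknown, collapse = ", ")))
  labels <- canonical_properties(set)
  set.seed(seed)
  out <- purrr::map_dfr(names(counts), function(st) {
    nk <- counts[[st]]
    if (nk == 0L) return(tibble())
    sub <- pro[pro$subtype == st, ]
    sub <- sub[match(labels, sub$label), ]
    cols <- lapply(seq_len(nrow(sub)), function(i)
      draw_property(nk, sub$center[i], sub$scale[i], sub$family[i],
                    sub$lo[i], sub$hi[i]))
    dplyr::bind_cols(tibble(cell_id = sprintf("%s_%03d", st, seq_len(nk)),
                            label = st),
                     stats::setNames(as_tibble(cols, .name_repair = "minimal"),
                                     labels))
  })
  out
}

#' The outlier VIP interneuron
#'
#' The single immunohistochemically confirmed VIP interneuron that clustered
#' with the projection neurons: its printed 38-property values, verbatim.
#'
#' @return One-row tibble: `cell_id`, `label`, plus the 38 properties.
#' @export
outlier_vip_vector <- function() {
  df <- load_proto_csv("outlier_vip.csv")
  dplyr::bind_cols(tibble(cell_id = "outlier_VIP", label = "outlierVIP"),
                   stats::setNames(as_tibble(as.list(df$value),
                                             .name_repair = "minimal"),
                                   df$label))
}
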