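# Unsupervised taxonomy: Z-scoring, two hierarchical-clustering regimes and
# silhouette-based choice of the number of clusters.

features_to_matrix <- function(features) {
  id <- features[["cell_id"]] %||% paste0("cell", seq_len(nrow(features)))
  num <- features[, setdiff(names(features), c("cell_id", "label")), drop = FALSE]
  m <- as.matrix(num)
  rownames(m) <- id
  m
}

#' Z-score a feature table
#'
#' Per-property standardization: `(x - mean) / SD` (sample SD, missing values
#' excluded from the moments). Constant properties are set to zero with a
#' warning; missing values are imputed as 0 after scaling, i.e. at the
#' population mean.
#'
#' @param features Tibble with `cell_id` (and optionally `label`) plus
#'   property columns.
#' @return Tibble of the same shape with standardized properties.
#' @export
zscore_features <- function(features) {
  if (nrow(features) < 2L) abort("need at least 2 cells to Z-score")
  keep <- intersect(c("cell_id", "label"), names(features))
  props <- setdiff(names(features), keep)
  constant <- character()
  scaled <- lapply(props, function(p) {
    x <- features[[p]]
    mu <- mean(x, na.rm = TRUE)
    sd_ <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(sd_) || sd_ == 0) {
      constant <<- c(constant, p)
      return(rep(0, length(x)))
    }
    z <- (x - mu) / sd_
    z[is.na(z)] <- 0
    z
  })
  if (length(constant))
    warn(paste0("constant properties set to zero: ",
                paste(constant, collapse = ", ")))
  dplyr::bind_cols(features[, keep, drop = FALSE],
                   stats::setNames(as_tibble(scaled, .name_repair = "minimal"),
                                   props))
}

#' Distance matrix between cells
#'
#' @param features Z-scored feature tibble.
#' @param metric `"pearson"` (correlation distance, `1 - r` between cell
#'   feature profiles) or `"euclidean"`.
#' @return A `dist` object.
#' @export
cell_distances <- function(features, metric = c("pearson", "euclidean")) {
  metric <- match.arg(metric)
  m <- features_to_matrix(features)
  if (anyNA(m)) abort("missing values remain; Z-score (which imputes) first")
  if (metric == "pearson") stats::as.dist(1 - stats::cor(t(m)))
  else stats::dist(m, method = "euclidean")
}

#' Hierarchical clustering of cells
#'
#' The population stage clusters all neurons on Pearson correlation distances
#' with average linkage; subcluster stages (within PNs or INs) use Euclidean
#' distances with Ward linkage.
#'
#' @param features Z-scored feature tibble.
#' @param metric `"pearson"` or `"euclidean"`.
#' @param linkage `"average"` or `"ward"`.
#' @return An `hclust` object with the distance matrix attached as attribute
#'   `"distances"`.
#' @export
hcluster_cells <- function(features, metric = c("pearson", "euclidean"),
                           linkage = c("average", "ward")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  d <- cell_distances(features, metric)
  h <- stats::hclust(d, method = if (linkage == "ward") "ward.D2" else "average")
  attr(h, "distances") <- d
  h
}

#' Cut a dendrogram into k clusters
#'
#' @param h An `hclust` object.
#' @param k Number of clusters, between 2 and the number of cells.
#' @return Integer cluster assignment named by cell.
#' @export
cut_dendrogram <- function(h, k) {
  n <- length(h$order)
  if (k < 2 || k > n) abort("`k` must be between 2 and the number of cells")
  stats::cutree(h, k = k)
}

#' Silhouette curve over candidate cluster numbers
#'
#' Average silhouette width for k = 2 ... `kmax` clusters cut from a
#' dendrogram, computed on the same distances used for clustering.
#' Singleton clusters take width 0. The best k is the argmax of the average
#' width (ties to the smallest k); a maximum below `random_threshold`
#' indicates random structure.
#'
#' @param h An `hclust` from [hcluster_cells()] (carries its distances), or
#'   any `hclust` if `distances` is supplied.
#' @param distances Optional `dist` object.
#' @param kmax Largest number of clusters to evaluate.
#' @param random_threshold Average-width threshold below which structure is
#'   considered random.
#' @return An object of class `silhouette_curve`: list with `curve` (tibble
#'   `k`, `avg_width`), `widths` (per-cell widths by k), `best_k`,
#'   `random_structure`.
#' @export
silhouette_curve <- function(h, distances = NULL, kmax = 9,
                             random_threshold = 0.25) {
  d <- distances %||% attr(h, "distances")
  if (is.null(d)) abort("no distances available; pass `distances`")
  n <- length(h$order)
  ks <- 2:min(kmax, n - 1)
  widths <- lapply(ks, function(k) {
    cl <- stats::cutree(h, k = k)
    sil <- cluster::silhouette(cl, d)
    tibble(cell_id = names(cl) %||% as.character(seq_along(cl)),
           k = k, cluster = sil[, "cluster"], width = sil[, "sil_width"])
  })
  curve <- tibble(k = ks,
                  avg_width = vapply(widths, function(w) mean(w$width),
                                     numeric(1)))
  best_k <- curve$k[which.max(curve$avg_width)]
  structure(list(curve = curve,
                 widths = dplyr::bind_rows(widths),
                 best_k = best_k,
                 random_structure = max(curve$avg_width) < random_threshold),
            class = "silhouette_curve")
}

#' @export
print.silhouette_curve <- function(x, ...) {
  cat("<silhouette_curve>\n")
  print(x$curve)
  cat(sprintf("best k = %d%s\n", x$best_k,
              if (x$random_structure) " (below random-structure threshold)" else ""))
  invisible(x)
}

#' @export
tidy.silhouette_curve <- function(x, ...) x$curve

#' @export
glance.silhouette_curve <- function(x, ...) {
  tibble(best_k = x$best_k,
         max_avg_width = max(x$curve$avg_width),
         random_structure = x$random_structure)
}

#' @export
autoplot.silhouette_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$avg_width)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.25, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$best_k, colour = "red",
                        linetype = "dotted") +
    ggplot2::labs(x = "number of clusters", y = "average silhouette width") +
    ggplot2::theme_minimal()
}
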