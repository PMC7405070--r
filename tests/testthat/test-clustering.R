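planted_blobs <- function(n_per = 10, p = 6, sep = 8, seed = 3) {
  set.seed(seed)
  m <- rbind(matrix(stats::rnorm(n_per * p), n_per),
             matrix(stats::rnorm(n_per * p, sep), n_per))
  tb <- tibble::as_tibble(as.data.frame(m))
  names(tb) <- paste0("f", seq_len(p))
  dplyr::bind_cols(tibble::tibble(cell_id = paste0("c", seq_len(2 * n_per))), tb)
}

test_that("Z-scoring centres, scales, warns on constants and imputes NAs", {
  tb <- tibble::tibble(cell_id = c("a", "b", "c"),
                       x = c(1, 2, 3), k = c(5, 5, 5), y = c(10, NA, 30))
  expect_warning(z <- zscore_features(tb), "constant")
  expect_equal(z$x, c(-1, 0, 1))
  expect_equal(z$k, c(0, 0, 0))
  expect_equal(z$y[2], 0)  # imputed at the mean
  set.seed(1)
  r <- tibble::tibble(cell_id = as.character(1:50), v = stats::rnorm(50, 3, 7))
  zr <- zscore_features(r)
  expect_equal(mean(zr$v), 0, tolerance = 1e-9)
  expect_equal(stats::sd(zr$v), 1, tolerance = 1e-9)
  expect_equal(zr$v, (r$v - mean(r$v)) / stats::sd(r$v))
  expect_error(zscore_features(r[1, ]), "at least 2")
})

test_that("two cells merge at their pairwise distance; duplicates merge first", {
  tb <- planted_blobs(n_per = 1)
  for (metric in c("pearson", "euclidean")) {
    h <- hcluster_cells(tb, metric, if (metric == "pearson") "average" else "ward")
    expect_equal(h$height, as.numeric(cell_distances(tb, metric)))
  }
  tb3 <- planted_blobs(n_per = 3)
  tb3[2, -1] <- tb3[1, -1]  # exact duplicate rows
  h3 <- hcluster_cells(tb3, "euclidean", "average")
  expect_equal(min(h3$height), 0)
  expect_setequal(abs(h3$merge[1, ]), c(1, 2))
})

test_that("merge structure equals the naive agglomerative oracle", {
  tb <- planted_blobs(n_per = 3, p = 5, sep = 4, seed = 11)
  n <- nrow(tb)
  for (cfg in list(c("pearson", "average"), c("euclidean", "ward"))) {
    h <- hcluster_cells(tb, cfg[1], cfg[2])
    d <- cell_distances(tb, cfg[1])
    oracle <- naive_agglomerative(d, if (cfg[2] == "ward") "ward" else "average")
    expect_equal(sort(h$height), sort(oracle$heights), tolerance = 1e-9)
    for (k in 2:(n - 1))
      expect_true(same_partition(cut_dendrogram(h, k), naive_cut(oracle, n, k)))
  }
})

test_that("cutting recovers planted structure; degenerate k errors", {
  tb <- planted_blobs()
  h <- hcluster_cells(tb, "euclidean", "ward")
  cl <- cut_dendrogram(h, 2)
  expect_true(same_partition(cl, rep(1:2, each = 10)))
  expect_equal(length(unique(cut_dendrogram(h, nrow(tb)))), nrow(tb))
  expect_error(cut_dendrogram(h, 1), "between 2")
  expect_error(cut_dendrogram(h, nrow(tb) + 1), "between 2")
})

test_that("silhouette widths equal the O(n^2) oracle and pick the planted k", {
  tb <- planted_blobs(n_per = 8, sep = 10, seed = 21)
  h <- hcluster_cells(tb, "euclidean", "ward")
  sc <- silhouette_curve(h)
  expect_equal(sc$best_k, 2)
  expect_gt(max(sc$curve$avg_width), 0.8)
  expect_false(sc$random_structure)
  d <- attr(h, "distances")
  for (k in c(2, 4, 7)) {
    cl <- cut_dendrogram(h, k)
    w <- sc$widths[sc$widths$k == k, ]
    expect_equal(w$width, naive_silhouette(cl, d), tolerance = 1e-9)
  }
  expect_true(all(sc$widths$width >= -1 & sc$widths$width <= 1))
  # the same check on the correlation-distance stage
  hp <- hcluster_cells(tb, "pearson", "average")
  scp <- silhouette_curve(hp)
  clp <- cut_dendrogram(hp, 3)
  expect_equal(scp$widths$width[scp$widths$k == 3],
               naive_silhouette(clp, attr(hp, "distances")), tolerance = 1e-9)
})

test_that("structureless data is flagged as random in most runs", {
  flags <- vapply(1:3, function(sd) {
    set.seed(sd)
    tb <- tibble::as_tibble(as.data.frame(matrix(stats::runif(40 * 8), 40)))
    names(tb) <- paste0("f", 1:8)
    tb <- dplyr::bind_cols(tibble::tibble(cell_id = as.character(1:40)), tb)
    silhouette_curve(hcluster_cells(zscore_features(tb), "euclidean", "ward"))$random_structure
  }, logical(1))
  expect_gte(sum(flags), 2)
})

test_that("clustering is invariant to column order and affine feature scaling", {
  tb <- planted_blobs(n_per = 5, seed = 31)
  z1 <- zscore_features(tb)
  perm <- tb[, c("cell_id", sample(names(tb)[-1]))]
  scaled <- tb
  scaled$f1 <- scaled$f1 * 40 - 7
  scaled$f3 <- scaled$f3 * 0.01 + 100
  h1 <- hcluster_cells(z1, "pearson", "average")
  h2 <- hcluster_cells(zscore_features(perm), "pearson", "average")
  h3 <- hcluster_cells(zscore_features(scaled), "pearson", "average")
  expect_equal(h1$height, h2$height, tolerance = 1e-9)
  expect_equal(h1$height, h3$height, tolerance = 1e-9)
  for (k in 2:5) {
    expect_true(same_partition(cut_dendrogram(h1, k), cut_dendrogram(h2, k)))
    expect_true(same_partition(cut_dendrogram(h1, k), cut_dendrogram(h3, k)))
  }
})

test_that("ward heights are monotone; average linkage is bounded", {
  tb <- planted_blobs(n_per = 7, seed = 41)
  hw <- hcluster_cells(tb, "euclidean", "ward")
  expect_true(all(diff(hw$height) >= -1e-9))
  ha <- hcluster_cells(tb, "pearson", "average")
  expect_true(all(diff(ha$height) >= -1e-9))
  expect_lte(max(ha$height), max(as.matrix(cell_distances(tb, "pearson"))) + 1e-9)
})
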