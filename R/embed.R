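# Validation embeddings: t-SNE and locally linear embedding with the
# dataset-specific settings used for the claustrum taxonomy.

tsne_profiles <- list(
  all = list(perplexity = 25, exaggeration = 1),
  pn  = list(perplexity = 8, exaggeration = 7),
  `in`  = list(perplexity = 7, exaggeration = 7)
)

lle_profiles <- list(pn = 14L, `in` = 13L)

#' t-SNE embedding of a feature table
#'
#' PCA-initialized Barnes-Hut t-SNE on Euclidean distances, learning rate
#' 200, at most 1000 iterations; dataset-specific perplexity/exaggeration:
#' all neurons 25/1, PN set 8/7, IN set 7/7. Exaggeration applies during the
#' standard early-exaggeration phase (first 250 iterations).
#'
#' @param features Z-scored feature tibble.
#' @param profile `"all"`, `"pn"` or `"in"`.
#' @param seed Random seed (the embedding is stochastic).
#' @param max_iter Iteration cap.
#' @return Tibble `cell_id`, `dim1`, `dim2`.
#' @export
tsne_embed <- function(features, profile = c("all", "pn", "in"), seed = 1,
                       max_iter = 1000) {
  profile <- match.arg(profile)
  p <- tsne_profiles[[profile]]
  m <- features_to_matrix(features)
  if (nrow(m) < 3 * p$perplexity)
    abort(sprintf("n = %d is too small for perplexity %d (need >= 3x)",
                  nrow(m), p$perplexity))
  set.seed(seed)
  pcs <- stats::prcomp(m, center = TRUE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  y0 <- pcs / stats::sd(pcs[, 1]) * 1e-4
  fit <- Rtsne::Rtsne(m, dims = 2, perplexity = p$perplexity,
                      theta = 0.5, eta = 200, max_iter = max_iter,
                      exaggeration_factor = p$exaggeration,
                      stop_lying_iter = 250L,
                      Y_init = y0, pca = FALSE, check_duplicates = FALSE)
  tibble(cell_id = rownames(m), dim1 = fit$Y[, 1], dim2 = fit$Y[, 2])
}

#' Locally linear embedding of a feature table
#'
#' Standard LLE with Tikhonov-regularized reconstruction weights: each cell
#' is reconstructed from its k nearest neighbours (PN set: 14, IN set: 13)
#' and the embedding is read off the bottom eigenvectors of
#' `(I - W)'(I - W)`. Deterministic; eigenvector signs are fixed so the
#' largest-magnitude loading is positive.
#'
#' @param features Z-scored feature tibble.
#' @param profile `"pn"` or `"in"`.
#' @param ndim Embedding dimension.
#' @param reg Regularization scale for the local Gram matrices.
#' @return Tibble `cell_id`, `dim1`, `dim2`, ...
#' @export
lle_embed <- function(features, profile = c("pn", "in"), ndim = 2,
                      reg = 1e-3) {
  profile <- match.arg(profile)
  k <- lle_profiles[[profile]]
  m <- features_to_matrix(features)
  n <- nrow(m)
  if (n <= k + 1) abort(sprintf("n = %d is too small for %d neighbours", n, k))
  dmat <- as.matrix(stats::dist(m))
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- order(dmat[i, ])[2:(k + 1)]
    Z <- sweep(m[nb, , drop = FALSE], 2, m[i, ])
    G <- Z %*% t(Z)
    G <- G + diag(k) * reg * sum(diag(G)) / k
    w <- solve(G, rep(1, k))
    W[i, nb] <- w / sum(w)
  }
  M <- t(diag(n) - W) %*% (diag(n) - W)
  eig <- eigen((M + t(M)) / 2, symmetric = TRUE)
  idx <- seq(n - 1, n - ndim)
  Y <- eig$vectors[, idx, drop = FALSE]
  Y <- vapply(seq_len(ncol(Y)), function(j) {
    v <- Y[, j]
    if (v[which.max(abs(v))] < 0) -v else v
  }, numeric(n))
  out <- as_tibble(stats::setNames(as.data.frame(Y * sqrt(n)),
                                   paste0("dim", seq_len(ndim))))
  dplyr::bind_cols(tibble(cell_id = rownames(m)), out)
}
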