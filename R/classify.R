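# Supervised classification: PCA to 99% retained variance feeding a
# single-hidden-layer feedforward network (10 hidden units, weight decay
# 0.001 by default; optionally re-tuned by 10-fold cross-validated grid
# search), arranged as a three-stage hierarchy: IN vs PN, then PN subtype
# (PN1-PN5) or IN subtype (PV/SST/VIP).

prep_xy <- function(features, labels) {
  if (!is.null(features[["label"]]) && missing(labels)) labels <- features$label
  x <- features_to_matrix(features)
  y <- factor(labels)
  if (nlevels(y) < 2) abort("need at least 2 classes")
  if (any(table(y) < 3)) abort("every class needs at least 3 cells")
  if (nrow(x) != length(y)) abort("features and labels disagree in length")
  list(x = x, y = y)
}

stage_transform <- function(stage, x) {
  miss_col <- setdiff(stage$feature_names, colnames(x))
  if (length(miss_col)) {
    warn(paste0(length(miss_col), " properties absent; imputed at stage mean"))
    x <- cbind(x, matrix(NA_real_, nrow(x), length(miss_col),
                         dimnames = list(NULL, miss_col)))
  }
  x <- x[, stage$feature_names, drop = FALSE]
  z <- sweep(sweep(x, 2, stage$mu), 2, stage$sdv, "/")
  z[is.na(z)] <- 0
  z %*% stage$rotation
}

fit_stage_core <- function(x, y, hidden, decay, seed, var_target, maxit) {
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  mu[!is.finite(mu)] <- 0
  z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
  z[is.na(z)] <- 0
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  cum <- cumsum(pca$sdev^2) / sum(pca$sdev^2)
  npc <- max(2L, which(cum >= var_target)[1])
  rot <- pca$rotation[, seq_len(npc), drop = FALSE]
  scores <- z %*% rot
  set.seed(seed)
  net <- nnet::nnet(scores, nnet::class.ind(y), size = hidden, decay = decay,
                    softmax = TRUE, maxit = maxit, trace = FALSE,
                    MaxNWts = 50000)
  list(mu = mu, sdv = sdv, rotation = rot, npc = npc,
       retained_variance = cum[npc], net = net, levels = levels(y))
}

#' Fit one classifier stage
#'
#' Standardizes the features, reduces them by PCA to the smallest number of
#' components retaining at least `var_target` of the variance, and trains a
#' single-hidden-layer softmax network. With `tune = TRUE` the hidden-layer
#' size and L2 weight decay are chosen by stratified 10-fold cross-validated
#' grid search (hidden 2/5/10/20 x decay 1e-4/1e-3/1e-2) before the final
#' refit on all data.
#'
#' @param features Tibble with `cell_id` and canonical property columns (a
#'   `label` column, if present, is ignored as a predictor).
#' @param labels Class labels (factor or character), one per row; defaults to
#'   `features$label`.
#' @param stage Stage identifier (`"in_vs_pn"`, `"pn_subtype"`,
#'   `"in_subtype"`, or free-form).
#' @param hidden Hidden units (ignored when `tune = TRUE`).
#' @param decay L2 weight decay (ignored when `tune = TRUE`).
#' @param tune Run the cross-validated grid search.
#' @param folds Folds for tuning.
#' @param seed Seed controlling fold assignment and network initialization.
#' @param var_target Minimum retained variance fraction for the PCA step.
#' @param maxit Optimizer iteration cap.
#' @return An object of class `ctype_stage`.
#' @export
fit_stage <- function(features, labels = features$label, stage = "stage",
                      hidden = 10, decay = 1e-3, tune = FALSE, folds = 10,
                      seed = 1, var_target = 0.99, maxit = 500) {
  d <- prep_xy(features, labels)
  if (tune) {
    grid <- expand.grid(hidden = c(2L, 5L, 10L, 20L),
                        decay = c(1e-4, 1e-3, 1e-2))
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      cv <- cross_validate(features, labels, hidden = grid$hidden[g],
                           decay = grid$decay[g], folds = folds, seed = seed,
                           var_target = var_target, maxit = maxit)
      cv$accuracy
    }, numeric(1))
    best <- which.max(acc)
    hidden <- grid$hidden[best]
    decay <- grid$decay[best]
  }
  core <- fit_stage_core(d$x, d$y, hidden, decay, seed, var_target, maxit)
  structure(c(core,
              list(stage = stage, feature_names = colnames(d$x),
                   hidden = hidden, decay = decay, tuned = tune,
                   n = nrow(d$x), seed = seed,
                   registry_version = registry_signature())),
            class = "ctype_stage")
}

registry_signature <- function() {
  unname(tools::md5sum(ct_extdata("property_registry.csv")))
}

#' @export
print.ctype_stage <- function(x, ...) {
  cat(sprintf("<ctype_stage '%s'> %d cells, %d features -> %d PCs (%.1f%% var), %d hidden units, decay %g\n",
              x$stage, x$n, length(x$feature_names), x$npc,
              100 * x$retained_variance, x$hidden, x$decay))
  cat("classes:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' Predict class probabilities from one stage
#'
#' @param object A `ctype_stage`.
#' @param newdata Feature tibble; missing properties are imputed at the
#'   stage mean with a warning.
#' @param ... Unused.
#' @return Matrix of class probabilities (rows sum to 1), cells x classes.
#' @export
predict.ctype_stage <- function(object, newdata, ...) {
  if (nrow(newdata) == 0L || length(setdiff(names(newdata),
                                            c("cell_id", "label"))) == 0L)
    abort("no features to predict from")
  scores <- stage_transform(object, features_to_matrix(newdata))
  p <- stats::predict(object$net, scores)
  if (is.null(dim(p))) p <- cbind(p, 1 - p)
  colnames(p) <- object$levels
  p / rowSums(p)
}

#' @export
glance.ctype_stage <- function(x, ...) {
  tibble(stage = x$stage, n = x$n, n_features = length(x$feature_names),
         n_components = x$npc, retained_variance = x$retained_variance,
         hidden = x$hidden, decay = x$decay, tuned = x$tuned)
}

#' @export
tidy.ctype_stage <- function(x, ...) {
  tibble(term = names(stats::coef(x$net)), estimate = unname(stats::coef(x$net)))
}

stratified_folds <- function(y, folds, seed) {
  set.seed(seed)
  f <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Cross-validated accuracy of a classifier stage
#'
#' Stratified k-fold cross-validation of the full standardize-PCA-network
#' pipeline (refit inside every fold); accuracy is the pooled fraction of
#' held-out cells classified correctly.
#'
#' @inheritParams fit_stage
#' @return Object of class `ctype_cv`: `accuracy`, `confusion` (tibble of
#'   truth x prediction counts), `predictions` (per-cell tibble).
#' @export
cross_validate <- function(features, labels = features$label, hidden = 10,
                           decay = 1e-3, folds = 10, seed = 1,
                           var_target = 0.99, maxit = 500) {
  d <- prep_xy(features, labels)
  f <- stratified_folds(d$y, folds, seed)
  preds <- character(length(d$y))
  for (k in seq_len(folds)) {
    tr <- f != k; te <- f == k
    if (!any(te)) next
    core <- fit_stage_core(d$x[tr, , drop = FALSE], droplevels(d$y[tr]),
                           hidden, decay, seed + 1000L * k, var_target, maxit)
    stage <- c(core, list(feature_names = colnames(d$x)))
    p <- stats::predict(core$net, stage_transform(stage, d$x[te, , drop = FALSE]))
    if (is.null(dim(p))) p <- cbind(p, 1 - p)
    preds[te] <- core$levels[max.col(p)]
  }
  out <- tibble(cell_id = rownames(d$x), truth = as.character(d$y),
                prediction = preds, fold = f)
  conf <- dplyr::count(out, .data$truth, .data$prediction)
  structure(list(accuracy = mean(out$truth == out$prediction),
                 confusion = conf, predictions = out,
                 hidden = hidden, decay = decay, folds = folds, seed = seed),
            class = "ctype_cv")
}

#' @export
print.ctype_cv <- function(x, ...) {
  cat(sprintf("<ctype_cv> pooled %d-fold CV accuracy: %.1f%%\n",
              x$folds, 100 * x$accuracy))
  invisible(x)
}

#' @export
glance.ctype_cv <- function(x, ...) {
  tibble(accuracy = x$accuracy, folds = x$folds, hidden = x$hidden,
         decay = x$decay)
}

#' @export
tidy.ctype_cv <- function(x, ...) x$confusion

#' Fit the full three-stage classifier
#'
#' Stage 1 separates INs from PNs on the 38-property set; the PN stage
#' resolves PN1-PN5 on the 38-property set; the IN stage resolves PV/SST/VIP
#' on the 63-property set.
#'
#' @param pnin 38-property tibble with `label` in `c("IN", "PN")`.
#' @param pn 38-property tibble with `label` in `c("PN1", ..., "PN5")`.
#' @param inn 63-property tibble with `label` in `c("PV", "SST", "VIP")`.
#' @param ... Passed to [fit_stage()] (e.g. `tune`, `hidden`, `decay`).
#' @param seed Seed for all three stages.
#' @return Object of class `claustrum_classifier`.
#' @export
fit_classifier <- function(pnin, pn, inn, ..., seed = 1) {
  structure(list(
    in_vs_pn = fit_stage(pnin, stage = "in_vs_pn", seed = seed, ...),
    pn_subtype = fit_stage(pn, stage = "pn_subtype", seed = seed, ...),
    in_subtype = fit_stage(inn, stage = "in_subtype", seed = seed, ...)
  ), class = "claustrum_classifier")
}

#' @export
print.claustrum_classifier <- function(x, ...) {
  cat("<claustrum_classifier> three-stage hierarchy\n")
  for (s in x) print(s)
  invisible(x)
}

#' Hierarchical prediction over the eight cell types
#'
#' Stage 1 decides IN versus PN; the matching subtype stage then resolves the
#' final label. Probabilities for all eight types are reported as the product
#' of the branch probability and the within-branch subtype probability, so
#' they sum to one; the final label follows the argmax chain.
#'
#' @param object A `claustrum_classifier`.
#' @param features38 38-property feature tibble.
#' @param features63 63-property feature tibble for the same cells (optional;
#'   without it the IN branch probability is split evenly over PV/SST/VIP).
#' @param ... Unused.
#' @return Tibble: `cell_id`, `p_IN`, `p_PN`, the eight per-type probability
#'   columns, `stage1` and final `label` with its probability.
#' @export
predict.claustrum_classifier <- function(object, features38,
                                         features63 = NULL, ...) {
  p1 <- predict(object$in_vs_pn, features38)
  ppn <- predict(object$pn_subtype, features38)
  pin <- if (!is.null(features63)) predict(object$in_subtype, features63)
         else {
    warn("no 63-property features supplied; IN subtypes get equal shares")
    matrix(1 / 3, nrow(features38), 3,
           dimnames = list(NULL, object$in_subtype$levels))
  }
  pn_lv <- object$pn_subtype$levels
  in_lv <- object$in_subtype$levels
  final <- cbind(p1[, "PN"] * ppn, p1[, "IN"] * pin)
  colnames(final) <- c(pn_lv, in_lv)
  stage1 <- colnames(p1)[max.col(p1)]
  label <- ifelse(stage1 == "PN", pn_lv[max.col(ppn)], in_lv[max.col(pin)])
  prob <- unname(ifelse(stage1 == "PN",
                 p1[, "PN"] * ppn[cbind(seq_len(nrow(ppn)), max.col(ppn))],
                 p1[, "IN"] * pin[cbind(seq_len(nrow(pin)), max.col(pin))]))
  out <- tibble(cell_id = features38$cell_id %||%
                  paste0("cell", seq_len(nrow(features38))),
                p_IN = unname(p1[, "IN"]), p_PN = unname(p1[, "PN"]))
  probs <- as_tibble(as.data.frame(final))
  names(probs) <- paste0("p_", names(probs))
  dplyr::bind_cols(out, probs,
                   tibble(stage1 = stage1, label = label, probability = prob))
}

#' Save / load a trained classifier
#'
#' Models are stored as versioned RDS archives carrying the registry
#' signature; loading rejects archives built against a different registry.
#'
#' @param object A `claustrum_classifier` or `ctype_stage`.
#' @param path File path.
#' @return `save_model`: `path`, invisibly. `load_model`: the restored
#'   object.
#' @export
save_model <- function(object, path) {
  saveRDS(list(format = "claustrotype_model", format_version = 1L,
               registry_version = registry_signature(), object = object),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  arch <- tryCatch(readRDS(path),
                   error = function(e) abort("corrupted or unreadable model file"))
  if (!is.list(arch) || !identical(arch$format, "claustrotype_model"))
    abort("not a claustrotype model archive")
  if (!identical(arch$registry_version, registry_signature()))
    abort("model was built against a different property registry version")
  arch$object
}

#' @export
autoplot.ctype_cv <- function(object, ...) {
  conf <- tidyr::complete(object$confusion, .data$truth, .data$prediction,
                          fill = list(n = 0L))
  ggplot2::ggplot(conf, ggplot2::aes(x = .data$prediction, y = .data$truth,
                                     fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c(guide = "none") +
    ggplot2::labs(x = "predicted", y = "true",
                  title = sprintf("pooled %d-fold CV accuracy %.1f%%",
                                  object$folds, 100 * object$accuracy)) +
    ggplot2::theme_minimal()
}
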