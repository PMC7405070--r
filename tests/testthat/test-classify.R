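gauss_classes <- function(n_per = 30, p = 8, sep = 10, classes = 2, seed = 2) {
  set.seed(seed)
  m <- do.call(rbind, lapply(seq_len(classes) - 1, function(k)
    matrix(stats::rnorm(n_per * p, k * sep), n_per)))
  tb <- tibble::as_tibble(as.data.frame(m))
  names(tb) <- paste0("f", seq_len(p))
  dplyr::bind_cols(
    tibble::tibble(cell_id = as.character(seq_len(classes * n_per)),
                   label = rep(LETTERS[seq_len(classes)], each = n_per)), tb)
}

test_that("widely separated classes cross-validate perfectly", {
  tb <- gauss_classes(n_per = 30, sep = 10)
  cv <- cross_validate(tb, seed = 1)
  expect_equal(cv$accuracy, 1)
  expect_s3_class(glance(cv), "tbl_df")
})

test_that("identical class distributions score at chance", {
  tb <- gauss_classes(n_per = 100, sep = 0, seed = 8)
  cv <- cross_validate(tb, seed = 8)
  expect_lt(abs(cv$accuracy - 0.5), 0.10)
})

test_that("degenerate label structures are rejected", {
  tb <- gauss_classes()
  expect_error(fit_stage(tb, labels = rep("A", nrow(tb))), "at least 2 classes")
  bad <- c(rep("A", nrow(tb) - 2), "B", "B")
  expect_error(fit_stage(tb, labels = bad), "at least 3 cells")
})

test_that("a fitted stage retains >= 99% variance and sums probabilities to 1", {
  tb <- gauss_classes(n_per = 25, sep = 4)
  st <- fit_stage(tb, stage = "demo", seed = 3)
  expect_gte(st$retained_variance, 0.99)
  expect_equal(st$hidden, 10)
  expect_equal(st$decay, 1e-3)
  p <- predict(st, tb)
  expect_equal(unname(rowSums(p)), rep(1, nrow(tb)), tolerance = 1e-6)
  expect_error(predict(st, tb[, "cell_id"]), "no features")
  # missing columns are mean-imputed with a warning
  expect_warning(p2 <- predict(st, tb[, 1:6]), "imputed")
  expect_equal(unname(rowSums(p2)), rep(1, nrow(tb)), tolerance = 1e-6)
})

test_that("the same seed reproduces folds and confusion exactly", {
  tb <- gauss_classes(n_per = 20, sep = 1.5, seed = 5)
  cv1 <- cross_validate(tb, seed = 11)
  cv2 <- cross_validate(tb, seed = 11)
  expect_identical(cv1$confusion, cv2$confusion)
  expect_identical(cv1$predictions, cv2$predictions)
  # permuted labels drop to chance
  set.seed(12)
  perm <- tb
  perm$label <- sample(perm$label)
  cvp <- cross_validate(perm, seed = 12)
  expect_lt(cvp$accuracy, 0.7)
})

test_that("accuracy does not decrease when class separation grows", {
  acc <- vapply(c(0.5, 2, 6), function(sep)
    cross_validate(gauss_classes(n_per = 20, sep = sep, seed = 4), seed = 4)$accuracy,
    numeric(1))
  expect_true(all(diff(acc) >= 0))
})

test_that("the three-stage hierarchy routes cells to their generating subtype", {
  pop <- sample_cohort(cohort_counts("population"), set = 38, seed = 60)
  pnin <- dplyr::mutate(pop, label = ifelse(label %in% c("PV", "SST", "VIP"),
                                            "IN", "PN"))
  pn <- sample_cohort(cohort_counts("pn"), set = 38, seed = 61)
  inn <- sample_cohort(cohort_counts("in"), set = 63, seed = 62)
  clf <- fit_classifier(pnin, pn, inn, seed = 7)

  # class-centroid cells: one per subtype, at the prototype centre
  centroids38 <- subtype_prototypes(38) |>
    dplyr::select(subtype, label, center) |>
    tidyr::pivot_wider(names_from = label, values_from = center) |>
    dplyr::rename(cell_id = subtype)
  centroids63 <- subtype_prototypes(63) |>
    dplyr::select(subtype, label, center) |>
    tidyr::pivot_wider(names_from = label, values_from = center) |>
    dplyr::rename(cell_id = subtype)
  c63 <- centroids63[match(centroids38$cell_id, centroids63$cell_id), ]
  c63$cell_id <- centroids38$cell_id
  pred <- predict(clf, centroids38, c63)
  expect_equal(pred$label, centroids38$cell_id)

  # eight-way probabilities are a distribution and match the argmax chain
  probs <- as.matrix(pred[, paste0("p_", c("PN1", "PN2", "PN3", "PN4", "PN5",
                                           "PV", "SST", "VIP"))])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(pred)), tolerance = 1e-6)
  expect_equal(pred$p_IN + pred$p_PN, rep(1, nrow(pred)), tolerance = 1e-6)
  chain <- ifelse(pred$stage1 == "IN",
                  c("PV", "SST", "VIP")[max.col(probs[, 6:8])],
                  paste0("PN", max.col(probs[, 1:5])))
  expect_equal(pred$label, chain)

  # save/load round trip: predictions are bitwise identical
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(clf, path)
  clf2 <- load_model(path)
  expect_identical(predict(clf2, centroids38, c63), pred)
  bad <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", bad)
  expect_error(load_model(bad), "corrupted|not a claustrotype")
})

test_that("the tuning grid can pick hyperparameters on a small problem", {
  tb <- gauss_classes(n_per = 15, sep = 6, seed = 13)
  st <- fit_stage(tb, tune = TRUE, folds = 5, seed = 13)
  expect_true(st$hidden %in% c(2, 5, 10, 20))
  expect_true(st$decay %in% c(1e-4, 1e-3, 1e-2))
  expect_true(st$tuned)
})
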