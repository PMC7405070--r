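flat_vi_sweepset <- function(currents = c(-60, -40, -20, 0, 20), rmp = -70,
                             rm = 200, noise_sd = 0, rate = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  volts <- lapply(currents, function(i) {
    n <- round(1.2 * rate)
    v <- rep(rmp, n)
    idx <- (round(0.1 * rate) + 1L):round(1.1 * rate)
    v[idx] <- rmp + rm * i / 1000
    v + stats::rnorm(n, 0, noise_sd)
  })
  sweepset(volts, currents, rate, cell_id = "vi")
}

test_that("V-I fit recovers exact passive properties on noiseless sweeps", {
  pp <- passive_properties(flat_vi_sweepset())
  expect_equal(pp$rmp, -70, tolerance = 1e-9)
  expect_equal(pp$rm, 200, tolerance = 1e-9)
})

test_that("noisy V-I fit equals the normal-equations oracle", {
  s <- flat_vi_sweepset(noise_sd = 0.5, seed = 99)
  pp <- passive_properties(s)
  idx <- claustrotype:::stim_index(s)
  tail_idx <- idx[idx > idx[length(idx)] - 0.2 * length(idx)]
  vss <- vapply(s$voltages, function(v) mean(v[tail_idx]), numeric(1))
  fit <- normal_eq_fit(s$current_pa, vss)
  expect_equal(pp$rmp, unname(fit["intercept"]), tolerance = 1e-9)
  expect_equal(pp$rm, unname(fit["slope"]) * 1000, tolerance = 1e-9)
})

test_that("too few subthreshold sweeps is an error", {
  expect_error(passive_properties(flat_vi_sweepset(currents = -20)),
               "at least 2 subthreshold")
})

test_that("current threshold, 2xct and max-activity sweeps are selected", {
  rate <- 10000
  sp <- list(numeric(0), numeric(0), numeric(0),
             c(0.4), c(0.3, 0.5), c(0.3, 0.5, 0.7), c(0.3, 0.45, 0.6, 0.8))
  s <- make_fake_sweepset(sp, c(-60, -40, 20, 60, 80, 120, 140), rate = rate)
  ci <- current_threshold(s)
  expect_equal(ci$ct, 60)
  expect_equal(s$current_pa[ci$sweep_2xct], 120)
  expect_equal(s$current_pa[ci$sweep_max], 140)

  # a low threshold doubles to a low 2xct level
  s2 <- make_fake_sweepset(list(numeric(0), c(0.4), c(0.3, 0.5), c(0.3, 0.5, 0.6)),
                           c(-30, 30, 60, 90), rate = rate)
  ci2 <- current_threshold(s2)
  expect_equal(ci2$ct, 30)
  expect_equal(s2$current_pa[ci2$sweep_2xct], 60)

  # ties in the AP count go to the lowest amplitude
  s3 <- make_fake_sweepset(list(numeric(0), numeric(0), c(0.3, 0.5), c(0.35, 0.55)),
                           c(-60, -20, 40, 60), rate = rate)
  expect_equal(s3$current_pa[current_threshold(s3)$sweep_max], 40)

  # all sweeps silent
  expect_error(current_threshold(flat_vi_sweepset()), "no current threshold")
  expect_error(extract_features(flat_vi_sweepset(), 38), "no current threshold")
})

test_that("extraction composes all levels with registry names and units", {
  pr <- sim_presets()$PN1
  pr$sigma <- 0
  s <- simulate_sweepset(pr, ladder = c(-60, -40, -20, 50, 100, 150, 200),
                         seed = 5, cell_id = "pn1")
  fx <- extract_features(s, 38)
  expect_named(fx, c("cell_id", canonical_properties(38)))
  expect_equal(fx$cell_id, "pn1")
  expect_equal(fx[["RMP (mV)"]], pr$el, tolerance = 0.5)
  expect_equal(fx[["Rm (MΩ)"]], pr$rm, tolerance = 5)
  expect_equal(fx$ct, 100)
  expect_gt(fx[["2xct: number of AP"]], 5)
  # ISI identity carried through extraction
  expect_equal(fx[["2xct: ISI ratio"]] * fx[["2xct: initial instant frequency"]] +
                 fx[["2xct: max adaptation (Hz)"]],
               fx[["2xct: initial instant frequency"]], tolerance = 1e-9)
})

test_that("features are invariant to shifting the stimulus window in time", {
  pr <- sim_presets()$PN3
  pr$sigma <- 0
  ladder <- c(-60, -20, 120, 240)
  v1 <- lapply(seq_along(ladder), function(i)
    simulate_trace(pr, ladder[i], seed = i, dt_ms = 0.02, duration_s = 1.2,
                   stim_onset = 0.1))
  v2 <- lapply(seq_along(ladder), function(i)
    simulate_trace(pr, ladder[i], seed = i, dt_ms = 0.02, duration_s = 1.5,
                   stim_onset = 0.4))
  s1 <- sweepset(v1, ladder, 50000, stim_onset = 0.1)
  s2 <- sweepset(v2, ladder, 50000, stim_onset = 0.4)
  f1 <- extract_features(s1, 38)
  f2 <- extract_features(s2, 38)
  expect_equal(as.data.frame(f1[-1]), as.data.frame(f2[-1]), tolerance = 1e-6)
  # and extraction is deterministic across runs
  expect_identical(as.data.frame(extract_features(s1, 38)), as.data.frame(f1))
})
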