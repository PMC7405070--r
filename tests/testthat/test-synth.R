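test_that("cohorts are reproducible and match the printed moments", {
  a <- sample_cohort(c(PV = 20, PN1 = 10), set = 38, seed = 17)
  b <- sample_cohort(c(PV = 20, PN1 = 10), set = 38, seed = 17)
  expect_identical(a, b)
  expect_false(identical(a, sample_cohort(c(PV = 20, PN1 = 10), set = 38, seed = 18)))
  expect_error(sample_cohort(c(XX = 5), set = 38, seed = 1), "unknown subtype")

  big <- sample_cohort(c(PV = 1000), set = 63, seed = 19)
  # PV membrane resistance: mean 159, SD = SEM * sqrt(19) = 45.8
  expect_lt(abs(mean(big[["Rm (MΩ)"]]) - 159), 3 * 45.8 / sqrt(1000))
  # an unbounded normal property reproduces its full distribution (KS)
  ks <- suppressWarnings(
    stats::ks.test(big[["RMP (mV)"]], "pnorm", -66.4, 1.2 * sqrt(19)))
  expect_lt(unname(ks$statistic), 1.63 / sqrt(1000))
  # physical clipping
  expect_true(all(big[["2xct: Cv2:all"]] >= 0 & big[["2xct: Cv2:all"]] <= 2))
  expect_true(all(big[["Rm (MΩ)"]] > 0))
})

test_that("prototype tables cover both sets with positive scales", {
  p38 <- subtype_prototypes(38)
  p63 <- subtype_prototypes(63)
  expect_setequal(unique(p38$subtype),
                  c(paste0("PN", 1:5), "PV", "SST", "VIP"))
  expect_setequal(unique(p63$subtype), c("PV", "SST", "VIP"))
  expect_equal(nrow(p38), 8 * 38)
  expect_equal(nrow(p63), 3 * 63)
  expect_true(all(p38$scale > 0))
  expect_true(all(p63$scale > 0))
  # PN centres are the printed medians
  expect_equal(p38$center[p38$subtype == "PN1" & p38$label == "RMP (mV)"], -73.9)
  # IN centres are the printed means
  expect_equal(p63$center[p63$subtype == "VIP" & p63$label == "Rm (MΩ)"], 653)
})

test_that("the outlier VIP interneuron carries its printed values", {
  ov <- outlier_vip_vector()
  expect_equal(ov[["RMP (mV)"]], -64.9)
  expect_equal(ov[["2xct: Cv2:all"]], 0.86)
  expect_equal(ov$ct, 30)
  expect_equal(ov[["Rm (MΩ)"]], 755)
  expect_named(ov, c("cell_id", "label", canonical_properties(38)))
})

test_that("a silent step stays at rest and bad parameters are rejected", {
  v <- simulate_trace("PN1", 0, seed = 1)
  expect_equal(nrow(detect_aps(v, 50000, window = c(0.1, 1.1))), 0)
  expect_equal(mean(v[10000:50000]), sim_presets()$PN1$el, tolerance = 1)
  expect_identical(simulate_trace("VIP", 40, seed = 3),
                   simulate_trace("VIP", 40, seed = 3))
  bad <- sim_presets()$PN1
  bad$tau <- -5
  expect_error(simulate_trace(bad, 100), "unstable")
  expect_error(simulate_sweepset("nope"), "unknown subtype")
})

test_that("halving the integration step moves spike times by < 0.2 ms", {
  pr <- sim_presets()$PN1
  pr$sigma <- 0
  t1 <- detect_aps(simulate_trace(pr, 200, dt_ms = 0.02), 50000,
                   window = c(0.1, 1.1))$peak_time_ms
  t2 <- detect_aps(simulate_trace(pr, 200, dt_ms = 0.01), 100000,
                   window = c(0.1, 1.1))$peak_time_ms
  expect_equal(length(t1), length(t2))
  expect_lt(max(abs(t1 - t2)), 0.2)
})

test_that("the doublet-firing preset shows an ADP at threshold in most cells", {
  present <- vapply(1:5, function(sd) {
    s <- simulate_sweepset("PN3", ladder = c(-60, -20, 120), seed = sd)
    extract_features(s, 38)[["ADP probability"]]
  }, numeric(1))
  expect_gte(mean(present), 0.8)
})

test_that("extracted anchors recover the generating parameters", {
  fx <- sim_features_all()
  presets <- sim_presets()
  pro <- subtype_prototypes(38)
  ok <- vapply(seq_len(nrow(fx)), function(i) {
    pr <- presets[[fx$label[i]]]
    sc <- pro$scale[pro$subtype == fx$label[i] &
                      pro$label == "2xct: number of AP"]
    abs(fx[["RMP (mV)"]][i] - pr$el) < 2 &&
      abs(fx[["Rm (MΩ)"]][i] - pr$rm) / pr$rm < 0.15 &&
      abs(fx$ct[i] - pr$ct) <= 20 &&
      abs(fx[["2xct: number of AP"]][i] -
            pro$center[pro$subtype == fx$label[i] &
                         pro$label == "2xct: number of AP"]) <= 3 * sc
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("simulated subtypes respect the published group orderings", {
  fx <- sim_features_all()
  is_in <- fx$label %in% c("PV", "SST", "VIP")
  # interneurons have deeper AHPs, narrower spikes and weaker amplitude
  # adaptation within the initial pair
  expect_lt(stats::median(fx[["AHP amplitude (mV)"]][is_in]),
            stats::median(fx[["AHP amplitude (mV)"]][!is_in]))
  expect_gt(stats::median(fx[["AP half-width (ms)"]][!is_in]),
            stats::median(fx[["AP half-width (ms)"]][is_in]))
  expect_gt(stats::median(fx[["2xct: 1st/2nd AP ratio"]][!is_in]),
            stats::median(fx[["2xct: 1st/2nd AP ratio"]][is_in]))
  # fast-spiking PV fires at least twice as many spikes as VIP at 2xct
  expect_gte(fx[["2xct: number of AP"]][fx$label == "PV"],
             2 * fx[["2xct: number of AP"]][fx$label == "VIP"])
  expect_lt(fx[["AP half-width (ms)"]][fx$label == "PV"],
            fx[["AP half-width (ms)"]][fx$label == "PN1"])
})

test_that("simulated sweep families run the full pipeline end to end", {
  s <- simulate_sweepset("SST", seed = 6)
  expect_s3_class(s, "sweepset")
  expect_equal(s$temperature, 24)
  ci <- current_threshold(s)
  expect_equal(ci$ct, sim_presets()$SST$ct, tolerance = 20.1)
  fx63 <- extract_features(s, 63)
  expect_named(fx63, c("cell_id", canonical_properties(63)))
  expect_false(is.na(fx63[["Max AP: # AP"]]))
  pp <- passive_properties(s)
  expect_equal(pp$rmp, sim_presets()$SST$el, tolerance = 2)
})
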