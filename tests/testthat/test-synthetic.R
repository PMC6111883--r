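test_that("a noise-free subject emits bit-identical pulses", {
  sim <- withr::with_seed(1, generate_subject_ecg(
    ecg_morph_params(rr_sd = 0, baseline_amp = 0, noise_sd = 0,
                     beat_gain_sd = 0, artifact_prob = 0),
    n_beats = 10))
  pulses <- segment_pulses(sim$signal, sim$r_peaks)
  expect_equal(nrow(pulses), 10L)
  ref <- pulses[1, ]
  expect_lt(max(abs(sweep(pulses, 2, ref))), 1e-9)
})

test_that("default ECG generation is detectable and seed-stable", {
  sim <- withr::with_seed(2, generate_subject_ecg(n_beats = 40))
  peaks <- detect_r_peaks(bandpass_baseline_correct(sim$signal))
  hits <- sum(vapply(sim$r_peaks,
                     function(r) any(abs(peaks - r) <= 5), logical(1)))
  expect_gte(hits, 39)

  sim2 <- withr::with_seed(2, generate_subject_ecg(n_beats = 40))
  expect_identical(sim$signal, sim2$signal)
  expect_identical(sim$r_peaks, sim2$r_peaks)

  expect_error(generate_subject_ecg(n_beats = 0), "n_beats")
  expect_error(ecg_morph_params(rr_mean = 0.2), "0.3")
  expect_error(ecg_morph_params(noise_sd = -1), "non-negative")
})

test_that("noise-free MSP cycles round-trip the base pattern exactly", {
  pat <- withr::with_seed(3, make_msp_base_pattern(0.2))
  quiet <- msp_subject_params(pat, gain_sd = 0, add_sd = 0,
                              contact_severity = 0)
  cyc <- withr::with_seed(4, generate_subject_msp(quiet, n_cycles = 2))
  feat <- concatenate_modes(aggregate_cycle(cyc$red[[1]]),
                            aggregate_cycle(cyc$yellow[[1]]))
  expect_equal(as.numeric(feat), pat)

  # constant 50% contact loss exactly halves the edge detectors
  half <- msp_subject_params(pat, gain_sd = 0, add_sd = 0,
                             contact_severity = 0.5)
  cyc2 <- withr::with_seed(4, generate_subject_msp(half, n_cycles = 1))
  feat2 <- concatenate_modes(aggregate_cycle(cyc2$red[[1]]),
                             aggregate_cycle(cyc2$yellow[[1]]))
  edge <- as.vector(outer(c(1:4, 29:32), (0:3) * 32, "+"))
  expect_equal(as.numeric(feat2)[edge], pat[edge] / 2)
  expect_equal(as.numeric(feat2)[-edge], pat[-edge])
})

test_that("noisy MSP features are unbiased around the base pattern", {
  pat <- withr::with_seed(5, make_msp_base_pattern(0.1))
  par <- msp_subject_params(pat, gain_sd = 0.05, add_sd = 0.02,
                            contact_severity = 0)
  cyc <- withr::with_seed(6, generate_subject_msp(par, n_cycles = 1000))
  feats <- vapply(seq_len(1000), function(i) {
    as.numeric(concatenate_modes(aggregate_cycle(cyc$red[[i]]),
                                 aggregate_cycle(cyc$yellow[[i]])))
  }, numeric(128))
  mu <- rowMeans(feats)
  se <- apply(feats, 1, stats::sd) / sqrt(1000)
  expect_true(all(abs(mu - pat) <= 3 * se + 1e-12))
})

test_that("cohorts are reproducible and prefix-stable in the seed", {
  c1 <- simulate_cohort(5, seed = 11, n_beats = 10, n_cycles = 3)
  c2 <- simulate_cohort(5, seed = 11, n_beats = 10, n_cycles = 3)
  expect_identical(c1$ecg, c2$ecg)
  expect_identical(c1$msp, c2$msp)

  c3 <- simulate_cohort(5, seed = 12, n_beats = 10, n_cycles = 3)
  expect_false(identical(c1$ecg[[1]]$signal, c3$ecg[[1]]$signal))

  # subject i is unchanged when the cohort grows
  c8 <- simulate_cohort(8, seed = 11, n_beats = 10, n_cycles = 3)
  expect_identical(c1$ecg[[3]], c8$ecg[[3]])
  expect_identical(c1$msp[[5]], c8$msp[[5]])

  expect_error(simulate_cohort(1), "n_subjects")
})

test_that("a null cohort is indistinguishable, a clean one separable", {
  # shared parameters, only noise differs: EER near chance
  null <- simulate_cohort(12, seed = 21, inter_subject_scale = 0)
  pool <- run_protocol(process_cohort(null))
  expect_equal(compute_eer(far_frr_curve(pool, "msp")), 50, tolerance = 6)

  # dispersed parameters, no noise: perfect separation
  sep <- simulate_noise_free(4, seed = 22)
  pool2 <- run_protocol(process_cohort(sep))
  expect_lt(max(pool2$ecg[pool2$genuine]),
            min(pool2$ecg[!pool2$genuine]) / 5)
  expect_lt(max(pool2$msp[pool2$genuine]),
            min(pool2$msp[!pool2$genuine]) / 5)
  expect_equal(compute_eer(far_frr_curve(pool2, "ecg")), 0)
})

# MSP-only record sets (skip the ECG pipeline), duplicated into both
# modality slots so run_protocol() can score them
msp_only_records <- function(coh) {
  rec <- dplyr::bind_rows(lapply(seq_len(nrow(coh)), function(i) {
    process_msp(coh$msp[[i]]$red, coh$msp[[i]]$yellow, seed = i,
                subject_id = coh$subject[i])
  }))
  rbind(rec, dplyr::mutate(rec, modality = "ecg"))
}

test_that("raising intra-subject noise never helps verification", {
  eers <- vapply(c(0.02, 0.08, 0.2), function(cg) {
    mean(vapply(31:33, function(sd) {
      coh <- simulate_cohort(8, seed = sd, msp_cycle_gain_sd = cg,
                             n_beats = 2)
      compute_eer(far_frr_curve(run_protocol(msp_only_records(coh)), "msp"))
    }, numeric(1)))
  }, numeric(1))
  expect_lte(eers[1], eers[2] + 1)
  expect_lte(eers[2], eers[3] + 1)
})

test_that("contact-severity variance degrades MSP verification", {
  eer_at <- function(csd, dp) {
    mean(vapply(41:45, function(sd) {
      coh <- simulate_cohort(8, seed = sd, contact_sd = csd,
                             detach_prob = dp, n_beats = 2)
      compute_eer(far_frr_curve(run_protocol(msp_only_records(coh)), "msp"))
    }, numeric(1)))
  }
  expect_lt(eer_at(0, 0), eer_at(0.15, 0.1))
})
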