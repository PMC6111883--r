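clean_ecg <- function(n_beats = 40, seed = 11) {
  withr::with_seed(seed, generate_subject_ecg(
    ecg_morph_params(rr_sd = 0, baseline_amp = 0, noise_sd = 0.01,
                     beat_gain_sd = 0, artifact_prob = 0),
    n_beats = n_beats))
}

test_that("R-peak detection recovers known beat positions", {
  sim <- clean_ecg()  # rr = 0.8 s -> beats exactly 200 samples apart
  expect_true(all(diff(sim$r_peaks) == 200))
  peaks <- detect_r_peaks(bandpass_baseline_correct(sim$signal))
  expect_equal(length(peaks), length(sim$r_peaks))
  expect_true(all(abs(peaks - sim$r_peaks) <= 5))
  expect_true(all(diff(peaks) >= 50))
})

test_that("degenerate signals yield no detections", {
  expect_identical(detect_r_peaks(numeric(600)), integer(0))
  expect_identical(detect_r_peaks(rep(3.2, 600)), integer(0))
  expect_error(detect_r_peaks(numeric(100)), "2 s")
})

test_that("two pulses inside the refractory window give one detection", {
  x <- numeric(1500)
  t0 <- (seq_along(x) - 1) / 250
  bump <- function(ctr) exp(-((t0 - ctr)^2) / (2 * 0.012^2))
  # legitimate surrounding beats so the detector has an RR context
  for (ctr in c(1, 1.8, 2.6, 3.4, 4.2, 5)) x <- x + bump(ctr)
  x <- x + bump(3.4 + 40 / 250)  # 160 ms after an existing beat
  peaks <- detect_r_peaks(x)
  span <- peaks[peaks >= 3.4 * 250 - 5 & peaks <= 3.4 * 250 + 45]
  expect_lte(length(span), 1)
})

test_that("segmentation windows are 160 samples anchored at the R-peak", {
  x <- sin(seq_len(300) / 7)
  p <- segment_pulses(x, 101)
  expect_equal(dim(p), c(1L, 160L))
  expect_equal(p[1, ], x[34:193])
  expect_equal(p[1, 68], x[101])

  # window would start before the signal: silently skipped
  expect_equal(nrow(segment_pulses(x, 51)), 0L)
  expect_equal(nrow(segment_pulses(x, c(51, 101, 205))), 2L)
  expect_error(segment_pulses(x, 500), "valid indices")

  long <- rnorm(9000)
  peaks <- seq(100, by = 200, length.out = 36)
  expect_equal(nrow(segment_pulses(long, peaks)), 36L)
})

test_that("pair averaging halves the count with elementwise means", {
  p <- matrix(rnorm(36 * 160), 36)
  avg <- average_successive_pulses(p)
  expect_equal(nrow(avg), 18L)
  for (k in c(1, 9, 18)) {
    expect_equal(avg[k, ], (p[2 * k - 1, ] + p[2 * k, ]) / 2)
  }

  same <- matrix(rep(rnorm(160), 2), 2, byrow = TRUE)
  expect_equal(average_successive_pulses(same)[1, ], same[1, ])

  expect_error(average_successive_pulses(matrix(rnorm(160), 1)),
               "at least 2")
  expect_warning(avg5 <- average_successive_pulses(matrix(rnorm(5 * 160), 5)),
                 "odd")
  expect_equal(nrow(avg5), 2L)
  # more than 36 rows: only the first 36 used
  p40 <- rbind(p, matrix(rnorm(4 * 160), 4))
  expect_equal(average_successive_pulses(p40), avg)
})

test_that("record grouping preserves order and round-trips", {
  avg <- matrix(seq_len(18 * 160), 18)
  rs <- build_ecg_records(avg, "subj")
  expect_s3_class(rs, "wa_record_set")
  expect_equal(rs$record, 1:6)
  expect_equal(rs$features[[1]], avg[1:3, ])
  expect_equal(rs$features[[6]], avg[16:18, ])
  expect_equal(do.call(rbind, rs$features), avg)
  expect_error(build_ecg_records(avg[1:17, ]), "18")
})

test_that("pipeline is deterministic, structural, aligned and linear", {
  sim <- clean_ecg()
  rs1 <- process_ecg(sim$signal)
  rs2 <- process_ecg(sim$signal)
  expect_identical(rs1, rs2)

  # structure: 6 records x 3 pulses x 160 samples
  m <- do.call(rbind, rs1$features)
  expect_equal(dim(m), c(18L, 160L))
  expect_true(all(is.finite(m)))

  # R alignment: QRS maximum at or adjacent to offset 68 (1-based)
  peak_at <- apply(m[, 63:73], 1, which.max) + 62
  expect_true(all(abs(peak_at - 68) <= 1))

  # linearity: scaling the signal scales every record vector
  rs3 <- process_ecg(3.5 * sim$signal)
  expect_equal(do.call(rbind, rs3$features), 3.5 * m, tolerance = 1e-10)

  # too few beats is an explicit error
  short <- clean_ecg(n_beats = 20)
  expect_error(process_ecg(short$signal), "36")
})
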