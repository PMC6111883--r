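# Independent brute-force oracles, written before the implementations
# they check and kept free of any package internals.

# Guided filter by explicit per-window loops: population moments,
# windows truncated at vector ends and at block boundaries.
gf_oracle <- function(input, guide, radius, eps, boundaries = integer(0)) {
  L <- length(input)
  cuts <- c(0, boundaries[boundaries < L], L)
  out <- numeric(L)
  for (blk in seq_len(length(cuts) - 1)) {
    idx <- (cuts[blk] + 1):cuts[blk + 1]
    g <- guide[idx]
    x <- input[idx]
    Lb <- length(idx)
    a <- numeric(Lb)
    b <- numeric(Lb)
    for (k in seq_len(Lb)) {
      win <- max(1, k - radius):min(Lb, k + radius)
      mg <- mean(g[win])
      mx <- mean(x[win])
      cov_gx <- mean(g[win] * x[win]) - mg * mx
      var_g <- mean(g[win]^2) - mg^2
      a[k] <- cov_gx / (var_g + eps)
      b[k] <- mx - a[k] * mg
    }
    for (i in seq_len(Lb)) {
      win <- max(1, i - radius):min(Lb, i + radius)
      out[cuts[blk] + i] <- mean(a[win] * g[i] + b[win])
    }
  }
  out
}

# FAR/FRR by explicit counting at one threshold (accept iff score <= th).
rates_oracle <- function(genuine, imposter, th) {
  fa <- 0
  for (v in imposter) if (v <= th) fa <- fa + 1
  fr <- 0
  for (v in genuine) if (v > th) fr <- fr + 1
  c(far = fa / length(imposter), frr = fr / length(genuine))
}

# Small helper: a fully deterministic two-modality trial pool with the
# wa_pool column layout, for metric tests that need exact values.
make_pool <- function(gen_ecg, imp_ecg, gen_msp = gen_ecg,
                      imp_msp = imp_ecg) {
  stopifnot(length(gen_msp) == length(gen_ecg),
            length(imp_msp) == length(imp_ecg))
  out <- tibble::tibble(
    subject = "s1",
    combo = 1L,
    probe_subject = rep(c("s1", "s2"),
                        c(length(gen_ecg), length(imp_ecg))),
    record = 1L,
    genuine = rep(c(TRUE, FALSE), c(length(gen_ecg), length(imp_ecg))),
    ecg = c(gen_ecg, imp_ecg),
    msp = c(gen_msp, imp_msp)
  )
  class(out) <- c("wa_pool", class(out))
  out
}

# A tiny cohort record set built directly from per-subject feature
# generators, bypassing the signal pipelines (for protocol tests that
# need full control of the feature vectors).
make_record_set <- function(n_subjects, seed = 1, noise = 0.05) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(n_subjects), function(s) {
      base_e <- rnorm(160)
      base_m <- abs(rnorm(128)) + 1
      dplyr::bind_rows(
        wa_record_set(sprintf("s%02d", s), "ecg",
                      lapply(1:6, function(r)
                        matrix(rep(base_e, 3), 3, byrow = TRUE) +
                          noise * matrix(rnorm(3 * 160), 3))),
        wa_record_set(sprintf("s%02d", s), "msp",
                      lapply(1:6, function(r)
                        matrix(rep(base_m, 3), 3, byrow = TRUE) +
                          noise * matrix(rnorm(3 * 128), 3)))
      )
    }))
  })
}

# Noise-free, well-separated synthetic cohort (degenerate world).
simulate_noise_free <- function(n, seed) {
  simulate_cohort(
    n, seed = seed,
    ecg = ecg_morph_params(rr_sd = 0, baseline_amp = 0, noise_sd = 0,
                           beat_gain_sd = 0, artifact_prob = 0),
    msp_gain_sd = 0, msp_add_sd = 0, msp_cycle_gain_sd = 0,
    contact_sd = 0, detach_prob = 0, noise_burst_prob = 0
  )
}

amplitude_at <- function(x, freq, fs) {
  n <- length(x)
  2 * abs(stats::fft(x))[round(freq * n / fs) + 1] / n
}
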