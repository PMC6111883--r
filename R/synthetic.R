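# Synthetic cohort generator: per-subject stable ECG pulse morphology
# (five Gaussian waves per beat) and per-subject stable 128-D MSP
# intensity patterns, with controllable intra-subject noise,
# inter-subject dispersion and sensor-contact degradation.  Every
# generated quantity carries ground truth, so the whole pipeline is
# testable without hardware.

#' ECG morphology parameters
#'
#' One beat is the sum of five Gaussian bumps (P, Q, R, S, T; Q and S
#' negative) placed relative to the R-peak.  Defaults describe a normal
#' sinus beat at 75 bpm with wave timings and amplitudes in the usual
#' physiological range (amplitudes in arbitrary units relative to
#' R = 1).
#'
#' @param waves 5 x 3 numeric matrix (rows P, Q, R, S, T; columns
#'   `amp`, `center_s` relative to the R-peak, `width_s`).
#' @param rr_mean,rr_sd Mean and standard deviation of the RR interval
#'   in seconds (draws are truncated below at 0.4 s).
#' @param baseline_amp,baseline_freq Sinusoidal baseline-wander
#'   amplitude (a.u.) and frequency (Hz).
#' @param noise_sd Additive white-noise standard deviation (a.u.).
#' @param beat_gain_sd Log-normal per-beat amplitude jitter (electrode
#'   contact variability); 0 disables it.
#' @param artifact_prob Per-beat probability that a muscle-tremor
#'   episode starts: the episode covers the next four beats, whose
#'   neighbourhood gets high-frequency (> 20 Hz) noise of
#'   `artifact_scale` times the white-noise sd.  Such EMG-like
#'   episodes sit above the QRS detector's 5--15 Hz band (detection
#'   survives) but inside the 0.5--40 Hz feature band, so the affected
#'   records are catastrophically far from their own template --
#'   reproducing the heavy genuine-distance tails of real
#'   finger-on-electrode acquisition; 0 disables them.
#' @param artifact_scale Noise multiplier inside an artifact episode.
#' @return A list of class `ecg_morph_params`.
#' @export
ecg_morph_params <- function(waves = default_ecg_waves(),
                             rr_mean = 0.8, rr_sd = 0.02,
                             baseline_amp = 0.08, baseline_freq = 0.3,
                             noise_sd = 0.03, beat_gain_sd = 0.05,
                             artifact_prob = 0.03, artifact_scale = 5) {
  if (any(waves[, "width_s"] <= 0)) stop("wave widths must be positive",
                                         call. = FALSE)
  if (rr_mean <= 0.3) stop("rr_mean must exceed 0.3 s", call. = FALSE)
  if (rr_sd < 0 || noise_sd < 0 || beat_gain_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (artifact_prob < 0 || artifact_prob > 1 || artifact_scale < 0) {
    stop("invalid artifact parameters", call. = FALSE)
  }
  structure(list(waves = waves, rr_mean = rr_mean, rr_sd = rr_sd,
                 baseline_amp = baseline_amp,
                 baseline_freq = baseline_freq,
                 noise_sd = noise_sd, beat_gain_sd = beat_gain_sd,
                 artifact_prob = artifact_prob,
                 artifact_scale = artifact_scale),
            class = "ecg_morph_params")
}

default_ecg_waves <- function() {
  m <- rbind(
    P = c(0.15, -0.160, 0.022),
    Q = c(-0.12, -0.024, 0.010),
    R = c(1.00, 0.000, 0.012),
    S = c(-0.22, 0.026, 0.011),
    T = c(0.35, 0.260, 0.042)
  )
  colnames(m) <- c("amp", "center_s", "width_s")
  m
}

#' Generate a continuous synthetic ECG for one subject
#'
#' Beats are placed at RR intervals drawn from a truncated normal;
#' each beat adds the five Gaussian waves scaled by a per-beat gain,
#' on top of sinusoidal baseline wander (random phase) and white
#' noise.  True R-peak sample indices are returned as ground truth.
#' Randomness comes from the caller's RNG state.
#'
#' @param params An [ecg_morph_params()].
#' @param n_beats Number of beats (>= 1).
#' @param fs Sampling rate in Hz.
#' @return List with `signal` (numeric vector), `r_peaks` (1-based
#'   integer indices) and `fs`.
#' @export
generate_subject_ecg <- function(params = ecg_morph_params(),
                                 n_beats = 40L, fs = 250) {
  if (n_beats < 1) stop("n_beats must be >= 1", call. = FALSE)
  rr <- pmax(0.4, params$rr_mean + params$rr_sd * rnorm(n_beats - 1L))
  beat_t <- 1.0 + c(0, cumsum(rr))
  n <- as.integer(ceiling((beat_t[n_beats] + 1.0) * fs))
  tt <- (seq_len(n) - 1L) / fs
  x <- numeric(n)
  # Electrode-contact quality drifts slowly, so the per-beat gain is a
  # stationary AR(1) (lag-1 correlation 0.9) on the log scale: beats of
  # the same record share most of their gain, and occasional stretches
  # of poor contact give realistically heavy-tailed genuine distances.
  w <- numeric(n_beats)
  z <- rnorm(n_beats)
  w[1] <- z[1]
  for (b in seq_len(n_beats)[-1]) w[b] <- 0.9 * w[b - 1] +
    sqrt(1 - 0.81) * z[b]
  gains <- exp(params$beat_gain_sd * w)
  for (b in seq_len(n_beats)) {
    for (w in seq_len(nrow(params$waves))) {
      a <- params$waves[w, "amp"] * gains[b]
      mu <- beat_t[b] + params$waves[w, "center_s"]
      sg <- params$waves[w, "width_s"]
      lo <- max(1L, as.integer(floor((mu - 7 * sg) * fs)) + 1L)
      hi <- min(n, as.integer(ceiling((mu + 7 * sg) * fs)) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      x[idx] <- x[idx] + a * exp(-((tt[idx] - mu)^2) / (2 * sg^2))
    }
  }
  phase <- runif(1, 0, 2 * pi)
  x <- x + params$baseline_amp * sin(2 * pi * params$baseline_freq * tt +
                                       phase)
  if (params$noise_sd > 0) x <- x + params$noise_sd * rnorm(n)
  if (params$artifact_prob > 0 && params$noise_sd > 0) {
    starts <- which(runif(n_beats) < params$artifact_prob)
    bad <- unique(unlist(lapply(starts, function(b)
      b:min(n_beats, b + 3L))))
    if (length(bad) > 0) {
      # EMG-like tremor: white noise high-passed above the QRS
      # detector's band, added around each affected beat
      tremor <- filtfilt_sos(rnorm(n), list(biquad_highpass(20, fs)), fs)
      half <- as.integer(round(0.3 * fs))
      mask <- rep(FALSE, n)
      for (b in bad) {
        ctr <- as.integer(round(beat_t[b] * fs)) + 1L
        mask[max(1L, ctr - half):min(n, ctr + half)] <- TRUE
      }
      x[mask] <- x[mask] + params$artifact_scale * params$noise_sd *
        tremor[mask]
    }
  }
  list(signal = x, r_peaks = as.integer(round(beat_t * fs)) + 1L, fs = fs)
}

#' MSP subject parameters
#'
#' @param base_pattern Positive length-128 intensity pattern (blocks
#'   `[red | yellow | red-run IR | yellow-run IR]`, each smooth over
#'   the 32 detectors).  See [make_msp_base_pattern()].
#' @param gain_sd Relative multiplicative noise per reading
#'   (independent across sources and detectors, so it largely averages
#'   out in the per-cycle aggregation).
#' @param add_sd Additive noise (a.u.) per reading.
#' @param cycle_gain_sd Log-normal gain shared by every reading of a
#'   cycle -- LED drive and contact-pressure variability across wear
#'   events.  Unlike `gain_sd` it does not average out over sources,
#'   so it is the main driver of intra-subject MSP distance spread.
#' @param contact_severity Mean attenuation of the edge detectors
#'   (indices 1--4 and 29--32 of each block) in `[0, 1]`; emulates
#'   photodiodes at the band edge lifting off the skin.
#' @param contact_sd Standard deviation of the per-cycle severity draw;
#'   0 models a firmly attached (separate) sensor, positive values the
#'   integrated band whose contact varies across cycles.
#' @param detach_prob Per-cycle probability that the band edge lifts
#'   off completely for that cycle: the severity jumps by an extra
#'   `U(0.3, 0.7)`.  Rare but catastrophic for the affected cycle;
#'   0 disables it.
#' @param noise_burst_prob Per-cycle probability of a motion episode:
#'   every detector of the cycle picks up extra noise (relative sd
#'   `noise_burst_sd`, shared across sources so it survives the
#'   per-type aggregation).  0 disables it.
#' @param noise_burst_sd Relative standard deviation of a motion
#'   episode.
#' @return A list of class `msp_subject_params`.
#' @export
msp_subject_params <- function(base_pattern = make_msp_base_pattern(0),
                               gain_sd = 0.04, add_sd = 0.01,
                               cycle_gain_sd = 0,
                               contact_severity = 0.15,
                               contact_sd = 0, detach_prob = 0,
                               noise_burst_prob = 0,
                               noise_burst_sd = 0.35) {
  if (length(base_pattern) != MSP_FEATURE_LEN || any(base_pattern <= 0)) {
    stop("base_pattern must be 128 positive intensities", call. = FALSE)
  }
  if (gain_sd < 0 || add_sd < 0 || contact_sd < 0 || cycle_gain_sd < 0) {
    stop("standard deviations must be non-negative", call. = FALSE)
  }
  if (contact_severity < 0 || contact_severity > 1) {
    stop("contact_severity must lie in [0, 1]", call. = FALSE)
  }
  if (detach_prob < 0 || detach_prob > 1 ||
      noise_burst_prob < 0 || noise_burst_prob > 1 || noise_burst_sd < 0) {
    stop("invalid artifact parameters", call. = FALSE)
  }
  structure(list(base_pattern = base_pattern, gain_sd = gain_sd,
                 add_sd = add_sd, cycle_gain_sd = cycle_gain_sd,
                 contact_severity = contact_severity,
                 contact_sd = contact_sd, detach_prob = detach_prob,
                 noise_burst_prob = noise_burst_prob,
                 noise_burst_sd = noise_burst_sd),
            class = "msp_subject_params")
}

#' Draw a smooth per-subject MSP base pattern
#'
#' Each 32-detector block is a block-specific mean level modulated, on
#' the log scale, by a low-order random Fourier series plus two narrow
#' Gaussian bumps at random detector positions.  The bumps give each
#' subject sharp local structure (the kind of abrupt transitions real
#' wrist anatomy produces) that a local affine fit of another
#' subject's template cannot reproduce.  `scale = 0` returns the
#' population profile (identical across subjects).
#'
#' @param scale Inter-subject dispersion (log-scale sd of the Fourier
#'   amplitudes and block levels).
#' @param levels Population mean level per block.
#' @return Numeric vector of length 128.
#' @export
make_msp_base_pattern <- function(scale = 0.12,
                                  levels = c(1.0, 0.9, 1.3, 1.2)) {
  d <- seq_len(N_DETECTORS)
  unlist(lapply(seq_along(levels), function(b) {
    lvl <- levels[b] * exp(rnorm(1, 0, scale / 2))
    s <- numeric(N_DETECTORS)
    for (k in 1:3) {
      s <- s + rnorm(1, 0, scale / k) * sin(2 * pi * k * d / N_DETECTORS +
                                              runif(1, 0, 2 * pi))
    }
    for (j in 1:2) {
      ctr <- runif(1, 4, N_DETECTORS - 3)
      s <- s + rnorm(1, 0, 1.5 * scale) * exp(-(d - ctr)^2 / (2 * 1.5^2))
    }
    lvl * exp(s)
  }), use.names = FALSE)
}

msp_edge_detectors <- c(1:4, 29:32)

#' Generate raw MSP cycles for one subject
#'
#' For each acquisition mode (red/IR and yellow/IR), `n_cycles` cycles
#' of 16 x 32 readings are drawn: reading = block base value x
#' (1 + gain noise) + additive noise, clipped at zero.  Edge detectors
#' are first attenuated by `1 - severity`, with the severity drawn per
#' cycle from `N(contact_severity, contact_sd)` clamped to `[0, 1]`.
#' Randomness comes from the caller's RNG state.
#'
#' @param params An [msp_subject_params()].
#' @param n_cycles Cycles per mode (the protocol uses 20).
#' @return List with `red` and `yellow`: lists of [msp_cycle()]s.
#' @export
generate_subject_msp <- function(params = msp_subject_params(),
                                 n_cycles = MSP_CYCLES_PER_MODE) {
  if (n_cycles < 1) stop("n_cycles must be >= 1", call. = FALSE)
  gen_mode <- function(mode) {
    vis_block <- if (mode == "red_ir") 1L else 2L
    ir_block <- if (mode == "red_ir") 3L else 4L
    block <- function(b) params$base_pattern[(b - 1L) * N_DETECTORS +
                                               seq_len(N_DETECTORS)]
    lapply(seq_len(n_cycles), function(i) {
      sev <- rnorm(1, params$contact_severity, params$contact_sd)
      if (params$detach_prob > 0 && runif(1) < params$detach_prob) {
        sev <- sev + runif(1, 0.3, 0.7)
      }
      sev <- min(1, max(0, sev))
      cyc_gain <- exp(rnorm(1, 0, params$cycle_gain_sd))
      base <- rbind(
        matrix(rep(block(vis_block), each = 8L), nrow = 8L),
        matrix(rep(block(ir_block), each = 8L), nrow = 8L)
      )
      base[, msp_edge_detectors] <- base[, msp_edge_detectors] * (1 - sev)
      base <- base * cyc_gain
      if (params$noise_burst_prob > 0 &&
          runif(1) < params$noise_burst_prob) {
        burst <- 1 + params$noise_burst_sd * rnorm(N_DETECTORS)
        base <- base * matrix(rep(burst, each = N_SOURCES),
                              nrow = N_SOURCES)
        base[base < 0] <- 0
      }
      noisy <- base * (1 + params$gain_sd *
                         matrix(rnorm(length(base)), nrow = N_SOURCES)) +
        params$add_sd * matrix(rnorm(length(base)), nrow = N_SOURCES)
      noisy[noisy < 0] <- 0
      msp_cycle(noisy, mode)
    })
  }
  list(red = gen_mode("red_ir"), yellow = gen_mode("yellow_ir"))
}

#' Simulate a ground-truthed cohort
#'
#' Subject parameters are drawn i.i.d. around the population defaults
#' with dispersion `inter_subject_scale`; each subject then gets a
#' continuous ECG signal (with true R-peak indices) and raw MSP cycles
#' for both modes.  All randomness flows from `seed` through
#' per-subject derived streams, so subject `i` is identical in any
#' cohort of size >= `i` generated from the same seed.
#'
#' @param n_subjects Cohort size (>= 2).
#' @param seed Master seed.
#' @param inter_subject_scale Dispersion of subject parameters (0 makes
#'   all subjects share parameters; larger separates them).
#' @param ecg Population [ecg_morph_params()].
#' @param msp_gain_sd,msp_add_sd,msp_cycle_gain_sd,contact_severity,contact_sd,detach_prob,noise_burst_prob
#'   Population MSP noise/contact settings (see
#'   [msp_subject_params()]).  The cohort defaults
#'   (`msp_cycle_gain_sd = 0.06`, `detach_prob = 0.03`) give each
#'   subject a realistic intra-subject MSP distance spread with rare
#'   catastrophic contact losses.
#' @param n_beats Beats per subject's ECG (>= 38 so that 36 clean
#'   pulses survive windowing).
#' @param n_cycles MSP cycles per mode.
#' @return A tibble of class `wa_cohort` with one row per subject and
#'   list-columns `ecg` (list: `signal`, `r_peaks`, `fs`), `msp`
#'   (list: `red`, `yellow`) and `params`; the master seed is kept as
#'   an attribute.
#' @export
simulate_cohort <- function(n_subjects = 150L, seed = 42L,
                            inter_subject_scale = 0.12,
                            ecg = ecg_morph_params(),
                            msp_gain_sd = 0.04, msp_add_sd = 0.01,
                            msp_cycle_gain_sd = 0.06,
                            contact_severity = 0.15, contact_sd = 0,
                            detach_prob = 0, noise_burst_prob = 0.04,
                            n_beats = 40L,
                            n_cycles = MSP_CYCLES_PER_MODE) {
  if (n_subjects < 2) stop("n_subjects must be >= 2", call. = FALSE)
  subject_seeds <- withr::with_seed(as.integer(seed),
                                    sample.int(.Machine$integer.max - 1L,
                                               n_subjects))
  rows <- lapply(seq_len(n_subjects), function(i) {
    withr::with_seed(subject_seeds[i], {
      sp <- draw_subject_params(ecg, inter_subject_scale, msp_gain_sd,
                                msp_add_sd, msp_cycle_gain_sd,
                                contact_severity, contact_sd, detach_prob,
                                noise_burst_prob)
      sig <- generate_subject_ecg(sp$ecg, n_beats)
      cyc <- generate_subject_msp(sp$msp, n_cycles)
      tibble::tibble(subject = sprintf("s%03d", i),
                     ecg = list(sig), msp = list(cyc), params = list(sp))
    })
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "inter_subject_scale") <- inter_subject_scale
  class(out) <- c("wa_cohort", class(out))
  out
}

# Per-subject parameter draw: multiplicative log-normal dispersion on
# wave amplitudes/widths and additive jitter on non-R wave centers; the
# R center stays at zero because it is the alignment anchor.
draw_subject_params <- function(ecg, scale, gain_sd, add_sd,
                                cycle_gain_sd, severity, contact_sd,
                                detach_prob = 0, noise_burst_prob = 0) {
  w <- ecg$waves
  nw <- nrow(w)
  w[, "amp"] <- w[, "amp"] * exp(scale * rnorm(nw))
  # identity lives mainly in wave timing and width: these shape
  # differences are not locally affine in another subject's template,
  # so they survive template-guided filtering of an imposter probe
  w[, "width_s"] <- w[, "width_s"] * exp(scale * rnorm(nw))
  shift <- rnorm(nw, 0, 0.1 * scale)
  shift[rownames(w) == "R"] <- 0
  w[, "center_s"] <- w[, "center_s"] + shift
  # snap the subject's beat period to the 250 Hz sample grid so that a
  # noise-free subject produces bit-identical pulses
  rr <- round(max(0.5, ecg$rr_mean * exp(0.25 * scale * rnorm(1))) * 250) / 250
  list(
    ecg = ecg_morph_params(w, rr_mean = rr, rr_sd = ecg$rr_sd,
                           baseline_amp = ecg$baseline_amp,
                           baseline_freq = ecg$baseline_freq,
                           noise_sd = ecg$noise_sd,
                           beat_gain_sd = ecg$beat_gain_sd,
                           artifact_prob = ecg$artifact_prob,
                           artifact_scale = ecg$artifact_scale),
    msp = msp_subject_params(make_msp_base_pattern(scale),
                             gain_sd = gain_sd, add_sd = add_sd,
                             cycle_gain_sd = cycle_gain_sd,
                             contact_severity = severity,
                             contact_sd = contact_sd,
                             detach_prob = detach_prob,
                             noise_burst_prob = noise_burst_prob)
  )
}

#' Process a simulated cohort into record sets
#'
#' Runs [process_ecg()] and [process_msp()] on every subject of a
#' [simulate_cohort()] result.  The per-subject 18-of-20 MSP selection
#' seeds are derived deterministically from `seed`.
#'
#' @param cohort A `wa_cohort`.
#' @param seed Seed for the MSP record selection; defaults to the
#'   cohort's master seed.
#' @return A cohort-level [wa_record_set()] tibble with both
#'   modalities.
#' @export
process_cohort <- function(cohort, seed = NULL) {
  seed <- as.integer(seed %||% attr(cohort, "seed") %||% 1L)
  n <- nrow(cohort)
  sel_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max - 1L, n))
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    sig <- cohort$ecg[[i]]
    cyc <- cohort$msp[[i]]
    dplyr::bind_rows(
      process_ecg(sig$signal, fs = sig$fs,
                  subject_id = cohort$subject[i]),
      process_msp(cyc$red, cyc$yellow, seed = sel_seeds[i],
                  subject_id = cohort$subject[i])
    )
  }))
}
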