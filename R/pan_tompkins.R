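# Pan-Tompkins QRS detection: band-pass -> derivative -> squaring ->
# moving-window integration -> adaptive two-level thresholding with a
# refractory period and RR search-back.  All stage constants are
# arguments so the parameterization stays auditable.

#' Detect R-peaks with a Pan-Tompkins detector
#'
#' The classic cascade: a 5--15 Hz QRS band-pass (zero-phase biquads), a
#' five-point derivative, squaring, and a 150 ms moving-window
#' integrator.  Local maxima of the integrated energy are classified as
#' signal or noise by adaptive running thresholds
#' (`THR = NPK + 0.25 (SPK - NPK)`), with a 200 ms refractory period and
#' an RR-interval search-back that rescues missed beats at half
#' threshold.  Each accepted energy peak is refined to the local maximum
#' of the input signal so the returned index lands on the R wave itself.
#'
#' @param signal Baseline-corrected ECG, numeric vector (or data frame,
#'   amplitude in the last column).  At least 2 s long.
#' @param fs Sampling rate in Hz.
#' @param band QRS passband in Hz, length-2 numeric.
#' @param integration_s Moving-integration window length in seconds.
#' @param refractory_s Minimum separation between detections in seconds.
#' @param searchback If `TRUE`, look back for a sub-threshold beat when
#'   more than 1.66 times the running RR average has elapsed.
#' @return Strictly increasing integer vector of 1-based R-peak sample
#'   indices; `integer(0)` when no QRS energy is found (e.g. a flat
#'   signal).
#' @examples
#' sim <- generate_subject_ecg(ecg_morph_params(noise_sd = 0), n_beats = 10)
#' peaks <- detect_r_peaks(bandpass_baseline_correct(sim$signal))
#' @export
detect_r_peaks <- function(signal, fs = 250, band = c(5, 15),
                           integration_s = 0.15, refractory_s = 0.2,
                           searchback = TRUE) {
  x <- as_signal(signal)
  n <- length(x)
  if (n < 2 * fs) stop("signal shorter than 2 s", call. = FALSE)
  if (all(x == x[1])) return(integer(0))

  bp <- filtfilt_sos(x, list(biquad_highpass(band[1], fs),
                             biquad_lowpass(band[2], fs)), fs)
  # centered five-point derivative, zero at the edges
  dv <- c(0, 0, (2 * bp[5:n] + bp[4:(n - 1)] -
                   bp[2:(n - 3)] - 2 * bp[1:(n - 4)]) / 8, 0, 0)
  sq <- dv^2
  win <- max(1L, as.integer(round(integration_s * fs)))
  integ <- as.numeric(stats::filter(sq, rep(1 / win, win), sides = 2))
  integ[is.na(integ)] <- 0

  refr <- as.integer(round(refractory_s * fs))
  cand <- local_maxima(integ)
  cand <- cand[integ[cand] > 0]
  if (length(cand) == 0) return(integer(0))

  # adaptive thresholds initialized from the first two seconds
  lead <- integ[seq_len(min(n, 2L * fs))]
  spk <- 0.25 * max(lead)
  npk <- 0.5 * mean(lead)
  thr <- npk + 0.25 * (spk - npk)

  accepted <- integer(0)
  rr_hist <- numeric(0)
  last <- -Inf
  noise_since <- integer(0)  # candidates since the last accepted beat

  for (k in cand) {
    pk <- integ[k]
    if (k - last < refr) next
    if (pk > thr) {
      if (length(accepted) > 0) rr_hist <- c(rr_hist, k - last)
      accepted <- c(accepted, k)
      last <- k
      noise_since <- integer(0)
      spk <- 0.125 * pk + 0.875 * spk
    } else {
      noise_since <- c(noise_since, k)
      npk <- 0.125 * pk + 0.875 * npk
      # search-back: long gap since the last beat -> take the best
      # missed candidate above half threshold
      if (searchback && length(rr_hist) > 0 && length(accepted) > 0) {
        rr_avg <- mean(tail_n(rr_hist, 8))
        if (k - last > 1.66 * rr_avg && length(noise_since) > 0) {
          ok <- noise_since[integ[noise_since] > 0.5 * thr &
                              noise_since - last >= refr]
          if (length(ok) > 0) {
            kb <- ok[which.max(integ[ok])]
            rr_hist <- c(rr_hist, kb - last)
            accepted <- c(accepted, kb)
            last <- max(accepted)
            noise_since <- noise_since[noise_since > kb]
            spk <- 0.25 * integ[kb] + 0.75 * spk
          }
        }
      }
    }
    thr <- npk + 0.25 * (spk - npk)
  }
  accepted <- sort(accepted)

  # refine each energy peak to the R wave on the input signal
  half <- as.integer(round(integration_s * fs / 2)) + 2L
  peaks <- vapply(accepted, function(k) {
    lo <- max(1L, k - half)
    hi <- min(n, k + half)
    lo + which.max(x[lo:hi]) - 1L
  }, integer(1))
  peaks <- sort(unique(peaks))
  # refinement can pull neighbours onto the same R; re-impose refractory
  if (length(peaks) > 1) {
    keep <- c(TRUE, diff(peaks) >= refr)
    peaks <- peaks[keep]
  }
  as.integer(peaks)
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

tail_n <- function(v, k) if (length(v) > k) v[(length(v) - k + 1):length(v)] else v
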