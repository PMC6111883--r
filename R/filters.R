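# Zero-phase IIR filtering built from second-order (biquad) sections.
# No DSP package is assumed: coefficients follow the standard audio-EQ
# ("RBJ") cookbook Butterworth forms and each section is run forward and
# backward over an odd-reflection padded signal, so the net response has
# zero phase and squared magnitude.

biquad_lowpass <- function(fc, fs, q = 1 / sqrt(2)) {
  w0 <- 2 * pi * fc / fs
  alpha <- sin(w0) / (2 * q)
  cw <- cos(w0)
  a0 <- 1 + alpha
  list(
    b = c((1 - cw) / 2, 1 - cw, (1 - cw) / 2) / a0,
    a = c(1, -2 * cw / a0, (1 - alpha) / a0)
  )
}

biquad_highpass <- function(fc, fs, q = 1 / sqrt(2)) {
  w0 <- 2 * pi * fc / fs
  alpha <- sin(w0) / (2 * q)
  cw <- cos(w0)
  a0 <- 1 + alpha
  list(
    b = c((1 + cw) / 2, -(1 + cw), (1 + cw) / 2) / a0,
    a = c(1, -2 * cw / a0, (1 - alpha) / a0)
  )
}

biquad_notch <- function(fc, fs, q = 30) {
  w0 <- 2 * pi * fc / fs
  alpha <- sin(w0) / (2 * q)
  cw <- cos(w0)
  a0 <- 1 + alpha
  list(
    b = c(1, -2 * cw, 1) / a0,
    a = c(1, -2 * cw / a0, (1 - alpha) / a0)
  )
}

# Single causal pass of one biquad with zero initial conditions.
biquad_pass <- function(x, coef) {
  v <- stats::filter(c(0, 0, x), coef$b, method = "convolution", sides = 1)
  v <- v[-(1:2)]
  as.numeric(stats::filter(v, -coef$a[2:3], method = "recursive"))
}

# Forward-backward pass over an odd-reflection padded signal; `sections`
# is a list of biquads applied in cascade.
filtfilt_sos <- function(x, sections, fs) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(3 * fs))
  if (pad > 0) {
    pre <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    post <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    y <- c(pre, x, post)
  } else {
    y <- x
  }
  for (s in sections) y <- biquad_pass(y, s)
  y <- rev(y)
  for (s in sections) y <- biquad_pass(y, s)
  y <- rev(y)
  if (pad > 0) y <- y[seq(pad + 1L, pad + n)]
  y
}

#' Band-pass baseline correction of an ECG signal
#'
#' Removes baseline drift and out-of-band noise with a zero-phase
#' Butterworth band-pass (second-order high-pass and low-pass sections
#' run forward and backward).  The DC component and slow electrode
#' drift fall well below the low edge and are strongly attenuated.
#'
#' @param signal Numeric vector of ECG samples, or a data frame whose
#'   last column holds the amplitude (e.g. the `time_s`/`amplitude`
#'   layout read by [read_ecg_signal()]).
#' @param low_hz,high_hz Passband edges in Hz. Must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @param fs Sampling rate in Hz.
#' @return Numeric vector, same length as the input.
#' @examples
#' x <- sin(2 * pi * 10 * seq(0, 4, by = 1 / 250))
#' y <- bandpass_baseline_correct(x + 5, fs = 250)
#' mean(y)  # DC removed
#' @export
bandpass_baseline_correct <- function(signal, low_hz = 0.5, high_hz = 40,
                                      fs = 250) {
  x <- as_signal(signal)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < fs/2",
         call. = FALSE)
  }
  if (length(x) < 2 * fs) {
    stop("signal too short for band-pass warm-up (need >= 2 s)",
         call. = FALSE)
  }
  filtfilt_sos(x, list(biquad_highpass(low_hz, fs),
                       biquad_lowpass(high_hz, fs)), fs)
}

#' Notch filter for power-line interference
#'
#' Second-order IIR notch (quality factor `q`) applied zero-phase.
#' Emulates the wearable device's hardware 60 Hz stage; may be skipped
#' for pre-filtered input.
#'
#' @inheritParams bandpass_baseline_correct
#' @param notch_hz Center frequency to reject, in Hz (`< fs/2`).
#' @param q Quality factor (center frequency over -3 dB bandwidth).
#' @return Numeric vector, same length as the input.
#' @export
notch_filter <- function(signal, notch_hz = 60, fs = 250, q = 30) {
  x <- as_signal(signal)
  if (!(notch_hz > 0 && notch_hz < fs / 2)) {
    stop("notch frequency must lie in (0, fs/2)", call. = FALSE)
  }
  filtfilt_sos(x, list(biquad_notch(notch_hz, fs, q)), fs)
}

# Accept bare numeric vectors or tabular signals (amplitude in the last
# column, as written by the columnar text format).
as_signal <- function(signal) {
  if (is.data.frame(signal)) {
    x <- signal[[ncol(signal)]]
  } else {
    x <- signal
  }
  if (!is.numeric(x)) stop("signal must be numeric", call. = FALSE)
  as.numeric(x)
}
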