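# From continuous ECG to the 6-records x 3-averaged-pulses structure
# used for enrollment and verification.

ECG_PULSE_LEN <- 160L
ECG_PRE <- 67L   # samples kept before the R-peak
ECG_POST <- 92L  # samples kept after the R-peak (window inclusive)
N_RECORDS <- 6L
PULSES_PER_RECORD <- 3L

#' Extract fixed-length P-QRS-T pulses around R-peaks
#'
#' Each pulse spans 67 samples before to 92 samples after its R-peak
#' (160 samples, 0.64 s at 250 Hz), both ends inclusive, so the R-peak
#' always sits at position 68 (1-based) of the fragment.  Peaks whose
#' window would run past either end of the signal are silently skipped.
#'
#' @param signal Numeric ECG vector (typically baseline-corrected).
#' @param r_peaks Integer vector of 1-based R-peak sample indices.
#' @return Numeric matrix with one 160-sample pulse per row; the
#'   attribute `r_peaks` records which peaks survived.
#' @export
segment_pulses <- function(signal, r_peaks) {
  x <- as_signal(signal)
  r_peaks <- as.integer(r_peaks)
  if (any(r_peaks < 1L | r_peaks > length(x))) {
    stop("r_peaks must be valid indices into the signal", call. = FALSE)
  }
  keep <- r_peaks - ECG_PRE >= 1L & r_peaks + ECG_POST <= length(x)
  kept <- r_peaks[keep]
  out <- matrix(0, nrow = length(kept), ncol = ECG_PULSE_LEN)
  for (i in seq_along(kept)) {
    out[i, ] <- x[(kept[i] - ECG_PRE):(kept[i] + ECG_POST)]
  }
  structure(out, r_peaks = kept)
}

#' Average successive pulse pairs
#'
#' Non-overlapping pairs `(1,2), (3,4), ...` are averaged elementwise,
#' halving the count: the canonical 36 extracted pulses become 18
#' averaged pulses.  When more than `max_pulses` rows are supplied only
#' the first `max_pulses` are used; an odd count is truncated by one
#' with a warning.
#'
#' @param pulses Numeric matrix, one pulse per row.
#' @param max_pulses Upper bound on pulses used (default 36).
#' @return Numeric matrix with `nrow(pulses) / 2` rows.
#' @export
average_successive_pulses <- function(pulses, max_pulses = 36L) {
  if (!is.matrix(pulses) || nrow(pulses) < 2) {
    stop("need at least 2 pulses to average", call. = FALSE)
  }
  if (nrow(pulses) > max_pulses) pulses <- pulses[seq_len(max_pulses), , drop = FALSE]
  n <- nrow(pulses)
  if (n %% 2L == 1L) {
    warning("odd pulse count; dropping the last pulse")
    pulses <- pulses[seq_len(n - 1L), , drop = FALSE]
    n <- n - 1L
  }
  odd <- seq(1L, n, by = 2L)
  (pulses[odd, , drop = FALSE] + pulses[odd + 1L, , drop = FALSE]) / 2
}

#' Group 18 averaged pulses into six records of three
#'
#' Records preserve acquisition order: record r holds averaged pulses
#' `3r-2, 3r-1, 3r`.
#'
#' @param averaged Numeric matrix with exactly 18 rows (160 columns for
#'   ECG).
#' @param subject_id Identifier stored with the record set.
#' @param modality `"ecg"` or `"msp"`.
#' @return A record-set tibble (see [wa_record_set()]).
#' @export
build_ecg_records <- function(averaged, subject_id = "s1", modality = "ecg") {
  if (!is.matrix(averaged) || nrow(averaged) != N_RECORDS * PULSES_PER_RECORD) {
    stop("exactly 18 averaged pulses are required, got ",
         if (is.matrix(averaged)) nrow(averaged) else "a non-matrix",
         call. = FALSE)
  }
  if (!all(is.finite(averaged))) stop("non-finite pulse values", call. = FALSE)
  wa_record_set(subject_id, modality,
                lapply(seq_len(N_RECORDS), function(r) {
                  averaged[(PULSES_PER_RECORD * (r - 1) + 1):(PULSES_PER_RECORD * r), ,
                           drop = FALSE]
                }))
}

#' Record-set container
#'
#' The canonical per-subject, per-modality structure: a tibble with one
#' row per record and a list-column `features` holding the 3 x L matrix
#' of feature vectors (L = 160 for ECG, 128 for MSP).  Cohort-level
#' record sets are just row-bound subject record sets.
#'
#' @param subject_id Character scalar.
#' @param modality `"ecg"` or `"msp"`.
#' @param records List of six 3 x L numeric matrices.
#' @return A tibble of class `wa_record_set` with columns `subject`,
#'   `modality`, `record`, `features`.
#' @export
wa_record_set <- function(subject_id, modality, records) {
  stopifnot(length(records) == N_RECORDS)
  out <- tibble::tibble(
    subject = as.character(subject_id),
    modality = match.arg(modality, c("ecg", "msp")),
    record = seq_len(N_RECORDS),
    features = records
  )
  class(out) <- c("wa_record_set", class(out))
  out
}

#' Process a continuous ECG signal into a record set
#'
#' Runs the full front end: band-pass baseline correction (plus an
#' optional power-line notch), Pan-Tompkins R-peak detection, extraction
#' of 160-sample pulses, pair averaging of the first 36 pulses into 18,
#' and grouping into six records of three.
#'
#' @param signal Numeric vector, or a two-column data frame
#'   (`time_s`, `amplitude`).
#' @param fs Sampling rate in Hz.
#' @param subject_id Identifier for the emitted record set.
#' @param low_hz,high_hz Baseline-correction passband.
#' @param notch_hz Optional notch center frequency; `NULL` disables the
#'   software notch (the default: the device already applies one in
#'   hardware).
#' @return A [wa_record_set()] tibble (6 records x 3 pulses x 160).
#' @export
process_ecg <- function(signal, fs = 250, subject_id = "s1",
                        low_hz = 0.5, high_hz = 40, notch_hz = NULL) {
  x <- as_signal(signal)
  x <- bandpass_baseline_correct(x, low_hz, high_hz, fs)
  if (!is.null(notch_hz)) x <- notch_filter(x, notch_hz, fs)
  peaks <- detect_r_peaks(x, fs)
  pulses <- segment_pulses(x, peaks)
  if (nrow(pulses) < 36L) {
    stop("need at least 36 segmentable pulses, found ", nrow(pulses),
         call. = FALSE)
  }
  build_ecg_records(average_successive_pulses(pulses), subject_id, "ecg")
}
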