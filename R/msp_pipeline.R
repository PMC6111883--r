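# From raw multispectral skin photomatrix cycles (16 LED sources x 32
# photodiode detectors, two acquisition modes) to the 6-records x 3 x
# 128-D feature structure.

N_SOURCES <- 16L
N_DETECTORS <- 32L
MSP_FEATURE_LEN <- 128L
MSP_BLOCKS <- c(32L, 64L, 96L)  # cut points between the four 32-D blocks
MSP_CYCLES_PER_MODE <- 20L

#' Construct one MSP acquisition cycle
#'
#' @param readings 16 x 32 numeric matrix of photocurrent intensities
#'   (sources in rows, detectors in columns), all non-negative.
#' @param mode `"red_ir"` or `"yellow_ir"` -- which LED module acquired
#'   the cycle.
#' @param source_type Character vector of length 16 labelling each
#'   source `"visible"` or `"infrared"` (8 of each).
#' @return A list of class `msp_cycle`.
#' @export
msp_cycle <- function(readings, mode = c("red_ir", "yellow_ir"),
                      source_type = rep(c("visible", "infrared"), each = 8)) {
  mode <- match.arg(mode)
  if (!is.matrix(readings) || nrow(readings) != N_SOURCES ||
      ncol(readings) != N_DETECTORS) {
    stop("readings must be a 16 x 32 matrix", call. = FALSE)
  }
  if (any(readings < 0) || !all(is.finite(readings))) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  source_type <- match.arg(source_type, c("visible", "infrared"),
                           several.ok = TRUE)
  if (length(source_type) != N_SOURCES ||
      sum(source_type == "visible") != 8L) {
    stop("source_type must label 8 visible and 8 infrared sources",
         call. = FALSE)
  }
  structure(list(readings = readings, mode = mode,
                 source_type = source_type), class = "msp_cycle")
}

#' Aggregate a cycle over same-type sources
#'
#' The eight visible-source rows are averaged into one 32-value
#' intensity vector (one value per detector) and likewise for the eight
#' infrared rows, giving the per-cycle mode vector.  The mean (rather
#' than the sum) keeps the feature scale independent of the LED count.
#'
#' @param cycle An [msp_cycle()].
#' @return A list of class `msp_mode_vector` with elements `visible`
#'   (32), `infrared` (32) and `mode`.
#' @export
aggregate_cycle <- function(cycle) {
  if (!inherits(cycle, "msp_cycle")) {
    cycle <- do.call(msp_cycle, cycle)
  }
  vis <- cycle$source_type == "visible"
  structure(list(
    visible = colMeans(cycle$readings[vis, , drop = FALSE]),
    infrared = colMeans(cycle$readings[!vis, , drop = FALSE]),
    mode = cycle$mode
  ), class = "msp_mode_vector")
}

#' Concatenate red- and yellow-mode vectors into one 128-D feature
#'
#' Block order is fixed as `[32 red | 32 yellow | 32 red-run IR |
#' 32 yellow-run IR]` (32 red, 32 yellow, 64 infrared intensities), so
#' Euclidean distances between features are well defined.
#'
#' @param red_mode Mode vector from a `"red_ir"` cycle.
#' @param yellow_mode Mode vector from a `"yellow_ir"` cycle.
#' @param cycle_index Optional provenance index stored as an attribute.
#' @return Numeric vector of length 128.
#' @export
concatenate_modes <- function(red_mode, yellow_mode, cycle_index = NA_integer_) {
  if (!identical(red_mode$mode, "red_ir") ||
      !identical(yellow_mode$mode, "yellow_ir")) {
    stop("expected one red_ir and one yellow_ir mode vector", call. = FALSE)
  }
  v <- c(red_mode$visible, yellow_mode$visible,
         red_mode$infrared, yellow_mode$infrared)
  stopifnot(length(v) == MSP_FEATURE_LEN)
  structure(v, cycle_index = cycle_index)
}

#' Randomly select 18 of 20 features and group into six records
#'
#' To mirror the ECG record structure, 18 of the 20 per-cycle features
#' are drawn uniformly without replacement (seeded, so record
#' assignment is reproducible) and grouped into six records of three in
#' selection order.
#'
#' @param features List of exactly 20 length-128 numeric vectors.
#' @param seed Integer seed for the selection.
#' @param subject_id Identifier for the emitted record set.
#' @return A [wa_record_set()] tibble (6 records x 3 x 128).
#' @export
select_and_group <- function(features, seed = 1L, subject_id = "s1") {
  if (length(features) != MSP_CYCLES_PER_MODE) {
    stop("exactly 20 feature vectors are required, got ", length(features),
         call. = FALSE)
  }
  if (!all(vapply(features, length, integer(1)) == MSP_FEATURE_LEN)) {
    stop("every feature must have length 128", call. = FALSE)
  }
  sel <- withr::with_seed(as.integer(seed),
                          sample.int(MSP_CYCLES_PER_MODE, 18L))
  mat <- do.call(rbind, features)[sel, , drop = FALSE]
  wa_record_set(subject_id, "msp",
                lapply(seq_len(N_RECORDS), function(r) {
                  mat[(PULSES_PER_RECORD * (r - 1) + 1):(PULSES_PER_RECORD * r), ,
                      drop = FALSE]
                }))
}

#' Process raw MSP cycles from both modes into a record set
#'
#' Cycle i of the red/IR run is paired with cycle i of the yellow/IR
#' run (acquisition order), each pair is aggregated and concatenated
#' into a 128-D feature, and [select_and_group()] forms the records.
#'
#' @param red_cycles,yellow_cycles Lists of 20 [msp_cycle()] objects.
#' @param seed Seed for the 18-of-20 selection.
#' @param subject_id Identifier for the emitted record set.
#' @return A [wa_record_set()] tibble.
#' @export
process_msp <- function(red_cycles, yellow_cycles, seed = 1L,
                        subject_id = "s1") {
  if (length(red_cycles) != length(yellow_cycles)) {
    stop("red and yellow runs must contain the same number of cycles",
         call. = FALSE)
  }
  feats <- purrr::map2(red_cycles, yellow_cycles, function(r, y) {
    concatenate_modes(aggregate_cycle(r), aggregate_cycle(y))
  })
  select_and_group(feats, seed, subject_id)
}
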