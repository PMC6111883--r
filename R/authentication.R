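# Template/probe construction, Euclidean-distance scoring, per-modality
# max normalization, and single-threshold majority-voting fusion.

#' Build an enrollment template from two records
#'
#' A template is the elementwise mean of the six feature vectors (N = 6)
#' contained in two enrollment records.
#'
#' @param vectors A 6 x L numeric matrix, a list of six equal-length
#'   vectors, or a [wa_record_set()] subset holding exactly two records.
#' @param modality `"ecg"` or `"msp"`; inferred from a record set.
#' @return A list of class `wa_template` with elements `vector`,
#'   `modality`, `n_enrolled`.
#' @export
build_template <- function(vectors, modality = NULL) {
  m <- as_feature_matrix(vectors, 6L, "template")
  modality <- modality %||% attr(m, "modality") %||% guess_modality(ncol(m))
  structure(list(vector = colMeans(m), modality = modality,
                 n_enrolled = 6L), class = "wa_template")
}

#' Build an authentication probe from one record
#'
#' A probe is the elementwise mean of the three feature vectors (M = 3)
#' of a single record.
#'
#' @param vectors A 3 x L numeric matrix, a list of three equal-length
#'   vectors, or a one-record [wa_record_set()] subset.
#' @param modality `"ecg"` or `"msp"`; inferred from a record set.
#' @return A list of class `wa_probe` with elements `vector`,
#'   `modality`, `n_averaged`.
#' @export
build_probe <- function(vectors, modality = NULL) {
  m <- as_feature_matrix(vectors, 3L, "probe")
  modality <- modality %||% attr(m, "modality") %||% guess_modality(ncol(m))
  structure(list(vector = colMeans(m), modality = modality,
                 n_averaged = 3L), class = "wa_probe")
}

as_feature_matrix <- function(vectors, expected_rows, what) {
  modality <- NULL
  if (inherits(vectors, "wa_record_set") ||
      (is.data.frame(vectors) && "features" %in% names(vectors))) {
    modality <- unique(vectors$modality)
    if (length(modality) != 1L) {
      stop("record subset mixes modalities", call. = FALSE)
    }
    vectors <- do.call(rbind, vectors$features)
  } else if (is.list(vectors) && !is.data.frame(vectors)) {
    lens <- vapply(vectors, length, integer(1))
    if (length(unique(lens)) != 1L) {
      stop("feature vectors differ in dimension", call. = FALSE)
    }
    vectors <- do.call(rbind, vectors)
  }
  if (!is.matrix(vectors) || nrow(vectors) != expected_rows) {
    stop("a ", what, " needs exactly ", expected_rows,
         " feature vectors, got ",
         if (is.matrix(vectors)) nrow(vectors) else "a non-matrix",
         call. = FALSE)
  }
  if (!all(is.finite(vectors))) stop("non-finite feature values", call. = FALSE)
  structure(vectors, modality = modality)
}

guess_modality <- function(len) {
  if (len == MSP_FEATURE_LEN) "msp" else "ecg"
}

#' Euclidean distance between a template and a probe
#'
#' The plain (un-squared) Euclidean norm of the difference; set
#' `squared = TRUE` for the squared form (the two differ after max
#' normalization).
#'
#' @param template,probe `wa_template` / `wa_probe` objects or bare
#'   numeric vectors of equal length.
#' @param squared Use the squared norm.
#' @return Non-negative scalar.
#' @export
feature_distance <- function(template, probe, squared = FALSE) {
  t_vec <- if (inherits(template, "wa_template")) template$vector else template
  p_vec <- if (inherits(probe, "wa_probe")) probe$vector else probe
  if (length(t_vec) != length(p_vec)) {
    stop("template and probe dimensions differ", call. = FALSE)
  }
  d2 <- sum((t_vec - p_vec)^2)
  if (squared) d2 else sqrt(d2)
}

#' Max-normalize a pool of raw distances
#'
#' Divides every raw distance by the pool maximum so the largest
#' normalized distance in the modality equals exactly 1.  Applied per
#' modality, this puts ECG and MSP scores on a common [0, 1] scale and
#' makes a single shared threshold meaningful.
#'
#' @param raw_distances Non-negative numeric vector with at least one
#'   positive entry.
#' @return A list with `normalized` (same order as the input) and
#'   `norm_constant` (the maximum used).
#' @export
normalize_pool <- function(raw_distances) {
  if (length(raw_distances) == 0 || any(raw_distances < 0) ||
      !all(is.finite(raw_distances))) {
    stop("raw distances must be finite and non-negative", call. = FALSE)
  }
  mx <- max(raw_distances)
  if (mx <= 0) {
    stop("degenerate pool: all distances are zero", call. = FALSE)
  }
  list(normalized = raw_distances / mx, norm_constant = mx)
}

#' Single-modality accept decision
#'
#' Accept when the normalized distance does not exceed the shared
#' threshold (ties accept, keeping the FAR/FRR step functions
#' right-continuous).
#'
#' @param normalized Normalized distance(s) in `[0, 1]`.
#' @param th Shared threshold in `[0, 1]`.
#' @return Logical vector of accept flags.
#' @export
decide_single <- function(normalized, th) {
  if (any(th < 0 | th > 1)) stop("threshold must lie in [0, 1]", call. = FALSE)
  normalized <= th
}

#' Majority-voting fusion of two modality decisions
#'
#' The fused decision accepts when `g1 + g2 > alpha`: with two
#' classifiers, `alpha = 1` accepts only when both vote accept (AND)
#' and `alpha = 0` when at least one does (OR).
#'
#' @param g1,g2 Logical accept flags (vectors recycle as usual).
#' @param alpha Vote threshold, 0 (OR) or 1 (AND).
#' @return Logical vector of fused accept flags.
#' @export
fuse_decisions <- function(g1, g2, alpha = 1L) {
  if (!all(alpha %in% c(0L, 1L))) stop("alpha must be 0 or 1", call. = FALSE)
  (as.integer(g1) + as.integer(g2)) > alpha
}
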