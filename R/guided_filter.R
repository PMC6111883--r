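# One-dimensional guided filtering with the enrolled user template as
# the guide signal.  Within every moving window the guide is affinely
# fitted to the input (a = cov(g, x) / (var(g) + eps), b = mean(x) -
# a mean(g)); the output averages the fitted values over all windows
# covering a sample.  Windows are truncated at the vector ends and at
# block boundaries, so for MSP the affine fit never spans two source
# types.

#' Guided-filter parameters
#'
#' @param radius Window half-width in samples (default 4: small windows
#'   preserve the sharp transitions seen in MSP intensity patterns).
#' @param eps Absolute regularization added to the window variance of
#'   the guide.  If `NULL`, it is derived per call as
#'   `eps_rel * (max(guide) - min(guide))^2`.
#' @param eps_rel Relative regularization used when `eps` is `NULL`.
#'   The default 3e-4 keeps the affine fit essentially exact wherever
#'   the template has structure (QRS, T, MSP transitions) while still
#'   averaging noise out of flat stretches; much larger values shrink
#'   mid-amplitude waves toward window means and bias genuine probes
#'   away from their own template.
#' @param block_boundaries Integer cut points; a window never spans a
#'   cut (a cut at 32 separates samples 1..32 from 33..).  `NULL` or
#'   `integer(0)` filters the whole vector as one block.
#' @return A list of class `gf_params`.
#' @export
gf_params <- function(radius = 4L, eps = NULL, eps_rel = 3e-4,
                      block_boundaries = NULL) {
  radius <- as.integer(radius)
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  if (!is.null(eps) && eps <= 0) stop("eps must be > 0", call. = FALSE)
  if (eps_rel <= 0) stop("eps_rel must be > 0", call. = FALSE)
  bb <- sort(unique(as.integer(block_boundaries)))
  structure(list(radius = radius, eps = eps, eps_rel = eps_rel,
                 block_boundaries = bb), class = "gf_params")
}

# Columnwise cumulative sums of a matrix in one vectorized pass: the
# full-vector cumsum is corrected by each column's carried-over total.
cum_rows <- function(M) {
  L <- nrow(M)
  K <- ncol(M)
  cs <- matrix(cumsum(M), L, K)
  if (K > 1L) cs <- cs - matrix(rep(c(0, cs[L, -K]), each = L), L, K)
  cs
}

# Truncated box sums over the rows of a matrix (columnwise signals):
# windows shrink at the ends, so missing samples contribute zero.
box_sum <- function(M, r) {
  if (!is.matrix(M)) M <- matrix(M)
  L <- nrow(M)
  cs <- rbind(0, cum_rows(M))
  hi <- pmin(seq_len(L) + r, L) + 1L
  lo <- pmax(seq_len(L) - r, 1L)
  cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]
}

box_counts <- function(L, r) {
  pmin(seq_len(L) + r, L) - pmax(seq_len(L) - r, 1L) + 1L
}

# Core: filter every column of X (L x K) with the same guide.
gf_filter_matrix <- function(X, guide, params) {
  L <- length(guide)
  if (nrow(X) != L) stop("input and guide lengths differ", call. = FALSE)
  eps <- params$eps %||% (params$eps_rel * diff(range(guide))^2)
  if (eps <= 0) eps <- .Machine$double.eps
  bounds <- c(0L, params$block_boundaries[params$block_boundaries < L], L)
  out <- X
  for (b in seq_len(length(bounds) - 1L)) {
    idx <- (bounds[b] + 1L):bounds[b + 1L]
    Lb <- length(idx)
    if (Lb < 2L) stop("block shorter than 2 samples", call. = FALSE)
    r <- params$radius
    g <- guide[idx]
    Xb <- X[idx, , drop = FALSE]
    nn <- box_counts(Lb, r)
    mg <- box_sum(matrix(g), r)[, 1] / nn
    vg <- box_sum(matrix(g * g), r)[, 1] / nn - mg^2
    mx <- box_sum(Xb, r) / nn
    mgx <- box_sum(Xb * g, r) / nn
    a <- (mgx - mg * mx) / (vg + eps)
    bcoef <- mx - a * mg
    out[idx, ] <- (box_sum(a, r) / nn) * g + box_sum(bcoef, r) / nn
  }
  out
}

#' One-dimensional guided filter
#'
#' Filters `input` using `guide` as the guidance signal.  Window
#' statistics use population moments; windows are truncated at vector
#' ends and at `block_boundaries`.
#'
#' @param input,guide Numeric vectors of equal length.
#' @param params A [gf_params()] object.
#' @return Numeric vector, same length as `input`.
#' @examples
#' g <- sin(seq(0, 3, length.out = 64))
#' x <- g + rnorm(64, sd = 0.1)
#' y <- guided_filter_1d(x, g, gf_params(radius = 4))
#' @export
guided_filter_1d <- function(input, guide, params = gf_params()) {
  if (length(input) != length(guide)) {
    stop("input and guide must have equal length", call. = FALSE)
  }
  Lmin <- min(diff(c(0L, params$block_boundaries[params$block_boundaries <
                                                   length(input)],
                     length(input))))
  if (Lmin < 2L) stop("block shorter than 2 samples", call. = FALSE)
  gf_filter_matrix(matrix(as.numeric(input)), as.numeric(guide), params)[, 1]
}

#' Denoise a probe with its enrolled template as guide
#'
#' Applies [guided_filter_1d()] with modality-appropriate block
#' boundaries: none for a 160-sample ECG probe, cuts at 32/64/96 for a
#' 128-D MSP feature so the affine fit never spans heterogeneous source
#' types.  The filter is applied to the probe only -- the template is
#' the guide and enters the subsequent distance unchanged.
#'
#' @param probe,template Numeric vectors of matching length (160 or
#'   128).
#' @param params A [gf_params()]; its `block_boundaries` are overridden
#'   by the modality defaults unless `keep_blocks = TRUE`.
#' @param keep_blocks Use `params$block_boundaries` as given.
#' @return Filtered probe vector.
#' @export
apply_template_gf <- function(probe, template, params = gf_params(),
                              keep_blocks = FALSE) {
  if (length(probe) != length(template)) {
    stop("probe and template dimensions differ", call. = FALSE)
  }
  if (!keep_blocks) {
    params$block_boundaries <- modality_blocks(length(probe))
  }
  guided_filter_1d(probe, template, params)
}

modality_blocks <- function(len) {
  if (len == MSP_FEATURE_LEN) MSP_BLOCKS else integer(0)
}
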