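# Verification protocol and performance metrics: for every subject and
# every 2-of-6 enrollment combination, a template faces the subject's
# own four held-out records (genuine trials) and every other subject's
# records at the same held-out indices (imposter trials).  Pooled,
# max-normalized distances yield FAR/FRR curves and the EER / PD.1 /
# FRR0 summaries.

#' Enumerate enrollment record combinations
#'
#' All `choose(n, k)` combinations of `k` enrollment records out of
#' `n`, in deterministic lexicographic order (2-of-6 gives the 15
#' repetitions of the protocol).
#'
#' @param n_records Number of records per subject (default 6).
#' @param k Records used for enrollment (default 2).
#' @return Integer matrix with one combination per column.
#' @export
enumerate_enrollments <- function(n_records = 6L, k = 2L) {
  if (k > n_records) stop("k must not exceed n_records", call. = FALSE)
  utils::combn(n_records, k)
}

# Stack a cohort record set into per-modality probe/record matrices.
# Probe row order is (subject, record): row (s-1)*6 + r.
modality_matrices <- function(records, modality) {
  rs <- records[records$modality == modality, ]
  rs <- rs[order(match(rs$subject, unique(records$subject)), rs$record), ]
  subjects <- unique(rs$subject)
  probes <- do.call(rbind, lapply(rs$features, colMeans))
  list(subjects = subjects,
       features = rs$features,  # (s-1)*6 + r indexing
       probes = probes)
}

# Templates for every (subject, combo): mean of the 6 vectors of the two
# combo records.  Row order (subject, combo): row (s-1)*15 + c.
template_matrix <- function(mm, combos) {
  n <- length(mm$subjects)
  ncmb <- ncol(combos)
  out <- matrix(0, n * ncmb, ncol(mm$probes))
  for (s in seq_len(n)) {
    base <- (s - 1L) * N_RECORDS
    for (cc in seq_len(ncmb)) {
      stacked <- rbind(mm$features[[base + combos[1, cc]]],
                       mm$features[[base + combos[2, cc]]])
      out[(s - 1L) * ncmb + cc, ] <- colMeans(stacked)
    }
  }
  out
}

cross_distances <- function(Tm, Pm, squared = FALSE) {
  d2 <- outer(rowSums(Tm^2), rowSums(Pm^2), "+") - 2 * tcrossprod(Tm, Pm)
  d2[d2 < 0] <- 0
  if (squared) d2 else sqrt(d2)
}

# Raw distances for one modality under an optional template-guided
# filter.  Returns, per combo, the n_template x (4 n) distance matrix
# flattened into the trial table ordering.
modality_raw_distances <- function(mm, combos, gf_on, params, squared) {
  n <- length(mm$subjects)
  ncmb <- ncol(combos)
  Tm <- template_matrix(mm, combos)
  if (!gf_on) {
    D <- cross_distances(Tm, mm$probes, squared)
    return(list(Tm = Tm, dist = function(t_row, cols) D[t_row, cols]))
  }
  Pt <- t(mm$probes)  # L x (6n), columnwise probes for the filter
  blocks <- modality_blocks(nrow(Pt))
  list(Tm = Tm, dist = function(t_row, cols) {
    g <- Tm[t_row, ]
    p <- params
    p$block_boundaries <- blocks
    Xf <- gf_filter_matrix(Pt[, cols, drop = FALSE], g, p)
    d2 <- colSums((Xf - g)^2)
    if (squared) d2 else sqrt(d2)
  })
}

#' Run the verification protocol on a cohort record set
#'
#' For every subject and each of the 15 enrollment combinations, builds
#' the template from the two enrollment records and scores the
#' subject's four held-out records (genuine) plus every other subject's
#' records at the same held-out indices (imposter).  Raw Euclidean
#' distances are computed per modality -- after guided-filtering the
#' probe with the template as guide where enabled -- and max-normalized
#' over the pooled genuine + imposter distances of the run.
#'
#' @param records Cohort [wa_record_set()] tibble containing both
#'   modalities for every subject.
#' @param gf Guided-filter condition: `"none"`, `"ecg"` (ECG probes
#'   only) or `"both"`.
#' @param gf_parameters A [gf_params()] object (block boundaries are set
#'   per modality).
#' @param squared Use squared Euclidean distances.
#' @return A tibble of class `wa_pool` with one row per trial:
#'   `subject`, `combo`, `probe_subject`, `record`, `genuine`, and the
#'   normalized distances `ecg`, `msp`.  Attributes `norm_constants`
#'   and `gf` record the normalization and filter condition.
#' @export
run_protocol <- function(records, gf = c("none", "ecg", "both"),
                         gf_parameters = gf_params(), squared = FALSE) {
  gf <- match.arg(gf)
  subjects <- unique(records$subject)
  n <- length(subjects)
  if (n < 2) stop("cohort must contain at least 2 subjects", call. = FALSE)
  for (mod in c("ecg", "msp")) {
    if (sum(records$modality == mod) != n * N_RECORDS) {
      stop("every subject needs ", N_RECORDS, " ", mod, " records",
           call. = FALSE)
    }
  }
  combos <- enumerate_enrollments(N_RECORDS, 2L)
  ncmb <- ncol(combos)

  mods <- list(
    ecg = modality_raw_distances(modality_matrices(records, "ecg"), combos,
                                 gf %in% c("ecg", "both"), gf_parameters,
                                 squared),
    msp = modality_raw_distances(modality_matrices(records, "msp"), combos,
                                 gf == "both", gf_parameters, squared)
  )

  held <- lapply(seq_len(ncmb), function(cc) setdiff(seq_len(N_RECORDS),
                                                     combos[, cc]))
  n_held <- length(held[[1]])
  rows_per_combo <- n * n_held          # probes per template
  total <- n * ncmb * rows_per_combo    # trials overall

  subj_idx <- integer(total); combo_idx <- integer(total)
  probe_idx <- integer(total); rec_idx <- integer(total)
  d_ecg <- numeric(total); d_msp <- numeric(total)
  pos <- 0L
  for (s in seq_len(n)) {
    for (cc in seq_len(ncmb)) {
      cols <- rep((seq_len(n) - 1L) * N_RECORDS, each = n_held) +
        rep(held[[cc]], times = n)
      t_row <- (s - 1L) * ncmb + cc
      idx <- pos + seq_len(rows_per_combo)
      subj_idx[idx] <- s
      combo_idx[idx] <- cc
      probe_idx[idx] <- rep(seq_len(n), each = n_held)
      rec_idx[idx] <- rep(held[[cc]], times = n)
      d_ecg[idx] <- mods$ecg$dist(t_row, cols)
      d_msp[idx] <- mods$msp$dist(t_row, cols)
      pos <- pos + rows_per_combo
    }
  }

  ne <- normalize_pool(d_ecg)
  nm <- normalize_pool(d_msp)
  out <- tibble::tibble(
    subject = subjects[subj_idx],
    combo = combo_idx,
    probe_subject = subjects[probe_idx],
    record = rec_idx,
    genuine = subj_idx == probe_idx,
    ecg = ne$normalized,
    msp = nm$normalized
  )
  attr(out, "norm_constants") <- c(ecg = ne$norm_constant,
                                   msp = nm$norm_constant)
  attr(out, "gf") <- gf
  class(out) <- c("wa_pool", class(out))
  out
}

pool_scores <- function(pool, mode) {
  switch(mode,
         ecg = pool$ecg,
         msp = pool$msp,
         fused_and = pmax(pool$ecg, pool$msp),
         fused_or = pmin(pool$ecg, pool$msp),
         stop("unknown mode ", mode, call. = FALSE))
}

#' FAR/FRR curve over the shared threshold
#'
#' Sweeps the accept threshold over every distinct pooled normalized
#' distance (plus 0 and 1) and counts false accepts among imposters and
#' false rejects among genuines.  Acceptance is `distance <= th` per
#' modality; fused modes vote AND (`fused_and`) or OR (`fused_or`), so
#' their effective score is the pairwise max or min of the two
#' normalized distances.
#'
#' @param pool A `wa_pool` from [run_protocol()].
#' @param mode `"ecg"`, `"msp"`, `"fused_and"` or `"fused_or"`.
#' @param thresholds Optional explicit threshold grid; the default is
#'   every distinct normalized distance of the modalities involved,
#'   plus 0 and 1.
#' @return A tibble of class `wa_curve` with columns `threshold`,
#'   `far`, `frr` (rates in `[0, 1]`, FAR non-decreasing and FRR
#'   non-increasing).
#' @export
far_frr_curve <- function(pool, mode = c("ecg", "msp", "fused_and",
                                         "fused_or"),
                          thresholds = NULL) {
  mode <- match.arg(mode)
  if (!any(pool$genuine) || !all(is.finite(pool$ecg))) {
    stop("pool must contain genuine trials", call. = FALSE)
  }
  if (!any(!pool$genuine)) stop("pool must contain imposter trials",
                                call. = FALSE)
  sc <- pool_scores(pool, mode)
  if (is.null(thresholds)) {
    vals <- if (mode %in% c("ecg", "msp")) sc else c(pool$ecg, pool$msp)
    thresholds <- sort(unique(c(0, 1, vals)))
  } else {
    thresholds <- sort(unique(thresholds))
  }
  gen <- sort(sc[pool$genuine])
  imp <- sort(sc[!pool$genuine])
  far <- findInterval(thresholds, imp) / length(imp)
  frr <- 1 - findInterval(thresholds, gen) / length(gen)
  out <- tibble::tibble(threshold = thresholds, far = far, frr = frr)
  attr(out, "mode") <- mode
  class(out) <- c("wa_curve", class(out))
  out
}

#' Equal error rate of a FAR/FRR curve
#'
#' Finds the threshold where the non-decreasing FAR step function meets
#' the non-increasing FRR step function.  If the two are exactly equal
#' at a grid threshold that common value is returned; otherwise the
#' crossing of the linear interpolants between the bracketing grid
#' points is used.
#'
#' @param curve A `wa_curve` from [far_frr_curve()].
#' @return EER in percent.
#' @export
compute_eer <- function(curve) {
  far <- curve$far; frr <- curve$frr
  i <- which(far >= frr)[1]
  if (is.na(i)) return(100 * far[length(far)])
  if (far[i] == frr[i]) return(100 * far[i])
  if (i == 1L) return(100 * (far[1] + frr[1]) / 2)
  f1 <- far[i - 1]; f2 <- far[i]; r1 <- frr[i - 1]; r2 <- frr[i]
  denom <- (f2 - f1) - (r2 - r1)
  lambda <- if (denom == 0) 0 else (r1 - f1) / denom
  100 * (f1 + lambda * (f2 - f1))
}

#' Detection probability at a FAR operating point
#'
#' `PD = 100 - FRR` at the largest threshold whose FAR does not exceed
#' `far_level` percent (PD.1 uses `far_level = 1`).
#'
#' @param curve A `wa_curve`.
#' @param far_level Operating FAR in percent.
#' @return Detection probability in percent (`NA` if even the smallest
#'   threshold exceeds the FAR level).
#' @export
compute_pd_at_far <- function(curve, far_level = 1) {
  ok <- which(curve$far <= far_level / 100)
  if (length(ok) == 0) return(NA_real_)
  100 * (1 - curve$frr[max(ok)])
}

#' False rejection rate at zero FAR
#'
#' FRR at the largest threshold with FAR exactly 0 -- the strictest
#' usable operating point.  Returns 100 when no threshold achieves zero
#' FAR (an imposter at distance 0).
#'
#' @param curve A `wa_curve`.
#' @return FRR0 in percent.
#' @export
compute_frr_at_zero_far <- function(curve) {
  ok <- which(curve$far == 0)
  if (length(ok) == 0) return(100)
  100 * curve$frr[max(ok)]
}

#' Evaluate a cohort across guided-filter and fusion conditions
#'
#' Runs [run_protocol()] once per guided-filter condition (each with
#' its own normalization constants), derives FAR/FRR curves for the
#' requested modes, and tabulates EER, PD.1 and FRR0.
#'
#' @param records Cohort [wa_record_set()] with both modalities.
#' @param gf Character vector of guided-filter conditions to evaluate.
#' @param modes Character vector of decision modes.
#' @param gf_parameters A [gf_params()] object.
#' @return A tibble of class `wa_eval` with columns `gf`, `mode`,
#'   `eer`, `pd1`, `frr0` (percent).  The per-condition curves are kept
#'   in the `curves` attribute (a named list).
#' @export
evaluate_cohort <- function(records, gf = c("none", "ecg", "both"),
                            modes = c("ecg", "msp", "fused_and",
                                      "fused_or"),
                            gf_parameters = gf_params()) {
  gf <- match.arg(gf, several.ok = TRUE)
  modes <- match.arg(modes, several.ok = TRUE)
  rows <- list()
  curves <- list()
  for (g in gf) {
    pool <- run_protocol(records, gf = g, gf_parameters = gf_parameters)
    for (m in modes) {
      curve <- far_frr_curve(pool, m)
      curves[[paste(g, m, sep = ".")]] <- curve
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gf = g, mode = m,
        eer = compute_eer(curve),
        pd1 = compute_pd_at_far(curve, 1),
        frr0 = compute_frr_at_zero_far(curve)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "curves") <- curves
  attr(out, "n_subjects") <- length(unique(records$subject))
  class(out) <- c("wa_eval", class(out))
  out
}

#' @exportS3Method generics::tidy
tidy.wa_eval <- function(x, ...) {
  out <- x
  attr(out, "curves") <- NULL
  class(out) <- class(tibble::tibble())
  tibble::as_tibble(out)
}

#' @exportS3Method generics::glance
glance.wa_eval <- function(x, ...) {
  tibble::tibble(
    n_subjects = attr(x, "n_subjects"),
    n_conditions = nrow(x),
    min_eer = min(x$eer),
    min_frr0 = min(x$frr0),
    best_mode = x$mode[which.min(x$eer)]
  )
}

#' @exportS3Method generics::tidy
tidy.wa_pool <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  tibble::as_tibble(out)
}

#' @exportS3Method generics::glance
glance.wa_pool <- function(x, ...) {
  tibble::tibble(
    n_genuine = sum(x$genuine),
    n_imposter = sum(!x$genuine),
    gf = attr(x, "gf"),
    norm_ecg = attr(x, "norm_constants")[["ecg"]],
    norm_msp = attr(x, "norm_constants")[["msp"]]
  )
}

#' Plot a FAR/FRR curve
#'
#' @param object A `wa_curve`.
#' @param ... Unused.
#' @return A ggplot with FAR and FRR against the shared threshold.
#' @exportS3Method ggplot2::autoplot
autoplot.wa_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), c("far", "frr"),
                            names_to = "rate", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value,
                                   colour = toupper(.data$rate))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "shared threshold", y = "rate", colour = NULL,
                  title = paste("FAR/FRR,", attr(object, "mode"))) +
    ggplot2::theme_minimal()
}

#' Plot genuine/imposter score distributions
#'
#' @param pool A `wa_pool`.
#' @param mode Decision mode whose effective score is shown.
#' @return A ggplot histogram, filled by trial label.
#' @export
plot_pool <- function(pool, mode = "ecg") {
  df <- tibble::tibble(score = pool_scores(pool, mode),
                       label = ifelse(pool$genuine, "genuine", "imposter"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$label)) +
    ggplot2::geom_histogram(bins = 60, alpha = 0.6,
                            position = "identity") +
    ggplot2::labs(x = "normalized distance", y = "trials", fill = NULL) +
    ggplot2::theme_minimal()
}
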