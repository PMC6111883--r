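test_that("enrollment combinations enumerate lexicographically", {
  cmb <- enumerate_enrollments(6, 2)
  expect_equal(ncol(cmb), 15L)
  expect_equal(cmb[, 1], c(1L, 2L))
  expect_equal(cmb[, 15], c(5L, 6L))
  expect_equal(enumerate_enrollments(3, 2),
               matrix(c(1L, 2L, 1L, 3L, 2L, 3L), 2))
  expect_equal(ncol(enumerate_enrollments(6, 6)), 1L)
  expect_error(enumerate_enrollments(3, 4), "exceed")
})

test_that("the protocol produces the right trial structure", {
  rs2 <- make_record_set(2)
  pool2 <- run_protocol(rs2)
  expect_equal(sum(pool2$genuine), 2 * 15 * 4)
  expect_equal(sum(!pool2$genuine), 2 * 15 * 4 * 1)

  rs5 <- make_record_set(5)
  pool5 <- run_protocol(rs5)
  expect_equal(sum(pool5$genuine), 5 * 15 * 4)
  expect_equal(sum(!pool5$genuine), 5 * 15 * 4 * 4)

  # per subject and combo: exactly 4 genuine and 4 (n - 1) imposters,
  # at the record indices excluded from the enrollment
  one <- dplyr::filter(pool5, subject == "s01", combo == 1)
  expect_equal(sum(one$genuine), 4L)
  expect_equal(sum(!one$genuine), 16L)
  expect_equal(sort(unique(one$record)), 3:6)

  expect_error(run_protocol(make_record_set(1)), "2 subjects")
  expect_error(run_protocol(rs2[rs2$modality == "ecg", ]), "msp")
})

test_that("protocol distances match direct template/probe computation", {
  rs <- make_record_set(3, seed = 21)
  pool <- run_protocol(rs)
  nc <- attr(pool, "norm_constants")
  cmb <- enumerate_enrollments(6, 2)

  check <- dplyr::slice(dplyr::filter(pool, !genuine), c(1, 17, 40))
  for (i in seq_len(nrow(check))) {
    tr <- check[i, ]
    enr <- rs[rs$subject == tr$subject & rs$modality == "ecg" &
                rs$record %in% cmb[, tr$combo], ]
    tpl <- build_template(enr)
    prb <- build_probe(rs[rs$subject == tr$probe_subject &
                            rs$modality == "ecg" &
                            rs$record == tr$record, ])
    expect_equal(tr$ecg, feature_distance(tpl, prb) / nc[["ecg"]],
                 tolerance = 1e-12)
  }
})

test_that("guided-filter conditions renormalize and shrink genuine scores", {
  rs <- make_record_set(4, seed = 31, noise = 0.2)
  p0 <- run_protocol(rs, gf = "none")
  p1 <- run_protocol(rs, gf = "ecg")
  p2 <- run_protocol(rs, gf = "both")
  expect_equal(p0$msp, p1$msp)  # ECG-only condition leaves MSP alone
  expect_false(isTRUE(all.equal(p0$ecg, p1$ecg)))
  expect_false(isTRUE(all.equal(p1$msp, p2$msp)))
  expect_equal(max(p2$ecg), 1)
  expect_equal(max(p2$msp), 1)
})

test_that("FAR/FRR curves match an explicit recount and are monotone", {
  withr::with_seed(77, {
    pool <- make_pool(runif(40, 0, 0.6), runif(60, 0.2, 1),
                      runif(40, 0, 0.7), runif(60, 0.1, 1))
    for (mode in c("ecg", "msp", "fused_and", "fused_or")) {
      cv <- far_frr_curve(pool, mode)
      expect_true(all(diff(cv$far) >= 0))
      expect_true(all(diff(cv$frr) <= 0))
      sc <- switch(mode, ecg = pool$ecg, msp = pool$msp,
                   fused_and = pmax(pool$ecg, pool$msp),
                   fused_or = pmin(pool$ecg, pool$msp))
      for (th in seq(0, 1, by = 0.1)) {
        want <- rates_oracle(sc[pool$genuine], sc[!pool$genuine], th)
        i <- max(which(cv$threshold <= th))
        expect_equal(cv$far[i], want[["far"]])
        expect_equal(cv$frr[i], want[["frr"]])
      }
    }
  })
})

test_that("curve edge cases: separation and identical pools", {
  sep <- make_pool(c(0.1, 0.2), c(0.8, 0.9))
  cv <- far_frr_curve(sep, "ecg")
  at <- max(which(cv$threshold <= 0.5))
  expect_equal(cv$far[at], 0)
  expect_equal(cv$frr[at], 0)

  same <- make_pool(seq(0.1, 0.9, by = 0.1), seq(0.1, 0.9, by = 0.1))
  cvs <- far_frr_curve(same, "ecg")
  expect_equal(cvs$far + cvs$frr, rep(1, nrow(cvs)))
})

test_that("EER finds the FAR/FRR crossing", {
  expect_equal(compute_eer(far_frr_curve(make_pool(c(0.1, 0.2),
                                                   c(0.8, 0.9)), "ecg")), 0)
  g <- runif(100)
  expect_equal(compute_eer(far_frr_curve(make_pool(g, g), "ecg")), 50)
  # hand sweep: FAR = FRR = 1/2 exactly at th = 0.3
  expect_equal(compute_eer(far_frr_curve(make_pool(c(0.1, 0.4),
                                                   c(0.3, 0.6)), "ecg")), 50)
  # interpolated crossing between grid points
  cv <- tibble::tibble(threshold = c(0, 0.4, 0.6, 1),
                       far = c(0, 0.1, 0.3, 1),
                       frr = c(1, 0.3, 0.1, 0))
  lambda <- (0.3 - 0.1) / ((0.3 - 0.1) - (0.1 - 0.3))
  expect_equal(compute_eer(cv), 100 * (0.1 + lambda * 0.2))
})

test_that("EER is invariant under increasing transforms of one modality", {
  withr::with_seed(13, {
    pool <- make_pool(runif(50, 0, 0.5), runif(80, 0.2, 1))
    e0 <- compute_eer(far_frr_curve(pool, "ecg"))
    pool$ecg <- pool$ecg^2  # strictly increasing on [0, 1]
    expect_equal(compute_eer(far_frr_curve(pool, "ecg")), e0)
  })
})

test_that("PD at an operating FAR and FRR0 follow their definitions", {
  sep <- far_frr_curve(make_pool(c(0.1, 0.2), c(0.8, 0.9)), "ecg")
  expect_equal(compute_pd_at_far(sep, 1), 100)
  expect_equal(compute_frr_at_zero_far(sep), 0)

  g <- seq_len(100) / 101
  ident <- far_frr_curve(make_pool(g, g), "ecg")
  expect_equal(compute_pd_at_far(ident, 1), 1)
  expect_equal(compute_pd_at_far(ident, 100), 100 - 100 * min(ident$frr))

  # one imposter below all genuines: no usable operating point
  low <- far_frr_curve(make_pool(c(0.5, 0.6, 0.9), c(0.2, 0.95)), "ecg")
  expect_equal(compute_frr_at_zero_far(low), 100)

  mixed <- far_frr_curve(make_pool(c(0.2, 0.5, 0.7), c(0.6, 0.9)), "ecg")
  expect_equal(compute_frr_at_zero_far(mixed), 100 / 3)
})

test_that("fusion bounds hold at every shared threshold", {
  withr::with_seed(99, {
    pool <- make_pool(runif(60, 0, 0.6), runif(90, 0.3, 1),
                      runif(60, 0, 0.6), runif(90, 0.3, 1))
    grid <- sort(unique(c(0, 1, pool$ecg, pool$msp)))
    cvs <- lapply(c("ecg", "msp", "fused_and", "fused_or"), function(m) {
      far_frr_curve(pool, m, thresholds = grid)
    })
    names(cvs) <- c("ecg", "msp", "and", "or")
    expect_true(all(cvs$or$frr <= pmin(cvs$ecg$frr, cvs$msp$frr)))
    expect_true(all(cvs$or$far >= pmax(cvs$ecg$far, cvs$msp$far)))
    expect_true(all(cvs$and$far <= pmin(cvs$ecg$far, cvs$msp$far)))
    expect_true(all(cvs$and$frr >= pmax(cvs$ecg$frr, cvs$msp$frr)))
  })
})

test_that("evaluate_cohort tabulates conditions with tidy/glance access", {
  rs <- make_record_set(4, seed = 8, noise = 0.15)
  ev <- evaluate_cohort(rs, gf = c("none", "both"),
                        modes = c("ecg", "fused_or"))
  expect_equal(nrow(ev), 4L)
  expect_true(all(ev$eer >= 0 & ev$eer <= 100))
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "wa_eval"))
  gl <- glance(ev)
  expect_equal(gl$n_subjects, 4L)
  expect_named(attr(ev, "curves"))

  plt <- autoplot(attr(ev, "curves")[[1]])
  expect_s3_class(plt, "ggplot")
  expect_s3_class(plot_pool(run_protocol(rs), "fused_or"), "ggplot")
})
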