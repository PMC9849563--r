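test_that("polar-space R-squared matches its defining cases", {
  set.seed(2)
  a <- scale_phase(to_polar(runif(50, 0, 100)))
  expect_equal(r_squared(a, a)$mean, 1.0)
  m <- matrix(rep(colMeans(a), each = nrow(a)), nrow(a))
  expect_equal(r_squared(a, m)$mean, 0.0)
  # hand-computed two-point case
  act <- rbind(c(0.4, 0.5), c(0.6, 0.5))
  prd <- rbind(c(0.5, 0.5), c(0.5, 0.5))
  r <- r_squared(act, prd)
  expect_equal(r$px, 0.0)
  expect_true(is.na(r$py))              # zero target variance: undefined
  expect_equal(r$mean, 0.0)
  expect_error(r_squared(prd, prd), "variance")  # both components constant
  expect_error(r_squared(a[1, , drop = FALSE], a[1, , drop = FALSE]),
               "at least 2")
})

test_that("phase error summaries handle offsets, wraparound and sentinels", {
  p <- quantize_phase(runif(300, 0, 100))
  s0 <- phase_error_summary(p, p)
  expect_equal(s0$mean, 0); expect_equal(s0$q75, 0)
  s2 <- phase_error_summary(p, (p + 2) %% 100)
  expect_equal(s2$mean, 2)
  s98 <- phase_error_summary(p, (p + 98) %% 100)
  expect_equal(s98$mean, 2)                      # wraparound
  # invariant under swapping actual and predicted
  q <- quantize_phase(runif(300, 0, 100))
  expect_equal(phase_error_summary(p, q), phase_error_summary(q, p))
  # sentinels excluded
  pa <- p; pa[1:100] <- NA
  expect_equal(phase_error_summary(pa, p)$n, 200)
  expect_error(phase_error_summary(rep(NA_real_, 5), rep(NA_real_, 5)),
               "overlapping")
})

test_that("median trajectories time-normalize strides onto 101 points", {
  sess <- generate_session("LGW", 12, zero_noise(), seed = 41)
  mt <- median_trajectory(sess$series, sess$heel_strikes)
  expect_equal(length(mt$phase), 101L)
  expect_equal(dim(mt$median), c(101L, 4L))
  expect_equal(mt$n_strides, 11L)
  # identical strides: the median IS the stride, and the IQR band collapses
  expect_equal(mt$median, mt$q25, tolerance = 1e-9)
  one <- median_trajectory(sess$series, sess$heel_strikes[1:2])
  expect_equal(one$median, mt$median, tolerance = 1e-9)
  # per-point median across strides of constant level: median of {1,3,100}=3
  lv <- c(1, 3, 100)
  n <- 60L
  fz <- rep(lv / 200, each = n)                  # keep loads in range
  const <- gait_series(fz = fz, thigh = rep(lv, each = n),
                       knee = rep(lv, each = n), ankle = rep(lv, each = n),
                       rate = 200)
  hs <- c(1L, 61L, 121L, 180L)
  mt3 <- median_trajectory(const, hs)
  expect_true(all(abs(mt3$median[2:99, "thigh"] - 3) < 1e-9))
  expect_error(median_trajectory(const, hs[1]), "complete stride")
})

test_that("Pearson correlation of median trajectories is affine-invariant", {
  sess <- generate_session("SA", 10, zero_noise(), seed = 43)
  a <- median_trajectory(sess$series, sess$heel_strikes)
  expect_equal(unname(pearson_median_correlation(a, a)), rep(1, 4))
  b <- a; b$median <- 2 * a$median + 7
  expect_equal(unname(pearson_median_correlation(a, b)), rep(1, 4))
  d <- a; d$median <- -sweep(a$median, 2, colMeans(a$median))
  expect_equal(unname(pearson_median_correlation(a, d)), rep(-1, 4))
  z <- a; z$median[, 2] <- 5
  expect_error(pearson_median_correlation(a, z), "variance")
})

test_that("evaluation reports bundle R2 and error, with per-mode breakdown", {
  set.seed(5)
  actual <- quantize_phase(runif(400, 0, 100))
  predicted <- (actual + rnorm(400, 0, 1)) %% 100
  mode <- rep(c("LGW", "SA"), each = 200)
  rep_ <- evaluate_predictions(actual, predicted, mode)
  expect_s3_class(rep_, "gait_eval")
  expect_lt(rep_$error$mean, 2)
  expect_gt(rep_$r2$mean, 0.95)
  expect_named(rep_$by_mode, c("LGW", "SA"))
  flat <- write_eval_report(rep_, json_path = withr::local_tempfile(),
                            csv_path = withr::local_tempfile())
  expect_true("r2_mean" %in% flat$metric)
  expect_true("LGW_err_mean" %in% flat$metric)
})
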