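test_that("input scaling maps the printed anchor values and inverts exactly", {
  expect_equal(scale_signal(0, "load"), 0.5)
  expect_equal(scale_signal(1, "load"), 0.6)
  expect_equal(scale_signal(0, "angle"), 0.5)
  expect_equal(scale_signal(36, "angle"), 0.6)

  x <- seq(-180, 180, by = 1)
  for (kind in c("load", "angle")) {
    expect_true(all(diff(scale_signal(x, kind)) > 0))  # strictly increasing
    expect_lt(max(abs(unscale_signal(scale_signal(x, kind), kind) - x)), 1e-9)
  }
  # angles spanning +/-180 degrees stay inside the network's [0, 1] range
  expect_true(all(scale_signal(x, "angle") >= 0 & scale_signal(x, "angle") <= 1))
  expect_error(scale_signal(NaN, "load"), "finite")
  expect_error(scale_signal(Inf, "angle"), "finite")
})

test_that("load normalization is the body-weight ratio and rejects bad weights", {
  expect_equal(normalize_load(700, 700), 1.0)
  expect_equal(normalize_load(0, 700), 0.0)
  expect_equal(normalize_load(350, 700), 0.5)
  # linear in the raw load
  raw <- c(100, 200, 300)
  expect_equal(normalize_load(2 * raw, 700), 2 * normalize_load(raw, 700))
  expect_error(normalize_load(100, 0), "positive")
  expect_error(normalize_load(100, -5), "positive")
})

test_that("resampling hits 200 Hz, preserves duration, constants and amplitude", {
  s200 <- gait_series(fz = runif(50), thigh = rnorm(50), knee = rnorm(50),
                      ankle = rnorm(50), rate = 200)
  expect_identical(resample_series(s200, 200), s200)

  s100 <- gait_series(fz = rep(0.5, 100), thigh = rep(3, 100),
                      knee = rep(-7, 100), ankle = rep(0, 100), rate = 100)
  up <- resample_series(s100, 200)
  expect_equal(series_rate(up), 200)
  expect_lt(abs(nrow(up) - 200), 3)                  # ~1 s of samples
  expect_equal(range(up$knee), c(-7, -7))            # constants exact

  t1k <- (0:999) / 1000
  sine <- gait_series(fz = rep(0, 1000), thigh = 30 * sin(2 * pi * 2 * t1k),
                      knee = rep(0, 1000), ankle = rep(0, 1000), rate = 1000)
  down <- resample_series(sine, 200)
  expect_lt(abs(max(down$thigh) - 30) / 30, 0.01)    # amplitude within 1%
  expect_error(resample_series(gait_series(1, 1, 1, 1, rate = 100)),
               "at least 2")
})

test_that("bias removal shifts angles only; a quiet window de-means itself", {
  s <- gait_series(fz = runif(40), thigh = rnorm(40, 12), knee = rnorm(40, -4),
                   ankle = rnorm(40, 2), rate = 200)
  expect_equal(remove_bias(s), s)
  s2 <- remove_bias(s, c(thigh = 0, knee = 10, ankle = 0))
  expect_equal(s2$knee, s$knee - 10)
  expect_equal(s2$fz, s$fz)
  expect_equal(s2$thigh, s$thigh)
  s3 <- remove_bias(s, window = 1:40)
  expect_equal(mean(s3$thigh), 0)
  expect_equal(mean(s3$knee), 0)
  expect_equal(mean(s3$ankle), 0)
})

test_that("session CSV round-trips values, rate and label columns", {
  s <- gait_series(fz = runif(30), thigh = rnorm(30), knee = rnorm(30),
                   ankle = rnorm(30), rate = 200)
  s$phase_pct <- c(rep(NA_real_, 5), seq(0, 99.5, length.out = 25))
  path <- withr::local_tempfile(fileext = ".csv")
  write_gait_csv(s, path)
  r <- read_gait_csv(path)
  expect_equal(series_rate(r), 200, tolerance = 1e-6)
  expect_equal(r$fz, s$fz, tolerance = 1e-12)
  expect_equal(is.na(r$phase_pct), is.na(s$phase_pct))  # sentinel as empty field
  # missing required column is a clean error
  bad <- data.frame(time = 1:3, fz = 1:3)
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_gait_csv(path), "missing required column")
})
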