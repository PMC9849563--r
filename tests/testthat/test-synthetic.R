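test_that("zero-noise sessions are periodic and seeded runs reproduce exactly", {
  s1 <- generate_session("LGW", 10, zero_noise(), seed = 1)
  s2 <- generate_session("LGW", 10, zero_noise(), seed = 1)
  expect_identical(s1, s2)
  gaps <- diff(s1$heel_strikes)
  expect_true(all(gaps == gaps[1]))              # identical strides
  one <- as.matrix(as.data.frame(s1$series)[1:gaps[1], -1])
  two <- as.matrix(as.data.frame(s1$series)[(gaps[1] + 1):(2 * gaps[1]), -1])
  expect_equal(one, two, ignore_attr = TRUE)
  expect_error(generate_session("running", 5), "arg")
  expect_error(generate_session("LGW", 0), "n_strides")
})

test_that("generated signals respect the template invariants", {
  for (mode in c("LGW", "SA")) {
    s <- generate_session(mode, 30, seed = 17)
    m <- as.matrix(as.data.frame(s$series)[-1])
    expect_true(all(is.finite(m)))
    expect_true(all(s$series$fz >= 0))
    expect_true(all(abs(m[, c("thigh", "knee", "ankle")]) <= 180))
    # ground-truth phase: fully labeled, on the grid
    expect_false(anyNA(s$phase))
    expect_true(all(s$phase * 2 == round(s$phase * 2)))
    # heel strikes coincide with load onset: the stride-start sample carries
    # (near-)zero load and load rises within a few samples
    hs <- s$heel_strikes
    expect_true(all(s$phase[hs] == 0))
    # swing tail just before each heel strike is unloaded
    pre <- hs[-1] - 3L
    expect_true(all(s$series$fz[pre] < 0.08))
  }
})

test_that("zero-noise template load is ~0 in swing with a loaded stance", {
  for (mode in c("LGW", "SA")) {
    tpl <- stride_template(mode)
    phi <- seq(0, 0.999, by = 0.001)
    m <- eval_template(tpl, phi)
    swing <- phi > tpl$stance_frac
    expect_true(all(m[swing, "fz"] < 0.05))
    expect_gt(max(m[, "fz"]), 0.95)              # peak near body weight
    expect_true(all(m[, "fz"] >= 0))
  }
  # LGW stance has the double-bump shape: two local maxima flank a valley
  tpl <- stride_template("LGW")
  s <- seq(0.1, 0.9, by = 0.001)
  f <- gaitphase:::.load_eval(tpl$load, s)
  mid <- f[abs(s - 0.5) < 0.02]
  expect_lt(max(mid), max(f) - 0.1)
})

test_that("stride-duration variability tracks the configured cadence CV", {
  cv <- 0.05
  s <- generate_session("LGW", 100, noise_spec(cadence_cv = cv), seed = 23)
  dur <- diff(s$heel_strikes)
  realized <- sd(dur) / mean(dur)
  expect_gt(realized, cv / 2)
  expect_lt(realized, 2 * cv)
})

test_that("segmentation recovers interior heel strikes within 3 samples", {
  for (mode in c("LGW", "SA")) {
    s <- generate_session(mode, 12, zero_noise(), seed = 29)
    hs_det <- find_heel_strikes(extract_phases(s$series$fz))
    interior <- s$heel_strikes[-1]               # first can merge at the edge
    offs <- vapply(interior, function(h) min(abs(hs_det - h)), numeric(1))
    expect_true(all(offs <= 3))
  }
})

test_that("sensor-configuration variants add the configured RMS offset", {
  s <- generate_session("LGW", 100, seed = 31)
  v0 <- make_variant(s$series, "goniometer",
                     noise_spec(variant_sd = c(thigh = 0, knee = 0, ankle = 0)),
                     seed = 1)
  expect_identical(v0, s$series)
  v1 <- make_variant(s$series, "goniometer", seed = 1)
  v1b <- make_variant(s$series, "goniometer", seed = 1)
  expect_identical(v1, v1b)
  rms <- sqrt(mean((v1$thigh - s$series$thigh)^2))
  expect_gt(rms, 4); expect_lt(rms, 9)           # configured 6.2 deg
  expect_equal(v1$fz, s$series$fz)               # load untouched
  # the two variants of one session differ from each other
  v2 <- make_variant(s$series, "mocap", seed = 1)
  expect_gt(sqrt(mean((v1$knee - v2$knee)^2)), 1)
})

test_that("prosthesis-like ankle flattening behaves and degrades correlation", {
  s <- generate_session("LGW", 40, zero_noise(), seed = 37)
  expect_identical(make_prosthesis_like(s$series, 0), s$series)
  flat <- make_prosthesis_like(s$series, 1)
  stance <- which(s$series$fz > 0.05)
  runs <- split(stance, cumsum(c(1, diff(stance) > 1)))
  for (r in runs[2:4])
    expect_lt(max(flat$ankle[r]) - min(flat$ankle[r]), 1e-9)
  expect_equal(flat$thigh, s$series$thigh)
  expect_error(make_prosthesis_like(s$series, 1.5), "\\[0, 1\\]")
  # flattening strictly lowers the ankle correlation against the template
  ref <- median_trajectory(s$series, s$heel_strikes)
  r_flat <- pearson_median_correlation(
    ref, median_trajectory(flat, s$heel_strikes))["ankle"]
  half <- make_prosthesis_like(s$series, 0.5)
  r_half <- pearson_median_correlation(
    ref, median_trajectory(half, s$heel_strikes))["ankle"]
  expect_lt(r_flat, r_half)
  expect_lt(r_half, 1 - 1e-6)
})
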