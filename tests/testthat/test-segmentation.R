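test_that("one segmenter step follows the stance/swing decision rules", {
  p <- segmentation_params()
  st0 <- segmentation_state(p)
  # well above the load threshold: stance regardless of buffer content
  expect_equal(segment_step(0.5, st0, p)$label, 1L)
  expect_equal(segment_step(0.5, rep(0.9, p$lag), p)$label, 1L)
  # zero load, all-zero buffer: the equality branch labels swing and
  # appends the raw sample
  r <- segment_step(0, st0, p)
  expect_equal(r$label, 0L)
  expect_equal(r$state, rep(0, p$lag))
  # below threshold but rising relative to the smoothed trend: stance
  expect_equal(segment_step(0.1, rep(0.05, p$lag), p)$label, 1L)
  # below threshold and falling: swing
  expect_equal(segment_step(0.1, rep(0.15, p$lag), p)$label, 0L)
  # smoothed buffer update on the non-equality branch
  r2 <- segment_step(0.1, rep(0.15, p$lag), p)
  expect_equal(r2$state[p$lag], 0.01 * 0.1 + 0.99 * 0.15)
  expect_error(segment_step(0.5, rep(0, 3), p), "lag")
})

test_that("whole-series extraction labels degenerate loads correctly", {
  expect_equal(extract_phases(rep(0, 100)), rep(0L, 100))
  expect_equal(extract_phases(rep(0.5, 100)), rep(1L, 100))
  expect_error(extract_phases(numeric(0)), "empty")
  # labels always binary, same length as input
  set.seed(7)
  load <- abs(rnorm(500, 0.4, 0.4))
  lab <- extract_phases(load)
  expect_length(lab, 500)
  expect_true(all(lab %in% c(0L, 1L)))
})

test_that("extraction equals plain thresholding on noise-free rectangular loads", {
  p <- segmentation_params()
  set.seed(42)
  for (rep_i in 1:5) {
    lens <- sample(20:60, 8, replace = TRUE)   # all runs exceed persistence
    level <- runif(4, 0.5, 1)
    load <- unlist(lapply(seq_along(lens), function(i)
      rep(if (i %% 2 == 0) level[i / 2] else 0, lens[i])))
    got <- extract_phases(load, p)
    want <- threshold_oracle(load, p$f_th)
    after_warmup <- (p$lag + 1):length(load)
    expect_equal(got[after_warmup], want[after_warmup])
  }
})

test_that("refinement removes short runs, flushes the tail, and is idempotent", {
  expect_equal(refine(rep(1L, 30)), rep(1L, 30))
  # hand-traced: a 2-sample stance burst inside swing is absorbed
  x <- c(rep(0L, 6), 1L, 1L, rep(0L, 6))
  expect_equal(refine(x, 5), rep(0L, 14))
  # two long alternating runs are untouched
  y <- rep(c(0L, 1L), each = 10)
  expect_equal(refine(y, 5), y)
  # every output is fully labeled (no -1 placeholders survive)
  set.seed(11)
  for (i in 1:20) {
    z <- sample(c(0L, 1L), 50, replace = TRUE)
    rz <- refine(z, 5)
    expect_true(all(rz %in% c(0L, 1L)))
    expect_equal(refine(rz, 5), rz)          # idempotent
  }
})

test_that("spurious segments up to the persistence length vanish; longer survive", {
  p_hist <- segmentation_params()$p_hist
  for (len in 1:8) {
    x <- c(rep(0L, 30), rep(1L, len), rep(0L, 30))
    r <- refine(x, p_hist)
    if (len <= p_hist) expect_equal(r, rep(0L, length(x)))
    else expect_equal(sum(r), len)
  }
})

test_that("heel strikes are the swing-to-stance transitions", {
  expect_equal(find_heel_strikes(rep(1L, 20)), integer(0))
  expect_equal(find_heel_strikes(c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 1L)), c(3L, 7L))
  # periodic synthetic gait: consecutive heel-strike gaps match the stride
  sess <- generate_session("LGW", 8, zero_noise(), seed = 5)
  hs <- find_heel_strikes(extract_phases(sess$series$fz))
  expect_gte(length(hs), 7)
  gaps <- diff(hs)
  expect_true(all(abs(gaps - 220) <= 1))     # 1.1 s strides at 200 Hz
})
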