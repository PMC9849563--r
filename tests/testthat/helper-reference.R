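# Slow, independent R reference implementation of the network forward pass,
# written directly from the layer definitions (used to cross-check the
# compiled implementation on tiny architectures).
ref_forward <- function(params, x, config) {
  w <- gaitphase:::.nn_unpack(params, config)
  sig <- function(z) 1 / (1 + exp(-z))
  N <- dim(x)[1L]; T <- config$window; K <- config$kernel
  U <- config$lstm_units
  pad_l <- (K - 1) %/% 2
  out <- matrix(NA_real_, N, config$outputs)
  for (n in seq_len(N)) {
    xs <- matrix(x[n, , ], T, config$channels)      # T x C
    A <- matrix(NA_real_, T, config$filters)
    for (t in seq_len(T)) {
      acc <- as.numeric(w$conv_b)
      for (j in seq_len(K)) {
        idx <- t + (j - 1L) - pad_l
        if (idx >= 1L && idx <= T)
          acc <- acc + as.numeric(xs[idx, ] %*% w[[paste0("conv_w", j)]])
      }
      A[t, ] <- sig(acc)
    }
    h <- numeric(U); cc <- numeric(U)
    for (t in seq_len(T)) {
      z <- as.numeric(A[t, ] %*% w$lstm_wx + h %*% w$lstm_wh + w$lstm_b)
      i <- sig(z[1:U]); f <- sig(z[(U + 1):(2 * U)])
      g <- sig(z[(2 * U + 1):(3 * U)]); o <- sig(z[(3 * U + 1):(4 * U)])
      cc <- f * cc + i * g
      h <- o * sig(cc)
    }
    d <- h
    l <- 1L
    while (!is.null(w[[paste0("dense_w", l)]])) {
      d <- sig(as.numeric(d %*% w[[paste0("dense_w", l)]] +
                            w[[paste0("dense_b", l)]]))
      l <- l + 1L
    }
    out[n, ] <- d
  }
  out
}

# simple threshold oracle for segmentation on noise-free rectangular loads
threshold_oracle <- function(load, f_th = 0.2) as.integer(load > f_th)

# tiny architecture for fast training/gradient tests
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(window = 10L, channels = 4L, filters = 4L, kernel = 3L,
         lstm_units = 5L, dense = c(6L, 4L), outputs = 2L,
         epochs = 3L, batch = 32L),
    list(...))
  do.call(gaitphase_config, args)
}
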