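## Internal network plumbing: parameter layout, initialization and the Adam
## optimizer. The flat parameter layout must match src/nn.cpp exactly:
## conv kernels (K matrices C x F), conv bias, lstm Wx (F x 4U),
## lstm Wh (U x 4U), lstm bias (4U; gate order i,f,g,o), then per dense
## layer W (in x out) and bias.

.nn_cfg_vec <- function(config) {
  as.integer(c(config$window, config$channels, config$filters, config$kernel,
               config$lstm_units, config$dense, config$outputs))
}

.nn_shapes <- function(config) {
  K <- config$kernel; C <- config$channels; F <- config$filters
  U <- config$lstm_units
  shapes <- list()
  for (j in seq_len(K)) shapes[[paste0("conv_w", j)]] <- c(C, F)
  shapes$conv_b <- c(1L, F)
  shapes$lstm_wx <- c(F, 4L * U)
  shapes$lstm_wh <- c(U, 4L * U)
  shapes$lstm_b <- c(1L, 4L * U)
  sizes <- c(U, config$dense, config$outputs)
  for (l in seq_len(length(sizes) - 1L)) {
    shapes[[paste0("dense_w", l)]] <- c(sizes[l], sizes[l + 1L])
    shapes[[paste0("dense_b", l)]] <- c(1L, sizes[l + 1L])
  }
  shapes
}

.nn_n_params <- function(config) {
  sum(vapply(.nn_shapes(config), prod, numeric(1)))
}

## Glorot-uniform weights, zero biases, unit forget-gate bias (the usual
## recurrent-network conventions); draws come from R's RNG so a set.seed()
## upstream makes initialization reproducible.
.nn_init <- function(config) {
  K <- config$kernel; C <- config$channels; F <- config$filters
  U <- config$lstm_units
  shapes <- .nn_shapes(config)
  glorot <- function(fan_in, fan_out, n) {
    lim <- sqrt(6 / (fan_in + fan_out))
    stats::runif(n, -lim, lim)
  }
  params <- numeric(0)
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    n <- prod(sh)
    block <-
      if (grepl("^conv_w", nm)) glorot(K * C, K * F, n)
      else if (nm == "lstm_wx") glorot(F, 4 * U, n)
      else if (nm == "lstm_wh") glorot(U, 4 * U, n)
      else if (grepl("^dense_w", nm)) glorot(sh[1L], sh[2L], n)
      else if (nm == "lstm_b") c(rep(0, U), rep(1, U), rep(0, 2 * U))
      else rep(0, n)
    params <- c(params, block)
  }
  params
}

## flat vector -> named list of matrices (for coef() and serialization)
.nn_unpack <- function(params, config) {
  shapes <- .nn_shapes(config)
  out <- list()
  off <- 0L
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    n <- prod(sh)
    out[[nm]] <- matrix(params[(off + 1L):(off + n)], sh[1L], sh[2L])
    off <- off + n
  }
  out
}

.adam_init <- function(n) {
  list(m = numeric(n), v = numeric(n), t = 0L)
}

.adam_step <- function(params, grad, state, lr = 0.001, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  params <- params - lr * mhat / (sqrt(vhat) + eps)
  list(params = params, state = state)
}

## mean squared error without a gradient (validation monitoring)
.nn_mse <- function(params, x, y, cfg_vec) {
  yhat <- .nn_forward_cpp(params, x, cfg_vec)
  mean((yhat - y)^2)
}
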