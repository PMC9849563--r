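#' Configuration of the conv-LSTM phase predictor
#'
#' The network maps a 250 ms history (50 samples at 200 Hz) of the four
#' scaled sensor channels to the two scaled polar phase coordinates.
#' Architecture: input (50 x 4) -> 1-D convolution (32 filters, kernel 8,
#' stride 1, 'same' padding) -> LSTM (20 units, last-step output) -> dense 30
#' -> dense 10 -> dense 2, with a sigmoid activation on every trainable
#' layer. The defaults give exactly 6,258 trainable parameters
#' (conv 1,056 + LSTM 4,240 + dense 630 + 310 + 22).
#'
#' @param window History length in samples (50 = 250 ms at 200 Hz).
#' @param channels Number of input channels (load + 3 joint angles).
#' @param filters,kernel Convolution filters and kernel size.
#' @param lstm_units LSTM units.
#' @param dense Hidden dense-layer sizes.
#' @param outputs Output size (2: scaled polar phase components).
#' @param epochs,batch Training epochs and minibatch size.
#' @param lr Adam learning rate.
#' @param train_frac Fraction of windows used for training (rest is
#'   validation).
#' @param resplit_each_epoch Reshuffle and re-split train/validation at every
#'   epoch instead of once up front. Off by default: the per-epoch re-split
#'   leaks validation windows into training across epochs, so the one-shot
#'   split gives an honest validation loss.
#' @param seed Integer seed controlling initialization and shuffling, or
#'   `NULL` to use the ambient RNG state.
#' @return A list of class `gaitphase_config`.
#' @export
gaitphase_config <- function(window = 50L, channels = 4L, filters = 32L,
                             kernel = 8L, lstm_units = 20L,
                             dense = c(30L, 10L), outputs = 2L,
                             epochs = 15L, batch = 256L, lr = 0.001,
                             train_frac = 0.7, resplit_each_epoch = FALSE,
                             seed = 1L) {
  stopifnot(window >= 1, channels >= 1, filters >= 1, kernel >= 1,
            lstm_units >= 1, length(dense) >= 0, outputs >= 1,
            epochs >= 1, batch >= 1, lr > 0,
            train_frac > 0, train_frac <= 1)
  structure(list(window = as.integer(window), channels = as.integer(channels),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 lstm_units = as.integer(lstm_units),
                 dense = as.integer(dense), outputs = as.integer(outputs),
                 epochs = as.integer(epochs), batch = as.integer(batch),
                 lr = lr, train_frac = train_frac,
                 resplit_each_epoch = isTRUE(resplit_each_epoch),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "gaitphase_config")
}

#' @export
print.gaitphase_config <- function(x, ...) {
  cat("<gaitphase_config>\n")
  cat(sprintf("  input  : %d x %d (window x channels)\n", x$window, x$channels))
  cat(sprintf("  conv1d : %d filters, kernel %d, stride 1, same padding\n",
              x$filters, x$kernel))
  cat(sprintf("  lstm   : %d units\n", x$lstm_units))
  cat(sprintf("  dense  : %s -> %d outputs (sigmoid throughout)\n",
              paste(x$dense, collapse = " -> "), x$outputs))
  cat(sprintf("  params : %d trainable\n", n_params(x)))
  cat(sprintf("  train  : %d epochs, batch %d, Adam lr %g, split %.0f:%.0f\n",
              x$epochs, x$batch, x$lr, 100 * x$train_frac,
              100 * (1 - x$train_frac)))
  invisible(x)
}

#' Count trainable parameters of a configuration
#' @param config A [gaitphase_config()].
#' @return Integer number of trainable parameters.
#' @export
n_params <- function(config) as.integer(.nn_n_params(config))

#' Build an untrained phase-prediction network
#'
#' Initializes weights (Glorot uniform; biases zero except a unit LSTM forget
#' bias) for the architecture in `config`. With `config$seed` set the
#' initialization is reproducible.
#'
#' @param config A [gaitphase_config()].
#' @return An object of class `gaitphase_net` holding the flat parameter
#'   vector and the configuration.
#' @export
build_model <- function(config = gaitphase_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  structure(list(params = .nn_init(config), config = config,
                 trained = FALSE, history = NULL),
            class = "gaitphase_net")
}

#' @export
print.gaitphase_net <- function(x, ...) {
  cat(sprintf("<gaitphase_net: %s, %d trainable parameters>\n",
              if (x$trained) "trained" else "untrained",
              length(x$params)))
  print(x$config)
  invisible(x)
}

#' Build a sliding-window training set
#'
#' One window per sample `t >= window` whose phase label is not the `NA`
#' sentinel: the input is the scaled 50-sample history ending at `t` (causal
#' — no look-ahead) and the target is the scaled polar phase at `t`.
#'
#' @param series A `gait_series` in raw units (scaling is applied here), or a
#'   plain numeric matrix with columns fz, thigh, knee, ankle already scaled
#'   (`scaled = TRUE`).
#' @param phase Per-sample phase percentages with `NA` sentinels, as from
#'   [label_continuous_phase()]; same length as the series.
#' @param config A [gaitphase_config()].
#' @param scaled Set `TRUE` if `series` is already in scaled units.
#' @return A list of class `gait_windows`: `x` (N x window x channels array),
#'   `y` (N x 2 matrix of scaled polar targets), `t` (the 1-based sample
#'   index each window predicts), `phase` (its phase label).
#' @export
make_windows <- function(series, phase, config = gaitphase_config(),
                         scaled = FALSE) {
  if (inherits(series, "gait_series"))
    series <- cbind(fz = series$fz, thigh = series$thigh,
                    knee = series$knee, ankle = series$ankle)
  series <- as.matrix(series)
  if (ncol(series) != config$channels)
    stop("series must have ", config$channels, " channels")
  if (nrow(series) != length(phase))
    stop("series and phase must be aligned (same length)")
  if (!scaled) {
    series[, 1L] <- scale_signal(series[, 1L], "load")
    for (j in 2:4) series[, j] <- scale_signal(series[, j], "angle")
  }
  w <- config$window
  n <- nrow(series)
  keep <- which(!is.na(phase) & seq_len(n) >= w)
  N <- length(keep)
  x <- array(0, dim = c(N, w, config$channels))
  if (N > 0L) {
    for (i in seq_len(N)) {
      t <- keep[i]
      x[i, , ] <- series[(t - w + 1L):t, ]
    }
  }
  y <- scale_phase(to_polar(phase[keep]))
  dimnames(y) <- NULL
  structure(list(x = x, y = y, t = keep, phase = phase[keep]),
            class = "gait_windows")
}

#' @export
print.gait_windows <- function(x, ...) {
  cat(sprintf("<gait_windows: %d windows of %d x %d>\n",
              dim(x$x)[1L], dim(x$x)[2L], dim(x$x)[3L]))
  invisible(x)
}

#' Concatenate window datasets
#' @param ... `gait_windows` objects with identical window shape.
#' @return A single `gait_windows` object.
#' @export
bind_windows <- function(...) {
  ws <- list(...)
  x <- do.call(abind1, lapply(ws, `[[`, "x"))
  structure(list(x = x,
                 y = do.call(rbind, lapply(ws, `[[`, "y")),
                 t = unlist(lapply(ws, `[[`, "t")),
                 phase = unlist(lapply(ws, `[[`, "phase"))),
            class = "gait_windows")
}

## rbind for 3-d arrays along the first margin
abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1L]])
  n <- sum(vapply(arrs, function(a) dim(a)[1L], numeric(1)))
  out <- array(0, dim = c(n, d[2L], d[3L]))
  off <- 0L
  for (a in arrs) {
    k <- dim(a)[1L]
    if (k > 0L) out[(off + 1L):(off + k), , ] <- a
    off <- off + k
  }
  out
}

#' Train the phase-prediction network
#'
#' Minibatch Adam on the mean-squared error of the two scaled polar outputs.
#' Windows are shuffled and split into training and validation sets in the
#' configured ratio (default 7:3) once up front; set
#' `config$resplit_each_epoch` to re-split at every epoch instead.
#'
#' @param net A `gaitphase_net` from [build_model()].
#' @param windows A `gait_windows` dataset from [make_windows()].
#' @param config Training configuration; defaults to the network's own.
#' @param seed Optional seed for the shuffle/split (otherwise the ambient
#'   RNG state is used, so a seed set before [build_model()] makes the whole
#'   build+train run reproducible).
#' @param verbose Print per-epoch losses.
#' @return The trained `gaitphase_net`, with `history` (per-epoch training
#'   and validation loss) and `val_idx` (window indices held out).
#' @export
train_model <- function(net, windows, config = net$config, seed = NULL,
                        verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  N <- dim(windows$x)[1L]
  if (N < 1L) stop("empty window dataset")
  cfg_vec <- .nn_cfg_vec(config)
  params <- net$params
  batch <- min(config$batch, N)
  astate <- .adam_init(length(params))
  split_once <- !config$resplit_each_epoch
  perm <- sample.int(N)
  n_tr <- max(1L, round(config$train_frac * N))
  tr_idx <- perm[seq_len(n_tr)]
  va_idx <- if (n_tr < N) perm[(n_tr + 1L):N] else integer(0L)
  hist <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                     val_loss = NA_real_)
  va_x <- windows$x[va_idx, , , drop = FALSE]
  va_y <- windows$y[va_idx, , drop = FALSE]
  for (ep in seq_len(config$epochs)) {
    if (!split_once) {
      perm <- sample.int(N)
      tr_idx <- perm[seq_len(n_tr)]
      va_idx <- if (n_tr < N) perm[(n_tr + 1L):N] else integer(0L)
      va_x <- windows$x[va_idx, , , drop = FALSE]
      va_y <- windows$y[va_idx, , drop = FALSE]
    }
    ord <- sample(tr_idx)
    losses <- numeric(0)
    for (b0 in seq(1L, length(ord), by = batch)) {
      bi <- ord[b0:min(b0 + batch - 1L, length(ord))]
      bx <- windows$x[bi, , , drop = FALSE]
      by <- windows$y[bi, , drop = FALSE]
      lg <- .nn_loss_grad_cpp(params, bx, by, cfg_vec)
      st <- .adam_step(params, lg$grad, astate, lr = config$lr)
      params <- st$params
      astate <- st$state
      losses <- c(losses, lg$loss)
    }
    hist$train_loss[ep] <- mean(losses)
    hist$val_loss[ep] <- if (length(va_idx))
      .nn_mse(params, va_x, va_y, cfg_vec) else NA_real_
    if (verbose)
      message(sprintf("epoch %2d/%d  train mse %.3e  val mse %.3e",
                      ep, config$epochs, hist$train_loss[ep],
                      hist$val_loss[ep]))
  }
  net$params <- params
  net$trained <- TRUE
  net$history <- hist
  net$val_idx <- va_idx
  net$config <- config
  net
}

#' Predict scaled polar phase for a batch of windows
#'
#' Low-level forward pass. Most users want [predict.gaitphase_fit()] or
#' [predict.gaitphase_net()], which also convert to phase percentages.
#'
#' @param net A `gaitphase_net`.
#' @param x N x window x channels array of scaled inputs.
#' @param chunk Forward-pass chunk size (memory control).
#' @return N x 2 matrix of scaled polar outputs.
#' @export
forward_windows <- function(net, x, chunk = 4096L) {
  N <- dim(x)[1L]
  cfg_vec <- .nn_cfg_vec(net$config)
  out <- matrix(NA_real_, N, net$config$outputs)
  for (b0 in seq(1L, N, by = chunk)) {
    bi <- b0:min(b0 + chunk - 1L, N)
    out[bi, ] <- .nn_forward_cpp(net$params, x[bi, , , drop = FALSE], cfg_vec)
  }
  out
}

#' Predict continuous gait phase from sensor windows
#'
#' Runs the network over windows (or over every sample of a raw
#' `gait_series`) and converts the two scaled polar outputs to phase
#' percentages. A degenerate output at the circle center (undefined angle)
#' yields the `NA` sentinel.
#'
#' @param object A `gaitphase_net`.
#' @param newdata A `gait_windows` dataset or a raw `gait_series`.
#' @param ... Unused.
#' @return For `gait_windows`: numeric vector of phase percentages, one per
#'   window. For a `gait_series`: vector as long as the series with `NA` for
#'   the first `window - 1` samples (no full history yet).
#' @export
predict.gaitphase_net <- function(object, newdata, ...) {
  cfg <- object$config
  if (inherits(newdata, "gait_series")) {
    n <- nrow(newdata)
    phase_all <- rep(0, n)                       # dummy labels: window everywhere
    w <- make_windows(newdata, phase_all, cfg)
    yhat <- forward_windows(object, w$x)
    out <- rep(NA_real_, n)
    out[w$t] <- from_polar(yhat[, 1L], yhat[, 2L], on_center = "na")
    return(out)
  }
  if (!inherits(newdata, "gait_windows"))
    stop("'newdata' must be a gait_series or gait_windows")
  yhat <- forward_windows(object, newdata$x)
  from_polar(yhat[, 1L], yhat[, 2L], on_center = "na")
}

#' Save a trained network as JSON
#'
#' Single-file text serialization: configuration plus the flat weight vector.
#'
#' @param net A `gaitphase_net`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gaitphase_model <- function(net, path) {
  cfg <- unclass(net$config)
  cfg$dense <- as.list(cfg$dense)
  payload <- list(format = "gaitphase_net", version = 1L,
                  config = cfg, trained = net$trained,
                  params = net$params,
                  history = net$history)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load a network saved by [write_gaitphase_model()]
#' @param path JSON file.
#' @return A `gaitphase_net`.
#' @export
read_gaitphase_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$format, "gaitphase_net"))
    stop("not a gaitphase model file: ", path)
  cf <- payload$config
  config <- gaitphase_config(window = cf$window, channels = cf$channels,
                             filters = cf$filters, kernel = cf$kernel,
                             lstm_units = cf$lstm_units,
                             dense = unlist(cf$dense), outputs = cf$outputs,
                             epochs = cf$epochs, batch = cf$batch,
                             lr = cf$lr, train_frac = cf$train_frac,
                             resplit_each_epoch = cf$resplit_each_epoch,
                             seed = cf$seed)
  structure(list(params = payload$params, config = config,
                 trained = isTRUE(payload$trained),
                 history = payload$history),
            class = "gaitphase_net")
}
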