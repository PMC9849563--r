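#' Fit the continuous gait-phase predictor to labeled sessions
#'
#' The package's headline estimator. Given one or more gait sessions, this
#' runs the full pipeline: if no phase labels are supplied they are derived
#' from the vertical load (streaming stance/swing segmentation, heel-strike
#' detection, linear-in-time phase labeling), sensor channels are scaled,
#' sliding 250 ms windows are built, and the conv-LSTM network is trained
#' with minibatch Adam on the mean-squared error of the scaled polar phase
#' targets.
#'
#' @param series A `gait_series`, or a list of them (sessions are windowed
#'   independently so windows never straddle session boundaries).
#' @param phase Optional per-sample phase labels (vector, or list matching
#'   `series`) with `NA` sentinels; derived from the load when `NULL`.
#' @param config A [gaitphase_config()]; `config$seed` makes the whole fit
#'   reproducible.
#' @param verbose Print per-epoch losses.
#' @return An object of class `gaitphase_fit`: the trained network (`net`),
#'   `config`, per-epoch `history`, window count `n_windows`, and the
#'   held-out validation predictions (`val`) used by [residuals.gaitphase_fit()]
#'   and [summary.gaitphase_fit()].
#' @examples
#' \donttest{
#' sess <- generate_session("LGW", 40, seed = 1)
#' cfg <- gaitphase_config(epochs = 3, seed = 1)
#' fit <- gaitphase_fit(sess$series, sess$phase, cfg)
#' summary(fit)
#' }
#' @export
gaitphase_fit <- function(series, phase = NULL, config = gaitphase_config(),
                          verbose = FALSE) {
  if (inherits(series, "gait_series")) series <- list(series)
  if (!is.null(phase) && !is.list(phase)) phase <- list(phase)
  if (is.null(phase)) {
    phase <- lapply(series, function(s) {
      labels <- extract_phases(s$fz)
      label_continuous_phase(find_heel_strikes(labels), nrow(s))
    })
  }
  if (length(phase) != length(series))
    stop("'phase' must match 'series' session-for-session")
  net <- build_model(config)            # seeds the RNG when config$seed set
  ws <- mapply(make_windows, series, phase,
               MoreArgs = list(config = config), SIMPLIFY = FALSE)
  windows <- if (length(ws) == 1L) ws[[1L]] else do.call(bind_windows, ws)
  if (dim(windows$x)[1L] < 1L)
    stop("no usable windows: sessions too short or unlabeled")
  net <- train_model(net, windows, config, verbose = verbose)
  val <- NULL
  if (length(net$val_idx)) {
    vp <- forward_windows(net, windows$x[net$val_idx, , , drop = FALSE])
    val <- list(actual = windows$phase[net$val_idx],
                predicted = from_polar(vp[, 1L], vp[, 2L], on_center = "na"),
                polar_actual = windows$y[net$val_idx, , drop = FALSE],
                polar_predicted = vp)
  }
  structure(list(net = net, config = config, history = net$history,
                 n_windows = dim(windows$x)[1L], val = val),
            class = "gaitphase_fit")
}

#' @export
print.gaitphase_fit <- function(x, ...) {
  cat(sprintf(
    "Continuous gait-phase predictor (conv-LSTM, %d trainable parameters)\n",
    length(x$net$params)))
  cat(sprintf("  trained on %d windows (%d x %d), %d epochs\n",
              x$n_windows, x$config$window, x$config$channels,
              x$config$epochs))
  h <- x$history
  cat(sprintf("  final loss: train %.3e, validation %.3e\n",
              h$train_loss[nrow(h)], h$val_loss[nrow(h)]))
  invisible(x)
}

#' @export
summary.gaitphase_fit <- function(object, ...) {
  out <- list(config = object$config, history = object$history,
              n_windows = object$n_windows, n_params = length(object$net$params))
  if (!is.null(object$val))
    out$val_eval <- evaluate_predictions(object$val$actual,
                                         object$val$predicted)
  class(out) <- "summary.gaitphase_fit"
  out
}

#' @export
print.summary.gaitphase_fit <- function(x, ...) {
  cat(sprintf("Conv-LSTM gait-phase predictor: %d parameters, %d windows\n",
              x$n_params, x$n_windows))
  print(x$config)
  h <- x$history
  cat(sprintf("Loss (MSE on scaled polar targets): train %.3e -> %.3e, val %.3e -> %.3e\n",
              h$train_loss[1L], h$train_loss[nrow(h)],
              h$val_loss[1L], h$val_loss[nrow(h)]))
  if (!is.null(x$val_eval)) {
    cat("Held-out validation windows:\n")
    print(x$val_eval)
  }
  invisible(x)
}

#' @export
coef.gaitphase_fit <- function(object, flat = FALSE, ...) {
  if (flat) object$net$params
  else .nn_unpack(object$net$params, object$config)
}

#' @export
coef.gaitphase_net <- function(object, flat = FALSE, ...) {
  if (flat) object$params else .nn_unpack(object$params, object$config)
}

#' @rdname predict.gaitphase_net
#' @export
predict.gaitphase_fit <- function(object, newdata, ...) {
  predict(object$net, newdata, ...)
}

#' Signed circular residuals on the held-out validation windows
#'
#' `((predicted - actual + 50) mod 100) - 50`: positive when the prediction
#' leads the true phase, in percent of the gait cycle, in `(-50, 50]`.
#'
#' @param object A `gaitphase_fit`.
#' @param ... Unused.
#' @return Numeric vector of signed errors.
#' @export
residuals.gaitphase_fit <- function(object, ...) {
  if (is.null(object$val)) stop("fit kept no validation windows")
  ((object$val$predicted - object$val$actual + 50) %% 100) - 50
}

#' Diagnostic plots for a fitted phase predictor
#'
#' @param x A `gaitphase_fit`.
#' @param which `"loss"` (training curves), `"polar"` (validation predictions
#'   on the scaled polar circle), or `"error"` (histogram of signed circular
#'   residuals).
#' @param ... Passed to the underlying plot calls.
#' @export
plot.gaitphase_fit <- function(x, which = c("loss", "polar", "error"), ...) {
  which <- match.arg(which)
  if (which == "loss") {
    h <- x$history
    graphics::plot(h$epoch, h$train_loss, type = "b", xlab = "epoch",
                   ylab = "MSE", ylim = range(h$train_loss, h$val_loss,
                                              na.rm = TRUE), ...)
    graphics::lines(h$epoch, h$val_loss, type = "b", col = 2)
    graphics::legend("topright", c("train", "validation"), col = 1:2, lty = 1)
  } else if (which == "polar") {
    if (is.null(x$val)) stop("fit kept no validation windows")
    graphics::plot(x$val$polar_actual, pch = ".", xlab = "px'", ylab = "py'",
                   asp = 1, ...)
    graphics::points(x$val$polar_predicted, pch = ".", col = 2)
    graphics::legend("topright", c("actual", "predicted"), col = 1:2, pch = 20)
  } else {
    graphics::hist(residuals(x), breaks = 50,
                   xlab = "signed circular error [% cycle]", main = "", ...)
  }
  invisible(x)
}
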