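#' Continuous gait-phase labels from heel-strike events
#'
#' The gait cycle runs from a heel strike (0%) to the next heel strike of the
#' same leg (100%). Between consecutive heel strikes the phase is linear in
#' time, quantized to the 0.5% grid (ties toward zero); 100% wraps to 0%, so
#' labels live on `{0, 0.5, ..., 99.5}`. Samples outside any complete stride
#' (before the first or after the last heel strike) get the sentinel `NA`:
#' their phase is undefined and they are excluded from training and
#' evaluation.
#'
#' @param heel_strikes Strictly increasing 1-based sample indices of heel
#'   strikes, within `[1, n_samples]`.
#' @param n_samples Length of the session in samples.
#' @return Numeric vector of length `n_samples`: phase percentage in
#'   `[0, 99.5]` on the 0.5% grid, or `NA` where unlabeled. Fewer than two
#'   heel strikes yield all `NA`.
#' @export
label_continuous_phase <- function(heel_strikes, n_samples) {
  n_samples <- as.integer(n_samples)
  p <- rep(NA_real_, n_samples)
  k <- length(heel_strikes)
  if (k >= 1L) {
    if (any(diff(heel_strikes) <= 0))
      stop("heel_strikes must be strictly increasing")
    if (heel_strikes[1L] < 1L || heel_strikes[k] > n_samples)
      stop("heel_strikes out of range")
  }
  if (k < 2L) return(p)
  for (i in seq_len(k - 1L)) {
    h0 <- heel_strikes[i]
    h1 <- heel_strikes[i + 1L]
    t <- h0:(h1 - 1L)
    p[t] <- quantize_phase(100 * (t - h0) / (h1 - h0))
  }
  p
}

#' Quantize phase percentages to the 0.5% grid
#'
#' Rounds to the nearest multiple of 0.5 with ties toward zero; 100 wraps
#' to 0.
#'
#' @param p_c Phase percentages in `[0, 100)`.
#' @return Values on `{0, 0.5, ..., 99.5}` (NA passed through).
#' @export
quantize_phase <- function(p_c) {
  q <- ceiling(2 * p_c - 0.5) / 2     # nearest 0.5, ties toward zero
  q %% 100
}

#' Phase percentage to polar coordinates
#'
#' Encodes the cyclic phase as a point on the unit circle,
#' `(cos(theta), sin(theta))` with `theta = 2*pi*p_c/100`, removing the
#' 100% to 0% discontinuity that otherwise corrupts regression targets near
#' the cycle boundary.
#'
#' @param p_c Phase percentages; values outside `[0, 100)` are wrapped.
#' @return Matrix with columns `px`, `py`; rows on the unit circle.
#' @export
to_polar <- function(p_c) {
  theta <- 2 * pi * (p_c %% 100) / 100
  cbind(px = cos(theta), py = sin(theta))
}

#' Scale polar phase components into network output range
#'
#' `p' = (p + 5) / 10` maps `[-1, 1]` to `[0.4, 0.6]`, the data convention of
#' the target device's communication layer (the network predicts in this
#' range).
#'
#' @param p Polar component(s) in `[-1, 1]` (vector or matrix).
#' @return Scaled value(s) in `[0.4, 0.6]`.
#' @export
scale_phase <- function(p) (p + 5) / 10

#' Invert the polar phase scaling
#' @param p_s Scaled polar component(s) in `[0.4, 0.6]`.
#' @return Unscaled component(s) in `[-1, 1]`.
#' @export
unscale_phase <- function(p_s) 10 * p_s - 5

#' Phase percentage from scaled polar coordinates
#'
#' Inverse of [to_polar()] composed with [scale_phase()]:
#' `p_c = (atan2(py, px) mod 2*pi) * 100 / (2*pi)` after unscaling both
#' components. Inputs need not lie exactly on the unit circle (network
#' outputs do not), but the circle center (0.5, 0.5) has no defined angle.
#'
#' @param px_s,py_s Scaled polar components.
#' @param on_center `"error"` (default) to stop when a point is at the
#'   circle center, `"na"` to return the `NA` sentinel there.
#' @param tol Radius below which a point counts as the center.
#' @return Phase percentages in `[0, 100)`.
#' @export
from_polar <- function(px_s, py_s, on_center = c("error", "na"),
                       tol = 1e-9) {
  on_center <- match.arg(on_center)
  px <- unscale_phase(px_s)
  py <- unscale_phase(py_s)
  center <- sqrt(px^2 + py^2) < tol
  if (any(center) && on_center == "error")
    stop("phase undefined at the circle center (0.5, 0.5)")
  p_c <- (atan2(py, px) %% (2 * pi)) * 100 / (2 * pi)
  p_c[p_c >= 100] <- 0              # guard against atan2 rounding at 2*pi
  p_c[center] <- NA_real_
  p_c
}

#' Circular distance between gait phases
#'
#' The gait phase is cyclic: an actual phase of 99% and a prediction of 1%
#' are 2% apart, not 98%. The error is `min(|d|, 100 - |d|)`, symmetric and
#' bounded by 50%.
#'
#' @param actual,predicted Phase percentages in `[0, 100)` (vectors are
#'   recycled as usual).
#' @return Circular error(s) in percent of gait cycle, in `[0, 50]`.
#' @export
circular_error <- function(actual, predicted) {
  d <- abs(actual - predicted) %% 100
  pmin(d, 100 - d)
}
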