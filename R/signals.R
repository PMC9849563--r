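#' Construct a uniformly sampled four-channel gait record
#'
#' A `gait_series` is the pipeline's universal input: a data frame with
#' columns `time` (seconds), `fz` (weight-normalized vertical load, body-weight
#' units), and `thigh`, `knee`, `ankle` (joint angles in degrees; thigh
#' extension, knee flexion and ankle dorsiflexion positive), sampled uniformly
#' at `rate` samples per second.
#'
#' @param fz Numeric vector of weight-normalized vertical load (BW).
#' @param thigh,knee,ankle Numeric vectors of joint angles (degrees), same
#'   length as `fz`.
#' @param rate Sampling rate in Hz. The pipeline's working rate is 200 Hz;
#'   use [resample_series()] to convert.
#' @param time Optional vector of sample times (seconds). Defaults to
#'   `(seq_along(fz) - 1) / rate`.
#' @return A data frame of class `gait_series` with attribute `rate`.
#' @seealso [resample_series()], [scale_signal()], [read_gait_csv()]
#' @export
gait_series <- function(fz, thigh, knee, ankle, rate = 200, time = NULL) {
  n <- length(fz)
  if (length(thigh) != n || length(knee) != n || length(ankle) != n)
    stop("all channels must have the same length")
  if (n < 1L) stop("gait_series must contain at least one sample")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive number")
  if (is.null(time)) time <- (seq_len(n) - 1) / rate
  vals <- c(fz, thigh, knee, ankle, time)
  if (!all(is.finite(vals))) stop("all channel values must be finite")
  out <- data.frame(time = time, fz = fz, thigh = thigh, knee = knee,
                    ankle = ankle)
  attr(out, "rate") <- rate
  class(out) <- c("gait_series", "data.frame")
  out
}

#' @export
print.gait_series <- function(x, ...) {
  cat(sprintf("<gait_series: %d samples at %g Hz (%.2f s)>\n",
              nrow(x), attr(x, "rate"), nrow(x) / attr(x, "rate")))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' @export
plot.gait_series <- function(x, channels = c("fz", "thigh", "knee", "ankle"),
                             ...) {
  old <- graphics::par(mfrow = c(length(channels), 1L),
                       mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (ch in channels) {
    ylab <- if (ch == "fz") "load [BW]" else paste0(ch, " [deg]")
    graphics::plot(x$time, x[[ch]], type = "l", xlab = "time [s]",
                   ylab = ylab, ...)
  }
  invisible(x)
}

#' Sampling rate of a gait series
#' @param series A `gait_series`.
#' @return Sampling rate in Hz.
#' @export
series_rate <- function(series) {
  r <- attr(series, "rate")
  if (is.null(r)) stop("object has no 'rate' attribute; not a gait_series?")
  r
}

## Channel gains for the network input scaling: the load channel passes
## through unchanged, angles are divided by 36 so that +/-180 deg maps into
## [0, 1] after the affine (v/g + 5)/10 step.
.gains <- c(load = 1, angle = 36)

.check_kind <- function(kind) {
  kind <- match.arg(kind, c("load", "angle"))
  kind
}

#' Scale a raw sensor value into network input range
#'
#' Applies the affine scaling `v_n = (v / g + 5) / 10`, with gain `g = 1` for
#' the weight-normalized vertical load and `g = 36` for joint angles. A load
#' of 0 BW maps to 0.5 and 1 BW to 0.6; angles in \[-180, 180\] degrees map
#' into \[0, 1\].
#'
#' @param v Numeric vector of raw channel values (BW or degrees).
#' @param kind `"load"` or `"angle"`.
#' @return Scaled values, same length as `v`.
#' @seealso [unscale_signal()] for the exact inverse.
#' @export
scale_signal <- function(v, kind = c("load", "angle")) {
  kind <- .check_kind(kind)
  if (!all(is.finite(v))) stop("non-finite value passed to scale_signal()")
  (v / .gains[[kind]] + 5) / 10
}

#' Invert the network input scaling
#'
#' Exact algebraic inverse of [scale_signal()]: `v = (10 * v_n - 5) * g`.
#'
#' @param v_n Numeric vector of scaled values.
#' @param kind `"load"` or `"angle"`.
#' @return Raw values in the original units.
#' @export
unscale_signal <- function(v_n, kind = c("load", "angle")) {
  kind <- .check_kind(kind)
  if (!all(is.finite(v_n))) stop("non-finite value passed to unscale_signal()")
  (10 * v_n - 5) * .gains[[kind]]
}

#' Normalize vertical load by body weight
#'
#' @param raw_load Vertical load in force units (e.g. N).
#' @param body_weight Body weight in the same units; must be positive.
#' @return Weight-normalized load in body-weight (BW) units.
#' @export
normalize_load <- function(raw_load, body_weight) {
  if (!is.numeric(body_weight) || length(body_weight) != 1L ||
      !is.finite(body_weight) || body_weight <= 0)
    stop("'body_weight' must be a single positive number")
  raw_load / body_weight
}

#' Resample a gait series to a target rate
#'
#' Linear interpolation of every channel onto a uniform grid at `rate`
#' (default 200 Hz, the pipeline's working rate). Works for both up- and
#' downsampling; duration is preserved to within one sample period. No
#' anti-alias filtering is applied: gait signals are far below the Nyquist
#' frequency at the rates of interest.
#'
#' @param series A `gait_series` at any source rate.
#' @param rate Target sampling rate in Hz.
#' @return A `gait_series` at `rate`.
#' @export
resample_series <- function(series, rate = 200) {
  src <- series_rate(series)
  n <- nrow(series)
  if (n < 2L) stop("resampling needs at least 2 samples")
  if (src == rate) return(series)
  t_src <- series$time
  duration <- (n - 1L) / src
  t_new <- series$time[1L] + seq(0, duration, by = 1 / rate)
  interp <- function(y) stats::approx(t_src, y, xout = t_new,
                                      method = "linear", rule = 2)$y
  gait_series(fz = interp(series$fz), thigh = interp(series$thigh),
              knee = interp(series$knee), ankle = interp(series$ankle),
              rate = rate, time = t_new)
}

#' Remove angular biases from the joint channels
#'
#' Sensor setups differ in their angle baselines (mounting offsets, zeroing
#' conventions); this shifts each angle channel by a constant so different
#' configurations share a common baseline. The load channel is untouched.
#' The baseline can be given directly as per-channel offsets, or estimated as
#' the channel means over a quiet-standing window.
#'
#' @param series A `gait_series`.
#' @param baseline Named numeric vector with elements `thigh`, `knee`,
#'   `ankle`: the offsets to subtract. Ignored when `window` is given.
#' @param window Optional integer vector of row indices of a quiet-standing
#'   window; the baseline is then the per-channel mean over that window.
#' @return The de-biased `gait_series`.
#' @export
remove_bias <- function(series, baseline = c(thigh = 0, knee = 0, ankle = 0),
                        window = NULL) {
  if (!is.null(window)) {
    baseline <- c(thigh = mean(series$thigh[window]),
                  knee  = mean(series$knee[window]),
                  ankle = mean(series$ankle[window]))
  }
  for (ch in c("thigh", "knee", "ankle")) {
    off <- baseline[[ch]]
    if (is.null(off) || !is.finite(off)) stop("missing baseline for ", ch)
    series[[ch]] <- series[[ch]] - off
  }
  series
}

#' Read a gait session from CSV
#'
#' Expects a header with columns `time,fz,thigh,knee,ankle` (UTF-8, `.`
#' decimal). The sampling rate is taken from `rate` if given, otherwise
#' inferred from the median spacing of the `time` column.
#'
#' @param path Path to the CSV file.
#' @param rate Optional declared sampling rate (Hz).
#' @return A `gait_series`. Extra columns (e.g. `phase_bin`, `phase_pct`)
#'   are carried along.
#' @export
read_gait_csv <- function(path, rate = NULL) {
  df <- utils::read.csv(path, header = TRUE)
  need <- c("time", "fz", "thigh", "knee", "ankle")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (is.null(rate)) {
    dt <- stats::median(diff(df$time))
    if (!is.finite(dt) || dt <= 0)
      stop("cannot infer sampling rate from 'time' column; pass 'rate'")
    rate <- 1 / dt
  }
  out <- gait_series(fz = df$fz, thigh = df$thigh, knee = df$knee,
                     ankle = df$ankle, rate = rate, time = df$time)
  extra <- setdiff(names(df), need)
  for (ch in extra) out[[ch]] <- df[[ch]]
  out
}

#' Write a gait session to CSV
#'
#' Writes `time,fz,thigh,knee,ankle` plus any extra columns present (e.g.
#' `phase_bin` stance/swing labels or `phase_pct` continuous phase, where the
#' unlabeled sentinel `NA` becomes an empty field).
#'
#' @param series A `gait_series` (possibly with extra columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gait_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}
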