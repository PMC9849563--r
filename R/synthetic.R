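#' Stride template for a given ambulation mode
#'
#' Hand-designed smooth stride shapes used by the synthetic session
#' generator. Joint angles are low-order Fourier series over normalized
#' phase; the vertical load is a stance-only profile — a double bump with a
#' mid-stance valley for level-ground walking (LGW), a smoother single peak
#' for stair ascent (SA) — with a steep loading edge at heel strike, an
#' unloading edge before toe-off, and exactly zero load throughout swing.
#'
#' @param mode `"LGW"` (level-ground walking) or `"SA"` (stair ascent).
#' @return A list of class `stride_template` with elements `mode`,
#'   `stride_s` (nominal stride duration, seconds), `stance_frac`
#'   (stance fraction of the cycle), `angles` (per-channel Fourier
#'   coefficients `a0`, `ac`, `as`) and `load` (Fourier coefficients of the
#'   stance core profile plus edge widths).
#' @export
stride_template <- function(mode = c("LGW", "SA")) {
  mode <- match.arg(mode)
  if (mode == "LGW") {
    tpl <- list(
      mode = mode, stride_s = 1.1, stance_frac = 0.60,
      angles = list(
        thigh = list(a0 = 0,  ac = c(18),      as = c(6)),
        knee  = list(a0 = 25, ac = c(-15, -8), as = c(-12, 6)),
        ankle = list(a0 = 0,  ac = c(-5, 4),   as = c(-7, 3))),
      ## double bump: shoulders 0.45 BW, peaks ~1.10 at 22/78% of stance,
      ## mid-stance valley ~0.78
      load = list(a0 = 0.8575, ac = c(-0.165, -0.2425),
                  rise = 0.02, fall = 0.06))
  } else {
    tpl <- list(
      mode = mode, stride_s = 1.4, stance_frac = 0.65,
      angles = list(
        thigh = list(a0 = 10, ac = c(25),     as = c(8)),
        knee  = list(a0 = 40, ac = c(-28, 5), as = c(-10, 0)),
        ankle = list(a0 = 5,  ac = c(-8, -3), as = c(10, 0))),
      ## single smooth peak ~1.05 BW at mid-stance
      load = list(a0 = 0.75, ac = c(-0.30), rise = 0.02, fall = 0.06))
  }
  class(tpl) <- "stride_template"
  tpl
}

## Fourier series over normalized phase in [0, 1)
.fourier_eval <- function(coefs, phi) {
  out <- rep(coefs$a0, length(phi))
  for (k in seq_along(coefs$ac))
    out <- out + coefs$ac[k] * cos(2 * pi * k * phi)
  if (!is.null(coefs$as))
    for (k in seq_along(coefs$as))
      out <- out + coefs$as[k] * sin(2 * pi * k * phi)
  out
}

.smoothstep <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x * x * (3 - 2 * x)
}

## stance load profile over stance-normalized s in [0, 1]; zero outside
.load_eval <- function(load, s) {
  core <- rep(load$a0, length(s))
  for (k in seq_along(load$ac))
    core <- core + load$ac[k] * cos(2 * pi * k * s)
  edge <- .smoothstep(s / load$rise) * .smoothstep((1 - s) / load$fall)
  f <- core * edge
  f[s < 0 | s > 1] <- 0
  pmax(f, 0)
}

#' Evaluate a stride template on a phase grid
#'
#' @param template A [stride_template()].
#' @param phi Normalized phase values in `[0, 1)`.
#' @return Matrix with columns `fz`, `thigh`, `knee`, `ankle`.
#' @export
eval_template <- function(template, phi) {
  s <- phi / template$stance_frac       # stance-normalized phase
  cbind(fz    = .load_eval(template$load, s),
        thigh = .fourier_eval(template$angles$thigh, phi),
        knee  = .fourier_eval(template$angles$knee, phi),
        ankle = .fourier_eval(template$angles$ankle, phi))
}

#' Variability specification for synthetic sessions
#'
#' @param cadence_cv Fractional standard deviation of stride duration across
#'   strides.
#' @param amplitude_cv Fractional standard deviation of the per-stride
#'   amplitude scaling (applied to angle excursions about their mean and to
#'   the load profile).
#' @param sensor_sd Additive white sensor-noise standard deviation per
#'   channel (`fz` in BW, angles in degrees).
#' @param variant_sd Per-channel RMS magnitude (degrees) of the smooth
#'   between-sensor-configuration angle offsets applied by [make_variant()],
#'   emulating the several-degree discrepancies between motion-capture and
#'   goniometer measurements of the same gait.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(cadence_cv = 0.05, amplitude_cv = 0.05,
                       sensor_sd = c(fz = 0.01, thigh = 0.5, knee = 0.5,
                                     ankle = 0.5),
                       variant_sd = c(thigh = 6.2, knee = 4.3, ankle = 3.7)) {
  stopifnot(cadence_cv >= 0, amplitude_cv >= 0, all(sensor_sd >= 0),
            all(variant_sd >= 0))
  structure(list(cadence_cv = cadence_cv, amplitude_cv = amplitude_cv,
                 sensor_sd = sensor_sd, variant_sd = variant_sd),
            class = "noise_spec")
}

#' Zero-variability specification (identical strides, no noise)
#' @return A `noise_spec` with all variabilities zero.
#' @export
zero_noise <- function() {
  noise_spec(cadence_cv = 0, amplitude_cv = 0,
             sensor_sd = c(fz = 0, thigh = 0, knee = 0, ankle = 0),
             variant_sd = c(thigh = 0, knee = 0, ankle = 0))
}

#' Generate a synthetic gait session with known ground truth
#'
#' Concatenates `n_strides` strides of the mode's template with jittered
#' durations and amplitudes plus additive sensor noise. Each stride begins at
#' a heel strike, so ground-truth heel strikes coincide with load onset by
#' construction, and the ground-truth phase is linear in time within each
#' stride (quantized to the 0.5% grid).
#'
#' @param mode `"LGW"` or `"SA"`.
#' @param n_strides Number of strides (>= 1).
#' @param noise A [noise_spec()]; [zero_noise()] gives identical strides.
#' @param seed Integer seed (one seed controls the whole session), or `NULL`
#'   to use the ambient RNG state.
#' @param rate Sampling rate (Hz).
#' @return A list of class `gait_session`: `series` (a `gait_series`),
#'   `phase` (ground-truth phase percentages, 0.5% grid, all samples
#'   labeled), `heel_strikes` (1-based stride-start indices) and `mode`.
#' @export
generate_session <- function(mode = c("LGW", "SA"), n_strides,
                             noise = noise_spec(), seed = NULL, rate = 200) {
  mode <- match.arg(mode)
  if (n_strides < 1L) stop("n_strides must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  tpl <- stride_template(mode)
  ch <- c("fz", "thigh", "knee", "ankle")
  dur_z <- pmin(pmax(stats::rnorm(n_strides), -2.5), 2.5)
  amp_z <- pmin(pmax(stats::rnorm(n_strides), -2.5), 2.5)
  n_i <- pmax(4L, as.integer(round(
    tpl$stride_s * (1 + noise$cadence_cv * dur_z) * rate)))
  heel_strikes <- cumsum(c(1L, n_i[-n_strides]))
  chunks <- vector("list", n_strides)
  phase_chunks <- vector("list", n_strides)
  for (i in seq_len(n_strides)) {
    phi <- (seq_len(n_i[i]) - 1L) / n_i[i]
    m <- eval_template(tpl, phi)
    a <- 1 + noise$amplitude_cv * amp_z[i]
    m[, "fz"] <- a * m[, "fz"]
    for (cc in c("thigh", "knee", "ankle")) {
      mu <- tpl$angles[[cc]]$a0
      m[, cc] <- mu + a * (m[, cc] - mu)
    }
    chunks[[i]] <- m
    phase_chunks[[i]] <- quantize_phase(100 * phi)
  }
  m <- do.call(rbind, chunks)
  n <- nrow(m)
  for (cc in ch) {
    sdv <- noise$sensor_sd[[cc]]
    if (sdv > 0) m[, cc] <- m[, cc] + stats::rnorm(n, 0, sdv)
  }
  m[, "fz"] <- pmax(m[, "fz"], 0)
  series <- gait_series(fz = m[, "fz"], thigh = m[, "thigh"],
                        knee = m[, "knee"], ankle = m[, "ankle"],
                        rate = rate)
  structure(list(series = series, phase = unlist(phase_chunks),
                 heel_strikes = heel_strikes, mode = mode),
            class = "gait_session")
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf("<gait_session: %s, %d strides, %d samples at %g Hz>\n",
              x$mode, length(x$heel_strikes), nrow(x$series),
              series_rate(x$series)))
  invisible(x)
}

#' Emulate a different sensor configuration
#'
#' Measuring the same gait with motion capture versus goniometers yields
#' joint-angle records that differ by several degrees RMS (soft-tissue
#' artifact, mounting, axis alignment). This applies a smooth per-channel
#' angle offset process — a bounded constant plus a slow sinusoidal wander —
#' with RMS near `noise$variant_sd`, plus a small white measurement noise.
#' The load channel is untouched. Zero variant SDs return the series
#' unchanged.
#'
#' @param series A `gait_series`.
#' @param variant `"mocap"` or `"goniometer"`; selects an independent offset
#'   realization (the two variants of one session differ from each other as
#'   well as from the reference).
#' @param noise A [noise_spec()]; uses `variant_sd`.
#' @param seed Optional seed.
#' @return The perturbed `gait_series`.
#' @export
make_variant <- function(series, variant = c("mocap", "goniometer"),
                         noise = noise_spec(), seed = NULL) {
  variant <- match.arg(variant)
  if (!is.null(seed)) set.seed(seed + 7L * match(variant, c("mocap",
                                                            "goniometer")))
  n <- nrow(series)
  tt <- series$time
  for (cc in c("thigh", "knee", "ankle")) {
    sdv <- noise$variant_sd[[cc]]
    if (sdv == 0) next
    z0 <- pmin(pmax(stats::rnorm(1L), -1.8), 1.8)
    f <- stats::runif(1L, 0.05, 0.2)
    psi <- stats::runif(1L, 0, 2 * pi)
    offset <- sdv * (sqrt(0.4) * z0 +
                     sqrt(0.6) * sqrt(2) * sin(2 * pi * f * tt + psi))
    series[[cc]] <- series[[cc]] + offset + stats::rnorm(n, 0, 0.3)
  }
  series
}

#' Emulate a state-machine prosthetic ankle
#'
#' Powered-prosthesis stance ankle trajectories under impedance control are
#' far flatter than the biological ankle, especially the mid-to-late-stance
#' push-off excursion. This attenuates the ankle excursion about its stance
#' mean, per stance period, by `flatten_ankle`: 0 leaves the series
#' unchanged, 1 holds the stance ankle constant at its mean. Stance periods
#' are taken as contiguous runs with load above 0.05 BW.
#'
#' @param series A `gait_series`.
#' @param flatten_ankle Flattening factor in `[0, 1]`.
#' @return The modified `gait_series`.
#' @export
make_prosthesis_like <- function(series, flatten_ankle) {
  if (!is.numeric(flatten_ankle) || length(flatten_ankle) != 1L ||
      is.na(flatten_ankle) || flatten_ankle < 0 || flatten_ankle > 1)
    stop("'flatten_ankle' must be a single value in [0, 1]")
  if (flatten_ankle == 0) return(series)
  stance <- series$fz > 0.05
  r <- rle(stance)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    idx <- starts[i]:ends[i]
    m <- mean(series$ankle[idx])
    series$ankle[idx] <- m + (1 - flatten_ankle) * (series$ankle[idx] - m)
  }
  series
}
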