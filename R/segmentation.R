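#' Parameters for the streaming stance/swing segmenter
#'
#' The segmenter is a streaming peak-detection scheme on the vertical load: a
#' short ring buffer of smoothed load values tracks the slow trend, and each
#' incoming sample is labeled stance either when it exceeds the hard load
#' threshold `f_th` or when it is rising relative to the smoothed trend.
#'
#' @param f_th Load threshold in BW above which a sample is always stance.
#'   The default 0.2 BW matches the stance-to-swing transition load used by
#'   state-machine prosthesis controllers.
#' @param lag Length of the smoothed ring buffer (samples).
#' @param influence Weight of a new sample in the smoothed buffer update.
#' @param p_hist Minimum persistence (samples): label runs of `p_hist` or
#'   fewer samples are treated as spurious and merged away by [refine()].
#'   At 200 Hz the default 5 ignores phase changes shorter than 25 ms.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(f_th = 0.2, lag = 8L, influence = 0.01,
                                p_hist = 5L) {
  stopifnot(f_th > 0, f_th < 1, lag >= 1, influence >= 0, influence <= 1,
            p_hist >= 1)
  structure(list(f_th = f_th, lag = as.integer(lag), influence = influence,
                 p_hist = as.integer(p_hist)),
            class = "segmentation_params")
}

#' Initial segmenter state
#'
#' The smoothed ring buffer starts at all zeros, matching a subject standing
#' on the contralateral leg (no load) before the first step.
#'
#' @param params A [segmentation_params()] object.
#' @return Numeric vector of length `lag` (all zeros).
#' @export
segmentation_state <- function(params = segmentation_params()) {
  rep(0, params$lag)
}

## Equality of the incoming sample with the buffer mean is compared with an
## absolute tolerance: during true swing both are exactly 0 and the branch
## keeps appending the raw sample, but exact floating equality is fragile.
.seg_eq_tol <- 1e-9

#' One step of the streaming stance/swing segmenter
#'
#' Processes a single vertical-load sample. The sample is clamped to
#' \[0, 1\] BW; if it equals the mean of the smoothed buffer the sample is
#' swing and the raw value is appended to the buffer, otherwise the sample is
#' stance when above `f_th` or when at or above the buffer mean (load rising),
#' and the buffer is appended with the smoothed update
#' `influence * f_z + (1 - influence) * previous`.
#'
#' @param f_z One vertical-load sample (BW).
#' @param state Smoothed ring buffer (numeric, length `lag`); see
#'   [segmentation_state()].
#' @param params A [segmentation_params()] object.
#' @return List with `label` (0 swing, 1 stance) and the updated `state`.
#' @seealso [extract_phases()] for whole-series labeling.
#' @export
segment_step <- function(f_z, state, params = segmentation_params()) {
  if (length(state) != params$lag)
    stop("state length must equal params$lag")
  f_z <- min(max(f_z, 0), 1)
  m <- mean(state)
  state <- c(state[-1L], 0)          # shift; last slot filled below
  lag <- params$lag
  if (abs(f_z - m) < .seg_eq_tol) {
    label <- 0L
    state[lag] <- f_z
  } else {
    if (f_z > params$f_th) {
      label <- 1L
    } else if (f_z >= m) {           # load rising toward foot contact
      label <- 1L
    } else {
      label <- 0L
    }
    state[lag] <- params$influence * f_z +
      (1 - params$influence) * state[lag - 1L]
  }
  list(label = label, state = state)
}

#' Extract stance/swing labels from a vertical-load series
#'
#' Runs [segment_step()] over every sample (buffer initialized to zeros) and
#' then [refine()]s the raw labels to remove spurious short phase changes.
#'
#' @param load Numeric vector of weight-normalized vertical load (BW), or a
#'   `gait_series` whose `fz` column is used.
#' @param params A [segmentation_params()] object.
#' @param refine Apply the persistence refinement (default `TRUE`).
#' @return Integer vector of per-sample labels (0 swing, 1 stance), same
#'   length as the input.
#' @export
extract_phases <- function(load, params = segmentation_params(),
                           refine = TRUE) {
  if (inherits(load, "gait_series")) load <- load$fz
  n <- length(load)
  if (n == 0L) stop("empty load series")
  lag <- params$lag
  influence <- params$influence
  f_th <- params$f_th
  buf <- rep(0, lag)
  out <- integer(n)
  ## inlined segment_step for speed; running sum replaces mean()
  s <- 0
  for (t in seq_len(n)) {
    f <- load[t]
    if (f < 0) f <- 0 else if (f > 1) f <- 1
    m <- s / lag
    old <- buf[1L]
    if (abs(f - m) < .seg_eq_tol) {
      out[t] <- 0L
      newv <- f
    } else {
      out[t] <- if (f > f_th) 1L else if (f >= m) 1L else 0L
      newv <- influence * f + (1 - influence) * buf[lag]
    }
    buf <- c(buf[-1L], newv)
    s <- s - old + newv
  }
  if (refine) out <- refine(out, params$p_hist)
  out
}

#' Merge spurious short label runs
#'
#' Post-refinement of raw stance/swing labels: walking through the series, a
#' label change whose preceding run lasted `p_hist` samples or fewer is
#' treated as sensor interference — the short run is overwritten with the
#' incoming label and fuses with the following run. The final run is flushed
#' with its own label so the output is fully labeled. Idempotent.
#'
#' @param raw Integer vector of labels in `{0, 1}`.
#' @param p_hist Persistence threshold (samples); default from
#'   [segmentation_params()].
#' @return Refined label vector, same length.
#' @export
refine <- function(raw, p_hist = segmentation_params()$p_hist) {
  n <- length(raw)
  if (n == 0L) return(integer(0L))
  if (!all(raw %in% c(0L, 1L))) stop("labels must be 0 or 1")
  p_re <- rep(-1L, n)
  p_past <- raw[1L]
  count <- 0L
  idx_bgn <- 1L
  for (t in seq_len(n)) {
    p_current <- raw[t]
    if (p_current != p_past) {
      idx_fin <- t - 1L
      if (count > p_hist) {
        p_re[idx_bgn:idx_fin] <- p_past
        idx_bgn <- t
        count <- 1L
      } else {
        ## short run: absorb it into the incoming label, keep idx_bgn
        p_re[idx_bgn:idx_fin] <- p_current
        count <- count + 1L
      }
    } else {
      count <- count + 1L
    }
    p_past <- p_current
  }
  p_re[idx_bgn:n] <- p_past    # flush trailing run
  p_re
}

#' Heel-strike indices from refined stance/swing labels
#'
#' A heel strike is foot-ground initial contact, detected as a swing-to-stance
#' (0 to 1) label transition; it defines 0% of the gait cycle.
#'
#' @param refined Integer vector of labels in `{0, 1}`.
#' @return Strictly increasing integer vector of 1-based sample indices of
#'   the first stance sample of each step; possibly empty.
#' @export
find_heel_strikes <- function(refined) {
  n <- length(refined)
  if (n < 2L) return(integer(0L))
  if (!all(refined %in% c(0L, 1L))) stop("labels must be 0 or 1")
  which(refined[-1L] == 1L & refined[-n] == 0L) + 1L
}
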