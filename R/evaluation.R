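#' Coefficient of determination in polar phase space
#'
#' Standard `1 - SS_res/SS_tot`, computed per scaled polar component
#' (`px'`, `py'`) and averaged. Operating in polar space avoids the
#' 100%-to-0% wrap that would wreck a naive R-squared on percentages.
#'
#' A component whose targets have zero variance has no defined R-squared; it
#' is reported as `NA` and dropped from the mean (an error is raised only
#' when both components are degenerate).
#'
#' @param actual,predicted N x 2 matrices of (scaled) polar phase pairs.
#' @return List with `px`, `py` (per-component R-squared) and `mean`.
#' @export
r_squared <- function(actual, predicted) {
  actual <- as.matrix(actual); predicted <- as.matrix(predicted)
  if (!all(dim(actual) == dim(predicted)))
    stop("actual and predicted must have the same shape")
  if (nrow(actual) < 2L) stop("need at least 2 observations")
  comp <- function(j) {
    ss_tot <- sum((actual[, j] - mean(actual[, j]))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - sum((actual[, j] - predicted[, j])^2) / ss_tot
  }
  out <- list(px = comp(1L), py = comp(2L))
  if (all(is.na(c(out$px, out$py))))
    stop("zero target variance; R-squared undefined")
  out$mean <- mean(c(out$px, out$py), na.rm = TRUE)
  out
}

#' Summary statistics of the circular phase error
#'
#' Per-sample circular error ([circular_error()]) over all samples where both
#' series carry a label (sentinel `NA` excluded), summarized by mean, median
#' and the 25th/75th percentiles.
#'
#' @param actual,predicted Phase-percentage vectors (with `NA` sentinels),
#'   aligned sample-by-sample.
#' @return List with `n`, `mean`, `median`, `q25`, `q75` (percent of cycle).
#' @export
phase_error_summary <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("actual and predicted must be aligned (same length)")
  ok <- !is.na(actual) & !is.na(predicted)
  if (!any(ok)) stop("no overlapping labeled samples")
  err <- circular_error(actual[ok], predicted[ok])
  q <- stats::quantile(err, c(0.25, 0.5, 0.75), names = FALSE)
  list(n = sum(ok), mean = mean(err), median = q[2L], q25 = q[1L],
       q75 = q[3L])
}

#' Median stride trajectory on a common phase grid
#'
#' Each complete stride (between consecutive heel strikes) is time-normalized
#' to 101 phase points (0, 1, ..., 100% of the cycle) by linear
#' interpolation; the pointwise median and 25th/75th percentiles are taken
#' across strides per channel.
#'
#' @param series A `gait_series`.
#' @param heel_strikes 1-based heel-strike indices (need at least 2, i.e. one
#'   complete stride).
#' @param n_points Number of phase grid points (default 101).
#' @return List of class `median_trajectory` with `phase` (grid, percent) and
#'   per-channel matrices `median`, `q25`, `q75` (n_points x 4, columns
#'   fz/thigh/knee/ankle), plus `n_strides`.
#' @export
median_trajectory <- function(series, heel_strikes, n_points = 101L) {
  ch <- c("fz", "thigh", "knee", "ankle")
  k <- length(heel_strikes)
  if (k < 2L) stop("need at least one complete stride (2 heel strikes)")
  grid <- seq(0, 100, length.out = n_points)
  n_str <- k - 1L
  arr <- array(NA_real_, dim = c(n_points, 4L, n_str),
               dimnames = list(NULL, ch, NULL))
  for (i in seq_len(n_str)) {
    idx <- heel_strikes[i]:heel_strikes[i + 1L]
    ph <- 100 * (idx - idx[1L]) / (idx[length(idx)] - idx[1L])
    for (j in seq_along(ch))
      arr[, j, i] <- stats::approx(ph, series[[ch[j]]][idx], xout = grid)$y
  }
  qs <- apply(arr, c(1L, 2L), stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  structure(list(phase = grid,
                 median = qs[2L, , ], q25 = qs[1L, , ], q75 = qs[3L, , ],
                 n_strides = n_str),
            class = "median_trajectory")
}

#' @export
plot.median_trajectory <- function(x, channels = c("fz", "thigh", "knee",
                                                   "ankle"), ...) {
  old <- graphics::par(mfrow = c(length(channels), 1L),
                       mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  for (ch in channels) {
    ylab <- if (ch == "fz") "load [BW]" else paste0(ch, " [deg]")
    ylim <- range(x$q25[, ch], x$q75[, ch])
    graphics::plot(x$phase, x$median[, ch], type = "n", xlab = "phase [%]",
                   ylab = ylab, ylim = ylim, ...)
    graphics::polygon(c(x$phase, rev(x$phase)),
                      c(x$q25[, ch], rev(x$q75[, ch])),
                      col = "grey85", border = NA)
    graphics::lines(x$phase, x$median[, ch])
  }
  invisible(x)
}

#' Pearson correlation between two median stride trajectories
#'
#' The similarity measure used to compare gait records across datasets,
#' devices, or against a template: the standard Pearson r per channel over
#' the common phase grid.
#'
#' @param a,b `median_trajectory` objects (or n x 4 matrices) on the same
#'   grid.
#' @return Named numeric vector of correlations (fz, thigh, knee, ankle).
#' @export
pearson_median_correlation <- function(a, b) {
  ma <- if (inherits(a, "median_trajectory")) a$median else as.matrix(a)
  mb <- if (inherits(b, "median_trajectory")) b$median else as.matrix(b)
  if (!all(dim(ma) == dim(mb)))
    stop("trajectories must share the same grid and channels")
  out <- vapply(seq_len(ncol(ma)), function(j) {
    if (stats::sd(ma[, j]) == 0 || stats::sd(mb[, j]) == 0)
      stop("zero variance in a channel; correlation undefined")
    stats::cor(ma[, j], mb[, j])
  }, numeric(1))
  names(out) <- colnames(ma)
  if (is.null(names(out)) || any(names(out) == ""))
    names(out) <- c("fz", "thigh", "knee", "ankle")[seq_along(out)]
  out
}

#' Full evaluation report for a set of predictions
#'
#' Bundles the polar-space R-squared and the circular-error summary, with an
#' optional per-mode breakdown.
#'
#' @param actual,predicted Phase-percentage vectors with `NA` sentinels.
#' @param mode Optional per-sample mode factor (e.g. `"LGW"`/`"SA"`) for the
#'   breakdown.
#' @return A list of class `gait_eval` with `r2` (px/py/mean), `error`
#'   (mean/median/q25/q75), `n`, and `by_mode` when `mode` is given.
#' @export
evaluate_predictions <- function(actual, predicted, mode = NULL) {
  ok <- !is.na(actual) & !is.na(predicted)
  if (!any(ok)) stop("no overlapping labeled samples")
  pol_a <- scale_phase(to_polar(actual[ok]))
  pol_p <- scale_phase(to_polar(predicted[ok]))
  rep_one <- function(a, p, pa, pp)
    list(r2 = r_squared(pa, pp), error = phase_error_summary(a, p))
  out <- rep_one(actual[ok], predicted[ok], pol_a, pol_p)
  out$n <- sum(ok)
  if (!is.null(mode)) {
    mode_ok <- mode[ok]
    out$by_mode <- lapply(split(seq_along(mode_ok), mode_ok), function(i)
      rep_one(actual[ok][i], predicted[ok][i], pol_a[i, , drop = FALSE],
              pol_p[i, , drop = FALSE]))
  }
  class(out) <- "gait_eval"
  out
}

#' @export
print.gait_eval <- function(x, ...) {
  cat("<gait_eval>\n")
  cat(sprintf("  n samples      : %d\n", x$n))
  cat(sprintf("  R2 (px, py)    : %.4f, %.4f  (mean %.4f)\n",
              x$r2$px, x$r2$py, x$r2$mean))
  cat(sprintf("  circular error : mean %.2f%%, median %.2f%% [IQR %.2f-%.2f]\n",
              x$error$mean, x$error$median, x$error$q25, x$error$q75))
  for (m in names(x$by_mode))
    cat(sprintf("  %-4s           : R2 %.4f, mean error %.2f%%\n", m,
                x$by_mode[[m]]$r2$mean, x$by_mode[[m]]$error$mean))
  invisible(x)
}

#' Write an evaluation report to JSON and flat CSV
#'
#' @param report A `gait_eval` from [evaluate_predictions()].
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a flat data frame of the report values.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL) {
  flat <- data.frame(
    metric = c("n", "r2_px", "r2_py", "r2_mean", "err_mean", "err_median",
               "err_q25", "err_q75"),
    value = c(report$n, report$r2$px, report$r2$py, report$r2$mean,
              report$error$mean, report$error$median, report$error$q25,
              report$error$q75))
  for (m in names(report$by_mode)) {
    bm <- report$by_mode[[m]]
    flat <- rbind(flat, data.frame(
      metric = paste0(m, c("_r2_mean", "_err_mean")),
      value = c(bm$r2$mean, bm$error$mean)))
  }
  if (!is.null(json_path)) {
    payload <- unclass(report)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path))
    utils::write.csv(flat, csv_path, row.names = FALSE, quote = FALSE)
  invisible(flat)
}
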