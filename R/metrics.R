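#' Time-domain sway metrics
#'
#' The sixteen classical time-domain measures of center-of-pressure sway,
#' computed on a filtered COP segment (a quiet-standing analysis window).
#' Following the standard taxonomy, path measures (velocity, acceleration)
#' quantify the regulatory activity of the postural control system, extension
#' measures (range, RMS distance, sway area, 95% confidence ellipse area)
#' quantify how far the COP strays from its mean, and the hybrid frequency
#' measures express path length relative to extension as the frequency of an
#' equivalent circular (overall) or sinusoidal (directional) motion.
#'
#' All functions take a segment: a data frame with numeric columns `ml_mm` and
#' `cc_mm` (COP coordinates in mm), plus the sampling rate `fs` in Hz (taken
#' from an `fs_hz` column when present). The elapsed duration of an N-sample
#' segment is `T = (N - 1) / fs`, the time actually spanned by the samples.
#'
#' @name sway-metrics
#' @param segment Data frame with columns `ml_mm`, `cc_mm` (and optionally
#'   `fs_hz`).
#' @param fs Sampling rate in Hz; defaults to the segment's `fs_hz` column.
NULL

segment_fs <- function(segment, fs) {
  if (!is.null(fs)) return(fs)
  if ("fs_hz" %in% names(segment)) return(segment$fs_hz[1])
  abort("sampling rate unknown: supply `fs` or an `fs_hz` column")
}

check_segment <- function(segment, min_n = 1L) {
  stopifnot(is.data.frame(segment), all(c("ml_mm", "cc_mm") %in% names(segment)))
  if (nrow(segment) < min_n) {
    abort(sprintf("segment must have at least %d samples, got %d", min_n,
                  nrow(segment)))
  }
  invisible(segment)
}

#' @describeIn sway-metrics Arithmetic mean COP position `(ml, cc)` in mm.
#' @export
mean_cop <- function(segment) {
  check_segment(segment, 1L)
  c(ml = mean(segment$ml_mm), cc = mean(segment$cc_mm))
}

#' @describeIn sway-metrics Resultant distance (RD) series: per-sample
#'   Euclidean distance from the mean COP, in mm.
#' @export
resultant_distances <- function(segment) {
  check_segment(segment, 1L)
  m <- mean_cop(segment)
  sqrt((segment$ml_mm - m[["ml"]])^2 + (segment$cc_mm - m[["cc"]])^2)
}

#' @describeIn sway-metrics Mean velocities `(vel_cc, vel_ml, vel_ov)` in
#'   mm/s: per-axis path length over elapsed time, and overall (vector) path
#'   length over elapsed time.
#' @export
velocity_metrics <- function(segment, fs = NULL) {
  check_segment(segment, 2L)
  fs <- segment_fs(segment, fs)
  t_elapsed <- (nrow(segment) - 1) / fs
  d_ml <- diff(segment$ml_mm)
  d_cc <- diff(segment$cc_mm)
  c(vel_cc = sum(abs(d_cc)) / t_elapsed,
    vel_ml = sum(abs(d_ml)) / t_elapsed,
    vel_ov = sum(sqrt(d_ml^2 + d_cc^2)) / t_elapsed)
}

#' @describeIn sway-metrics Mean absolute accelerations `(acc_cc, acc_ml,
#'   acc_ov)` in mm/s^2. Per axis: mean absolute change of the signed
#'   frame-to-frame velocity (absolute values, so decelerations do not cancel
#'   accelerations). Overall: mean absolute change of the scalar speed.
#' @export
acceleration_metrics <- function(segment, fs = NULL) {
  check_segment(segment, 3L)
  fs <- segment_fs(segment, fs)
  v_cc <- diff(segment$cc_mm) * fs
  v_ml <- diff(segment$ml_mm) * fs
  speed <- sqrt(diff(segment$ml_mm)^2 + diff(segment$cc_mm)^2) * fs
  c(acc_cc = mean(abs(diff(v_cc))) * fs,
    acc_ml = mean(abs(diff(v_ml))) * fs,
    acc_ov = mean(abs(diff(speed))) * fs)
}

#' @describeIn sway-metrics Per-axis ranges `(range_cc, range_ml)`: maximal
#'   excursion (max - min) in mm.
#' @export
range_metrics <- function(segment) {
  check_segment(segment, 1L)
  c(range_cc = diff(range(segment$cc_mm)),
    range_ml = diff(range(segment$ml_mm)))
}

#' @describeIn sway-metrics RMS distances `(rms_cc, rms_ml, rms_ov)` in mm.
#'   Per axis: the population (divide-by-N) standard deviation; overall: the
#'   RMS of the resultant-distance series. Under the population convention the
#'   identity `rms_ov^2 = rms_cc^2 + rms_ml^2` holds exactly.
#' @export
rms_metrics <- function(segment) {
  check_segment(segment, 1L)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  rd <- resultant_distances(segment)
  c(rms_cc = pop_sd(segment$cc_mm),
    rms_ml = pop_sd(segment$ml_mm),
    rms_ov = sqrt(mean(rd^2)))
}

#' @describeIn sway-metrics Sway area in mm^2/s: total area of the triangles
#'   spanned by consecutive COP samples and the mean COP, per second of
#'   elapsed time (the area swept around the mean COP per second).
#' @export
sway_area <- function(segment, fs = NULL) {
  check_segment(segment, 2L)
  fs <- segment_fs(segment, fs)
  t_elapsed <- (nrow(segment) - 1) / fs
  m <- mean_cop(segment)
  x <- segment$ml_mm - m[["ml"]]
  y <- segment$cc_mm - m[["cc"]]
  n <- length(x)
  cross <- x[-n] * y[-1] - x[-1] * y[-n]
  sum(0.5 * abs(cross)) / t_elapsed
}

#' @describeIn sway-metrics 95% confidence ellipse area in mm^2: area of the
#'   ellipse expected to contain 95% of the COP samples under a bivariate
#'   normal model, `2 * pi * F95(2, N - 2) * sqrt(det(S))` with `S` the sample
#'   (divide-by-(N-1)) covariance of the coordinates.
#' @export
ellipse95_area <- function(segment) {
  check_segment(segment, 4L)
  n <- nrow(segment)
  s_cc <- var(segment$cc_mm)
  s_ml <- var(segment$ml_mm)
  s_cm <- cov(segment$cc_mm, segment$ml_mm)
  disc <- s_cc * s_ml - s_cm^2
  if (disc < 0) disc <- 0  # numerically negative only for degenerate segments
  2 * pi * qf(0.95, 2, n - 2) * sqrt(disc)
}

#' @describeIn sway-metrics Frequency revolve `(freq_cc, freq_ml, freq_ov)` in
#'   Hz. Overall: the rotational frequency of a circular motion with radius
#'   equal to the mean resultant distance and the segment's overall path
#'   speed, `vel_ov / (2 * pi * mean(RD))`. Directional: the frequency of a
#'   sinusoid with mean absolute value equal to the axis' mean absolute
#'   deviation and the axis' path speed, `vel_axis / (4 * sqrt(2) *
#'   mean(|dev|))`. Undefined (returned as `NA`) when the corresponding mean
#'   distance is zero (no motion), never reported as 0.
#' @export
frequency_metrics <- function(segment, fs = NULL) {
  check_segment(segment, 2L)
  fs <- segment_fs(segment, fs)
  vel <- velocity_metrics(segment, fs)
  rd_mean <- mean(resultant_distances(segment))
  m <- mean_cop(segment)
  mad_cc <- mean(abs(segment$cc_mm - m[["cc"]]))
  mad_ml <- mean(abs(segment$ml_mm - m[["ml"]]))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  c(freq_cc = safe_div(vel[["vel_cc"]], 4 * sqrt(2) * mad_cc),
    freq_ml = safe_div(vel[["vel_ml"]], 4 * sqrt(2) * mad_ml),
    freq_ov = safe_div(vel[["vel_ov"]], 2 * pi * rd_mean))
}

#' Compute all sixteen sway metrics of one window
#'
#' Bundles the individual measure functions of [sway-metrics] into a one-row
#' tibble in the canonical column order of [sway_metric_names()].
#'
#' @inheritParams sway-metrics
#' @return One-row tibble with the 16 metric columns plus `n_samples`.
#' @export
compute_sway_metrics <- function(segment, fs = NULL) {
  check_segment(segment, 4L)
  fs <- segment_fs(segment, fs)
  vals <- c(velocity_metrics(segment, fs),
            acceleration_metrics(segment, fs),
            range_metrics(segment),
            rms_metrics(segment),
            sway_area = sway_area(segment, fs),
            ellipse95 = ellipse95_area(segment),
            frequency_metrics(segment, fs))
  out <- tibble::as_tibble(as.list(vals[sway_metric_names()]))
  out$n_samples <- nrow(segment)
  out
}

#' Average per-window metrics into one value per dog
#'
#' Arithmetic mean per metric across windows. Frequency measures that are
#' undefined (`NA`, zero motion) in some windows are averaged over the defined
#' windows only and stay `NA` if undefined everywhere; all other metrics are
#' required to be complete.
#'
#' @param window_metrics Tibble of per-window metric rows (16 metric columns).
#' @return One-row tibble of averaged metrics plus `n_windows_used`.
#' @export
aggregate_windows <- function(window_metrics) {
  if (nrow(window_metrics) == 0L) abort("no windows to aggregate")
  freq_cols <- c("freq_cc", "freq_ml", "freq_ov")
  hard_cols <- setdiff(sway_metric_names(), freq_cols)
  if (any(is.na(window_metrics[hard_cols]))) {
    abort("non-frequency metrics must be complete in every window")
  }
  out <- dplyr::summarise(
    window_metrics,
    dplyr::across(dplyr::all_of(hard_cols), mean),
    dplyr::across(dplyr::all_of(freq_cols), ~ {
      v <- .x[!is.na(.x)]
      if (length(v) == 0L) NA_real_ else mean(v)
    })
  )
  out <- out[sway_metric_names()]
  out$n_windows_used <- nrow(window_metrics)
  out
}
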