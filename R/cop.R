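#' Center of pressure of a single pressure frame
#'
#' The COP is the pressure-weighted centroid of the sensel grid. Sensel centers
#' sit at `(col * pitch_mm, row * pitch_mm)` with the origin at the first
#' sensel center; the column axis is mediolateral (ML), the row axis
#' craniocaudal (CC). Frames whose total pressure falls below
#' `min_total_pressure` carry no usable stance signal (the dog is off the mat
#' or mid-step) and are flagged invalid rather than raising an error.
#'
#' @param frame Numeric matrix of non-negative pressures.
#' @param pitch_mm Sensel pitch in mm.
#' @param min_total_pressure Minimum total frame pressure for a valid COP.
#' @return A named list: `ml_mm`, `cc_mm`, `valid`. Coordinates are `NA` when
#'   invalid.
#' @export
compute_cop <- function(frame, pitch_mm, min_total_pressure = 0) {
  if (any(frame < 0)) {
    abort("frame pressures must be non-negative", class = "caninesway_validation_error")
  }
  total <- sum(frame)
  if (total < min_total_pressure || total <= 0) {
    return(list(ml_mm = NA_real_, cc_mm = NA_real_, valid = FALSE))
  }
  nr <- nrow(frame); nc <- ncol(frame)
  col_mass <- colSums(frame)
  row_mass <- rowSums(frame)
  ml <- sum(col_mass * (seq_len(nc) - 1)) / total * pitch_mm
  cc <- sum(row_mass * (seq_len(nr) - 1)) / total * pitch_mm
  list(ml_mm = ml, cc_mm = cc, valid = TRUE)
}

#' Extract the COP trajectory of a recording
#'
#' Applies [compute_cop()] to every frame, in order.
#'
#' @param recording A [pressure_recording()].
#' @param min_total_pressure Validity threshold passed to [compute_cop()]. The
#'   default, 1% of the median total frame pressure of the recording, rejects
#'   near-empty noise frames while being insensitive to calibration units.
#' @param dog_id Optional subject id carried into the output.
#' @return A tibble (one row per frame): `dog_id`, `trial_id`, `frame`
#'   (0-based), `ml_mm`, `cc_mm`, `valid`, `fs_hz`.
#' @export
extract_cop_series <- function(recording, min_total_pressure = NULL,
                               dog_id = NA_character_) {
  if (!inherits(recording, "pressure_recording")) {
    abort("`recording` must be a pressure_recording.")
  }
  n <- length(recording$frames)
  if (n == 0L) abort("recording has no frames")
  if (is.null(min_total_pressure)) {
    min_total_pressure <- 0.01 * median(vapply(recording$frames, sum, numeric(1)))
  }
  cops <- lapply(recording$frames, compute_cop, pitch_mm = recording$pitch_mm,
                 min_total_pressure = min_total_pressure)
  tibble::tibble(
    dog_id = dog_id,
    trial_id = recording$trial_id,
    frame = seq_len(n) - 1L,
    ml_mm = vapply(cops, `[[`, numeric(1), "ml_mm"),
    cc_mm = vapply(cops, `[[`, numeric(1), "cc_mm"),
    valid = vapply(cops, `[[`, logical(1), "valid"),
    fs_hz = recording$fs_hz
  )
}

# Single IIR pass y = filter(b, a, x) with virtual steady-state history at
# level x0 (so a constant input at x0 passes through exactly, DC gain 1).
iir_pass <- function(b, a, x, x0) {
  nb <- length(b)
  xp <- c(rep(x0, nb - 1L), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v[-seq_len(nb - 1L)])
  as.numeric(stats::filter(v, -a[-1], method = "recursive",
                           init = rep(x0, length(a) - 1L)))
}

# Zero-phase forward-backward IIR application with odd-reflection padding and
# steady-state edge initialization, so a constant input is reproduced exactly
# and features are not time-shifted. (signal::filtfilt starts from zero state,
# which leaves a start-up transient on short stance segments.)
filtfilt_zerophase <- function(b, a, x) {
  n_coef <- max(length(a), length(b))
  nfact <- 3L * (n_coef - 1L)
  if (length(x) <= nfact) {
    abort(sprintf("series too short to filter: need at least %d samples, got %d",
                  nfact + 1L, length(x)),
          class = "caninesway_length_error")
  }
  b <- c(b, rep(0, n_coef - length(b)))
  a <- c(a, rep(0, n_coef - length(a)))
  n <- length(x)
  ext <- c(2 * x[1] - x[(nfact + 1L):2L], x,
           2 * x[n] - x[(n - 1L):(n - nfact)])
  y <- iir_pass(b, a, ext, ext[1])
  y <- rev(iir_pass(b, a, rev(y), y[length(y)]))
  y[(nfact + 1L):(nfact + n)]
}

#' Low-pass filter a COP series
#'
#' Applies a 4th-order Butterworth low-pass filter (default cutoff 5 Hz)
#' forward and backward (zero phase) to both COP coordinates. Quiet-standing
#' sway lives well below 5 Hz; the filter strips sensor noise that would
#' otherwise inflate the velocity and acceleration measures.
#'
#' @param series COP tibble from [extract_cop_series()] (columns `ml_mm`,
#'   `cc_mm`, `valid`, `fs_hz`); may span several trials (`trial_id` groups are
#'   filtered independently).
#' @param cutoff_hz Cutoff frequency in Hz.
#' @param order Butterworth order (the filter is applied twice, so the
#'   effective attenuation is that of twice this order).
#' @return The series with `ml_mm`, `cc_mm` replaced by filtered values.
#' @export
lowpass_filter <- function(series, cutoff_hz = 5, order = 4) {
  stopifnot(all(c("ml_mm", "cc_mm", "fs_hz") %in% names(series)))
  if (any(!series$valid)) {
    abort("cannot filter a series with invalid samples; drop or impute them first",
          class = "caninesway_validation_error")
  }
  series |>
    dplyr::group_by(dplyr::across(dplyr::any_of(c("dog_id", "trial_id")))) |>
    dplyr::group_modify(function(df, key) {
      fs <- df$fs_hz[1]
      bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
      df$ml_mm <- filtfilt_zerophase(bf$b, bf$a, df$ml_mm)
      df$cc_mm <- filtfilt_zerophase(bf$b, bf$a, df$cc_mm)
      df
    }) |>
    dplyr::ungroup()
}
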