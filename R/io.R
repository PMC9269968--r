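#' Construct a pressure-mat recording
#'
#' A `pressure_recording` bundles the ordered pressure frames of one trial with
#' the mat geometry (sensel pitch) and the sampling rate. Frames are matrices of
#' non-negative pressures in arbitrary (calibration-dependent) units; rows run
#' along the craniocaudal (CC) axis, columns along the mediolateral (ML) axis.
#'
#' @param trial_id Single string identifying the trial.
#' @param frames List of numeric matrices, all the same dimension, pressures
#'   `>= 0`.
#' @param pitch_mm Sensel pitch in mm (same in both axes), `> 0`.
#' @param fs_hz Sampling rate in frames per second, `> 0`. The pressure mat
#'   protocol this package targets samples at 67 frames/s.
#' @return An object of class `pressure_recording`.
#' @export
pressure_recording <- function(trial_id, frames, pitch_mm, fs_hz = 67) {
  if (!is.character(trial_id) || length(trial_id) != 1L || is.na(trial_id)) {
    abort("`trial_id` must be a single non-missing string.")
  }
  if (!is.list(frames) || length(frames) == 0L) {
    abort("`frames` must be a non-empty list of matrices.")
  }
  dims <- vapply(frames, function(f) {
    if (!is.matrix(f) || !is.numeric(f)) {
      abort("every frame must be a numeric matrix")
    }
    dim(f)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("all frames must share the same shape", class = "caninesway_validation_error")
  }
  if (any(vapply(frames, function(f) any(!is.finite(f)) || any(f < 0), logical(1)))) {
    abort("pressures must be finite and non-negative",
          class = "caninesway_validation_error")
  }
  if (!is.numeric(pitch_mm) || length(pitch_mm) != 1L || pitch_mm <= 0) {
    abort("`pitch_mm` must be a single positive number.")
  }
  if (!is.numeric(fs_hz) || length(fs_hz) != 1L || fs_hz <= 0) {
    abort("`fs_hz` must be a single positive number.")
  }
  structure(
    list(trial_id = trial_id, frames = frames,
         pitch_mm = as.numeric(pitch_mm), fs_hz = as.numeric(fs_hz)),
    class = "pressure_recording"
  )
}

#' @export
print.pressure_recording <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<pressure_recording> trial '%s': %d frames of %dx%d sensels, pitch %g mm, %g Hz\n",
              x$trial_id, length(x$frames), d[1], d[2], x$pitch_mm, x$fs_hz))
  invisible(x)
}

frame_stack_cols <- c("trial_id", "frame_idx", "row", "col", "pressure")

#' Read a tidy-CSV frame stack
#'
#' The frame-stack dialect is long-format CSV with columns `trial_id`,
#' `frame_idx` (contiguous from 0 within each trial), `row`, `col` (0-based
#' sensel indices) and `pressure`. Sensels absent from a frame are zero
#' pressure; the grid shape is the smallest grid covering every mentioned
#' sensel of the trial.
#'
#' @param path Path to the CSV file.
#' @inheritParams pressure_recording
#' @return A list of [pressure_recording()] objects, one per `trial_id`, in
#'   order of first appearance.
#' @seealso [write_frame_stack()]
#' @export
read_frame_stack <- function(path, pitch_mm, fs_hz = 67) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#")
  missing_cols <- setdiff(frame_stack_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("frame stack '%s' is missing columns: %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "caninesway_schema_error")
  }
  if (any(!is.finite(df$pressure)) || any(df$pressure < 0)) {
    abort(sprintf("frame stack '%s' contains negative or non-finite pressures", path),
          class = "caninesway_validation_error")
  }
  trials <- unique(df$trial_id)
  lapply(trials, function(tid) {
    sub <- df[df$trial_id == tid, , drop = FALSE]
    idx <- sort(unique(sub$frame_idx))
    n_frames <- length(idx)
    if (!identical(as.integer(idx), seq_len(n_frames) - 1L)) {
      abort(sprintf("trial '%s': frame_idx must be contiguous from 0 (got gaps)", tid),
            class = "caninesway_format_error")
    }
    nr <- max(sub$row) + 1L
    nc <- max(sub$col) + 1L
    frames <- lapply(seq_len(n_frames) - 1L, function(k) {
      fr <- sub[sub$frame_idx == k, , drop = FALSE]
      m <- matrix(0, nr, nc)
      m[cbind(fr$row + 1L, fr$col + 1L)] <- fr$pressure
      m
    })
    pressure_recording(tid, frames, pitch_mm = pitch_mm, fs_hz = fs_hz)
  })
}

#' Write recordings as a tidy-CSV frame stack
#'
#' All sensels (including zero-pressure ones) are written so the round trip
#' through [read_frame_stack()] is bit-exact and shape-preserving.
#'
#' @param recordings A `pressure_recording` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(recordings, path) {
  if (inherits(recordings, "pressure_recording")) recordings <- list(recordings)
  rows <- purrr::map_dfr(recordings, function(rec) {
    d <- dim(rec$frames[[1]])
    grid <- expand.grid(row = seq_len(d[1]) - 1L, col = seq_len(d[2]) - 1L)
    purrr::map_dfr(seq_along(rec$frames), function(k) {
      tibble::tibble(trial_id = rec$trial_id, frame_idx = k - 1L,
                     row = grid$row, col = grid$col,
                     pressure = as.vector(rec$frames[[k]]))
    })
  })
  readr::write_csv(rows, path)
  invisible(path)
}

cohort_schema <- list(
  dog_id = "c", age_years = "d", weight_kg = "d", height_cm = "d",
  length_cm = "d", sex = "c", bcs = "i", total_joint_pain = "i",
  cp_status = "c", cbpi_severity = "d", cbpi_interference = "d",
  load_score = "d", group = "c"
)

validate_cohort <- function(df, path = "<cohort>") {
  chk <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) {
      abort(sprintf("%s: %s", path, msg), class = "caninesway_validation_error")
    }
  }
  chk(df$weight_kg <= 0, "weight_kg must be positive")
  chk(df$bcs < 1 | df$bcs > 9, "bcs must be within 1-9")
  chk(df$total_joint_pain < 0 | df$total_joint_pain > 64,
      "total_joint_pain must be within 0-64")
  chk(df$cbpi_severity < 0 | df$cbpi_severity > 10, "cbpi_severity must be within 0-10")
  chk(df$cbpi_interference < 0 | df$cbpi_interference > 10,
      "cbpi_interference must be within 0-10")
  chk(df$load_score < 0 | df$load_score > 52, "load_score must be within 0-52")
  chk(!is.na(df$cp_status) & !df$cp_status %in% c("normal", "abnormal"),
      "cp_status must be 'normal' or 'abnormal'")
  chk(!is.na(df$group) & !df$group %in% c("A", "B", "ineligible", "unset"),
      "group must be one of A, B, ineligible, unset")
  df
}

#' Read a cohort metadata table
#'
#' One row per dog: `dog_id`, `age_years`, `weight_kg`, `height_cm` (withers),
#' `length_cm`, `sex`, `bcs` (body condition score 1-9), `total_joint_pain`
#' (orthopedic manipulation score, 0-64), `cp_status` (conscious proprioception,
#' `"normal"`/`"abnormal"`), `cbpi_severity` and `cbpi_interference` (Canine
#' Brief Pain Inventory subscales, 0-10), `load_score` (Liverpool
#' Osteoarthritis in Dogs, 0-52) and `group` (`"A"` adult, `"B"` senior,
#' `"ineligible"`, `"unset"`). Blank clinical cells become `NA`, never zero:
#' owner questionnaires are frequently incomplete and zero is a meaningful
#' score.
#'
#' @param path Path to the CSV file.
#' @return A tibble, one row per dog, in file order.
#' @export
read_cohort_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, comment = "#",
                        col_types = readr::as.col_spec(
                          setNames(unlist(cohort_schema), names(cohort_schema))))
  missing_cols <- setdiff(names(cohort_schema), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("cohort table '%s' is missing columns: %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "caninesway_schema_error")
  }
  validate_cohort(df[names(cohort_schema)], path)
}

#' Write a cohort metadata table
#' @param dogs Tibble as returned by [read_cohort_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(dogs, path) {
  validate_cohort(dogs)
  readr::write_csv(dogs[names(cohort_schema)], path, na = "")
  invisible(path)
}

#' Metric column names of the sway metrics set
#'
#' The sixteen time-domain center-of-pressure measures, in canonical order:
#' velocities and accelerations (path measures), ranges, RMS distances, sway
#' area and 95% confidence ellipse area (extension measures), and frequency
#' revolve, each for the craniocaudal (cc), mediolateral (ml) and, where
#' defined, overall (ov) directions.
#'
#' @return Character vector of length 16.
#' @export
sway_metric_names <- function() {
  c("vel_cc", "vel_ml", "vel_ov", "acc_cc", "acc_ml", "acc_ov",
    "range_cc", "range_ml", "rms_cc", "rms_ml", "rms_ov",
    "sway_area", "ellipse95", "freq_cc", "freq_ml", "freq_ov")
}

metric_units <- c(
  vel_cc = "mm/s", vel_ml = "mm/s", vel_ov = "mm/s",
  acc_cc = "mm/s^2", acc_ml = "mm/s^2", acc_ov = "mm/s^2",
  range_cc = "mm", range_ml = "mm",
  rms_cc = "mm", rms_ml = "mm", rms_ov = "mm",
  sway_area = "mm^2/s", ellipse95 = "mm^2",
  freq_cc = "Hz", freq_ml = "Hz", freq_ov = "Hz"
)

#' Write a per-dog sway metrics table
#'
#' Column order is fixed (`dog_id`, the 16 metrics of [sway_metric_names()],
#' `n_windows_used`); a leading `#` comment line documents the units. Read-back
#' with [read_metrics_table()] reproduces values to full double precision.
#'
#' @param metrics Tibble with `dog_id`, the 16 metric columns and
#'   `n_windows_used`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(metrics, path) {
  cols <- c("dog_id", sway_metric_names(), "n_windows_used")
  missing_cols <- setdiff(cols, names(metrics))
  if (length(missing_cols) > 0) {
    abort(sprintf("metrics table is missing columns: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "caninesway_schema_error")
  }
  ok <- tryCatch({
    writeLines(sprintf("# units: %s",
                       paste(sprintf("%s [%s]", names(metric_units), metric_units),
                             collapse = ", ")),
               path)
    TRUE
  }, error = function(e) {
    abort(sprintf("cannot write metrics table to '%s': %s", path,
                  conditionMessage(e)))
  })
  readr::write_csv(metrics[cols], path, na = "", append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a per-dog sway metrics table written by [write_metrics_table()]
#' @param path Path to the CSV file.
#' @return A tibble with `dog_id`, the 16 metric columns and `n_windows_used`.
#' @export
read_metrics_table <- function(path) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        col_types = readr::cols(dog_id = readr::col_character(),
                                                .default = readr::col_double()))
  cols <- c("dog_id", sway_metric_names(), "n_windows_used")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("metrics table '%s' is missing columns: %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "caninesway_schema_error")
  }
  df[cols]
}

#' Import a supplementary processed-data sheet
#'
#' Adapter for externally deposited processed data (e.g. a study's
#' supplementary spreadsheet exported to CSV). Because such sheets rarely share
#' this package's column names, the mapping from package names to sheet names
#' is supplied by the caller; unmapped package columns come back as `NA`.
#'
#' @param path CSV export of the sheet.
#' @param mapping Named character vector: names are `caninesway` column names
#'   (cohort columns and/or metric columns), values are the sheet's column
#'   names.
#' @return A tibble with the mapped columns under package names, one row per
#'   sheet row.
#' @export
import_s2 <- function(path, mapping) {
  if (is.null(names(mapping)) || any(names(mapping) == "")) {
    abort("`mapping` must be a fully named character vector.")
  }
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing_cols <- setdiff(unname(mapping), names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("sheet '%s' lacks mapped columns: %s", path,
                  paste(missing_cols, collapse = ", ")),
          class = "caninesway_schema_error")
  }
  out <- tibble::as_tibble(setNames(df[unname(mapping)], names(mapping)))
  num_cols <- setdiff(names(out), c("dog_id", "sex", "cp_status", "group"))
  out[num_cols] <- lapply(out[num_cols], as.numeric)
  out
}
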