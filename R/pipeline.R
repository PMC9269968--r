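#' Per-window sway metrics for a cohort of COP recordings
#'
#' For each dog: low-pass filters the trial COP series, selects the analysis
#' windows of acceptable standing ([select_windows()]), computes the sixteen
#' sway metrics per window ([compute_sway_metrics()]). Dogs for whom the
#' required number of windows cannot be found are excluded (dropped with a
#' warning naming them), mirroring the study protocol.
#'
#' @param cop COP tibble across dogs and trials (columns `dog_id`, `trial_id`,
#'   `frame`, `ml_mm`, `cc_mm`, `valid`, `fs_hz`).
#' @param masks Acceptability tibble (`dog_id`, `trial_id`, `frame_idx`,
#'   `acceptable`).
#' @param n_windows,window_len Selection protocol (7 windows of 70 frames).
#' @param cutoff_hz Low-pass cutoff.
#' @return Tibble, one row per selected window: `dog_id`, `trial_id`,
#'   `start_frame`, `window_idx`, the 16 metrics, `n_samples`.
#' @export
window_metrics <- function(cop, masks, n_windows = 7, window_len = 70,
                           cutoff_hz = 5) {
  filtered <- lowpass_filter(cop, cutoff_hz = cutoff_hz)
  dog_ids <- unique(cop$dog_id)
  excluded <- character()
  out <- purrr::map_dfr(dog_ids, function(id) {
    dmask <- masks[masks$dog_id == id, c("trial_id", "frame_idx", "acceptable")]
    sel <- tryCatch(
      select_windows(dmask, n_windows = n_windows, window_len = window_len),
      caninesway_exclusion_error = function(e) NULL
    )
    if (is.null(sel)) {
      excluded <<- c(excluded, id)
      return(NULL)
    }
    dcop <- filtered[filtered$dog_id == id, ]
    purrr::map_dfr(seq_len(nrow(sel)), function(k) {
      trial <- dcop[dcop$trial_id == sel$trial_id[k], ]
      seg <- apply_window(trial, sel$start_frame[k], window_len)
      m <- compute_sway_metrics(seg)
      dplyr::bind_cols(
        tibble::tibble(dog_id = id, trial_id = sel$trial_id[k],
                       start_frame = sel$start_frame[k],
                       window_idx = sel$window_idx[k]),
        m
      )
    })
  })
  if (length(excluded) > 0) {
    warn(sprintf("%d dog(s) excluded (fewer than %d acceptable windows): %s",
                 length(excluded), n_windows, paste(excluded, collapse = ", ")))
  }
  out
}

#' Average window metrics into the per-dog metrics table
#'
#' @param window_metrics Output of [window_metrics()].
#' @return Tibble, one row per dog: `dog_id`, 16 averaged metrics,
#'   `n_windows_used`.
#' @export
dog_metrics <- function(window_metrics) {
  window_metrics |>
    dplyr::group_by(.data$dog_id) |>
    dplyr::group_modify(~ aggregate_windows(.x)) |>
    dplyr::ungroup()
}

# the 13 measures carried into cohort analyses (frequency revolve excluded
# for poor trial-to-trial reliability)
analysis_metrics <- function() {
  setdiff(sway_metric_names(), c("freq_cc", "freq_ml", "freq_ov"))
}

#' Cohort-level analysis of a metrics table
#'
#' Reproduces the analysis battery of the posturography protocol on a per-dog
#' metrics table plus cohort metadata:
#' trial-to-trial reliability (ICC(2,k) per metric, adults only), morphometric
#' regressions of log metrics on weight/height/length (adults only), the
#' row-wise correlation matrix of log metrics (all dogs), group medians and
#' ranges per metric, and forward stepwise logistic discrimination of seniors
#' from adults over the log metrics with in-sample ROC AUC. All model-based
#' analyses use natural-log metrics; the median table is on the raw scale.
#'
#' @param metrics Per-dog metrics tibble ([dog_metrics()]).
#' @param dogs Cohort tibble with at least `dog_id`, `weight_kg`, `height_cm`,
#'   `length_cm`, `group` (levels `"A"`/`"B"`).
#' @param window_metrics Optional per-window metrics ([window_metrics()]) for
#'   the reliability analysis; if omitted, reliability is skipped.
#' @param p_enter Stepwise entry threshold.
#' @return List of class `sway_cohort_analysis`: `reliability` (tibble of ICC
#'   per metric), `morphometrics` (tibble of r/p per metric x morphometric),
#'   `correlations` (matrix), `group_medians` (tibble), `stepwise`
#'   (`sway_stepwise`), `n_adults`, `n_seniors`.
#' @export
analyze_cohort <- function(metrics, dogs, window_metrics = NULL, p_enter = 0.05) {
  stopifnot(all(metrics$dog_id %in% dogs$dog_id))
  d <- dplyr::inner_join(metrics, dogs, by = "dog_id")
  d <- d[d$group %in% c("A", "B"), ]
  adults <- d[d$group == "A", ]
  vars <- analysis_metrics()

  reliability <- NULL
  if (!is.null(window_metrics)) {
    wm <- window_metrics[window_metrics$dog_id %in% adults$dog_id, ]
    reliability <- purrr::map_dfr(sway_metric_names(), function(v) {
      mat <- wm |>
        dplyr::select(dplyr::all_of(c("dog_id", "window_idx", v))) |>
        tidyr::pivot_wider(names_from = "window_idx", values_from = dplyr::all_of(v)) |>
        dplyr::select(-"dog_id") |>
        as.matrix()
      mat <- mat[complete.cases(mat), , drop = FALSE]
      if (nrow(mat) < 3) {
        return(tibble::tibble(metric = v, icc = NA_real_, ci_low = NA_real_,
                              ci_high = NA_real_, label = NA_character_,
                              n = nrow(mat)))
      }
      r <- icc_2k(mat)
      tibble::tibble(metric = v, icc = r$icc, ci_low = r$ci_low,
                     ci_high = r$ci_high, label = r$label, n = r$n_subjects)
    })
  }

  morph_vars <- c("weight_kg", "height_cm", "length_cm")
  morphometrics <- purrr::map_dfr(vars, function(v) {
    purrr::map_dfr(morph_vars, function(mv) {
      res <- linreg_corr(adults[[mv]], transform_metrics(adults[[v]]))
      dplyr::bind_cols(tibble::tibble(metric = v, morphometric = mv), res)
    })
  })

  logm <- d[vars]
  logm[] <- lapply(logm, transform_metrics)
  correlations <- corr_matrix(logm)

  group_medians <- d |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vars),
                                   list(median = median,
                                        min = min,
                                        max = max)),
                     n = dplyr::n(), .groups = "drop")

  step_data <- dplyr::bind_cols(logm, senior = d$group == "B")
  stepwise <- forward_stepwise(step_data, "senior", vars,
                               family = "logistic", p_enter = p_enter)

  structure(
    list(reliability = reliability, morphometrics = morphometrics,
         correlations = correlations, group_medians = group_medians,
         stepwise = stepwise,
         n_adults = nrow(adults), n_seniors = sum(d$group == "B")),
    class = "sway_cohort_analysis"
  )
}

#' @export
print.sway_cohort_analysis <- function(x, ...) {
  cat(sprintf("<sway_cohort_analysis> %d adults, %d seniors\n",
              x$n_adults, x$n_seniors))
  if (!is.null(x$reliability)) {
    cat(sprintf("  reliability: %d/%d metrics good or excellent\n",
                sum(x$reliability$label %in% c("good", "excellent"), na.rm = TRUE),
                nrow(x$reliability)))
  }
  print(x$stepwise)
  invisible(x)
}
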