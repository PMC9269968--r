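#' Tidy an ICC result
#' @param x A `sway_icc` object.
#' @param ... Unused.
#' @return One-row tibble: `estimate`, `conf.low`, `conf.high`, `label`,
#'   `n_subjects`, `k_raters`.
#' @export
tidy.sway_icc <- function(x, ...) {
  tibble::tibble(estimate = x$icc, conf.low = x$ci_low, conf.high = x$ci_high,
                 label = x$label, n_subjects = x$n_subjects, k_raters = x$k_raters)
}

#' Glance at an ICC result
#' @inheritParams tidy.sway_icc
#' @return One-row tibble of the ANOVA mean squares and sample sizes.
#' @export
glance.sway_icc <- function(x, ...) {
  tibble::tibble(msr = x$msr, msc = x$msc, mse = x$mse,
                 n_subjects = x$n_subjects, k_raters = x$k_raters)
}

#' Tidy a stepwise fit
#' @param x A `sway_stepwise` object.
#' @param ... Unused.
#' @return Tibble of final-model coefficient estimates with entry order and
#'   entry p-values for the selected terms.
#' @export
tidy.sway_stepwise <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  out <- tibble::tibble(term = rownames(sm), estimate = sm[, 1],
                        std.error = sm[, 2], p.value = sm[, 4])
  entry <- tibble::tibble(term = x$selected,
                          entry_order = seq_along(x$selected),
                          entry_p = x$p_trace)
  dplyr::left_join(out, entry, by = "term")
}

#' Glance at a stepwise fit
#' @inheritParams tidy.sway_stepwise
#' @return One-row tibble: `n_selected`, `r.squared` (or McFadden pseudo-R^2),
#'   `auc`, `bic`, `n`.
#' @export
glance.sway_stepwise <- function(x, ...) {
  tibble::tibble(n_selected = length(x$selected), r.squared = x$r2,
                 auc = x$auc, bic = tail(x$bic_trace, 1), n = x$n)
}

#' Tidy an interaction model
#' @param x A `sway_interaction` object.
#' @param ... Unused.
#' @return Tibble of terms with raw and standardized coefficients and
#'   p-values.
#' @export
tidy.sway_interaction <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.estimate = unname(x$std_coefficients),
                 p.value = unname(x$p_values))
}
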