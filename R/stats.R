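#' Default breed-size lifespan model
#'
#' Linear model predicting a dog's expected lifespan from withers height and
#' weight, used to convert chronological age into fractional lifespan.
#' Coefficients transcribed from Greer, Canapp & Canapp (2007), Res. Vet.
#' Sci. 82: expected lifespan (years) = 13.62 + 0.0702 x height (inches)
#' - 0.0538 x weight (pounds), re-expressed here per cm and per kg.
#'
#' @param intercept,coef_height,coef_weight Model coefficients (years, years
#'   per cm, years per kg).
#' @return A named list with the three coefficients.
#' @export
lifespan_model <- function(intercept = 13.62,
                           coef_height = 0.0702 / 2.54,
                           coef_weight = -0.0538 * 2.20462) {
  list(intercept = intercept, coef_height = coef_height, coef_weight = coef_weight)
}

#' Estimated lifespan from morphometrics
#'
#' @param height_cm Withers height in cm.
#' @param weight_kg Weight in kg.
#' @param model Coefficients from [lifespan_model()].
#' @return Predicted lifespan in years (vectorized).
#' @export
estimate_lifespan <- function(height_cm, weight_kg, model = lifespan_model()) {
  if (any(height_cm <= 0) || any(weight_kg <= 0)) {
    abort("height and weight must be positive")
  }
  pred <- model$intercept + model$coef_height * height_cm + model$coef_weight * weight_kg
  if (any(pred <= 0)) {
    abort("lifespan model predicts non-positive lifespan; model misconfigured")
  }
  pred
}

#' Assign age groups by fractional lifespan
#'
#' Fractional lifespan (FLS) is age divided by the morphometrically predicted
#' lifespan. Dogs of 5 kg or less are ineligible (their COP is not reliably
#' detected by the pressure mat); adults (group A) are older than 1 year with
#' FLS <= 0.75; seniors (group B) have FLS > 0.75.
#'
#' @param age_years,height_cm,weight_kg Vectors of equal length.
#' @param model Coefficients from [lifespan_model()].
#' @return Tibble with `fls` and `group` (`"A"`, `"B"` or `"ineligible"`).
#' @export
assign_group <- function(age_years, height_cm, weight_kg, model = lifespan_model()) {
  if (any(is.na(age_years)) || any(is.na(height_cm)) || any(is.na(weight_kg))) {
    abort("age, height and weight must be present for every dog")
  }
  fls <- age_years / estimate_lifespan(height_cm, weight_kg, model)
  group <- dplyr::case_when(
    weight_kg <= 5 ~ "ineligible",
    fls > 0.75 ~ "B",
    age_years <= 1 ~ "ineligible",
    .default = "A"
  )
  tibble::tibble(fls = fls, group = group)
}

#' Normalizing transforms
#'
#' COP measures are strictly positive and right-skewed; they are analysed on
#' the natural-log scale. Clinical scores include zeros, so they use
#' `log(x + 1)`.
#'
#' @param values Numeric vector.
#' @return Transformed vector.
#' @export
transform_metrics <- function(values) {
  if (any(values <= 0, na.rm = TRUE)) {
    abort("metric values must be positive for the log transform")
  }
  log(values)
}

#' @rdname transform_metrics
#' @export
transform_scores <- function(values) {
  if (any(values < 0, na.rm = TRUE)) {
    abort("scores must be non-negative for the log(x+1) transform")
  }
  log1p(values)
}

#' Intraclass correlation ICC(2,k)
#'
#' Two-way random effects, absolute agreement, average of k measurements
#' (McGraw & Wong's ICC(A,k)): the reliability of the mean of `k` trials when
#' both subjects and trials are random effects. Computed from the two-way
#' ANOVA mean squares as `(MSR - MSE) / (MSR + (MSC - MSE) / n)`, with the
#' F-based 95% confidence interval of McGraw & Wong (1996).
#'
#' @param mat Numeric matrix, subjects in rows, trials (raters) in columns; no
#'   missing cells, `n >= 3` subjects, `k >= 2` trials.
#' @param conf_level Confidence level for the interval.
#' @return Object of class `sway_icc`: `icc`, `ci_low`, `ci_high`,
#'   `n_subjects`, `k_raters`, `label` (see [classify_reliability()]), and the
#'   mean squares.
#' @export
icc_2k <- function(mat, conf_level = 0.95) {
  mat <- as.matrix(mat)
  if (any(is.na(mat))) abort("ICC requires a complete matrix (no missing cells)")
  n <- nrow(mat); k <- ncol(mat)
  if (n < 3 || k < 2) abort("ICC needs at least 3 subjects and 2 trials")
  grand <- mean(mat)
  row_m <- rowMeans(mat)
  col_m <- colMeans(mat)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (msc - mse) / n
  if (denom <= 0) abort("degenerate variance decomposition; ICC undefined")
  icc <- (msr - mse) / denom
  # McGraw-Wong CI for ICC(A,k), via the single-measure interval
  alpha <- 1 - conf_level
  r1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  a <- k * r1 / (n * (1 - r1))
  b <- 1 + k * r1 * (n - 1) / (n * (1 - r1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- qf(1 - alpha / 2, n - 1, v)
  f_u <- qf(1 - alpha / 2, v, n - 1)
  lo1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  hi1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  sb <- function(r) r * k / (1 + (k - 1) * r)  # single -> average measures
  structure(
    list(icc = icc, ci_low = sb(lo1), ci_high = sb(hi1),
         n_subjects = n, k_raters = k, label = classify_reliability(icc),
         msr = msr, msc = msc, mse = mse),
    class = "sway_icc"
  )
}

#' @export
print.sway_icc <- function(x, ...) {
  cat(sprintf("ICC(2,%d) = %.3f [%.3f, %.3f], n = %d subjects (%s reliability)\n",
              x$k_raters, x$icc, x$ci_low, x$ci_high, x$n_subjects, x$label))
  invisible(x)
}

#' Qualitative reliability label of an ICC value
#'
#' Thresholds: > 0.9 excellent; (0.75, 0.9] good; \[0.5, 0.75\] moderate;
#' < 0.5 poor.
#'
#' @param icc ICC value (`<= 1`).
#' @return `"excellent"`, `"good"`, `"moderate"` or `"poor"` (vectorized).
#' @export
classify_reliability <- function(icc) {
  if (any(icc > 1)) abort("ICC cannot exceed 1")
  dplyr::case_when(
    icc > 0.9 ~ "excellent",
    icc > 0.75 ~ "good",
    icc >= 0.5 ~ "moderate",
    .default = "poor"
  )
}

#' Simple linear regression / Pearson correlation
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, finite.
#' @return One-row tibble: `r` (Pearson), `p` (two-sided, from the t
#'   statistic), `slope`, `intercept`, `n`.
#' @export
linreg_corr <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (var(x) == 0) abort("x has zero variance; regression undefined")
  slope <- cov(x, y) / var(x)
  intercept <- mean(y) - slope * mean(x)
  if (var(y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, slope = slope,
                          intercept = intercept, n = n))
  }
  ct <- cor.test(x, y)
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, slope = slope,
                 intercept = intercept, n = n)
}

#' Row-wise (listwise-deletion) correlation matrix
#'
#' Pearson correlations computed over the rows complete in all columns
#' ("row-wise" in JMP terminology: a row with any missing value is dropped
#' from every pair).
#'
#' @param table Data frame of numeric columns.
#' @return Correlation matrix with unit diagonal.
#' @export
corr_matrix <- function(table) {
  m <- as.matrix(table)
  keep <- complete.cases(m)
  if (sum(keep) < 3) abort("fewer than 3 complete rows; correlations undefined")
  cor(m[keep, , drop = FALSE])
}

#' ROC area under the curve
#'
#' The probability that a randomly chosen positive case scores higher than a
#' randomly chosen negative case, ties counting one half (the Mann-Whitney
#' form; equivalent to the trapezoidal area under the empirical ROC curve).
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (logical, 0/1, or a two-level factor whose
#'   second level is positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.logical(labels)
  if (any(is.na(scores)) || any(is.na(labels))) abort("scores and labels must be complete")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) abort("both classes must be present")
  r <- rank(scores)  # average ranks handle ties
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Forward stepwise regression with p-value entry and a BIC limit
#'
#' Starting from the intercept-only model, at each step the candidate with the
#' smallest likelihood-ratio entry p-value is added, provided the p-value is
#' below `p_enter` and adding it does not increase the model BIC (the BIC sets
#' the limit on model size). Forward-only; no removal steps.
#'
#' @param data Data frame of complete cases.
#' @param response Name of the response column. For `family = "logistic"` it
#'   may be logical, 0/1 or a two-level factor (second level = positive).
#' @param candidates Character vector of candidate predictor columns.
#' @param family `"logistic"` or `"linear"`.
#' @param p_enter Entry threshold on the LR p-value.
#' @return Object of class `sway_stepwise`: `selected` (in entry order),
#'   `fit` (the final `glm`/`lm`), `coefficients`, `r2` (R^2, or McFadden
#'   pseudo-R^2), `bic_trace` (BIC from the null model onwards), `auc`
#'   (logistic only), `p_trace` (entry p-values), `n`.
#' @export
forward_stepwise <- function(data, response, candidates,
                             family = c("logistic", "linear"), p_enter = 0.05) {
  family <- match.arg(family)
  cols <- c(response, candidates)
  data <- data[complete.cases(data[cols]), cols, drop = FALSE]
  n <- nrow(data)
  if (n < length(candidates) + 2) warn("few observations relative to candidates")
  y <- data[[response]]
  if (family == "logistic") {
    if (is.factor(y)) y <- as.integer(y) - 1L
    data[[response]] <- as.integer(as.logical(y))
  }
  separation <- FALSE
  fit_fun <- function(terms) {
    fml <- stats::reformulate(if (length(terms)) terms else "1", response)
    if (family == "logistic") {
      # perfect separation shows up as fitted probabilities of 0/1; record it
      # once instead of spamming warnings for every candidate fit
      withCallingHandlers(
        glm(fml, data = data, family = binomial()),
        warning = function(w) {
          if (grepl("fitted probabilities numerically 0 or 1",
                    conditionMessage(w))) {
            separation <<- TRUE
            invokeRestart("muffleWarning")
          }
        }
      )
    } else {
      lm(fml, data = data)
    }
  }
  lr_p <- function(fit0, fit1) {
    if (family == "logistic") {
      stat <- fit0$deviance - fit1$deviance
      pchisq(stat, df = 1, lower.tail = FALSE)
    } else {
      a <- anova(fit0, fit1)
      a$`Pr(>F)`[2]
    }
  }
  selected <- character()
  current <- fit_fun(selected)
  bic_trace <- stats::BIC(current)
  p_trace <- numeric()
  remaining <- candidates
  while (length(remaining) > 0 && p_enter > 0) {
    trials <- lapply(remaining, function(cand) {
      fit1 <- fit_fun(c(selected, cand))
      list(cand = cand, fit = fit1, p = lr_p(current, fit1))
    })
    ps <- vapply(trials, `[[`, numeric(1), "p")
    best <- trials[[which.min(ps)]]
    if (!is.finite(best$p) || best$p >= p_enter) break
    if (stats::BIC(best$fit) > tail(bic_trace, 1)) break
    selected <- c(selected, best$cand)
    current <- best$fit
    bic_trace <- c(bic_trace, stats::BIC(current))
    p_trace <- c(p_trace, best$p)
    remaining <- setdiff(remaining, best$cand)
  }
  r2 <- if (family == "logistic") {
    1 - current$deviance / current$null.deviance  # McFadden
  } else {
    summary(current)$r.squared
  }
  auc <- if (family == "logistic" && length(selected) > 0) {
    roc_auc(fitted(current), data[[response]])
  } else if (family == "logistic") 0.5 else NA_real_
  structure(
    list(selected = selected, fit = current, coefficients = coef(current),
         r2 = r2, bic_trace = bic_trace, auc = auc, p_trace = p_trace,
         family = family, n = n, separation = separation),
    class = "sway_stepwise"
  )
}

#' @export
print.sway_stepwise <- function(x, ...) {
  cat(sprintf("Forward stepwise (%s), n = %d\n", x$family, x$n))
  if (length(x$selected) == 0) {
    cat("  no variables entered\n")
  } else {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
  }
  cat(sprintf("  R^2 = %.3f%s\n", x$r2,
              if (!is.na(x$auc)) sprintf(", AUC = %.3f", x$auc) else ""))
  invisible(x)
}

#' Joint pain x proprioception interaction model
#'
#' Linear model `y ~ pain + cp + pain:cp` for a transformed COP measure, with
#' standardized coefficients (numeric terms scaled by sd(term)/sd(y)) and
#' per-stratum Pearson correlations between pain and the response. With a
#' single proprioception level the interaction is dropped with a warning and
#' the model reduces to a simple regression on pain.
#'
#' @param data Data frame.
#' @param response,pain Names of the response and (transformed) pain columns.
#' @param cp Name of the proprioception status column (`"normal"` /
#'   `"abnormal"`).
#' @return List of class `sway_interaction`: `fit`, `coefficients`,
#'   `std_coefficients`, `p_values`, `per_stratum` (tibble of per-level `r`,
#'   `p`, `n`).
#' @export
interaction_model <- function(data, response, pain, cp = "cp_status") {
  cols <- c(response, pain, cp)
  data <- data[complete.cases(data[cols]), cols]
  data[[cp]] <- factor(data[[cp]], levels = c("normal", "abnormal"))
  data[[cp]] <- droplevels(data[[cp]])
  single_level <- nlevels(data[[cp]]) < 2
  fml <- if (single_level) {
    warn("single proprioception level; interaction dropped")
    stats::reformulate(pain, response)
  } else {
    stats::reformulate(sprintf("%s * %s", pain, cp), response)
  }
  fit <- lm(fml, data = data)
  sm <- summary(fit)$coefficients
  y_sd <- sd(data[[response]])
  std <- vapply(rownames(sm), function(term) {
    if (term == "(Intercept)") return(NA_real_)
    mm <- stats::model.matrix(fit)[, term]
    unname(coef(fit)[term] * sd(mm) / y_sd)
  }, numeric(1))
  per_stratum <- purrr::map_dfr(levels(data[[cp]]), function(lev) {
    sub <- data[data[[cp]] == lev, ]
    if (nrow(sub) < 3 || var(sub[[pain]]) == 0) {
      return(tibble::tibble(cp_status = lev, r = NA_real_, p = NA_real_,
                            n = nrow(sub)))
    }
    ct <- cor.test(sub[[pain]], sub[[response]])
    tibble::tibble(cp_status = lev, r = unname(ct$estimate), p = ct$p.value,
                   n = nrow(sub))
  })
  structure(
    list(fit = fit, coefficients = coef(fit), std_coefficients = std,
         p_values = sm[, "Pr(>|t|)"], per_stratum = per_stratum),
    class = "sway_interaction"
  )
}
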