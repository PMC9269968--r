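# Fixture builders and independent oracles shared across test files.

# random smooth-ish COP segment (AR(1) per axis)
random_segment <- function(n = 70, fs = 67, sigma = 2, phi = 0.9) {
  ar <- function() {
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sigma)
    for (t in seq_len(n - 1)) {
      x[t + 1] <- phi * x[t] + rnorm(1, 0, sigma * sqrt(1 - phi^2))
    }
    x
  }
  tibble::tibble(ml_mm = ar(), cc_mm = ar(), fs_hz = fs)
}

# uniform circular motion, radius r mm, f revolutions/s, duration s
circle_segment <- function(r = 3, f = 0.5, fs = 67, duration = 10) {
  n <- round(duration * fs)
  th <- 2 * pi * f * (seq_len(n) - 1) / fs
  tibble::tibble(ml_mm = r * cos(th), cc_mm = r * sin(th), fs_hz = fs)
}

# full-trial COP tibble wrapper
as_cop <- function(ml, cc, fs = 67, dog_id = "d1", trial_id = "t1") {
  tibble::tibble(dog_id = dog_id, trial_id = trial_id,
                 frame = seq_along(ml) - 1L, ml_mm = ml, cc_mm = cc,
                 valid = TRUE, fs_hz = fs)
}

# --- independent oracles -----------------------------------------------------

# ICC(2,k) mean squares through stats::aov (independent of the package's
# sums-of-squares arithmetic)
icc_aov_oracle <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  df <- data.frame(y = as.vector(mat),
                   subj = factor(rep(seq_len(n), k)),
                   rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + (msc - mse) / n)
}

# AUC by exhaustive pair counting (ties count one half)
auc_pairs_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# maximal runs of TRUE by a plain O(n) scan
runs_scan_oracle <- function(flags) {
  out <- NULL
  start <- NA
  for (i in seq_along(flags)) {
    if (flags[i] && is.na(start)) start <- i - 1L
    if ((!flags[i] || i == length(flags)) && !is.na(start)) {
      len <- (if (flags[i]) i else i - 1L) - start
      out <- rbind(out, c(start, len))
      start <- NA
    }
  }
  if (is.null(out)) {
    tibble::tibble(start = integer(), length = integer())
  } else {
    tibble::tibble(start = as.integer(out[, 1]), length = as.integer(out[, 2]))
  }
}

# maximum number of disjoint windows of `len` acceptable frames in one trial,
# by dynamic programming over start positions (independent of the greedy rule)
max_windows_dp <- function(flags, len) {
  n <- length(flags)
  ok <- vapply(seq_len(max(n - len + 1, 0)), function(s) all(flags[s:(s + len - 1)]),
               logical(1))
  dp <- integer(n + 2)
  for (s in rev(seq_len(n))) {
    dp[s] <- dp[s + 1]
    if (s <= length(ok) && ok[s]) dp[s] <- max(dp[s], 1L + dp[min(s + len, n + 1)])
  }
  dp[1]
}

# small random mask set for selection tests
random_masks <- function(n_trials, frames, p_true = 0.85) {
  masks <- lapply(seq_len(n_trials), function(i) runif(frames) < p_true)
  names(masks) <- sprintf("t%d", seq_len(n_trials))
  masks
}
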