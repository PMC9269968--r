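test_that("lifespan estimation and group assignment follow the eligibility rules", {
  expect_equal(estimate_lifespan(50, 20, list(intercept = 12, coef_height = 0,
                                              coef_weight = 0)), 12)
  expect_equal(estimate_lifespan(50, 20, list(intercept = 10, coef_height = 0.05,
                                              coef_weight = -0.02)), 12.1)
  # heavier dog, negative weight coefficient: shorter predicted lifespan
  m <- lifespan_model()
  expect_lt(estimate_lifespan(50, 40, m), estimate_lifespan(50, 20, m))
  expect_error(estimate_lifespan(-1, 20))
  expect_error(estimate_lifespan(50, 20, list(intercept = -5, coef_height = 0,
                                              coef_weight = 0)))

  flat <- list(intercept = 12, coef_height = 0, coef_weight = 0)
  g <- assign_group(c(9, 9.12, 0.9, 5, 5), height_cm = rep(50, 5),
                    weight_kg = c(20, 20, 20, 4.9, 20), model = flat)
  # FLS exactly 0.75 stays adult; 0.76 is senior; <= 5 kg ineligible
  expect_identical(g$group, c("A", "B", "ineligible", "ineligible", "A"))
  expect_equal(g$fls[1], 0.75)
  # monotone in age for fixed morphometrics
  ages <- seq(1.2, 14, length.out = 30)
  gr <- assign_group(ages, rep(50, 30), rep(20, 30), flat)$group
  expect_true(all(diff(match(gr, c("A", "B"))) >= 0))
  expect_error(assign_group(NA, 50, 20))
})

test_that("normalizing transforms are the natural log and log1p", {
  expect_equal(transform_metrics(exp(1)), 1)
  expect_equal(transform_metrics(1), 0)
  expect_equal(transform_scores(0), 0)
  expect_equal(transform_scores(exp(1) - 1), 1)
  x <- rexp(50) + 0.01
  expect_equal(transform_metrics(x), log(x))
  expect_equal(transform_scores(x), log(x + 1))
  expect_error(transform_metrics(c(1, 0)))
  expect_error(transform_scores(c(1, -0.5)))
})

test_that("ICC(2,k) matches the worked ANOVA example and the aov oracle", {
  m <- matrix(c(1, 3, 5, 2, 4, 6), nrow = 3)
  r <- icc_2k(m)
  expect_equal(r$icc, 8 / 8.5, tolerance = 1e-12)
  expect_identical(r$label, "excellent")
  expect_lte(r$ci_low, r$icc)
  expect_gte(r$ci_high, r$icc)

  # identical columns: perfect agreement
  same <- matrix(rnorm(10), 10, 4)[, c(1, 1, 1, 1)] + matrix(rnorm(40), 10, 4) * 0
  same <- matrix(rep(rnorm(10), 4), 10, 4)
  expect_equal(icc_2k(same)$icc, 1)

  set.seed(121)
  for (i in 1:100) {
    n <- sample(4:12, 1); k <- sample(2:7, 1)
    mat <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k) +
      rnorm(n, sd = runif(1, 0.5, 3))
    expect_equal(icc_2k(mat)$icc, icc_aov_oracle(mat), tolerance = 1e-10)
  }
  expect_error(icc_2k(matrix(rnorm(4), 2, 2)), "at least 3")
  expect_error(icc_2k(matrix(c(1, NA, 3, 4, 5, 6), 3, 2)), "complete")
})

test_that("ICC increases with k and decreases with added noise", {
  set.seed(131)
  subj <- rnorm(30, sd = 2)
  base <- sapply(1:7, function(j) subj + rnorm(30, sd = 1))
  noisy <- base + matrix(rnorm(30 * 7, sd = 2), 30, 7)
  expect_gt(icc_2k(base)$icc, icc_2k(noisy)$icc)
  expect_gt(icc_2k(base[, 1:7])$icc, icc_2k(base[, 1:2])$icc)
})

test_that("reliability labels use the half-open threshold bands", {
  expect_identical(classify_reliability(c(0.951, 0.9, 0.76, 0.75, 0.5, 0.45)),
                   c("excellent", "good", "good", "moderate", "moderate", "poor"))
  expect_error(classify_reliability(1.2))
})

test_that("linear regression and correlation agree with closed forms", {
  x <- 1:20
  exact <- linreg_corr(x, 2 * x + 1)
  expect_equal(exact$r, 1)
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(linreg_corr(x, -x)$r, -1)
  set.seed(141)
  a <- rnorm(40); b <- 0.4 * a + rnorm(40)
  res <- linreg_corr(a, b)
  expect_equal(res$r, cov(a, b) / (sd(a) * sd(b)))
  expect_equal(res$slope, cov(a, b) / var(a))
  expect_equal(res$p, cor.test(a, b)$p.value)
  expect_error(linreg_corr(rep(1, 10), rnorm(10)), "zero variance")
})

test_that("row-wise correlations use listwise deletion", {
  set.seed(151)
  d <- tibble::tibble(a = rnorm(20), b = rnorm(20))
  d$c <- d$a
  cm <- corr_matrix(d)
  expect_equal(unname(diag(cm)), rep(1, 3))
  expect_equal(cm["a", "c"], 1)
  d$b[1:3] <- NA
  cm2 <- corr_matrix(d)
  keep <- 4:20
  expect_equal(cm2["a", "b"], cor(d$a[keep], d$b[keep]))
  expect_error(corr_matrix(tibble::tibble(a = c(1, NA, 3), b = c(NA, 2, 3))),
               "fewer than 3")
})

test_that("roc_auc equals exhaustive pair counting, including ties", {
  expect_equal(roc_auc(c(0.9, 0.7, 0.6, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(5, 4, 2, 1), c(1, 1, 0, 0)), 1)
  set.seed(161)
  for (i in 1:200) {
    n <- sample(3:12, 1)
    scores <- sample(1:5, n, replace = TRUE) + rbinom(n, 1, 0.5) * 0.5
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))  # both classes guaranteed
    expect_identical(roc_auc(scores, labels), auc_pairs_oracle(scores, labels))
  }
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("roc_auc agrees with pROC on larger data", {
  skip_if_not_installed("pROC")
  set.seed(171)
  scores <- rnorm(150)
  labels <- rbinom(150, 1, plogis(scores))
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
})

test_that("forward stepwise respects the entry threshold and the BIC limit", {
  set.seed(181)
  n <- 300
  X <- as.data.frame(matrix(rnorm(n * 5), n, 5))
  names(X) <- paste0("x", 1:5)
  X$x2 <- X$x1 * 0.7 + X$x2 * 0.3  # correlated candidates
  # response driven by x1 only
  X$y <- rbinom(n, 1, plogis(1.5 * X$x1))
  fit <- forward_stepwise(X, "y", paste0("x", 1:5), family = "logistic")
  expect_identical(fit$selected[1], "x1")
  expect_true(all(diff(fit$bic_trace) < 0))
  expect_true(all(fit$selected %in% paste0("x", 1:5)))
  expect_gt(fit$auc, 0.5)
  expect_equal(fit$auc, roc_auc(fitted(fit$fit), X$y))

  # p_enter = 0 returns the empty (intercept-only) model
  empty <- forward_stepwise(X, "y", paste0("x", 1:5), family = "logistic",
                            p_enter = 0)
  expect_length(empty$selected, 0)
  expect_equal(empty$auc, 0.5)

  # a response independent of all candidates selects nothing (fixed seed)
  set.seed(191)
  X$y <- rbinom(n, 1, 0.5)
  none <- forward_stepwise(X, "y", paste0("x", 1:5), family = "logistic")
  expect_length(none$selected, 0)

  # linear family with a single informative candidate
  set.seed(201)
  d <- data.frame(x1 = rnorm(100), x2 = rnorm(100))
  d$y <- 2 * d$x1 + rnorm(100)
  lfit <- forward_stepwise(d, "y", c("x1", "x2"), family = "linear")
  expect_identical(lfit$selected[1], "x1")
  expect_gt(lfit$r2, 0.5)
  expect_true(is.na(lfit$auc))
})

test_that("the pain x proprioception interaction model recovers built-in effects", {
  set.seed(211)
  n <- 60
  d <- tibble::tibble(
    pain = log1p(rnbinom(n, size = 3, mu = 5)),
    cp_status = sample(c("normal", "abnormal"), n, replace = TRUE)
  )
  # interaction built in: pain slope doubles when proprioception is abnormal
  d$y <- 1 + 0.5 * d$pain + 0.8 * d$pain * (d$cp_status == "abnormal") +
    rnorm(n, sd = 0.4)
  fit <- interaction_model(d, "y", "pain")
  td <- tidy(fit)
  inter <- td$estimate[grepl(":", td$term)]
  expect_gt(inter, 0)
  expect_identical(nrow(fit$per_stratum), 2L)
  expect_gt(fit$per_stratum$r[fit$per_stratum$cp_status == "abnormal"],
            fit$per_stratum$r[fit$per_stratum$cp_status == "normal"])

  # null data: interaction near zero
  d$y <- rnorm(n)
  null_fit <- interaction_model(d, "y", "pain")
  tn <- tidy(null_fit)
  expect_lt(abs(tn$estimate[grepl(":", tn$term)]), 0.5)

  # single proprioception level degrades to a simple regression with a warning
  d$cp_status <- "normal"
  expect_warning(simple <- interaction_model(d, "y", "pain"), "single")
  expect_length(coef(simple$fit), 2)
})

test_that("tidy and glance methods return well-formed tibbles", {
  m <- matrix(rnorm(70), 10, 7) + rnorm(10, sd = 2)
  ti <- tidy(icc_2k(m))
  expect_named(ti, c("estimate", "conf.low", "conf.high", "label",
                     "n_subjects", "k_raters"))
  gl <- glance(icc_2k(m))
  expect_identical(gl$k_raters, 7L)

  set.seed(221)
  d <- data.frame(x1 = rnorm(120), x2 = rnorm(120))
  d$y <- rbinom(120, 1, plogis(2 * d$x1))
  fit <- forward_stepwise(d, "y", c("x1", "x2"), family = "logistic")
  expect_true(all(c("term", "estimate", "entry_order") %in% names(tidy(fit))))
  expect_identical(glance(fit)$n, 120L)
})
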