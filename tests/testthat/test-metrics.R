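test_that("basic descriptors match hand calculations", {
  const <- tibble::tibble(ml_mm = rep(2, 5), cc_mm = rep(3, 5), fs_hz = 67)
  expect_equal(unname(mean_cop(const)), c(2, 3))
  expect_equal(resultant_distances(const), rep(0, 5))

  seg <- tibble::tibble(ml_mm = c(0, 0, 0), cc_mm = c(0, 2, 4), fs_hz = 67)
  expect_equal(unname(mean_cop(seg)), c(0, 2))
  expect_equal(unname(range_metrics(seg)), c(4, 0))
  r <- rms_metrics(seg)
  expect_equal(unname(r), c(sqrt(8 / 3), 0, sqrt(8 / 3)))

  # unit circle around the mean: every resultant distance is 1
  circ <- circle_segment(r = 1, f = 0.5, fs = 67, duration = 10)
  expect_equal(resultant_distances(circ), rep(1, nrow(circ)), tolerance = 1e-9)

  set.seed(71)
  s <- random_segment()
  expect_equal(unname(mean_cop(s)),
               c(sum(s$ml_mm) / nrow(s), sum(s$cc_mm) / nrow(s)))
  expect_equal(resultant_distances(s),
               sqrt((s$ml_mm - mean(s$ml_mm))^2 + (s$cc_mm - mean(s$cc_mm))^2))
})

test_that("velocity is path length over elapsed time", {
  seg <- tibble::tibble(ml_mm = c(0, 3, 3), cc_mm = c(0, 4, 4))
  v <- velocity_metrics(seg, fs = 1)
  expect_equal(unname(v), c(2, 1.5, 2.5))  # vel_cc, vel_ml, vel_ov
  expect_equal(unname(velocity_metrics(tibble::tibble(ml_mm = rep(1, 9),
                                                      cc_mm = rep(2, 9)), fs = 67)),
               c(0, 0, 0))
  # uniform circular motion approaches 2*pi*r*f
  circ <- circle_segment(r = 2, f = 0.5, fs = 67, duration = 10)
  expect_equal(velocity_metrics(circ)[["vel_ov"]], 2 * pi * 2 * 0.5,
               tolerance = 0.01)
  expect_error(velocity_metrics(tibble::tibble(ml_mm = 1, cc_mm = 1), fs = 1),
               "at least 2")
})

test_that("acceleration averages absolute velocity changes", {
  seg <- tibble::tibble(ml_mm = rep(0, 4), cc_mm = c(0, 1, 3, 3))
  a <- acceleration_metrics(seg, fs = 1)
  expect_equal(unname(a), c(1.5, 0, 1.5))  # acc_cc, acc_ml, acc_ov
  # constant velocity: zero acceleration
  lin <- tibble::tibble(ml_mm = seq(0, 9), cc_mm = seq(0, 18, by = 2))
  expect_equal(unname(acceleration_metrics(lin, fs = 1)), c(0, 0, 0))
  # overall (scalar-speed) acceleration is bounded by the component sum
  set.seed(81)
  for (i in 1:25) {
    s <- random_segment()
    a <- acceleration_metrics(s)
    expect_lte(a[["acc_ov"]], a[["acc_cc"]] + a[["acc_ml"]] + 1e-9)
  }
})

test_that("sway area sums mean-anchored triangle areas per second", {
  diamond <- tibble::tibble(ml_mm = c(1, 0, -1, 0), cc_mm = c(0, 1, 0, -1))
  expect_equal(sway_area(diamond, fs = 1), 0.5)
  # motion collinear through the mean sweeps no area
  line <- tibble::tibble(ml_mm = c(-2, -1, 1, 2), cc_mm = c(-4, -2, 2, 4))
  expect_equal(sway_area(line, fs = 1), 0)
  circ <- circle_segment(r = 2, f = 0.5, fs = 67, duration = 10)
  expect_equal(sway_area(circ), pi * 4 * 0.5, tolerance = 0.02)
})

test_that("the 95% ellipse area follows the bivariate-normal formula", {
  line <- tibble::tibble(ml_mm = 1:10 * 2, cc_mm = 1:10 * 3)
  expect_equal(ellipse95_area(line), 0)
  circ <- circle_segment(r = 2, f = 0.5, fs = 67, duration = 10)
  n <- nrow(circ)
  expect_equal(ellipse95_area(circ), pi * 4 * qf(0.95, 2, n - 2),
               tolerance = 0.02)
  expect_error(ellipse95_area(circ[1:3, ]), "at least 4")
})

test_that("frequency revolve matches the analytic circle and sinusoid", {
  circ <- circle_segment(r = 3, f = 0.5, fs = 67, duration = 10)
  fr <- frequency_metrics(circ)
  expect_equal(fr[["freq_ov"]], 0.5, tolerance = 0.01)

  # pure CC sinusoid at f: directional frequency is pi*f/(2*sqrt(2))
  fs <- 67; f0 <- 1
  t <- (0:669) / fs
  sine <- tibble::tibble(ml_mm = rep(0, 670), cc_mm = 4 * sin(2 * pi * f0 * t),
                         fs_hz = fs)
  fr <- frequency_metrics(sine)
  expect_equal(fr[["freq_cc"]], pi * f0 / (2 * sqrt(2)), tolerance = 0.01)
  expect_true(is.na(fr[["freq_ml"]]))  # no ML motion: undefined, not zero

  const <- tibble::tibble(ml_mm = rep(1, 70), cc_mm = rep(2, 70), fs_hz = 67)
  fr <- frequency_metrics(const)
  expect_true(all(is.na(fr)))
})

test_that("compute_sway_metrics equals its component operations", {
  set.seed(91)
  s <- random_segment()
  m <- compute_sway_metrics(s)
  expect_named(m, c(sway_metric_names(), "n_samples"))
  expect_equal(m$vel_ov, velocity_metrics(s)[["vel_ov"]])
  expect_equal(m$acc_cc, acceleration_metrics(s)[["acc_cc"]])
  expect_equal(m$range_ml, range_metrics(s)[["range_ml"]])
  expect_equal(m$rms_ov, rms_metrics(s)[["rms_ov"]])
  expect_equal(m$sway_area, sway_area(s))
  expect_equal(m$ellipse95, ellipse95_area(s))
  expect_equal(m$freq_cc, frequency_metrics(s)[["freq_cc"]])

  # a constant segment zeroes distances and leaves frequencies undefined
  const <- tibble::tibble(ml_mm = rep(1, 70), cc_mm = rep(1, 70), fs_hz = 67)
  mc <- compute_sway_metrics(const)
  expect_equal(mc$vel_ov + mc$acc_ov + mc$range_cc + mc$rms_ov +
                 mc$sway_area + mc$ellipse95, 0)
  expect_true(all(is.na(c(mc$freq_cc, mc$freq_ml, mc$freq_ov))))

  # circle joint consistency
  circ <- circle_segment(r = 3, f = 0.5, fs = 67, duration = 10)
  m <- compute_sway_metrics(circ)
  expect_equal(m$rms_ov, 3, tolerance = 1e-9)
  expect_equal(m$freq_ov, 0.5, tolerance = 0.01)
  expect_equal(m$vel_ov, 2 * pi * 3 * 0.5, tolerance = 0.01)
})

test_that("window averaging handles undefined frequencies correctly", {
  set.seed(101)
  rows <- purrr::map_dfr(1:7, ~ compute_sway_metrics(random_segment()))
  agg <- aggregate_windows(rows)
  expect_identical(agg$n_windows_used, 7L)
  for (v in sway_metric_names()) {
    expect_equal(agg[[v]], mean(rows[[v]]))
  }
  # identical entries average to themselves
  same <- rows[rep(1, 7), ]
  expect_equal(aggregate_windows(same)$rms_ov, rows$rms_ov[1])
  # a simple arithmetic check
  rows$vel_cc <- as.numeric(1:7)
  expect_equal(aggregate_windows(rows)$vel_cc, 4)
  # undefined frequencies are skipped, not zeroed
  rows$freq_ov[1:3] <- NA
  expect_equal(aggregate_windows(rows)$freq_ov, mean(rows$freq_ov[4:7]))
  rows$freq_ov <- NA_real_
  expect_true(is.na(aggregate_windows(rows)$freq_ov))
  expect_error(aggregate_windows(rows[0, ]), "no windows")
})

test_that("metrics are invariant to translation and time reversal and scale correctly", {
  set.seed(111)
  for (i in 1:50) {
    s <- random_segment(n = sample(20:80, 1))
    m <- compute_sway_metrics(s)

    shifted <- s; shifted$ml_mm <- s$ml_mm + 37.5; shifted$cc_mm <- s$cc_mm - 12
    expect_equal(as.data.frame(compute_sway_metrics(shifted)),
                 as.data.frame(m), tolerance = 1e-9)

    rev_s <- s[rev(seq_len(nrow(s))), ]
    expect_equal(as.data.frame(compute_sway_metrics(rev_s)),
                 as.data.frame(m), tolerance = 1e-9)

    c0 <- 2.5
    scaled <- s; scaled$ml_mm <- s$ml_mm * c0; scaled$cc_mm <- s$cc_mm * c0
    ms <- compute_sway_metrics(scaled)
    lin <- c("vel_cc", "vel_ml", "vel_ov", "acc_cc", "acc_ml", "acc_ov",
             "range_cc", "range_ml", "rms_cc", "rms_ml", "rms_ov")
    for (v in lin) expect_equal(ms[[v]], c0 * m[[v]], tolerance = 1e-9)
    expect_equal(ms$sway_area, c0^2 * m$sway_area, tolerance = 1e-9)
    expect_equal(ms$ellipse95, c0^2 * m$ellipse95, tolerance = 1e-9)
    for (v in c("freq_cc", "freq_ml", "freq_ov")) {
      expect_equal(ms[[v]], m[[v]], tolerance = 1e-9)
    }

    # velocity ordering and the RMS identity
    expect_lte(m$vel_ov, m$vel_cc + m$vel_ml + 1e-9)
    expect_gte(m$vel_ov, max(m$vel_cc, m$vel_ml) - 1e-9)
    expect_equal(m$rms_ov^2, m$rms_cc^2 + m$rms_ml^2, tolerance = 1e-9)
  }
})
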