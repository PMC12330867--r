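test_that("peak detection uses argmax with earliest-step tie-break", {
  p <- profile_of(rep(5, 32))
  pk <- find_peak(p)
  expect_identical(pk$peak_step, 1L)
  f <- rep(1, 32); f[10] <- 9
  expect_identical(find_peak(profile_of(f))$peak_step, 10L)
  expect_equal(find_peak(profile_of(f))$peak_pct_cc, 31.25)
  # scale invariance of the peak position
  expect_identical(find_peak(profile_of(3 * f))$peak_step, 10L)
})

test_that("dicrotic notch sits at an engineered slope break", {
  # steep descent to step 17, shallow descent after
  f <- numeric(32)
  f[1:8] <- seq(10, 100, length.out = 8)
  f[9:17] <- seq(100, 20, length.out = 9)
  f[18:32] <- seq(20, 12, length.out = 15)
  n <- find_dicrotic_notch(profile_of(f))
  expect_identical(n$notch_step, 17L)
  expect_equal(n$notch_pct_cc, 53.125)
})

test_that("a strictly concave descent has no notch", {
  f <- numeric(32)
  f[1:8] <- seq(10, 100, length.out = 8)
  x <- seq_len(24)
  f[9:32] <- 100 - (x / 24)^2 * 80   # concave decline (negative curvature)
  n <- find_dicrotic_notch(profile_of(f))
  expect_true(is.na(n$notch_step))
  expect_match(n$reason, "no positive slope break")
})

test_that("notch detection recovers the generator ground truth", {
  rr <- 60000 / 189
  for (notch in c(50, 53.125, 56)) {
    p <- waveform_params("BT", 19, 29, baseline_fraction = 0.32,
                         notch_pct_cc = notch)
    f <- make_waveform(p, cc_grid_pct(), rr)
    n <- find_dicrotic_notch(profile_of(f, rr))
    expect_lt(abs(n$notch_pct_cc - notch), 3.125 + 1e-9)
    # notch lies after the peak whenever defined
    expect_gt(n$notch_pct_cc, find_peak(profile_of(f, rr))$peak_pct_cc)
  }
})

test_that("notch is undefined for venous profiles", {
  expect_error(find_dicrotic_notch(profile_of(rep(1, 32), vessel = "SS")),
               "not defined")
})

test_that("upslope follows the step-3-to-peak definition", {
  f <- numeric(32); f[3] <- 0; f[10] <- 100
  f[4:9] <- seq(15, 90, length.out = 6)
  f[11:32] <- 20
  up <- upslope(profile_of(f, rr = 400))
  expect_equal(up$upslope_ul_s2, 100 / (7 * 400 / 32 / 1000))
  expect_equal(up$upslope_ul_s2, 1142.857, tolerance = 1e-4)
  # constant profile peaks at step 1: undefined and flagged
  expect_false(upslope(profile_of(rep(5, 32)))$defined)
})

test_that("PI and RI match the closed form for a sinusoidal profile", {
  m <- 10; a <- 4
  f <- m + a * sin(2 * pi * cc_grid_pct() / 100)
  pr <- pulsatility_indices(profile_of(f))
  # the 32-step grid hits the sine extrema only approximately
  expect_equal(pr$PI, 2 * a / m, tolerance = 0.01)
  expect_equal(pr$RI, 2 * a / (m + a), tolerance = 0.01)
  expect_identical(pulsatility_indices(profile_of(rep(7, 32)))$PI, 0)
  expect_identical(pulsatility_indices(profile_of(rep(7, 32)))$RI, 0)
  f0 <- c(0, rep(5, 31))
  expect_equal(pulsatility_indices(profile_of(f0))$RI, 1)
  # scale invariance
  expect_equal(pulsatility_indices(profile_of(3 * f))$PI, pr$PI)
  expect_equal(pulsatility_indices(profile_of(3 * f))$RI, pr$RI)
})

test_that("peak lags are ordered differences with antisymmetry", {
  ft <- data.frame(vessel = c("BT", "RC", "LC", "SS", "StS", "Art", "Ven"),
                   peak_pct_cc = c(25, 30, 28, 34.4, 31, 26, 33))
  lags <- peak_lags(ft)
  expect_equal(lags$lag_pct_cc[lags$from_vessel == "BT" &
                               lags$to_vessel == "SS"], 9.4)
  # antisymmetry via a reversed table
  rev_ft <- ft; rev_ft$peak_pct_cc <- -ft$peak_pct_cc
  expect_equal(peak_lags(rev_ft)$lag_pct_cc, -lags$lag_pct_cc)
  # identical peaks give zero lags
  same <- ft; same$peak_pct_cc <- 20
  expect_true(all(peak_lags(same)$lag_pct_cc == 0))
  # missing vessel drops its pairs with a record
  sub <- ft[ft$vessel != "StS", ]
  l2 <- peak_lags(sub)
  expect_false("StS" %in% l2$from_vessel)
  expect_match(attr(l2, "omitted"), "StS", all = FALSE)
})

test_that("peak recovery on noiseless dense profiles is within one step", {
  co <- make_cohort(2, 2, seed = 17, noise_sd = 0)
  res <- analyze_cohort(co)
  for (i in seq_along(co)) {
    tru <- c(co[[i]]$truth$arterial$peak_pct_cc,
             co[[i]]$truth$venous$peak_pct_cc)
    ft <- res$subjects[[i]]$features
    est <- ft$peak_pct_cc[match(names(tru), ft$vessel)]
    expect_true(all(abs(est - tru) <= 3.125 + 1e-9))
  }
})
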