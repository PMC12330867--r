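series_of <- function(pct, flow, vessel = "BT", rr = 400) {
  structure(data.frame(vessel = vessel, pct_cc = pct, flow_ul_s = flow),
            rr_ms = rr, vessel = vessel)
}

test_that("the canonical grid is 32 steps of exactly 3.125 %CC", {
  g <- cc_grid_pct()
  expect_length(g, 32)
  expect_identical(diff(g), rep(3.125, 31))
  expect_identical(g[3], 9.375)
  expect_identical(g[8], 25)
  expect_identical(g[32], 100)
})

test_that("constant flow over 75% coverage normalizes to constant steps", {
  pct <- seq(0, 75, length.out = 16)
  for (mode in c("periodic", "secant")) {
    p <- normalize_profile(series_of(pct, rep(42, 16)), extrapolation = mode)
    expect_equal(p$flow_ul_s, rep(42, 32))
    expect_true(any(p$extrapolated))
    expect_false(any(p$extrapolated[cc_grid_pct() <= 75]))
  }
})

test_that("secant extrapolation is exact on affine inputs", {
  pct <- seq(0, 70, length.out = 15)
  a <- 5; b <- 0.8
  p <- normalize_profile(series_of(pct, a + b * pct), extrapolation = "secant")
  expect_equal(p$flow_ul_s, a + b * cc_grid_pct(), tolerance = 1e-12)
  # two-point secant variant is also exact
  p2 <- normalize_profile(series_of(pct, a + b * pct),
                          extrapolation = "secant", n_fit = 2)
  expect_equal(p2$flow_ul_s, a + b * cc_grid_pct(), tolerance = 1e-12)
})

test_that("normalization is idempotent for samples already on the grid", {
  flow <- 30 + 20 * sin(2 * pi * cc_grid_pct() / 100)
  p <- normalize_profile(series_of(cc_grid_pct(), flow))
  expect_equal(p$flow_ul_s, flow, tolerance = 1e-12)
  expect_false(any(p$extrapolated))
})

test_that("dense sampling of the young default waveform peaks at step 10", {
  rr <- 60000 / 189
  wp <- ya_params()
  pct <- seq(0, 79, by = 1)
  art <- Reduce(`+`, lapply(wp[c("BT", "RC", "LC")], make_waveform,
                            t_pct = pct, rr_ms = rr))
  p <- normalize_profile(series_of(pct, art, vessel = "BT", rr = rr))
  expect_identical(find_peak(p)$peak_step, 10L)
})

test_that("sinus extrapolation under the secant mode never goes negative", {
  pct <- seq(0, 60, length.out = 10)
  flow <- pmax(20 - 0.5 * pct, 1)
  p <- normalize_profile(series_of(pct, flow, vessel = "SS"),
                         extrapolation = "secant")
  expect_true(all(p$flow_ul_s >= 0))
})

test_that("normalization rejects degenerate sample sets", {
  expect_error(normalize_profile(series_of(c(0, 10), c(1, 2))), "fewer than 3")
  s <- series_of(c(0, 10, 20), c(1, 2, NA))
  expect_error(normalize_profile(s), "fewer than 3")
})

test_that("reducing coverage from 100% to 75% moves volumes by <= 10%", {
  rr <- 60000 / 189
  wp <- ya_params()
  for (v in c("BT", "SS")) {
    full <- seq(0, 99.9, length.out = 40)
    part <- full[full <= 75]
    f_full <- make_waveform(wp[[v]], full, rr)
    prof_full <- normalize_profile(series_of(full, f_full, vessel = v, rr = rr))
    prof_part <- normalize_profile(series_of(part, f_full[full <= 75],
                                             vessel = v, rr = rr))
    v1 <- cycle_volume(prof_full)
    v2 <- cycle_volume(prof_part)
    expect_lt(abs(v2 - v1) / v1, 0.10)
  }
})

test_that("profile sums are step-wise with composite labels", {
  f1 <- profile_of(rep(1, 32)); f2 <- profile_of(rep(2, 32), vessel = "RC")
  f3 <- profile_of(rep(3, 32), vessel = "LC")
  s <- sum_profiles(list(f1, f2, f3))
  expect_identical(s$vessel, "Art")
  expect_equal(s$flow_ul_s, rep(6, 32))
  neg <- profile_of(-rep(1, 32))
  expect_equal(sum_profiles(list(f1, neg), label = "zero")$flow_ul_s,
               rep(0, 32))
  bad <- flow_profile32("SS", rep(1, 32), rr_ms = 500)
  expect_error(sum_profiles(list(f1, bad)), "mismatched rr_ms")
})

test_that("composite venous flow peaks after composite arterial flow", {
  co <- make_cohort(2, 2, seed = 31)
  res <- analyze_cohort(co)
  for (s in res$subjects) {
    lag <- s$lags$lag_pct_cc[s$lags$from_vessel == "Art" &
                             s$lags$to_vessel == "Ven"]
    expect_gt(lag, 0)
  }
})
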