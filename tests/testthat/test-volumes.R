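test_that("cycle volume is the step-rectangle integral", {
  p <- profile_of(rep(100, 32), rr_ms = 400)
  expect_equal(cycle_volume(p), 40)
  # against a trapezoidal oracle on the same 32 points (periodic closure)
  f <- 50 + 30 * sin(2 * pi * cc_grid_pct() / 100)
  p2 <- profile_of(f, rr_ms = 317)
  trap <- sum((f + c(f[-1], f[1])) / 2) * (317 / 32) / 1000
  expect_lt(abs(cycle_volume(p2) - trap) / trap, 0.02)
})

test_that("perfusion, drainage and CBF follow the stated arithmetic", {
  s <- ya_subject(hr = 189)
  vols <- c(BT = 19.0, RC = 13.2, LC = 15.5, SS = 6.2, StS = 6.8)
  pf <- perfusion_and_cbf(vols, s)
  expect_equal(pf$perfusion_ml_min, 47.7 * 189 / 1000)  # = 9.02 ml/min
  expect_equal(pf$perfusion_ml_min, 9.02, tolerance = 1e-3)
  expect_equal(pf$drainage_ml_min, 13.0 * 189 / 1000)
  expect_equal(pf$tissue_mass_g, (4084 + 2669) / 1000 * 1.05)
  expect_equal(pf$cbf_ml_min_100g, pf$perfusion_ml_min / pf$tissue_mass_g * 100)
  # 9.0 ml/min on 6753 ul of tissue is ~127 ml/min/100 g
  s2 <- ya_subject(); s2$gm_ul <- 4084; s2$wm_ul <- 2669
  expect_equal(9.0 / 7.09065 * 100, 126.93, tolerance = 1e-3)
  # doubling HR doubles perfusion and CBF exactly
  s3 <- ya_subject(hr = 378)
  pf3 <- perfusion_and_cbf(vols, s3)
  expect_equal(pf3$perfusion_ml_min, 2 * pf$perfusion_ml_min)
  expect_equal(pf3$cbf_ml_min_100g, 2 * pf$cbf_ml_min_100g)
})

test_that("allometric perfusion prediction evaluates the power law", {
  expect_equal(round(seymour_prediction(8), 1), 7.2)
  expect_equal(seymour_prediction(1), 1)
  expect_equal(seymour_prediction(0.001), 0.001^0.95)
  expect_equal(seymour_prediction(0.001), exp(0.95 * log(0.001)),
               tolerance = 1e-12)  # = 0.0014125...
})

test_that("identical arterial and venous profiles balance trivially", {
  f <- 40 + 25 * sin(2 * pi * cc_grid_pct() / 100)
  art <- flow_profile32("Art", f, 400)
  ven <- flow_profile32("Ven", f, 400)
  b <- av_balance(art, ven)
  expect_equal(b$CF, 1)
  expect_equal(b$balance_ul, rep(0, 32))
  expect_equal(b$oscillating_volume_ul, 0)
})

test_that("a phase-shifted venous copy conserves volume but oscillates", {
  f <- 40 + 25 * sin(2 * pi * cc_grid_pct() / 100)
  g <- 40 + 25 * sin(2 * pi * (cc_grid_pct() - 12.5) / 100)
  art <- flow_profile32("Art", f, 400)
  ven <- flow_profile32("Ven", g, 400)
  b <- av_balance(art, ven)
  expect_equal(b$CF, 1, tolerance = 1e-12)
  expect_equal(b$cumulative_balance_ul[32], 0, tolerance = 1e-9)
  expect_gt(b$oscillating_volume_ul, 0)
})

test_that("cumulative balance closes at zero for measured subjects", {
  co <- make_cohort(2, 2, seed = 23)
  res <- analyze_cohort(co)
  for (s in res$subjects) {
    h <- s$haemo
    expect_lt(abs(h$cumulative_balance_ul[32]),
              1e-9 * max(abs(h$cumulative_balance_ul)))
    # conservation: CF-corrected venous volume equals arterial volume
    expect_equal(h$CF * cycle_volume(s$profiles$Ven),
                 cycle_volume(s$profiles$Art), tolerance = 1e-12)
    expect_gte(h$oscillating_volume_ul, 0)
  }
})

test_that("scaling all flows scales the coupling quantities covariantly", {
  f <- 40 + 25 * sin(2 * pi * cc_grid_pct() / 100)
  g <- 12 + 5 * cos(2 * pi * cc_grid_pct() / 100)
  c_ <- 3
  art <- flow_profile32("Art", f, 400); ven <- flow_profile32("Ven", g, 400)
  art2 <- flow_profile32("Art", c_ * f, 400)
  ven2 <- flow_profile32("Ven", c_ * g, 400)
  b1 <- av_balance(art, ven); b2 <- av_balance(art2, ven2)
  expect_equal(b2$CF, b1$CF)
  expect_equal(b2$oscillating_volume_ul, c_ * b1$oscillating_volume_ul)
  expect_equal(cycle_volume(art2), c_ * cycle_volume(art))
  h1 <- hysteresis_loop(art, ven); h2 <- hysteresis_loop(art2, ven2)
  expect_equal(h2$area, c_^2 * h1$area)
})

test_that("hysteresis area matches the inscribed-polygon closed form", {
  th <- 2 * pi * (1:32) / 32
  for (r in c(1, 5, 20)) {
    art <- flow_profile32("Art", r * cos(th), 400)
    ven <- flow_profile32("Ven", r * sin(th), 400)
    h <- hysteresis_loop(art, ven)
    closed_form <- r^2 * (32 / 2) * sin(2 * pi / 32)
    expect_equal(h$area, closed_form, tolerance = 1e-12)
    expect_lt(abs(h$area - pi * r^2) / (pi * r^2), 0.007)
    expect_false(h$self_intersecting)
  }
  # proportional profiles are degenerate
  f <- 10 + (1:32)
  expect_equal(hysteresis_loop(profile_of(f), profile_of(2 * f))$area, 0)
})

test_that("ellipse hysteresis area matches the shoelace closed form", {
  th <- 2 * pi * (1:32) / 32
  a <- 60; b <- 7
  art <- flow_profile32("Art", 100 + a * cos(th), 400)
  ven <- flow_profile32("Ven", 20 + b * sin(th), 400)
  h <- hysteresis_loop(art, ven)
  expect_equal(h$area, a * b * (32 / 2) * sin(2 * pi / 32), tolerance = 1e-9)
  expect_lt(abs(h$area - pi * a * b) / (pi * a * b), 0.007)
})

test_that("input fractions are per-subject percentages summing to 100", {
  fr <- input_fractions(c(BT = 2, RC = 1, LC = 1))
  expect_equal(fr$BT_pct, 50)
  expect_equal(fr$carotids_pct, 50)
  fr2 <- input_fractions(c(BT = 19.0, RC = 13.2, LC = 15.5,
                           SS = 6.2, StS = 6.8))
  expect_equal(fr2$BT_pct, 100 * 19 / 47.7, tolerance = 1e-9)
  expect_equal(fr2$BT_pct, 39.8, tolerance = 0.05)
  expect_equal(fr2$carotids_pct, 60.2, tolerance = 0.05)
  expect_equal(fr2$BT_pct + fr2$RC_pct + fr2$LC_pct, 100, tolerance = 1e-9)
  expect_equal(fr2$SS_pct + fr2$StS_pct, 100, tolerance = 1e-9)
  expect_error(input_fractions(c(BT = 0, RC = 0, LC = 0)), "zero")
})

test_that("totals are exact sums of their parts across the cohort table", {
  co <- make_cohort(2, 2, seed = 29)
  res <- analyze_cohort(co)
  for (s in res$subjects) {
    h <- s$haemo
    expect_identical(unname(h$totals_ul["arteries"]),
                     unname(sum(h$volumes_ul[c("BT", "RC", "LC")])))
    expect_identical(unname(h$totals_ul["sinuses"]),
                     unname(sum(h$volumes_ul[c("SS", "StS")])))
  }
  # group mean of sums equals sum of group means (linearity of the mean)
  sm <- res$summary
  gm <- function(m, g) sm$mean[sm$metric == m & sm$age_group == g]
  for (g in c("YA", "OA")) {
    expect_equal(gm("volume_arteries", g),
                 gm("volume_BT", g) + gm("volume_RC", g) + gm("volume_LC", g),
                 tolerance = 1e-12)
  }
})
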