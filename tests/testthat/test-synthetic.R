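test_that("noiseless render decodes to the exact true mean velocity", {
  s <- ya_subject()
  p <- flat_params("BT", 20)  # near-constant flow
  r <- small_render(s, list(p), noise_sd = 0, n_frames = 8)
  an <- segment_series(r$dataset)
  ser <- vessel_series(r$dataset, an$BT, "BT")
  true_v <- r$truth$flow_at_frames$BT /
    (10 * r$truth$lumen$BT$area_raster_mm2)
  expect_equal(ser$mean_velocity_cm_s, true_v, tolerance = 1e-10)
  expect_equal(ser$flow_ul_s, r$truth$flow_at_frames$BT, tolerance = 1e-10)
})

test_that("frame times span the covered fraction starting at the R-wave", {
  s <- ya_subject()
  r <- small_render(s, list(flat_params()), noise_sd = 0,
                    coverage_fraction = 0.75, n_frames = 16)
  ft <- r$dataset$frame_times_ms
  expect_length(ft, 16)
  expect_identical(ft[1], 0)
  expect_lt(max(ft), 0.76 * r$dataset$rr_ms)
})

test_that("rendered lumen voxel count matches the analytic pixelated disk", {
  s <- ya_subject()
  for (radius in c(0.34, 0.379, 0.45, 0.6)) {
    # small volume keeps velocities well inside VENC at every radius
    p <- waveform_params("BT", 3, 30, baseline_fraction = 0.4,
                         notch_pct_cc = 53, lumen_radius_mm = radius)
    r <- small_render(s, list(p), noise_sd = 0, n_frames = 4)
    expect_identical(r$truth$lumen$BT$n_voxels[1],
                     pixelated_disk_count(radius))
  }
  # a ~0.45 mm^2 lumen at 150 um pixels covers ~20 voxels, inside the
  # 13-31 voxel range of real vessel cross-sections
  n <- pixelated_disk_count(sqrt(0.45 / pi))
  expect_gte(n, 13); expect_lte(n, 31)
})

test_that("velocities exceeding VENC raise an aliasing error", {
  s <- ya_subject()
  # tiny lumen forces mean velocity over VENC
  p <- waveform_params("BT", 60, 30, baseline_fraction = 0.3,
                       notch_pct_cc = 53, lumen_radius_mm = 0.34)
  expect_error(small_render(s, list(p), noise_sd = 0, n_frames = 4),
               "aliasing")
})

test_that("cohort generation is deterministic and has the right shape", {
  c1 <- make_cohort(2, 2, seed = 42)
  c2 <- make_cohort(2, 2, seed = 42)
  expect_identical(c1, c2)
  expect_length(c1, 4)
  expect_identical(vapply(c1, function(b) b$spec$age_group, ""),
                   c("YA", "YA", "OA", "OA"))
  for (b in c1) {
    expect_s3_class(b$arterial, "cine_dataset")
    expect_s3_class(b$venous, "cine_dataset")
    nf <- length(b$arterial$frame_times_ms)
    expect_gte(nf, 12); expect_lte(nf, 22)
    expect_true(all(abs(b$arterial$phase) <= pi + 1e-9))
  }
  c3 <- make_cohort(2, 2, seed = 43)
  expect_false(identical(c1, c3))
})

test_that("cohort ground-truth volumes integrate each true waveform", {
  co <- make_cohort(2, 1, seed = 7)
  for (b in co) for (sl in c("arterial", "venous")) {
    tr <- b$truth[[sl]]
    for (v in names(tr$waveforms)) {
      w <- tr$waveforms[[v]]
      v_int <- sum(w$flow_ul_s) * 0.05 * (tr$rr_ms / 1000) / 100
      expect_lt(abs(v_int - tr$volumes_ul[[v]]) / tr$volumes_ul[[v]], 0.01)
    }
  }
})

test_that("cohort true volumes are centred on the calibration means", {
  # sampling check at n = 12 per group: group means of the generator truth
  # fall within 2 SEM of the calibration targets
  co <- make_cohort(12, 12, seed = 5)
  cal <- calibration_targets()
  grp <- vapply(co, function(b) b$spec$age_group, "")
  bt <- vapply(co, function(b) b$truth$arterial$volumes_ul[["BT"]], 0)
  for (g in c("YA", "OA")) {
    tgt <- cal[cal$metric == "volume_BT" & cal$group == g, ]
    sem <- tgt$sd / sqrt(sum(grp == g))
    expect_lt(abs(mean(bt[grp == g]) - tgt$mean), 3 * sem)
  }
})
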