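test_that("background SD of a constant image is zero", {
  expect_identical(estimate_background_sd(matrix(3, 40, 40)), 0)
})

test_that("background SD recovers the sampling distribution SD", {
  set.seed(1)
  # corner patches of a 160x160 image hold 4 * 16 * 16 = 1024 voxels; use a
  # larger field so the auto region exceeds 2000 voxels
  img <- matrix(rnorm(240 * 240, mean = 5, sd = 1.7), 240, 240)
  est <- estimate_background_sd(img)
  expect_lt(abs(est - 1.7) / 1.7, 0.05)
  # explicit mask variant agrees with sd over the same voxels
  bg <- matrix(FALSE, 240, 240); bg[1:60, 1:60] <- TRUE
  expect_equal(estimate_background_sd(img, bg), sd(img[bg]))
})

test_that("background SD on rendered frames matches the Rician Monte-Carlo", {
  s <- ya_subject()
  for (sdn in c(0.5, 1.5)) {
    set.seed(2)
    r <- small_render(s, list(flat_params()), noise_sd = sdn, n_frames = 6)
    est <- mean(sapply(1:6, function(f)
      estimate_background_sd(r$dataset$magnitude[, , f])))
    # brute-force Monte-Carlo of the magnitude of complex Gaussian noise
    mc <- sd(sqrt(rnorm(2e5, 0, sdn)^2 + rnorm(2e5, 0, sdn)^2))
    expect_lt(abs(est - mc) / mc, 0.10)
  }
})

test_that("background region validation rejects bad regions", {
  img <- matrix(1, 50, 50)
  expect_error(estimate_background_sd(img, matrix(FALSE, 50, 50)), "empty")
  bg <- matrix(FALSE, 50, 50); bg[1:10, 1:10] <- TRUE
  expect_error(estimate_background_sd(img, bg, vessel_seeds = list(c(5, 5))),
               "overlaps")
})

test_that("a bright disk on Gaussian noise is recovered near its true size", {
  set.seed(3)
  sigma <- 1
  img <- matrix(rnorm(80 * 80, 0, sigma), 80, 80)
  seed <- c(40, 40)
  tru <- 0L
  for (i in -5:5) for (j in -5:5) if (sqrt(i^2 + j^2) <= 3) {
    img[40 + i, 40 + j] <- 10 * sigma
    tru <- tru + 1L
  }
  m <- segment_lumen(img, seed, threshold = 2 * sigma, clean = TRUE)
  expect_true(m$detected)
  expect_lt(abs(m$n_voxels - tru) / tru, 0.15)
})

test_that("segmentation reports non-detection distinctly", {
  m <- segment_lumen(matrix(0, 20, 20), c(10, 10), threshold = 1)
  expect_false(m$detected)
  expect_identical(m$n_voxels, 0L)
  expect_match(m$reason, "not detected")
})

test_that("noiseless rendered lumen is segmented voxel-exactly", {
  s <- ya_subject()
  p <- ya_params()["BT"]
  r <- small_render(s, p, noise_sd = 0, n_frames = 5)
  lum <- segment_series(r$dataset)
  expect_identical(lum$BT$area$n_voxels, r$truth$lumen$BT$n_voxels)
  expect_equal(lum$BT$area$area_mm2, r$truth$lumen$BT$area_raster_mm2)
})

test_that("raising the threshold never grows the mask", {
  set.seed(4)
  img <- matrix(abs(rnorm(60 * 60, 0, 1)), 60, 60)
  img[28:32, 28:32] <- 8
  prev <- Inf
  for (thr in c(0.5, 1, 2, 4)) {
    m <- segment_lumen(img, c(30, 30), thr)
    expect_lte(m$n_voxels, prev)
    prev <- m$n_voxels
  }
})

test_that("masks of distinct vessels on one slice never overlap", {
  co <- make_cohort(1, 1, seed = 9)
  for (b in co) {
    lum <- segment_series(b$arterial)
    nf <- dim(b$arterial$magnitude)[3]
    for (f in seq_len(nf)) {
      keys <- unlist(lapply(c("BT", "RC", "LC"), function(v) {
        vox <- lum[[v]]$masks[[f]]$voxels
        if (is.null(vox)) character(0) else paste(vox[, 1], vox[, 2])
      }))
      expect_identical(anyDuplicated(keys), 0L)
    }
  }
})

test_that("per-frame areas track a pulsatile lumen", {
  s <- ya_subject()
  p <- ya_params()["BT"]
  r <- small_render(s, p, noise_sd = 0, n_frames = 14,
                    area_pulse_fraction = 0.2)
  lum <- segment_series(r$dataset)
  expect_gt(cor(lum$BT$area$n_voxels, r$truth$lumen$BT$n_voxels,
                method = "spearman"), 0.9)
})

test_that("arterial and venous slices segment exactly their vessels", {
  co <- make_cohort(1, 1, seed = 10)
  lart <- segment_series(co[[1]]$arterial)
  lven <- segment_series(co[[1]]$venous)
  expect_setequal(names(lart), c("BT", "RC", "LC"))
  expect_setequal(names(lven), c("SS", "StS"))
})

test_that("frames with a sub-threshold seed propagate as missing samples", {
  s <- ya_subject()
  p <- ya_params()["BT"]
  r <- small_render(s, p, noise_sd = 0, n_frames = 5)
  ds <- r$dataset
  ds$magnitude[, , 3] <- 0  # kill one frame
  lum <- segment_series(ds)
  expect_false(lum$BT$area$detected[3])
  ser <- vessel_series(ds, lum$BT, "BT")
  expect_true(is.na(ser$flow_ul_s[3]))
  expect_false(anyNA(ser$flow_ul_s[-3]))
})
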