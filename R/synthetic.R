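#' Subject descriptor for a synthetic acquisition
#'
#' @param subject_id character id
#' @param age_group "YA" (young adult) or "OA" (old adult)
#' @param sex "M" or "F"
#' @param weight_g body weight (g)
#' @param heart_rate_bpm heart rate (beats/min)
#' @param gm_ul,wm_ul,csf_ul grey-matter, white-matter and CSF volumes
#'   (microlitres), as obtained from anatomical tissue segmentation
#' @param rng_seed integer seed recorded for provenance
#' @return object of class `subject_spec`
#' @export
subject_spec <- function(subject_id, age_group, sex, weight_g, heart_rate_bpm,
                         gm_ul, wm_ul, csf_ul, rng_seed = NA_integer_) {
  age_group <- match.arg(age_group, c("YA", "OA"))
  sex <- match.arg(sex, c("M", "F"))
  stopifnot(heart_rate_bpm > 0, weight_g > 0, gm_ul > 0, wm_ul > 0, csf_ul > 0)
  structure(
    list(subject_id = subject_id, age_group = age_group, sex = sex,
         weight_g = weight_g, heart_rate_bpm = heart_rate_bpm,
         gm_ul = gm_ul, wm_ul = wm_ul, csf_ul = csf_ul,
         rng_seed = as.integer(rng_seed)),
    class = "subject_spec"
  )
}

#' RR interval (ms) of a subject
#' @param subject a [subject_spec()]
#' @return RR interval in milliseconds
#' @export
rr_interval_ms <- function(subject) 60000 / subject$heart_rate_bpm

# ---------------------------------------------------------------------------
# Cohort calibration table.
#
# Group-level means/SDs the generator is calibrated to: per-vessel per-cycle
# volumes, peak cycle positions, pulsatility-index targets, heart rate, body
# weight, tissue volumes, cycle coverage, and lumen sizes (as voxel counts at
# 150 um in-plane resolution). One list per age group; never modified at run
# time.
.cohort_defaults <- list(
  YA = list(
    hr = c(mean = 189, sd = 58),
    weight = c(mean = 373, sd = 41),
    gm = c(mean = 4084, sd = 628),
    wm = c(mean = 2669, sd = 260),
    csf = c(mean = 941, sd = 335),
    coverage = c(mean = 0.792, sd = 0.058),
    volume = list(BT = c(19.0, 4.3), RC = c(13.2, 5.1), LC = c(15.5, 4.5),
                  SS = c(6.2, 3.7), StS = c(6.8, 1.8)),
    peak = list(BT = c(27.0, 4.0), RC = c(33.0, 4.0), LC = c(32.0, 4.0),
                SS = c(44.2, 15.6), StS = c(38.4, 9.0)),
    pi_target = c(BT = 1.48, RC = 1.03, LC = 1.29, SS = 0.35, StS = 0.35),
    lumen_vox = c(BT = 28, RC = 20, LC = 25, SS = 22, StS = 23),
    notch = c(mean = 53.125, sd = 2.0)
  ),
  OA = list(
    hr = c(mean = 152, sd = 42),
    weight = c(mean = 391, sd = 38),
    gm = c(mean = 4256, sd = 466),
    wm = c(mean = 2831, sd = 292),
    csf = c(mean = 1119, sd = 337),
    coverage = c(mean = 0.698, sd = 0.159),
    volume = list(BT = c(30.3, 6.7), RC = c(19.3, 6.7), LC = c(19.5, 9.0),
                  SS = c(5.6, 2.4), StS = c(5.7, 3.2)),
    peak = list(BT = c(21.5, 3.0), RC = c(27.0, 3.0), LC = c(26.5, 3.0),
                SS = c(33.5, 5.0), StS = c(28.6, 4.9)),
    pi_target = c(BT = 1.51, RC = 1.37, LC = 1.65, SS = 0.50, StS = 0.50),
    lumen_vox = c(BT = 31, RC = 22, LC = 23, SS = 13, StS = 14),
    notch = c(mean = 53.125, sd = 2.0)
  )
)

# Baseline fraction that yields a target pulsatility index for a given unit
# shape: PI = (max - min)/mean = 1/(b + mean(s)) with min = b, max = b + 1.
.baseline_for_pi <- function(params_proto, pi_target) {
  s <- .unit_shape_dense(params_proto)
  b <- max(0.02, 1 / pi_target - mean(s))
  b / (b + 1)
}

# Peak lumen-mean velocity targets (cm/s) that set vessel caliber: lumen area
# scales with each subject's peak flow so that peak mean velocity is constant
# across subjects (velocity homeostasis). Keeps velocities safely inside the
# one-sided VENC (50 cm/s arteries, 20 cm/s sinuses) for every subject.
.PEAK_VBAR_TARGET <- c(arterial = 18, venous = 5)

.rlnorm_m <- function(n, mean, sd) {
  cv <- sd / mean
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

.rnorm_trunc <- function(mean, sd, lo, hi) {
  for (i in 1:50) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

#' Default waveform parameter set for one subject
#'
#' Draws per-vessel ground-truth waveform parameters for a subject of the
#' given age group. Two physiological couplings to the subject's RR interval
#' are built in, both required to reproduce the dispersion of the published
#' group statistics: (1) per-cycle volume scales as `sqrt(rr / rr_group)`
#' with the residual lognormal jitter reduced accordingly — per-cycle stroke
#' volumes anti-correlate with heart rate, which is why the published
#' perfusion CV (0.26) is far below the independent combination of the
#' volume and heart-rate CVs; (2) systolic timing (peak, pulse width,
#' dicrotic notch, expressed in %CC) scales as `sqrt(rr_group / rr)` —
#' ejection time varies much less than the RR interval. On top of the
#' couplings, peaks get truncated-normal jitter and baselines are solved from
#' the group pulsatility-index targets. Lumen caliber derives from each
#' subject's peak flow via a fixed peak mean-velocity target.
#'
#' @param age_group "YA" or "OA"
#' @param rr_ms RR interval (ms) of the subject; sets the flow scale, the
#'   timing couplings and the lumen caliber
#' @param jitter logical; `FALSE` suppresses the random jitter (the
#'   deterministic RR couplings still apply)
#' @return named list of [waveform_params()], one per vessel
#' @export
default_waveform_params <- function(age_group = c("YA", "OA"),
                                    rr_ms = 60000 / 189, jitter = TRUE) {
  age_group <- match.arg(age_group)
  cal <- .cohort_defaults[[age_group]]
  pi_jitter_cv <- 0.2
  rr_g <- 60000 / cal$hr[[1]]
  cv_hr <- cal$hr[[2]] / cal$hr[[1]]
  fscale <- min(1.3, max(0.8, sqrt(rr_g / rr_ms)))
  out <- list()
  for (v in ALL_VESSELS) {
    vol <- cal$volume[[v]]
    pk <- cal$peak[[v]]
    cv_vol <- vol[2] / vol[1]
    resid_cv <- sqrt(max(cv_vol^2 - 0.25 * cv_hr^2, 0.12^2))
    volume <- vol[1] * sqrt(rr_ms / rr_g) *
      (if (jitter) .rlnorm_m(1, 1, resid_cv) else 1)
    peak <- pk[1] * fscale + (if (jitter) stats::rnorm(1, 0, pk[2]) else 0)
    # peaks stay in the physiologic window: arterial peaks are systolic;
    # venous peaks follow within the covered two-thirds of the cycle
    peak <- min(if (is_venous(v)) 65 else 50, max(12, peak))
    notch <- if (is_venous(v)) NA_real_ else {
      n0 <- cal$notch[1] * fscale + (if (jitter) stats::rnorm(1, 0, 2) else 0)
      min(72, max(peak + 8, n0))
    }
    width <- 12 * fscale
    pi_t <- cal$pi_target[[v]]
    if (jitter) pi_t <- .rlnorm_m(1, pi_t, pi_jitter_cv * pi_t)
    proto <- waveform_params(v, volume, peak, pulse_width_pct = width,
                             notch_pct_cc = notch)
    bf <- .baseline_for_pi(proto, pi_t)
    proto <- waveform_params(v, volume, peak, pulse_width_pct = width,
                             baseline_fraction = bf, notch_pct_cc = notch)
    # lumen caliber from the peak-velocity target: area (mm^2) such that
    # peak flow / area = 10 * target cm/s
    vbar <- .PEAK_VBAR_TARGET[[if (is_venous(v)) "venous" else "arterial"]]
    peak_flow <- waveform_truth(proto, rr_ms)$peak_flow_ul_s
    # caliber floor 0.34 mm (~2.27 px at 150 um): keeps the rasterized disk
    # essentially invariant under the segmentation-stage cleanup
    radius <- max(0.34, sqrt(peak_flow / (10 * vbar) / pi))
    out[[v]] <- waveform_params(v, volume, peak, pulse_width_pct = width,
                                baseline_fraction = bf,
                                notch_pct_cc = notch,
                                lumen_radius_mm = radius)
  }
  out
}

# Fixed seed-voxel layout (row, col) on the 200 x 160 grid; vessels separated
# well beyond any plausible lumen + noise halo.
.default_seeds <- list(
  arterial = list(BT = c(100, 50), RC = c(70, 110), LC = c(130, 110)),
  venous = list(SS = c(80, 80), StS = c(130, 80))
)

#' Default seed-voxel layout for a slice
#' @param slice_kind "arterial" or "venous"
#' @return named list of `(row, col)` integer pairs
#' @export
default_vessel_seeds <- function(slice_kind = c("arterial", "venous")) {
  .default_seeds[[match.arg(slice_kind)]]
}

#' Construct a cine dataset object
#'
#' @param slice_kind "arterial" or "venous"
#' @param magnitude,phase 3-D arrays (row, col, frame); phase in radians,
#'   range `(-pi, pi]`
#' @param venc_cm_s velocity-encoding limit (cm/s); velocity that maps to
#'   a phase of pi
#' @param frame_times_ms per-frame acquisition times after the R-wave (ms)
#' @param rr_ms RR interval (ms)
#' @param pixel_mm in-plane pixel size `(dy, dx)` in mm
#' @param slice_thickness_mm slice thickness (mm)
#' @param vessel_seeds named list of seed voxels `(row, col)` per vessel
#' @return object of class `cine_dataset`
#' @export
cine_dataset <- function(slice_kind, magnitude, phase, venc_cm_s,
                         frame_times_ms, rr_ms, pixel_mm = c(0.15, 0.15),
                         slice_thickness_mm = 1, vessel_seeds) {
  slice_kind <- match.arg(slice_kind, c("arterial", "venous"))
  stopifnot(
    length(dim(magnitude)) == 3, identical(dim(magnitude), dim(phase)),
    dim(magnitude)[3] == length(frame_times_ms),
    length(frame_times_ms) >= 3,
    !is.unsorted(frame_times_ms, strictly = TRUE),
    max(frame_times_ms) < rr_ms,
    all(magnitude >= 0),
    all(phase > -pi - 1e-9 & phase <= pi + 1e-9)
  )
  structure(
    list(slice_kind = slice_kind, magnitude = magnitude, phase = phase,
         venc_cm_s = venc_cm_s, frame_times_ms = frame_times_ms,
         rr_ms = rr_ms, pixel_mm = pixel_mm,
         slice_thickness_mm = slice_thickness_mm,
         vessel_seeds = vessel_seeds),
    class = "cine_dataset"
  )
}

#' Expected vessels on a slice
#' @param slice_kind "arterial" or "venous"
#' @return character vector of vessel names
#' @export
slice_vessels <- function(slice_kind) {
  if (slice_kind == "arterial") ARTERIAL_VESSELS else VENOUS_VESSELS
}

# Rasterize a disk: voxel offsets (relative to the seed) whose centres lie
# within radius_mm. Returns a data.frame of di, dj, and centre distance (mm).
.disk_offsets <- function(radius_mm, pixel_mm) {
  m <- ceiling(radius_mm / min(pixel_mm))
  g <- expand.grid(di = -m:m, dj = -m:m)
  d <- sqrt((g$di * pixel_mm[1])^2 + (g$dj * pixel_mm[2])^2)
  keep <- d <= radius_mm
  data.frame(di = g$di[keep], dj = g$dj[keep], d_mm = d[keep])
}

#' Render a gated cine phase-contrast acquisition of one slice
#'
#' Produces magnitude and phase frame stacks for the vessels whose waveform
#' parameters are supplied. Each vessel is a filled disk at its seed voxel with
#' a parabolic (Poiseuille) through-plane velocity profile, discretely rescaled
#' so that lumen-mean velocity times lumen area reproduces the ground-truth
#' flow at every frame time. Velocity is encoded as phase = pi * v / VENC;
#' complex Gaussian noise of standard deviation `noise_sd` is added to the
#' real and imaginary channels before magnitude/phase extraction, so magnitude
#' noise is Rician. Acquisition starts at the R-wave (t = 0) and covers
#' `coverage_fraction` of the cycle.
#'
#' @param subject a [subject_spec()]
#' @param waveforms named list of [waveform_params()] for the vessels of one
#'   slice (all arterial or all venous)
#' @param noise_sd complex-channel noise standard deviation (a.u.)
#' @param coverage_fraction fraction of the cardiac cycle covered, in
#'   `[0.5, 1]`
#' @param n_frames number of frames (>= 3)
#' @param venc_cm_s velocity-encoding limit; defaults to 50 cm/s for the
#'   arterial slice and 20 cm/s for the venous slice
#' @param signal_amplitude lumen magnitude signal amplitude (a.u.)
#' @param img_dim image grid `(rows, cols)`
#' @param pixel_mm in-plane pixel size `(dy, dx)` in mm
#' @param area_pulse_fraction peak relative modulation of lumen area over the
#'   cycle (0 = constant lumen)
#' @param vessel_seeds optional named list of seed voxels; defaults to the
#'   fixed slice layout
#' @return list with elements `dataset` (a [cine_dataset()]) and `truth`
#'   (a `ground_truth` list: dense true waveforms, true lumen areas and voxel
#'   counts, true flows/velocities/areas at the frame times, true peak and
#'   notch positions)
#' @export
render_cine <- function(subject, waveforms, noise_sd = 0.5,
                        coverage_fraction = 0.75, n_frames = 16,
                        venc_cm_s = NULL, signal_amplitude = 10,
                        img_dim = c(200, 160), pixel_mm = c(0.15, 0.15),
                        area_pulse_fraction = 0, vessel_seeds = NULL) {
  stopifnot(inherits(subject, "subject_spec"),
            coverage_fraction >= 0.5, coverage_fraction <= 1,
            n_frames >= 3, noise_sd >= 0)
  vessels <- vapply(waveforms, `[[`, "", "vessel")
  names(waveforms) <- vessels
  ven <- is_venous(vessels)
  if (any(ven) && !all(ven))
    stop("waveforms must be all arterial or all venous (one slice)")
  slice_kind <- if (all(ven)) "venous" else "arterial"
  if (is.null(venc_cm_s)) venc_cm_s <- if (slice_kind == "venous") 20 else 50
  if (is.null(vessel_seeds)) vessel_seeds <- default_vessel_seeds(slice_kind)
  if (!all(vessels %in% names(vessel_seeds)))
    stop("missing seed for some vessel")

  rr <- rr_interval_ms(subject)
  t_end <- coverage_fraction * rr
  if (t_end >= rr) t_end <- rr * (1 - 1 / n_frames)  # keep last frame inside the cycle
  ft <- seq(0, t_end, length.out = n_frames)
  t_pct <- 100 * ft / rr
  pix_area <- pixel_mm[1] * pixel_mm[2]

  mag <- array(0, dim = c(img_dim, n_frames))
  vel_cm <- array(0, dim = c(img_dim, n_frames))

  truth_wave <- lapply(waveforms, waveform_truth, rr_ms = rr)
  truth_lumen <- list()
  flows_at_frames <- list()
  areas_at_frames <- list()

  for (v in vessels) {
    wp <- waveforms[[v]]
    seed <- vessel_seeds[[v]]
    q <- make_waveform(wp, t_pct, rr)           # ul/s at frame times
    # optional lumen-area pulsation synchronized with the flow waveform
    if (area_pulse_fraction > 0) {
      z <- (q - mean(q)) / max(abs(q - mean(q)))
      r_t <- wp$lumen_radius_mm * sqrt(1 + area_pulse_fraction * z)
    } else {
      r_t <- rep(wp$lumen_radius_mm, n_frames)
    }
    n_vox_t <- integer(n_frames)
    for (f in seq_len(n_frames)) {
      off <- .disk_offsets(r_t[f], pixel_mm)
      rows <- seed[1] + off$di
      cols <- seed[2] + off$dj
      if (any(rows < 1 | rows > img_dim[1] | cols < 1 | cols > img_dim[2]))
        stop("vessel disk extends beyond the image grid")
      n_vox <- nrow(off)
      n_vox_t[f] <- n_vox
      area <- n_vox * pix_area
      vbar_mm_s <- q[f] / area                  # ul/s / mm^2 = mm/s
      prof <- 1 - (off$d_mm / r_t[f])^2
      prof <- prof / mean(prof)                 # discrete lumen mean = 1
      v_cm <- vbar_mm_s * prof / 10
      if (any(abs(v_cm) >= venc_cm_s))
        stop(sprintf("velocity aliasing: vessel %s exceeds VENC %g cm/s", v,
                     venc_cm_s))
      idx <- cbind(rows, cols, f)
      mag[idx] <- mag[idx] + signal_amplitude
      vel_cm[idx] <- vel_cm[idx] + v_cm
    }
    truth_lumen[[v]] <- list(
      n_voxels = n_vox_t,
      area_raster_mm2 = n_vox_t * pix_area,
      area_geom_mm2 = pi * wp$lumen_radius_mm^2,
      seed = seed
    )
    flows_at_frames[[v]] <- q
    areas_at_frames[[v]] <- n_vox_t * pix_area
  }

  phase_true <- pi * vel_cm / venc_cm_s
  re <- mag * cos(phase_true)
  im <- mag * sin(phase_true)
  if (noise_sd > 0) {
    re <- re + stats::rnorm(length(re), 0, noise_sd)
    im <- im + stats::rnorm(length(im), 0, noise_sd)
  }
  z_mag <- sqrt(re^2 + im^2)
  z_phase <- atan2(im, re)

  ds <- cine_dataset(slice_kind, z_mag, z_phase, venc_cm_s, ft, rr,
                     pixel_mm, 1, vessel_seeds[vessels])
  truth <- structure(
    list(subject_id = subject$subject_id, slice_kind = slice_kind,
         rr_ms = rr, frame_times_ms = ft,
         params = waveforms, waveforms = truth_wave, lumen = truth_lumen,
         flow_at_frames = flows_at_frames, area_at_frames = areas_at_frames,
         volumes_ul = vapply(truth_wave, `[[`, 0, "volume_ul"),
         peak_pct_cc = vapply(truth_wave, `[[`, 0, "peak_pct_cc"),
         noise_sd = noise_sd),
    class = "ground_truth"
  )
  list(dataset = ds, truth = truth)
}

#' Generate a synthetic two-group cohort
#'
#' Draws `n_young` young-adult and `n_old` old-adult subjects with
#' between-subject lognormal jitter around the group calibration table, and
#' renders the arterial and venous cine acquisitions for each. The number of
#' frames follows a fixed 15 ms frame interval (clipped to 12-22 frames), and
#' the covered fraction of the cycle is drawn per subject around the group
#' mean. Fully reproducible for a given seed.
#'
#' @param n_young,n_old group sizes (>= 1)
#' @param seed integer RNG seed
#' @param noise_sd complex-channel noise SD passed to [render_cine()]
#' @param ... further arguments passed to [render_cine()]
#' @return object of class `cine_cohort`: list of per-subject bundles with
#'   elements `spec`, `arterial`, `venous` (cine datasets) and `truth`
#'   (named list with the arterial and venous ground truths)
#' @export
make_cohort <- function(n_young, n_old, seed, noise_sd = 0.5, ...) {
  stopifnot(n_young >= 1, n_old >= 1)
  set.seed(seed)
  groups <- c(rep("YA", n_young), rep("OA", n_old))
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[i]
    cal <- .cohort_defaults[[g]]
    spec <- subject_spec(
      subject_id = sprintf("%s%02d", g, sum(groups[1:i] == g)),
      age_group = g,
      sex = if (stats::runif(1) < 0.58) "M" else "F",
      weight_g = .rlnorm_m(1, cal$weight[1], cal$weight[2]),
      heart_rate_bpm = .rlnorm_m(1, cal$hr[1], cal$hr[2]),
      gm_ul = .rlnorm_m(1, cal$gm[1], cal$gm[2]),
      wm_ul = .rlnorm_m(1, cal$wm[1], cal$wm[2]),
      csf_ul = .rlnorm_m(1, cal$csf[1], cal$csf[2]),
      rng_seed = (seed + 7919L * i) %% .Machine$integer.max
    )
    coverage <- .rnorm_trunc(cal$coverage[1], cal$coverage[2], 0.55, 0.92)
    rr <- rr_interval_ms(spec)
    n_frames <- min(22L, max(12L, as.integer(round(coverage * rr / 15)) + 1L))
    wp <- default_waveform_params(g, rr_ms = rr, jitter = TRUE)
    art <- render_cine(spec, wp[ARTERIAL_VESSELS], noise_sd = noise_sd,
                       coverage_fraction = coverage, n_frames = n_frames, ...)
    ven <- render_cine(spec, wp[VENOUS_VESSELS], noise_sd = noise_sd,
                       coverage_fraction = coverage, n_frames = n_frames, ...)
    out[[i]] <- list(spec = spec, arterial = art$dataset, venous = ven$dataset,
                     truth = list(arterial = art$truth, venous = ven$truth))
  }
  structure(out, class = "cine_cohort", seed = seed)
}
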