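# Shared small fixtures. Unit tests render on a reduced 64x64 grid with a
# compact seed layout so each render costs milliseconds; full-size defaults
# are exercised in the pipeline/acceptance tests.

small_seeds <- list(
  arterial = list(BT = c(32, 16), RC = c(16, 44), LC = c(48, 44)),
  venous = list(SS = c(20, 32), StS = c(44, 32))
)

small_render <- function(subject, waveforms, slice = "arterial", ...) {
  render_cine(subject, waveforms, img_dim = c(64, 64),
              vessel_seeds = small_seeds[[slice]], ...)
}

ya_subject <- function(hr = 189) {
  subject_spec("YA_fix", "YA", "M", weight_g = 373, heart_rate_bpm = hr,
               gm_ul = 4084, wm_ul = 2669, csf_ul = 941, rng_seed = 1L)
}

ya_params <- function() {
  # deterministic group-mean waveform parameters
  default_waveform_params("YA", rr_ms = 60000 / 189, jitter = FALSE)
}

# constant-flow single-vessel waveform: near-degenerate pulse on a high
# baseline gives almost-flat flow
flat_params <- function(vessel = "BT", volume = 20) {
  waveform_params(vessel, volume, peak_pct_cc = 30,
                  baseline_fraction = 1 - 1e-6, notch_pct_cc = 53.125)
}

# a profile from explicit flow values
profile_of <- function(flow, rr_ms = 400, vessel = "BT") {
  flow_profile32(vessel, flow, rr_ms)
}

# analytic pixelated-disk voxel count: centres within radius_mm of the seed
pixelated_disk_count <- function(radius_mm, pixel_mm = 0.15) {
  m <- ceiling(radius_mm / pixel_mm)
  g <- expand.grid(i = -m:m, j = -m:m)
  sum(sqrt(g$i^2 + g$j^2) * pixel_mm <= radius_mm)
}

# analytic count after the seeded 3x3 opening applied to the ideal pixelated
# disk (erode to the core, dilate by one Chebyshev step, clip to the disk);
# computed set-wise, independently of the package's matrix morphology
opened_disk_count <- function(radius_mm, pixel_mm = 0.15) {
  m <- ceiling(radius_mm / pixel_mm) + 1
  g <- expand.grid(i = -m:m, j = -m:m)
  inside <- sqrt(g$i^2 + g$j^2) * pixel_mm <= radius_mm
  key <- function(i, j) paste(i, j)
  disk <- key(g$i[inside], g$j[inside])
  in_disk <- function(i, j) key(i, j) %in% disk
  core <- mapply(function(i, j) {
    all(vapply(-1:1, function(di) all(vapply(-1:1, function(dj)
      in_disk(i + di, j + dj), TRUE)), TRUE))
  }, g$i[inside], g$j[inside])
  core_i <- g$i[inside][core]; core_j <- g$j[inside][core]
  near_core <- mapply(function(i, j)
    any(abs(i - core_i) <= 1 & abs(j - core_j) <= 1),
    g$i[inside], g$j[inside])
  sum(near_core)
}
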