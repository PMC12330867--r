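#' Decode velocity from a phase image
#'
#' Standard one-sided linear phase-contrast mapping: a phase of pi corresponds
#' to the velocity-encoding limit, so `v = venc * phase / pi` (cm/s), sign
#' preserved (flow direction).
#'
#' @param phase phase values in radians, range `(-pi, pi]` (vectorized)
#' @param venc_cm_s velocity-encoding limit (cm/s)
#' @return velocities in cm/s, same shape as `phase`
#' @export
decode_velocity <- function(phase, venc_cm_s) {
  if (any(phase <= -pi - 1e-9 | phase > pi + 1e-9, na.rm = TRUE))
    stop("phase must lie within (-pi, pi]")
  stopifnot(venc_cm_s > 0)
  venc_cm_s * phase / pi
}

#' Per-frame lumen-mean velocity and flow for one vessel
#'
#' Velocity at each cycle step is the arithmetic mean of the decoded voxel
#' velocities inside the lumen mask (mean over the section, not the maximum
#' voxel). Flow is mean velocity (cm/s) times 10 times lumen area (mm^2),
#' giving mm^3/s = microlitres/s. Frames on which the vessel was not detected
#' are emitted with `NA` flow (missing samples, recorded rather than dropped).
#' Voxels with decoded speed above 95% of VENC raise a near-aliasing flag.
#'
#' @param dataset a [cine_dataset()]
#' @param lumen element of a [segment_series()] result for one vessel
#'   (list with `masks` and `area`), frames aligned with the dataset
#' @param vessel vessel name
#' @return object of class `vessel_time_series`: data.frame with columns
#'   vessel, frame, time_ms, pct_cc, n_voxels, area_mm2, mean_velocity_cm_s,
#'   flow_ul_s, detected, near_aliasing; attributes `rr_ms`, `vessel`
#' @export
vessel_series <- function(dataset, lumen, vessel) {
  stopifnot(inherits(dataset, "cine_dataset"))
  n_frames <- dim(dataset$phase)[3]
  if (length(lumen$masks) != n_frames)
    stop("masks do not align with dataset frames")
  mv <- rep(NA_real_, n_frames)
  near <- rep(FALSE, n_frames)
  for (f in seq_len(n_frames)) {
    m <- lumen$masks[[f]]
    if (!isTRUE(m$detected)) next
    ph <- dataset$phase[, , f][m$voxels]
    v <- decode_velocity(ph, dataset$venc_cm_s)
    mv[f] <- mean(v)
    near[f] <- any(abs(v) > 0.95 * dataset$venc_cm_s)
  }
  area <- lumen$area$area_mm2
  out <- data.frame(
    vessel = vessel,
    frame = seq_len(n_frames),
    time_ms = dataset$frame_times_ms,
    pct_cc = 100 * dataset$frame_times_ms / dataset$rr_ms,
    n_voxels = lumen$area$n_voxels,
    area_mm2 = area,
    mean_velocity_cm_s = mv,
    flow_ul_s = mv * 10 * area,
    detected = lumen$area$detected,
    near_aliasing = near
  )
  structure(out, class = c("vessel_time_series", "data.frame"),
            rr_ms = dataset$rr_ms, vessel = vessel)
}

#' Vessel time series for every vessel of a dataset
#'
#' Convenience wrapper: segments the dataset (unless masks are supplied) and
#' computes [vessel_series()] for each expected vessel of the slice.
#'
#' @param dataset a [cine_dataset()]
#' @param lumen optional precomputed [segment_series()] result
#' @param ... passed to [segment_series()]
#' @return named list of `vessel_time_series`
#' @export
quantify_dataset <- function(dataset, lumen = NULL, ...) {
  if (is.null(lumen)) lumen <- segment_series(dataset, ...)
  vessels <- intersect(slice_vessels(dataset$slice_kind),
                       names(dataset$vessel_seeds))
  out <- lapply(vessels, function(v) vessel_series(dataset, lumen[[v]], v))
  names(out) <- vessels
  out
}
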