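#' Per-cycle blood volume of a profile
#'
#' Sum of the elementary volumes delivered during each of the 32 cycle steps:
#' `V = sum_k flow_k * (rr_ms / 32) / 1000` (microlitres/s times step
#' duration in seconds).
#'
#' @param profile a [flow_profile32()]
#' @return volume in microlitres per cardiac cycle
#' @export
cycle_volume <- function(profile) {
  stopifnot(inherits(profile, "flow_profile32"))
  sum(profile$flow_ul_s) * (profile$rr_ms / CC_STEPS) / 1000
}

#' Perfusion, drainage and cerebral blood flow
#'
#' Perfusion normalizes the arterial input per minute:
#' `perfusion = total arterial volume (ul/cycle) * HR (bpm) / 1000` ml/min,
#' and likewise drainage from the venous total. CBF divides perfusion by the
#' brain tissue mass, `(gm + wm) ul / 1000 * 1.05 g/ml` (mean brain tissue
#' density), reported per 100 g.
#'
#' @param volumes_ul named per-vessel volumes (microlitres/cycle) including
#'   the arterial vessels BT, RC, LC and/or the sinuses SS, StS
#' @param subject a [subject_spec()]
#' @return list with `perfusion_ml_min`, `drainage_ml_min`,
#'   `cbf_ml_min_100g`, `tissue_mass_g`
#' @export
perfusion_and_cbf <- function(volumes_ul, subject) {
  stopifnot(inherits(subject, "subject_spec"))
  art <- intersect(names(volumes_ul), ARTERIAL_VESSELS)
  ven <- intersect(names(volumes_ul), VENOUS_VESSELS)
  hr <- subject$heart_rate_bpm
  perf <- if (length(art)) sum(volumes_ul[art]) * hr / 1000 else NA_real_
  drain <- if (length(ven)) sum(volumes_ul[ven]) * hr / 1000 else NA_real_
  mass_g <- (subject$gm_ul + subject$wm_ul) / 1000 * 1.05
  if (mass_g <= 0) stop("zero brain tissue mass")
  list(perfusion_ml_min = perf, drainage_ml_min = drain,
       cbf_ml_min_100g = perf / mass_g * 100, tissue_mass_g = mass_g)
}

#' Allometric perfusion prediction
#'
#' Scaling law for primate brain perfusion as a function of brain volume:
#' `perfusion (ml/min) = brain_volume (ml) ^ 0.95`.
#'
#' @param brain_volume_ml brain volume in ml
#' @return predicted perfusion in ml/min
#' @export
seymour_prediction <- function(brain_volume_ml) {
  stopifnot(all(brain_volume_ml > 0))
  brain_volume_ml^0.95
}

#' Arterio-venous volume balance over the cardiac cycle
#'
#' The measured venous outflow underestimates total drainage (peripheral
#' veins are not imaged), so the venous profile is first corrected by the
#' factor `CF = V_art / V_ven` (ratio of arterial to venous per-cycle
#' volume), equating the two volumes per cycle. The step-wise balance is then
#' `balance_k = (art_k - CF * ven_k) * dt` (microlitres; dt = step duration),
#' alternating between blood surplus (positive) and deficit (negative). Its
#' running sum (cumulative balance) closes at zero at step 32 by construction
#' of CF; the oscillating volume is the peak-to-peak range of the cumulative
#' curve — the blood volume the craniospinal system must buffer (e.g. by CSF
#' displacement) each cycle under the Monro-Kellie constraint.
#'
#' @param art,ven composite arterial and venous [flow_profile32()] of the
#'   same subject (equal `rr_ms`)
#' @param oscillating `"peak_to_peak"` (default) or `"max_excursion"`
#'   (maximum positive excursion of the cumulative curve)
#' @return list with `CF`, `balance_ul` (32), `cumulative_balance_ul` (32),
#'   `oscillating_volume_ul`
#' @export
av_balance <- function(art, ven, oscillating = c("peak_to_peak",
                                                 "max_excursion")) {
  oscillating <- match.arg(oscillating)
  stopifnot(inherits(art, "flow_profile32"), inherits(ven, "flow_profile32"))
  if (abs(art$rr_ms - ven$rr_ms) > 1e-9 * art$rr_ms)
    stop("arterial and venous profiles have different rr_ms")
  v_art <- cycle_volume(art)
  v_ven <- cycle_volume(ven)
  if (v_ven <= 0) stop("venous cycle volume must be positive")
  cf <- v_art / v_ven
  dt_s <- art$rr_ms / CC_STEPS / 1000
  balance <- (art$flow_ul_s - cf * ven$flow_ul_s) * dt_s
  cumulative <- cumsum(balance)
  osc <- switch(oscillating,
                peak_to_peak = max(cumulative) - min(cumulative),
                max_excursion = max(c(0, cumulative)))
  list(CF = cf, balance_ul = balance, cumulative_balance_ul = cumulative,
       oscillating_volume_ul = osc)
}

#' Arterial-venous flow hysteresis loop and its area
#'
#' The ordered points `(art_k, ven_k)`, k = 1..32, closed by joining step 32
#' back to step 1, trace a loop in the flow-flow plane whose area indexes the
#' arterio-venous phase lag and the viscoelastic buffering of the cranial
#' system. The area is the absolute shoelace (signed polygon) area;
#' proportional profiles give a degenerate loop of area 0. Self-intersecting
#' loops are flagged.
#'
#' @param art,ven composite arterial and venous [flow_profile32()] of the
#'   same subject
#' @return list with `loop` (data.frame step, art_flow_ul_s, ven_flow_ul_s),
#'   `area` ((ul/s)^2), `self_intersecting` flag
#' @export
hysteresis_loop <- function(art, ven) {
  stopifnot(inherits(art, "flow_profile32"), inherits(ven, "flow_profile32"))
  x <- art$flow_ul_s
  y <- ven$flow_ul_s
  n <- length(x)
  j <- c(2:n, 1)
  area <- abs(sum(x * y[j] - x[j] * y)) / 2
  loop <- data.frame(step = seq_len(n), art_flow_ul_s = x, ven_flow_ul_s = y)
  list(loop = loop, area = area,
       self_intersecting = .polygon_self_intersects(x, y))
}

# Crossing test for the closed 32-gon (small n: pairwise segment checks).
.polygon_self_intersects <- function(x, y) {
  n <- length(x)
  seg <- cbind(x, y, x[c(2:n, 1)], y[c(2:n, 1)])
  cross <- function(ax, ay, bx, by, cx, cy)
    (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  for (i in 1:(n - 1)) for (k in (i + 1):n) {
    if (abs(i - k) %in% c(1, n - 1)) next  # adjacent edges share a vertex
    d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[k, 1], seg[k, 2])
    d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[k, 3], seg[k, 4])
    d3 <- cross(seg[k, 1], seg[k, 2], seg[k, 3], seg[k, 4], seg[i, 1], seg[i, 2])
    d4 <- cross(seg[k, 1], seg[k, 2], seg[k, 3], seg[k, 4], seg[i, 3], seg[i, 4])
    if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
        ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  }
  FALSE
}

#' Per-subject contributions of each vessel to input/output
#'
#' Percent of total arterial input carried by BT, RC, LC and the carotid
#' system (RC+LC), and percent of measured venous output carried by SS and
#' StS, for one subject. (Group-level tables report the mean of these
#' per-subject ratios; the ratio of group-mean volumes is a different
#' quantity and is computed separately where needed.)
#'
#' @param volumes_ul named per-vessel volumes (microlitres/cycle)
#' @return named list of percentages: `BT_pct`, `RC_pct`, `LC_pct`,
#'   `carotids_pct` (of arterial input); `SS_pct`, `StS_pct` (of venous
#'   output)
#' @export
input_fractions <- function(volumes_ul) {
  art <- intersect(ARTERIAL_VESSELS, names(volumes_ul))
  ven <- intersect(VENOUS_VESSELS, names(volumes_ul))
  out <- list()
  if (length(art)) {
    tot <- sum(volumes_ul[art])
    if (tot <= 0) stop("zero total arterial volume")
    for (v in art) out[[paste0(v, "_pct")]] <- 100 * volumes_ul[[v]] / tot
    if (all(c("RC", "LC") %in% art))
      out$carotids_pct <- 100 * (volumes_ul[["RC"]] + volumes_ul[["LC"]]) / tot
  }
  if (length(ven)) {
    tot <- sum(volumes_ul[ven])
    if (tot <= 0) stop("zero total venous volume")
    for (v in ven) out[[paste0(v, "_pct")]] <- 100 * volumes_ul[[v]] / tot
  }
  out
}

#' Full haemodynamic summary of one subject
#'
#' Assembles the per-vessel per-cycle volumes, totals, input/output
#' fractions, perfusion/drainage/CBF, and the arterio-venous coupling
#' quantities (CF, balance curves, oscillating volume, hysteresis loop) from
#' the five per-vessel profiles.
#'
#' @param profiles named list of [flow_profile32()] for BT, RC, LC, SS, StS
#' @param subject a [subject_spec()]
#' @param ... passed to [av_balance()]
#' @return object of class `subject_haemodynamics` (a list)
#' @export
subject_haemodynamics <- function(profiles, subject, ...) {
  stopifnot(all(ALL_VESSELS %in% names(profiles)))
  vol <- vapply(profiles[ALL_VESSELS], cycle_volume, 0)
  art <- sum_profiles(profiles[ARTERIAL_VESSELS])
  ven <- sum_profiles(profiles[VENOUS_VESSELS])
  totals <- c(arteries = sum(vol[ARTERIAL_VESSELS]),
              carotids = sum(vol[c("RC", "LC")]),
              sinuses = sum(vol[VENOUS_VESSELS]))
  pf <- perfusion_and_cbf(vol, subject)
  bal <- av_balance(art, ven, ...)
  hyst <- hysteresis_loop(art, ven)
  structure(
    list(subject_id = subject$subject_id, age_group = subject$age_group,
         sex = subject$sex, rr_ms = rr_interval_ms(subject),
         volumes_ul = vol, totals_ul = totals,
         fractions = input_fractions(vol),
         perfusion_ml_min = pf$perfusion_ml_min,
         drainage_ml_min = pf$drainage_ml_min,
         cbf_ml_min_100g = pf$cbf_ml_min_100g,
         CF = bal$CF, balance_ul = bal$balance_ul,
         cumulative_balance_ul = bal$cumulative_balance_ul,
         oscillating_volume_ul = bal$oscillating_volume_ul,
         osc_pct_csf = 100 * bal$oscillating_volume_ul / subject$csf_ul,
         hysteresis_area = hyst$area,
         hysteresis_self_intersecting = hyst$self_intersecting,
         art_profile = art, ven_profile = ven),
    class = "subject_haemodynamics"
  )
}
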