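#' Flow peak (point M) of a 32-step profile
#'
#' Argmax over the 32 steps; ties are broken by the earliest step.
#'
#' @param profile a [flow_profile32()]
#' @return list with `peak_flow_ul_s`, `peak_step`, `peak_pct_cc`
#' @export
find_peak <- function(profile) {
  stopifnot(inherits(profile, "flow_profile32"))
  k <- which.max(profile$flow_ul_s)  # which.max returns the first maximum
  list(peak_flow_ul_s = profile$flow_ul_s[k], peak_step = k,
       peak_pct_cc = profile$pct_cc[k])
}

#' Dicrotic notch (point D) of an arterial profile
#'
#' The notch marks the break between the steep and the slow decrease of
#' arterial flow at end-systole. It is located as the step after the peak
#' that maximizes the discrete second difference (the greatest slope break)
#' within the window (peak, 75 %CC]. Absent (with a reason) when no positive
#' second difference exists in the window.
#'
#' @param profile an arterial [flow_profile32()] whose peak occurs before
#'   50 %CC
#' @return list with `notch_step`, `notch_pct_cc` (NA when absent) and
#'   `reason`
#' @export
find_dicrotic_notch <- function(profile) {
  stopifnot(inherits(profile, "flow_profile32"))
  if (profile$vessel %in% VENOUS_VESSELS || identical(profile$vessel, "Ven"))
    stop("dicrotic notch is not defined for venous profiles")
  pk <- find_peak(profile)
  if (pk$peak_pct_cc >= 50)
    stop("no systolic peak before 50 %CC; notch undefined")
  f <- profile$flow_ul_s
  d2 <- c(NA, diff(f, differences = 2), NA)  # d2[k] = f[k+1] - 2 f[k] + f[k-1]
  window <- seq_len(CC_STEPS) > pk$peak_step & profile$pct_cc <= 75
  cand <- which(window & d2 > 0)
  if (length(cand) == 0) {
    return(list(notch_step = NA_integer_, notch_pct_cc = NA_real_,
                reason = "no positive slope break after the peak"))
  }
  k <- cand[which.max(d2[cand])]
  list(notch_step = k, notch_pct_cc = profile$pct_cc[k], reason = NULL)
}

#' Systolic upslope of a profile
#'
#' Flow increase from the start of the large systolic inflow (step 3 of the
#' cycle, 9.4 %CC) to the flow maximum, divided by the elapsed time:
#' `(peak_flow - flow[step 3]) / ((peak_step - 3) * rr_ms / 32 / 1000)` in
#' microlitres/s^2. Undefined (flagged) when the peak is at or before step 3.
#'
#' @param profile a [flow_profile32()]
#' @return list with `upslope_ul_s2` (NA when undefined) and `defined`
#' @export
upslope <- function(profile) {
  stopifnot(inherits(profile, "flow_profile32"))
  pk <- find_peak(profile)
  if (pk$peak_step <= 3)
    return(list(upslope_ul_s2 = NA_real_, defined = FALSE))
  dt_s <- (pk$peak_step - 3) * profile$rr_ms / CC_STEPS / 1000
  list(upslope_ul_s2 = (pk$peak_flow_ul_s - profile$flow_ul_s[3]) / dt_s,
       defined = TRUE)
}

#' Pulsatility and resistive indices of a profile
#'
#' `PI = (max - min) / mean` and `RI = (max - min) / max` (Pourcelot index),
#' computed over the 32 normalized steps. Undefined (flagged) for zero mean
#' (PI) or zero maximum (RI).
#'
#' @param profile a [flow_profile32()]
#' @return list with `PI`, `RI` (NA when undefined)
#' @export
pulsatility_indices <- function(profile) {
  stopifnot(inherits(profile, "flow_profile32"))
  f <- profile$flow_ul_s
  rng <- max(f) - min(f)
  PI <- if (mean(f) > 0) rng / mean(f) else NA_real_
  RI <- if (max(f) > 0) rng / max(f) else NA_real_
  list(PI = PI, RI = RI)
}

#' All waveform features of one profile
#'
#' @param profile a [flow_profile32()]
#' @return one-row data.frame: vessel, peak_flow_ul_s, peak_step,
#'   peak_pct_cc, notch_pct_cc (NA for venous/composite-venous profiles),
#'   upslope_ul_s2, PI, RI
#' @export
profile_features <- function(profile) {
  pk <- find_peak(profile)
  venous_like <- profile$vessel %in% c(VENOUS_VESSELS, "Ven")
  notch <- if (venous_like || pk$peak_pct_cc >= 50) NA_real_
           else find_dicrotic_notch(profile)$notch_pct_cc
  up <- upslope(profile)
  pi_ri <- pulsatility_indices(profile)
  data.frame(
    vessel = profile$vessel,
    peak_flow_ul_s = pk$peak_flow_ul_s,
    peak_step = pk$peak_step,
    peak_pct_cc = pk$peak_pct_cc,
    notch_pct_cc = notch,
    upslope_ul_s2 = up$upslope_ul_s2,
    PI = pi_ri$PI,
    RI = pi_ri$RI
  )
}

# Ordered vessel pairs reported for peak chronology (arrival-time lags).
.LAG_PAIRS <- list(
  c("BT", "RC"), c("BT", "LC"), c("BT", "SS"), c("LC", "SS"),
  c("StS", "SS"), c("Art", "Ven")
)

#' Pairwise peak-arrival lags for one subject
#'
#' `lag(v1 -> v2) = peak_pct_cc(v2) - peak_pct_cc(v1)` (percent CC) for the
#' ordered pairs BT->RC, BT->LC, BT->SS, LC->SS, StS->SS and Art->Ven. Pairs
#' with a missing vessel are omitted and recorded.
#'
#' @param features data.frame with columns `vessel` and `peak_pct_cc`
#'   (e.g. rbind of [profile_features()] rows, including composites)
#' @return data.frame with columns from_vessel, to_vessel, lag_pct_cc;
#'   attribute `omitted` lists pairs lacking a vessel
#' @export
peak_lags <- function(features) {
  stopifnot(nrow(features) >= 2)
  peaks <- stats::setNames(features$peak_pct_cc, features$vessel)
  rows <- list(); omitted <- character()
  for (p in .LAG_PAIRS) {
    if (all(p %in% names(peaks))) {
      rows[[length(rows) + 1]] <- data.frame(
        from_vessel = p[1], to_vessel = p[2],
        lag_pct_cc = unname(peaks[p[2]] - peaks[p[1]]))
    } else {
      omitted <- c(omitted, paste(p, collapse = "->"))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "omitted") <- omitted
  out
}
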