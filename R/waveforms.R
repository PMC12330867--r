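#' @keywords internal
"_PACKAGE"

# Vessel vocabulary. Arterial slice: basilar trunk (BT) and the right/left
# internal carotids (RC, LC). Venous slice: superior sagittal sinus (SS) and
# straight sinus (StS).
ARTERIAL_VESSELS <- c("BT", "RC", "LC")
VENOUS_VESSELS <- c("SS", "StS")
ALL_VESSELS <- c(ARTERIAL_VESSELS, VENOUS_VESSELS)

#' Is a vessel name a venous sinus?
#' @param vessel vessel name ("BT", "RC", "LC", "SS", "StS")
#' @return logical
#' @export
is_venous <- function(vessel) vessel %in% VENOUS_VESSELS

#' Ground-truth waveform parameters for one vessel
#'
#' Describes the periodic flow waveform of a single artery or sinus over one
#' cardiac cycle (CC), parameterized by its per-cycle blood volume, the cycle
#' position of its systolic peak, pulse width, diastolic baseline level, and
#' (arteries only) the dicrotic-notch position. The functional form is a
#' gamma-variate systolic pulse plus a smaller post-notch secondary bump for
#' arteries, and a delayed exponentially-smoothed (circularly convolved) pulse
#' for sinuses.
#'
#' @param vessel one of "BT", "RC", "LC", "SS", "StS"
#' @param volume_per_cc_ul blood volume conveyed per cardiac cycle (microlitres)
#' @param peak_pct_cc position of the flow maximum, percent of cardiac cycle
#' @param pulse_width_pct time-to-peak of the systolic pulse (percent of CC)
#' @param baseline_fraction diastolic baseline as a fraction of peak flow,
#'   in `[0, 1)`
#' @param notch_pct_cc dicrotic-notch position (percent of CC); arteries only
#' @param notch_amplitude secondary (post-notch) bump amplitude relative to the
#'   unit systolic peak; arteries only
#' @param venous_tau_pct time constant (percent of CC) of the causal
#'   exponential smoothing kernel applied to the venous pulse
#' @param lumen_radius_mm vessel lumen radius (mm), used by the cine renderer
#' @return object of class `waveform_params`
#' @export
waveform_params <- function(vessel,
                            volume_per_cc_ul,
                            peak_pct_cc,
                            pulse_width_pct = 12,
                            baseline_fraction = 0.3,
                            notch_pct_cc = NA_real_,
                            notch_amplitude = 0.2,
                            venous_tau_pct = 8,
                            lumen_radius_mm = 0.4) {
  vessel <- match.arg(vessel, ALL_VESSELS)
  stopifnot(
    volume_per_cc_ul > 0,
    peak_pct_cc > 0, peak_pct_cc < 100,
    pulse_width_pct > 0,
    baseline_fraction >= 0, baseline_fraction < 1,
    lumen_radius_mm > 0
  )
  if (!is_venous(vessel) && !is.na(notch_pct_cc)) {
    if (notch_pct_cc <= peak_pct_cc || notch_pct_cc >= 100)
      stop("notch_pct_cc must lie after the peak and inside the cycle")
  }
  structure(
    list(
      vessel = vessel,
      volume_per_cc_ul = volume_per_cc_ul,
      peak_pct_cc = peak_pct_cc,
      pulse_width_pct = pulse_width_pct,
      baseline_fraction = baseline_fraction,
      notch_pct_cc = if (is_venous(vessel)) NA_real_ else notch_pct_cc,
      notch_amplitude = notch_amplitude,
      venous_tau_pct = venous_tau_pct,
      lumen_radius_mm = lumen_radius_mm
    ),
    class = "waveform_params"
  )
}

# Unit-peak gamma-variate pulse on the %CC axis: zero before onset t0,
# maximum 1 at t0 + tp, shape exponent alpha.
.gamma_variate <- function(t, t0, tp, alpha = 3) {
  u <- (t - t0) / tp
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- u[pos]^alpha * exp(alpha * (1 - u[pos]))
  out
}

# Internal dense evaluation grid over one cycle (percent CC, half-open [0,100)).
.DENSE_PCT <- seq(0, 100 - 0.05, by = 0.05)

# Unit-peak arterial pulse shape (zero-baseline part): gamma-variate systolic
# pulse peaking at peak_pct plus a smaller secondary bump whose onset sits at
# the dicrotic notch and produces the steep-to-slow slope break there.
.arterial_shape <- function(t, peak_pct, width_pct, notch_pct, notch_amp) {
  t0 <- peak_pct - width_pct
  s <- .gamma_variate(t, t0, width_pct, alpha = 3)
  if (!is.na(notch_pct)) {
    s <- s + notch_amp * .gamma_variate(t, notch_pct, 6, alpha = 2)
  }
  s
}

# Unit-peak venous shape: the arterial-style gamma pulse circularly convolved
# with a causal exponential kernel (time constant tau %CC), then circularly
# shifted so its maximum falls exactly at peak_pct, and rescaled to unit peak.
.venous_shape_dense <- function(peak_pct, width_pct, tau_pct) {
  t <- .DENSE_PCT
  n <- length(t)
  base <- .gamma_variate(t, 25 - width_pct, width_pct, alpha = 3)
  kern <- exp(-t / tau_pct)
  kern <- kern / sum(kern)
  # circular convolution via FFT
  conv <- Re(stats::fft(stats::fft(base) * stats::fft(kern), inverse = TRUE)) / n
  conv[conv < 0] <- 0
  shift <- which.max(conv)
  target <- which.min(abs(t - peak_pct))
  conv <- conv[((seq_len(n) - 1 + (shift - target)) %% n) + 1]
  conv / max(conv)
}

# Dense unit-peak shape for any vessel; returns values on .DENSE_PCT.
.unit_shape_dense <- function(params) {
  if (is_venous(params$vessel)) {
    .venous_shape_dense(params$peak_pct_cc, params$pulse_width_pct,
                        params$venous_tau_pct)
  } else {
    s <- .arterial_shape(.DENSE_PCT, params$peak_pct_cc, params$pulse_width_pct,
                         params$notch_pct_cc, params$notch_amplitude)
    s / max(s)
  }
}

#' Evaluate a ground-truth flow waveform
#'
#' Returns instantaneous blood flow (microlitres/second) at positions `t_pct`
#' of the cardiac cycle. The waveform is `c * (b + s(t))` where `s` is the
#' unit-peak pulse shape, `b` the baseline level implied by
#' `baseline_fraction`, and `c` a scale fixed so that the integral of flow
#' over one full cycle equals `volume_per_cc_ul`.
#'
#' @param params a [waveform_params()] object
#' @param t_pct numeric vector of cycle positions in `[0, 100]` (percent CC),
#'   non-decreasing
#' @param rr_ms cardiac cycle duration (RR interval, milliseconds); needed to
#'   convert the per-cycle volume into a flow scale
#' @return numeric vector of flows (microlitres/second), same length as `t_pct`
#' @export
make_waveform <- function(params, t_pct, rr_ms) {
  stopifnot(inherits(params, "waveform_params"), rr_ms > 0)
  if (any(t_pct < 0 | t_pct > 100))
    stop("t_pct must lie within [0, 100] percent of the cardiac cycle")
  if (is.unsorted(t_pct))
    stop("t_pct grid must be non-decreasing")
  dense <- .waveform_dense(params, rr_ms)
  # periodic linear interpolation; 100 %CC wraps to 0
  tq <- t_pct %% 100
  stats::approx(
    x = c(.DENSE_PCT, 100),
    y = c(dense, dense[1]),
    xout = tq
  )$y
}

# Dense flow values (ul/s) on .DENSE_PCT, volume-calibrated.
.waveform_dense <- function(params, rr_ms) {
  s <- .unit_shape_dense(params)
  b <- params$baseline_fraction / (1 - params$baseline_fraction)
  w <- b + s
  # integral over one cycle in seconds: (rr_s / 100) * mean-sum over pct grid
  rr_s <- rr_ms / 1000
  step <- 0.05
  integ <- sum(w) * step * rr_s / 100
  (params$volume_per_cc_ul / integ) * w
}

#' True waveform summary (dense peak location and cycle integral)
#'
#' @param params a [waveform_params()] object
#' @param rr_ms RR interval (ms)
#' @return list with `peak_pct_cc`, `peak_flow_ul_s`, `volume_ul`,
#'   `min_flow_ul_s`, and the dense waveform (`pct`, `flow_ul_s`)
#' @export
waveform_truth <- function(params, rr_ms) {
  dense <- .waveform_dense(params, rr_ms)
  list(
    vessel = params$vessel,
    peak_pct_cc = .DENSE_PCT[which.max(dense)],
    peak_flow_ul_s = max(dense),
    min_flow_ul_s = min(dense),
    volume_ul = sum(dense) * 0.05 * (rr_ms / 1000) / 100,
    notch_pct_cc = params$notch_pct_cc,
    pct = .DENSE_PCT,
    flow_ul_s = dense
  )
}
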