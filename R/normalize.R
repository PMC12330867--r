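# The canonical cardiac-cycle grid: 32 steps, step k at k * 3.125 %CC
# (k = 1..32; step 32 = 100 %CC, i.e. the next R-wave). Step 3 sits at
# 9.375 %CC and step 8 at 25 %CC.
CC_STEPS <- 32L
CC_STEP_PCT <- 100 / 32

#' Cycle positions (percent CC) of the 32-step grid
#' @return numeric vector of length 32: `k * 3.125` for k = 1..32
#' @export
cc_grid_pct <- function() seq_len(CC_STEPS) * CC_STEP_PCT

#' Construct a 32-step flow profile
#'
#' @param vessel vessel (or composite, e.g. "Art", "Ven") label
#' @param flow_ul_s 32 flow values (microlitres/s) on the canonical grid
#' @param rr_ms RR interval (ms); one step lasts `rr_ms / 32`
#' @param extrapolated logical vector of length 32 marking steps that were
#'   extrapolated rather than interpolated (provenance)
#' @return object of class `flow_profile32`
#' @export
flow_profile32 <- function(vessel, flow_ul_s, rr_ms,
                           extrapolated = rep(FALSE, CC_STEPS)) {
  stopifnot(length(flow_ul_s) == CC_STEPS, rr_ms > 0,
            length(extrapolated) == CC_STEPS)
  structure(
    list(vessel = vessel, step = seq_len(CC_STEPS), pct_cc = cc_grid_pct(),
         flow_ul_s = as.numeric(flow_ul_s), rr_ms = rr_ms,
         extrapolated = extrapolated),
    class = "flow_profile32"
  )
}

#' Normalize a vessel time series onto the 32-step cycle grid
#'
#' Flow samples cover only part of the cycle (prospective gating from the
#' R-wave). Grid steps inside the sampled range are linear interpolations
#' between bracketing samples. Unsampled steps are filled by linear
#' extrapolation over the rest of the cycle; two modes are available.
#' `"periodic"` (default) closes the cycle: the waveform is periodic and the
#' first sample sits on the R-wave (t = 0), so the unsampled late-diastolic
#' span is interpolated linearly between the last sample and the next-cycle
#' R-wave sample — bounded by observed data at both ends. `"secant"`
#' continues the terminal trend instead, with the slope estimated by least
#' squares over the last `n_fit` samples (two noisy end samples alone would
#' propagate their error across the whole unsampled tail); extrapolated
#' sinus flow is then floored at 0 and arterial flow at the minimum observed
#' flow (the diastolic baseline), and steps before the first sample (rare)
#' extrapolate backward from the first `n_fit` samples likewise. Undetected
#' frames are treated as unsampled times.
#'
#' @param series a [vessel_series()] data.frame (or any data.frame with
#'   `pct_cc` and `flow_ul_s`), with `rr_ms` attribute or `rr_ms` supplied
#' @param extrapolation `"periodic"` (default) or `"secant"`
#' @param rr_ms RR interval override (ms)
#' @param floor_rule `"auto"` (0 for sinuses, minimum observed for arteries),
#'   or a number, or `NA` for no floor
#' @param n_fit number of terminal samples whose least-squares line sets the
#'   extrapolation slope (2 = the plain two-point secant)
#' @return a [flow_profile32()]
#' @export
normalize_profile <- function(series, extrapolation = c("periodic", "secant"),
                              rr_ms = attr(series, "rr_ms"),
                              floor_rule = "auto", n_fit = 4) {
  extrapolation <- match.arg(extrapolation)
  ok <- is.finite(series$flow_ul_s)
  x <- series$pct_cc[ok]
  y <- series$flow_ul_s[ok]
  if (length(x) < 3)
    stop("cannot normalize: fewer than 3 valid flow samples")
  if (is.unsorted(x, strictly = TRUE))
    stop("samples must be strictly increasing in pct_cc")
  vessel <- if (!is.null(attr(series, "vessel"))) attr(series, "vessel")
            else as.character(series$vessel[1])
  if (is.null(rr_ms)) stop("rr_ms is required")

  grid <- cc_grid_pct()
  n <- length(x)
  flow <- numeric(CC_STEPS)
  extrap <- rep(FALSE, CC_STEPS)

  inside <- grid >= x[1] & grid <= x[n]
  if (any(inside))
    flow[inside] <- stats::approx(x, y, xout = grid[inside])$y

  floor_val <- if (identical(floor_rule, "auto")) {
    if (is_venous(vessel)) 0 else min(y)
  } else if (is.na(floor_rule)) -Inf else as.numeric(floor_rule)

  after <- grid > x[n]
  before <- grid < x[1]
  if (extrapolation == "secant") {
    # least-squares line through the n_fit terminal samples (exact for
    # affine inputs; reduces to the two-point secant for n_fit = 2)
    ls_line <- function(xs, ys) {
      b <- if (length(xs) == 2) (ys[2] - ys[1]) / (xs[2] - xs[1])
           else stats::cov(xs, ys) / stats::var(xs)
      a <- mean(ys) - b * mean(xs)
      c(a = a, b = b)
    }
    if (any(after)) {
      k <- max(2, min(n_fit, n))
      co <- ls_line(x[(n - k + 1):n], y[(n - k + 1):n])
      flow[after] <- pmax(co["a"] + co["b"] * grid[after], floor_val)
      extrap[after] <- TRUE
    }
    if (any(before)) {
      k <- max(2, min(n_fit, n))
      co <- ls_line(x[1:k], y[1:k])
      flow[before] <- pmax(co["a"] + co["b"] * grid[before], floor_val)
      extrap[before] <- TRUE
    }
  } else {
    # periodic closure: interpolate across the R-wave between the last and
    # (wrapped) first sample
    if (any(after | before)) {
      gx <- c(x, x[1] + 100)
      gy <- c(y, y[1])
      g2 <- ifelse(grid < x[1], grid + 100, grid)
      out <- !(g2 >= x[1] & g2 <= x[n])
      flow[out] <- stats::approx(gx, gy, xout = g2[out])$y
      extrap[out] <- TRUE
    }
  }
  flow_profile32(vessel, flow, rr_ms, extrap)
}

#' Step-wise sum of flow profiles (composite arterial / venous flow)
#'
#' @param profiles list of [flow_profile32()] from the same subject (equal
#'   `rr_ms`)
#' @param label composite vessel label; defaults to "Art" for all-arterial
#'   input, "Ven" for all-venous, otherwise the concatenated names
#' @return a [flow_profile32()]; a step is marked extrapolated if it was
#'   extrapolated in any summand
#' @export
sum_profiles <- function(profiles, label = NULL) {
  stopifnot(length(profiles) >= 1)
  rr <- vapply(profiles, `[[`, 0, "rr_ms")
  if (diff(range(rr)) > 1e-9 * rr[1])
    stop("profiles have mismatched rr_ms (different subjects?)")
  vessels <- vapply(profiles, `[[`, "", "vessel")
  if (is.null(label)) {
    label <- if (all(vessels %in% ARTERIAL_VESSELS)) "Art"
             else if (all(vessels %in% VENOUS_VESSELS)) "Ven"
             else paste(vessels, collapse = "+")
  }
  flow <- Reduce(`+`, lapply(profiles, `[[`, "flow_ul_s"))
  extrap <- Reduce(`|`, lapply(profiles, `[[`, "extrapolated"))
  flow_profile32(label, flow, rr[1], extrap)
}
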