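# Per-curve DSC analytics: landmark detection, signal-to-concentration
# conversion, early PSR, BSW leakage fit and leakage-corrected CBV.
#
# Index conventions: all indices are 1-based positions in the dynamic
# series; windows quoted in documentation are inclusive. The first
# `n_discard` dynamics are non-steady-state and excluded from every
# computation. Time is in seconds throughout.

#' A single-voxel DSC time-intensity curve
#'
#' @param values Signal intensity per dynamic (arbitrary units).
#' @param dt Sampling interval in seconds (the TR).
#' @param te Echo time in seconds.
#' @return An object of class `time_curve`.
#' @export
time_curve <- function(values, dt, te) {
  pq_check(length(values) >= 30, "pq_param_error",
           "curve must have at least 30 dynamics")
  pq_check(all(is.finite(values)), "pq_param_error",
           "curve values must be finite")
  pq_check(dt > 0 && te > 0, "pq_param_error", "dt and te must be > 0")
  structure(list(values = as.numeric(values), dt = dt, te = te),
            class = "time_curve")
}

as_time_curve <- function(x, acq) {
  if (inherits(x, "time_curve")) x else time_curve(x, acq$tr, acq$te)
}

#' Detect bolus landmarks on a DSC time-intensity curve
#'
#' Discards the leading non-steady-state points, then scans forward with a
#' running baseline mean and standard deviation: bolus arrival is the first
#' index where two consecutive points fall below
#' `mean - k_sigma * sd` of the baseline accumulated up to two points
#' earlier. The baseline window is then the steady-state stretch ending two
#' points before arrival, the signal minimum is searched within
#' `min_window` dynamics of arrival, and the first-pass end comes from
#' [detect_first_pass_end()].
#'
#' @param curve A [time_curve()] (or a numeric vector plus `acq`).
#' @param min_baseline Minimum number of usable baseline points.
#' @param k_sigma Arrival threshold in baseline standard deviations.
#' @param n_discard Leading non-steady-state points to exclude.
#' @param min_window Dynamics after arrival searched for the signal minimum.
#' @param fallback_window Dynamics after the minimum used as first-pass end
#'   when the slope rule never fires.
#' @param acq Optional [acquisition_params()] used when `curve` is a bare
#'   numeric vector.
#'
#' @return An object of class `bolus_markers`: `discard_n`,
#'   `baseline_start`, `baseline_end` (inclusive), `s0` (baseline mean),
#'   `sd_baseline`, `arrival`, `t_min`, `fpe`, `fpe_fallback`.
#' @export
detect_bolus_markers <- function(curve, min_baseline = 8, k_sigma = 3,
                                 n_discard = 3, min_window = 20,
                                 fallback_window = 10, acq = NULL) {
  if (!inherits(curve, "time_curve")) curve <- as_time_curve(curve, acq)
  s <- curve$values
  n <- length(s)

  arrival <- NA_integer_
  first_i <- n_discard + min_baseline + 3L
  for (i in first_i:(n - 1L)) {
    bw <- (n_discard + 1L):(i - 3L)
    m <- mean(s[bw])
    sdev <- stats::sd(s[bw])
    thr <- m - k_sigma * sdev
    if (s[i] < thr && s[i + 1L] < thr) {
      arrival <- i
      break
    }
  }
  if (is.na(arrival)) {
    # distinguish "no bolus at all" from "bolus too early to baseline"
    body <- s[(n_discard + 1L):n]
    if (min(body) < mean(body) - k_sigma * stats::sd(body)) {
      pq_stop("pq_insufficient_baseline",
              "signal dip occurs before a %d-point baseline can be formed",
              min_baseline)
    }
    pq_stop("pq_no_bolus", "no bolus arrival found (threshold %g sd)", k_sigma)
  }

  bw <- (n_discard + 1L):(arrival - 3L)
  if (length(bw) < min_baseline) {
    pq_stop("pq_insufficient_baseline",
            "baseline window has %d < %d points", length(bw), min_baseline)
  }
  s0 <- mean(s[bw])
  pq_check(s0 > 0, "pq_param_error", "baseline mean must be positive")
  sd_baseline <- stats::sd(s[bw])

  mw_end <- min(arrival + min_window, n)
  t_min <- arrival - 1L + which.min(s[arrival:mw_end])

  fp <- detect_first_pass_end(curve, t_min, fallback_window = fallback_window)

  structure(list(discard_n = as.integer(n_discard),
                 baseline_start = bw[1L], baseline_end = bw[length(bw)],
                 s0 = s0, sd_baseline = sd_baseline,
                 arrival = as.integer(arrival), t_min = as.integer(t_min),
                 fpe = fp$fpe, fpe_fallback = fp$fallback),
            class = "bolus_markers")
}

#' Detect the end of the first vascular pass
#'
#' Implements the slope rule: with first differences
#' `d_i = S(i+1) - S(i)` for `i >= t_min`, the first-pass end is the first
#' index `i >= t_min + 3` at which the mean of the accumulated slopes is
#' still non-negative (the curve is, on average, ascending) but falls below
#' their sample standard deviation. A curve that only declines after its
#' minimum has no ascending slope, so the rule never fires and the end is
#' set `fallback_window` dynamics after the minimum (capped at the last
#' index) and flagged.
#'
#' @param curve A [time_curve()] or numeric vector.
#' @param t_min Index of the signal minimum.
#' @param fallback_window Dynamics used when the rule never fires.
#' @param acq Optional [acquisition_params()] for bare vectors.
#' @return A list with `fpe` (index) and `fallback` (logical).
#' @export
detect_first_pass_end <- function(curve, t_min, fallback_window = 10,
                                  acq = NULL) {
  s <- if (inherits(curve, "time_curve")) curve$values else
    as_time_curve(curve, acq)$values
  n <- length(s)
  pq_check(n - t_min >= 4, "pq_curve_too_short",
           "need at least 4 points after the signal minimum")
  d <- diff(s)[t_min:(n - 1L)]
  fpe <- NA_integer_
  for (j in 3:length(d)) {
    dj <- d[1:j]
    m <- mean(dj)
    if (m >= 0 && m < stats::sd(dj)) {
      fpe <- t_min + j
      break
    }
  }
  fallback <- is.na(fpe)
  if (fallback) fpe <- min(t_min + fallback_window, n)
  list(fpe = as.integer(fpe), fallback = fallback)
}

#' Convert a time-intensity curve to a concentration (Delta-R2*) curve
#'
#' \eqn{\Delta R_2^*(t) = -\ln(S(t)/S_0)/TE}. Non-positive signal values are
#' clipped to `s0 * 1e-6` before the logarithm; negative concentrations
#' (T1 effects) are retained.
#'
#' @param curve A [time_curve()] or numeric vector.
#' @param markers A `bolus_markers` object (supplies `s0`).
#' @param acq Optional [acquisition_params()] for bare vectors.
#' @return An object of class `conc_curve`: `delta_r2star` (1/s), `dt`.
#' @export
signal_to_delta_r2star <- function(curve, markers, acq = NULL) {
  if (!inherits(curve, "time_curve")) curve <- as_time_curve(curve, acq)
  pq_check(markers$s0 > 0, "pq_param_error", "markers$s0 must be positive")
  s <- pmax(curve$values, markers$s0 * 1e-6)
  structure(list(delta_r2star = -log(s / markers$s0) / curve$te,
                 dt = curve$dt),
            class = "conc_curve")
}

#' Early percentage of signal recovery
#'
#' `PSR = (S(fpe) - S(t_min)) / (s0 - S(t_min))`, a fraction; values above 1
#' (overshoot from T1 dominance) are permitted.
#'
#' @param curve A [time_curve()] or numeric vector.
#' @param markers A `bolus_markers` object.
#' @param noise_floor Minimum bolus depth `s0 - S(t_min)`; below this the
#'   voxel is rejected as having no usable bolus depth.
#' @param acq Optional [acquisition_params()] for bare vectors.
#' @return PSR as a single numeric fraction.
#' @export
compute_psr <- function(curve, markers, noise_floor = 0, acq = NULL) {
  s <- if (inherits(curve, "time_curve")) curve$values else
    as_time_curve(curve, acq)$values
  depth <- markers$s0 - s[markers$t_min]
  pq_check(depth > 0, "pq_param_error",
           "bolus depth must be positive (s0 > S_min)")
  if (depth <= noise_floor) {
    pq_stop("pq_qc_reject", "bolus depth %.3g below noise floor %.3g",
            depth, noise_floor)
  }
  (s[markers$fpe] - s[markers$t_min]) / depth
}

#' Boxerman-Schmainda-Weisskoff leakage fit
#'
#' Ordinary least squares of the voxel concentration on the reference curve
#' and its running integral over the fit window (arrival to the last
#' dynamic):
#' \eqn{\Delta R_2^*(t) \approx K_1 \bar R(t) - K_2 \int_0^t \bar R(\tau) d\tau.}
#'
#' @param voxel_conc A `conc_curve` for the voxel.
#' @param ref_conc A `conc_curve` for the reference tissue (NAWM mean).
#' @param markers `bolus_markers` defining the fit window start.
#' @return An object of class `leakage_fit`: `k1`, `k2`, `residual_rms`,
#'   plus the reference cumulative integral used (`ref_cum`).
#' @export
fit_bsw <- function(voxel_conc, ref_conc, markers) {
  y_all <- voxel_conc$delta_r2star
  r_all <- ref_conc$delta_r2star
  pq_check(length(y_all) == length(r_all), "pq_shape_error",
           "voxel and reference curves differ in length")
  w <- markers$arrival:length(y_all)
  cum_all <- pracma::cumtrapz(seq_along(r_all) * ref_conc$dt, r_all)[, 1]
  X <- cbind(r_all[w], cum_all[w])
  if (sum(r_all[w]^2) == 0 || qr(X)$rank < 2) {
    pq_stop("pq_degenerate_reference",
            "reference curve has no energy or rank-deficient design")
  }
  fit <- qr.solve(X, y_all[w])
  resid <- y_all[w] - X %*% fit
  structure(list(k1 = fit[1], k2 = -fit[2],
                 residual_rms = sqrt(mean(resid^2)), ref_cum = cum_all),
            class = "leakage_fit")
}

#' Leakage-corrected relative CBV
#'
#' Adds the fitted leakage term back to the voxel concentration curve,
#' \eqn{\Delta R_2^{*,corr}(t) = \Delta R_2^*(t) + K_2 \int_0^t \bar R}, and
#' integrates (trapezoid) from bolus arrival to the last dynamic. The result
#' is in concentration-time area units (dimensionless after NAWM
#' normalization); near-zero and negative values are not clipped.
#'
#' @param voxel_conc A `conc_curve` for the voxel.
#' @param fit A `leakage_fit` from [fit_bsw()].
#' @param markers `bolus_markers` defining the integration start.
#' @return Relative CBV (numeric scalar).
#' @export
corrected_cbv <- function(voxel_conc, fit, markers) {
  corr <- voxel_conc$delta_r2star + fit$k2 * fit$ref_cum
  w <- markers$arrival:length(corr)
  pracma::trapz(seq_along(w) * voxel_conc$dt, corr[w])
}

# uncorrected trapezoidal CBV over the same window (used for the NAWM
# reference denominator)
uncorrected_cbv <- function(conc, markers) {
  w <- markers$arrival:length(conc$delta_r2star)
  pracma::trapz(seq_along(w) * conc$dt, conc$delta_r2star[w])
}
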