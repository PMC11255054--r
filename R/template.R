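# First-pass concentration template shared by all simulated voxels.
#
# The template models the reference-tissue (NAWM) concentration time course
# at unit blood volume: a gamma-variate first pass plus a delayed, broadened,
# lower-amplitude recirculation, blended after the first pass into a small
# constant residual level (recirculated + steady-state contrast). Because the
# tail is constant, the cumulative integral of the template grows linearly
# late in the series, which is exactly the leakage basis the BSW fit uses;
# voxel-specific recovery deficits expressed on that basis are therefore
# fully removable by the correction.

#' Bolus concentration template for the DSC simulator
#'
#' Builds the shared tissue concentration template \eqn{C_1(t)}: a
#' gamma-variate first pass (shape `alpha`, scale `theta`), a recirculation
#' bump (`recirc_amp` of the main peak, delayed `recirc_delay` seconds,
#' broadened 1.5x), blended over `blend_width` seconds into a constant
#' residual concentration after `tau_plateau` seconds. The residual level is
#' chosen so that a pure reference-tissue voxel (unit blood volume, no
#' leakage) naturally recovers to `nawm_psr` of its signal drop at the end of
#' the first pass; the peak is scaled so that the same voxel's signal dips to
#' `nawm_dip` of baseline.
#'
#' @param acq An [acquisition_params()] object.
#' @param alpha,theta Gamma-variate shape and scale (seconds).
#' @param recirc_amp,recirc_delay Recirculation amplitude (fraction of the
#'   first-pass peak) and delay (seconds).
#' @param tau_plateau Seconds after bolus arrival at which the first pass is
#'   over and the template settles on its residual level.
#' @param blend_width Width (seconds) of the smooth transition onto the
#'   residual level.
#' @param nawm_dip Fraction of baseline signal at the reference-tissue
#'   minimum (sets the peak concentration).
#' @param nawm_psr Natural percentage of signal recovery of the reference
#'   tissue (sets the residual level).
#'
#' @return An object of class `bolus_template`: sampled template `conc`,
#'   normalized cumulative `cum_norm` (1 at the last dynamic), total area
#'   `area`, the sample times and the generating function `conc_fun(tau)`.
#' @export
bolus_template <- function(acq, alpha = 3, theta = 1.5,
                           recirc_amp = 0.3, recirc_delay = 12,
                           tau_plateau = 6.5, blend_width = 1.5,
                           nawm_dip = 0.55, nawm_psr = 0.9) {
  stopifnot(inherits(acq, "acq_params"))
  # residual level from the recovery fraction: S(plateau)/s0 = dip + psr*(1-dip)
  peak_conc <- -log(nawm_dip) / acq$te
  resid_conc <- -log(nawm_dip + nawm_psr * (1 - nawm_dip)) / acq$te

  gamma_var <- function(tau, a, th) {
    out <- numeric(length(tau))
    p <- tau > 0
    out[p] <- (tau[p] / (a * th))^a * exp(a - tau[p] / th)
    out
  }
  shape_raw <- function(tau) {
    gamma_var(tau, alpha, theta) +
      recirc_amp * gamma_var(tau - recirc_delay, alpha, theta * 1.5)
  }
  nrm <- max(shape_raw(seq(0, 60, by = 0.02)))
  conc_fun <- function(tau) {
    raw <- peak_conc * shape_raw(tau) / nrm
    w <- 1 / (1 + exp((tau - tau_plateau) / (blend_width / 4)))
    ifelse(tau <= 0, 0, raw * w + resid_conc * (1 - w))
  }

  times <- (seq_len(acq$n_dynamics) - 1) * acq$tr
  t_arrival <- (acq$n_discard + acq$n_baseline) * acq$tr
  conc <- conc_fun(times - t_arrival)
  cum <- pracma::cumtrapz(times, conc)[, 1]
  area <- cum[length(cum)]

  structure(list(conc = conc, cum_norm = cum / area, area = area,
                 times = times, t_arrival = t_arrival, conc_fun = conc_fun,
                 peak_conc = peak_conc, resid_conc = resid_conc,
                 tau_plateau = tau_plateau, acq = acq),
            class = "bolus_template")
}

# template resampled with a bolus-arrival delay (seconds); returns the
# concentration curve and its normalized cumulative on the acquisition grid
template_delayed <- function(template, delay) {
  conc <- template$conc_fun(template$times - template$t_arrival - delay)
  cum <- pracma::cumtrapz(template$times, conc)[, 1]
  list(conc = conc, cum_norm = cum / template$area)
}
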