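#' Acquisition parameters for a gradient-echo DSC-PWI sequence
#'
#' Bundles the sequence timing and signal model constants the pipeline needs:
#' echo time, repetition time (= dynamic sampling interval), number of
#' dynamics, the length of the pre-bolus baseline, the pre-contrast signal
#' level and the additive noise level. Defaults correspond to a typical
#' clinical gradient-echo DSC protocol (TE 40 ms, TR 1.5 s, 60 dynamics,
#' baseline of 12 points) at a signal-to-noise ratio of 50.
#'
#' @param te Echo time in seconds.
#' @param tr Repetition time in seconds; also the sampling interval of the
#'   dynamic series.
#' @param n_dynamics Number of dynamic volumes acquired.
#' @param n_baseline Number of steady-state pre-bolus baseline points
#'   (excluding the leading non-steady-state dynamics, see `n_discard`).
#' @param s0 Pre-contrast baseline signal level (arbitrary units).
#' @param noise_sd Standard deviation of additive Gaussian signal noise, in
#'   the same units as `s0`. `s0 / noise_sd` is the baseline SNR.
#' @param n_discard Leading dynamics acquired before the magnetization
#'   reaches steady state; they are held at `s0` by the simulator and
#'   discarded by the analysis.
#'
#' @return An object of class `acq_params` (a validated list).
#' @export
acquisition_params <- function(te = 0.040, tr = 1.5, n_dynamics = 60,
                               n_baseline = 12, s0 = 100, noise_sd = 2,
                               n_discard = 3) {
  pq_check(is.numeric(te) && te > 0, "pq_param_error", "te must be > 0")
  pq_check(is.numeric(tr) && tr > 0, "pq_param_error", "tr must be > 0")
  pq_check(n_dynamics >= 30, "pq_param_error", "n_dynamics must be >= 30")
  pq_check(n_baseline >= 8 && n_baseline <= n_dynamics / 3, "pq_param_error",
           "n_baseline must be in [8, n_dynamics/3]")
  pq_check(noise_sd >= 0, "pq_param_error", "noise_sd must be >= 0")
  pq_check(s0 > 0, "pq_param_error", "s0 must be > 0")
  pq_check(n_discard >= 0 && n_discard < n_baseline, "pq_param_error",
           "n_discard must be >= 0 and < n_baseline")
  structure(list(te = te, tr = tr, n_dynamics = as.integer(n_dynamics),
                 n_baseline = as.integer(n_baseline), s0 = s0,
                 noise_sd = noise_sd, n_discard = as.integer(n_discard)),
            class = "acq_params")
}

#' @export
print.acq_params <- function(x, ...) {
  cat(sprintf(
    "DSC acquisition: TE %.0f ms, TR %.2f s, %d dynamics (%d discarded + %d baseline), s0 %.1f, noise sd %.2f\n",
    x$te * 1000, x$tr, x$n_dynamics, x$n_discard, x$n_baseline, x$s0,
    x$noise_sd))
  invisible(x)
}
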