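#' Calibrated death-fraction targets and hazard multipliers per dose
#'
#' The four printed 24-h death fractions from time-lapse experiments (1% at
#' 50 uM, 11% at 80 uM, 34% at 100 uM, 98% at 300 uM) anchor the hazard
#' calibration; intermediate doses are monotone interpolations chosen once.
#' `death_mult` values were obtained by [calibrate_death()] (bisection against
#' a 20,000-cell Monte-Carlo death fraction) at the package's default
#' parameters and are frozen here as the versioned defaults.
#' @keywords internal
.preset_table <- function() {
  data.frame(
    dose = c(0, 20, 40, 50, 60, 80, 100, 150, 200, 300),
    target_death = c(0, 0.002, 0.005, 0.01, 0.03, 0.11, 0.34, 0.60, 0.80, 0.98),
    death_mult = c(0, 0.006104, 0.007629, 0.012207, 0.036621,
                   0.134277, 0.537109, 1.330566, 2.490234, 6.640625)
  )
}

#' Dose preset for the synthetic-data generator
#'
#' A preset bundles the initial H2O2 bolus with the calibrated death-hazard
#' multiplier and the dose-dependent p53-mode rule (the probability that a
#' cell's post-onset p53 waveform is sustained rather than oscillatory follows
#' a logistic curve in dose, mirroring the loss of p53 oscillations at high
#' dose).
#'
#' @param dose initial H2O2 concentration in uM; one of 0, 20, 40, 50, 60, 80,
#'   100, 150, 200, 300 unless `death_mult` is supplied explicitly.
#' @param death_mult hazard multiplier; defaults to the calibrated value for
#'   the dose (see [calibrate_death()]).
#' @param mode_mid,mode_scale logistic midpoint/scale (uM) of the sustained-mode
#'   probability `plogis((dose - mode_mid)/mode_scale)`.
#' @param name preset label.
#' @return object of class `dose_preset`.
#' @export
#' @examples
#' dose_preset(100)
dose_preset <- function(dose, death_mult = NULL,
                        mode_mid = 100, mode_scale = 40,
                        name = paste0(dose, "uM")) {
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0) {
    stop("input error: 'dose' must be a single non-negative number")
  }
  tab <- .preset_table()
  if (is.null(death_mult)) {
    i <- match(dose, tab$dose)
    if (is.na(i)) {
      stop("input error: no calibrated death_mult for dose ", dose,
           " uM; supply 'death_mult' explicitly")
    }
    death_mult <- tab$death_mult[i]
  }
  if (death_mult < 0) stop("input error: 'death_mult' must be >= 0")
  structure(list(name = name, H0 = dose, death_mult = death_mult,
                 mode_mid = mode_mid, mode_scale = mode_scale),
            class = "dose_preset")
}

#' @export
print.dose_preset <- function(x, ...) {
  cat(sprintf("dose_preset '%s': H0 = %g uM, death_mult = %g, P(sustained) = %.2f\n",
              x$name, x$H0, x$death_mult,
              stats::plogis((x$H0 - x$mode_mid) / x$mode_scale)))
  invisible(x)
}

#' Tunable options of the trajectory/snapshot generator
#'
#' All free constants of the synthetic single-cell generator, fixed once as the
#' package's study conditions. Times in minutes, intensities in arbitrary
#' units.
#'
#' @param frame_min sampling interval of the movie (20-min frames).
#' @param t_end movie length (24 h).
#' @param noise_sd sigma of the multiplicative lognormal measurement noise
#'   applied to every measured series; set 0 to disable (also disables the p53
#'   onset jitter).
#' @param jitter_cv coefficient of variation of the per-cell lognormal jitter
#'   on `theta_on`/`theta_off`; creates the dose-dependent responder fraction.
#' @param onset_jitter_sd sd (min) of the Gaussian jitter on the p53 onset
#'   delay after FOXO1 exit.
#' @param nf_base,nf_base_sd baseline FOXO1 nuclear fraction and its per-cell sd.
#' @param nf_active FOXO1 nuclear-fraction target during the phase.
#' @param p53_base baseline nuclear p53 level.
#' @param p53_shift_amp,p53_shift_tau,p53_pulse_amp,p53_period sustained
#'   shift (amplitude, rise time) and pulse amplitude/period (min) of the
#'   oscillatory p53 waveform (raised-cosine pulse train on a saturating
#'   shift).
#' @param p53_sus_amp,p53_sus_tau amplitude and rise time of the sustained
#'   (non-oscillatory) waveform; amplitude defaults to 2x the oscillatory
#'   pulse amplitude, reflecting the higher p53 reached by dying cells.
#' @param p53_route_mid,p53_route_scale logistic midpoint/scale (uM) of the
#'   probability that a phase-less cell activates p53 through the low-dose
#'   route.
#' @param low_dose_onset onset time (min) of the low-dose p53 route (1 frame).
#' @param hazard_a post-phase hazard coefficient, per min of completed FOXO1
#'   phase duration per min (longer nuclear residence raises the death rate
#'   once the phase ends).
#' @param hazard_b p53-proportional hazard coefficient, per a.u. per min.
#' @param gh2ax_base,gh2ax_fold,gh2ax_k,gh2ax_sd baseline, saturating fold
#'   increase, half-saturation dose (uM) and lognormal sigma of the snapshot
#'   gamma-H2AX channel.
#' @return list of class `sim_opts`.
#' @export
sim_opts <- function(frame_min = 20, t_end = 1440,
                     noise_sd = 0.1, jitter_cv = 0.1, onset_jitter_sd = 8,
                     nf_base = 0.30, nf_base_sd = 0.02, nf_active = 0.78,
                     p53_base = 1, p53_shift_amp = 0.8, p53_shift_tau = 10,
                     p53_pulse_amp = 3,
                     p53_period = 330, p53_sus_amp = 6, p53_sus_tau = 60,
                     p53_route_mid = 30, p53_route_scale = 12,
                     low_dose_onset = 20,
                     hazard_a = 2e-7, hazard_b = 1.5e-4,
                     gh2ax_base = 120, gh2ax_fold = 6, gh2ax_k = 150,
                     gh2ax_sd = 0.35) {
  stopifnot(frame_min > 0, t_end >= frame_min, noise_sd >= 0, jitter_cv >= 0,
            p53_period > 0, hazard_a >= 0, hazard_b >= 0)
  structure(as.list(environment()), class = "sim_opts")
}
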