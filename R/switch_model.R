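#' Parameters of the peroxiredoxin hyperoxidation switch
#'
#' Construct the rate-constant and threshold set for the 2-Cys peroxiredoxin
#' (PRDX) redox-cycle model that gates the FOXO1/p53 response. The model tracks
#' the fractions of the PRDX pool in the reduced-thiol (`r`), sulfenic-acid
#' (`s`), disulfide (`d`) and hyperoxidized sulfinic-acid (`h`) states together
#' with the H2O2 concentration `H` (uM). Mass-action kinetics:
#'
#' \deqn{dr/dt = k_{red} d - k_{ox} H r}
#' \deqn{ds/dt = k_{ox} H r - k_{ss} s - k_{hyp} H s + k_{srx} h}
#' \deqn{dd/dt = k_{ss} s - k_{red} d}
#' \deqn{dh/dt = k_{hyp} H s - k_{srx} h}
#' \deqn{dH/dt = -(k_{clear,base} + k_{clear,cell} \cdot prdx \cdot (1-h)) H}
#'
#' Clearance depends on the non-hyperoxidized pool, so high doses inactivate
#' their own removal machinery: H2O2 persists longer, hyperoxidation deepens,
#' and the time the hyperoxidized fraction spends above `theta_on` (the FOXO1
#' nuclear-residence window) grows with dose. Sulfiredoxin (SRXN1) repair
#' (`k_srx`) eventually pulls `h` below `theta_off`, closing the window.
#'
#' Default values are the package's calibrated reference set, fixed once so the
#' dose presets reproduce the qualitative single-cell phenomenology (no FOXO1
#' phase at <= 60 uM, a responder subset at 80 uM, near-universal response with
#' dose-increasing duration at >= 100 uM).
#'
#' @param k_ox peroxidatic-cysteine oxidation rate, per uM per min.
#' @param k_ss disulfide (resolving-cysteine) formation rate, per min.
#' @param k_red thioredoxin-system reduction rate of the disulfide, per min.
#' @param k_hyp hyperoxidation rate (SOH -> SO2H), per uM per min.
#' @param k_srx SRXN1 repair rate (SO2H -> SOH), per min.
#' @param k_clear_cell H2O2 clearance rate per unit non-hyperoxidized PRDX, per min.
#' @param k_clear_base PRDX-independent clearance, per min.
#' @param prdx_scale relative PRDX pool size, in (0, 1].
#' @param theta_on,theta_off hyperoxidized-fraction thresholds opening/closing
#'   the FOXO1 window; `0 <= theta_off < theta_on <= 1` (hysteresis).
#' @param tau_f FOXO1 nuclear-shuttling relaxation time, min.
#' @param tau_p53 delay from FOXO1 nuclear exit to p53 onset, min.
#' @return An object of class `switch_params` (a validated named list).
#' @seealso [perturb_params()] for the perturbation presets,
#'   [integrate_switch()] and [phase_schedule()].
#' @export
#' @examples
#' p <- switch_params()
#' st <- integrate_switch(p, dose = 100)
#' phase_schedule(st, p)
switch_params <- function(k_ox = 0.004, k_ss = 0.6, k_red = 0.3,
                          k_hyp = 0.004, k_srx = 0.0015,
                          k_clear_cell = 0.06, k_clear_base = 0.01,
                          prdx_scale = 1,
                          theta_on = 0.47, theta_off = 0.30,
                          tau_f = 4, tau_p53 = 60) {
  p <- list(k_ox = k_ox, k_ss = k_ss, k_red = k_red, k_hyp = k_hyp,
            k_srx = k_srx, k_clear_cell = k_clear_cell,
            k_clear_base = k_clear_base, prdx_scale = prdx_scale,
            theta_on = theta_on, theta_off = theta_off,
            tau_f = tau_f, tau_p53 = tau_p53)
  rates <- c("k_ox", "k_ss", "k_red", "k_hyp", "k_srx",
             "k_clear_cell", "k_clear_base")
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || is.na(p[[nm]]) ||
        p[[nm]] < 0) {
      stop("parameter error: '", nm, "' must be a single non-negative number")
    }
  }
  if (!(prdx_scale > 0 && prdx_scale <= 1)) {
    stop("parameter error: 'prdx_scale' must be in (0, 1]")
  }
  if (!(theta_off >= 0 && theta_off < theta_on && theta_on <= 1)) {
    stop("parameter error: need 0 <= theta_off < theta_on <= 1")
  }
  if (!(tau_f > 0)) stop("parameter error: 'tau_f' must be > 0")
  if (!(tau_p53 >= 0)) stop("parameter error: 'tau_p53' must be >= 0")
  structure(p, class = "switch_params")
}

#' @export
print.switch_params <- function(x, ...) {
  cat("PRDX hyperoxidation switch parameters\n")
  cat(sprintf("  oxidation  k_ox = %g /uM/min   disulfide k_ss = %g /min   reduction k_red = %g /min\n",
              x$k_ox, x$k_ss, x$k_red))
  cat(sprintf("  hyperox.   k_hyp = %g /uM/min  repair    k_srx = %g /min\n",
              x$k_hyp, x$k_srx))
  cat(sprintf("  clearance  base %g + cell %g x prdx_scale %g (per min)\n",
              x$k_clear_base, x$k_clear_cell, x$prdx_scale))
  cat(sprintf("  FOXO1 window: h in [%g (off), %g (on)], tau_f = %g min; p53 delay tau_p53 = %g min\n",
              x$theta_off, x$theta_on, x$tau_f, x$tau_p53))
  invisible(x)
}

#' Perturbation presets of the switch model
#'
#' Pure parameter maps emulating the genetic/pharmacological perturbations of
#' the PRDX/SRXN1 system:
#' \describe{
#'   \item{`default`}{unchanged parameters.}
#'   \item{`prdx1ko`}{PRDX1 knockout: `prdx_scale` reduced (default 0.15), so
#'     H2O2 clearance drops and the hyperoxidation/FOXO1 dose threshold falls
#'     to ~40-50 uM.}
#'   \item{`j14`}{SRXN1 inhibition (J14) / SRXN1 knockdown: `k_srx` scaled to
#'     near zero (default 0.1x), prolonging the FOXO1 phase and delaying p53.}
#'   \item{`srxn1oe`}{SRXN1 overexpression: `k_srx` multiplied (default 8x),
#'     raising the dose required for FOXO1 activation and shortening phases.}
#'   \item{`conoidinA`}{Conoidin A inhibition of PRDX1/2 catalysis: `k_ox` and
#'     `k_ss` reduced (0.7x and 0.2x); the sulfenic intermediate lingers, so
#'     hyperoxidation and FOXO1 activation occur at lower doses.}
#' }
#'
#' @param params a [switch_params()] object.
#' @param preset preset name.
#' @param strength optional scalar overriding the preset's default factor:
#'   `prdx_scale` for `prdx1ko`, the `k_srx` multiplier for `j14`/`srxn1oe`.
#' @return a modified `switch_params` object.
#' @export
perturb_params <- function(params,
                           preset = c("default", "prdx1ko", "j14",
                                      "srxn1oe", "conoidinA"),
                           strength = NULL) {
  stopifnot(inherits(params, "switch_params"))
  preset <- match.arg(preset)
  p <- unclass(params)
  p <- switch(preset,
    default = p,
    prdx1ko = { p$prdx_scale <- if (is.null(strength)) 0.15 else strength; p },
    j14 = { p$k_srx <- p$k_srx * if (is.null(strength)) 0.1 else strength; p },
    srxn1oe = { p$k_srx <- p$k_srx * if (is.null(strength)) 8 else strength; p },
    conoidinA = { p$k_ox <- p$k_ox * 0.7; p$k_ss <- p$k_ss * 0.2; p }
  )
  do.call(switch_params, p)
}

# Right-hand side of the redox-cycle ODE; y = c(r, s, d, h, H)
switch_deriv <- function(y, p) {
  H <- y[5L]
  ox <- p$k_ox * H * y[1L]
  hyp <- p$k_hyp * H * y[2L]
  red <- p$k_red * y[3L]
  ss <- p$k_ss * y[2L]
  srx <- p$k_srx * y[4L]
  c(red - ox,
    ox - ss - hyp + srx,
    ss - red,
    hyp - srx,
    -(p$k_clear_base + p$k_clear_cell * p$prdx_scale * (1 - y[4L])) * H)
}

#' Integrate the redox-cycle switch model
#'
#' Deterministic fixed-step 4th-order Runge-Kutta integration of the PRDX
#' redox cycle from a fully reduced pool at a given H2O2 bolus. States are
#' returned on the grid `seq(0, t_end, by = dt)`. When the initial chemistry is
#' fast relative to `dt` (high doses), each output step is subdivided into a
#' deterministic number of equal internal substeps so the explicit integrator
#' stays in its stability/accuracy region; the output grid is unchanged.
#'
#' @param params a [switch_params()] object.
#' @param dose initial H2O2 concentration, uM (>= 0).
#' @param t_end integration horizon, min.
#' @param dt output step, min (> 0).
#' @return A `redox_states` data frame with columns `t_min`, `r`, `s`, `d`,
#'   `h`, `H_uM`. The four fractions sum to 1 (to numerical precision) at every
#'   step.
#' @export
integrate_switch <- function(params, dose, t_end = 1440, dt = 1) {
  stopifnot(inherits(params, "switch_params"))
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0) {
    stop("parameter error: 'dose' must be a single non-negative number")
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("parameter error: 'dt' must be > 0")
  }
  if (t_end < dt) stop("parameter error: 't_end' must be >= 'dt'")
  n <- as.integer(round(t_end / dt))
  # fastest local rate at t = 0 bounds the stiffness over the whole run
  lam <- params$k_ox * dose + params$k_hyp * dose + params$k_ss + params$k_red
  nsub <- max(1L, as.integer(ceiling(dt * lam / 0.4)))
  ddt <- dt / nsub
  y <- c(1, 0, 0, 0, dose)
  out <- matrix(NA_real_, n + 1L, 5L)
  out[1L, ] <- y
  for (i in seq_len(n)) {
    for (j in seq_len(nsub)) {
      k1 <- switch_deriv(y, params)
      k2 <- switch_deriv(y + ddt / 2 * k1, params)
      k3 <- switch_deriv(y + ddt / 2 * k2, params)
      k4 <- switch_deriv(y + ddt * k3, params)
      y <- y + ddt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    out[i + 1L, ] <- y
  }
  st <- data.frame(t_min = seq(0, by = dt, length.out = n + 1L),
                   r = out[, 1L], s = out[, 2L], d = out[, 3L],
                   h = out[, 4L], H_uM = out[, 5L])
  class(st) <- c("redox_states", "data.frame")
  st
}

#' @export
print.redox_states <- function(x, ...) {
  cat(sprintf("redox_states: %d steps, t = %g..%g min, h peak %.3f at t = %g min\n",
              nrow(x), x$t_min[1L], x$t_min[nrow(x)], max(x$h),
              x$t_min[which.max(x$h)]))
  NextMethod()
}

#' @export
plot.redox_states <- function(x, ...) {
  graphics::matplot(x$t_min, cbind(x$r, x$s, x$d, x$h), type = "l", lty = 1,
                    xlab = "time (min)", ylab = "PRDX state fraction", ...)
  graphics::legend("topright", c("reduced", "SOH", "disulfide", "SO2H"),
                   col = 1:4, lty = 1, bty = "n")
  invisible(x)
}

# First-crossing times of h over (theta_on, theta_off) with hysteresis.
# Returns c(entry, exit) in the time units of t; NA when a crossing is absent.
hysteresis_crossings <- function(t, h, theta_on, theta_off) {
  i_on <- which(h >= theta_on)
  if (length(i_on) == 0L) return(c(NA_real_, NA_real_))
  entry <- i_on[1L]
  i_off <- which(h <= theta_off & seq_along(h) > entry)
  exit <- if (length(i_off) == 0L) NA_real_ else t[i_off[1L]]
  c(t[entry], exit)
}

#' FOXO1 phase window induced by a redox trajectory
#'
#' Applies the hysteresis rule to a hyperoxidation time course: the FOXO1
#' nuclear-residence window opens at the first time the hyperoxidized fraction
#' `h` reaches `theta_on` and closes at the first later time `h` falls to
#' `theta_off`. The two thresholds differ (hysteresis) to prevent chatter from
#' small fluctuations near a single cutoff.
#'
#' @param states a `redox_states` data frame from [integrate_switch()].
#' @param params a [switch_params()] object supplying the default thresholds.
#' @param theta_on,theta_off optional per-cell threshold overrides (used by the
#'   trajectory generator's cell-to-cell jitter).
#' @return list with elements `t_entry` and `t_exit` (min; `NA` when the phase
#'   never opens, or never closes within the window).
#' @export
phase_schedule <- function(states, params,
                           theta_on = params$theta_on,
                           theta_off = params$theta_off) {
  if (!is.data.frame(states) || nrow(states) == 0L ||
      !all(c("t_min", "h") %in% names(states))) {
    stop("input error: 'states' must be a non-empty redox_states table")
  }
  if (is.unsorted(states$t_min, strictly = TRUE)) {
    stop("input error: time grid must be strictly increasing")
  }
  cr <- hysteresis_crossings(states$t_min, states$h, theta_on, theta_off)
  list(t_entry = if (is.na(cr[1L])) NA_real_ else cr[1L],
       t_exit = if (is.na(cr[2L])) NA_real_ else cr[2L])
}
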