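#' Time-varying elastance chamber parameters
#'
#' Parameters of a heart chamber modeled by a time-varying elastance
#' P = E(t)·(V − V0) plus a linear resistive viscoelastic term
#' `viscoelastic_coefficient * dV/dt`.  The activation waveform is a
#' normalized double-Hill function, the standard smooth activation used
#' in 0D heart models: rising Hill of order `m1` with time constant
#' `tau1_frac * period`, falling Hill of order `m2` with
#' `tau2_frac * period`, shifted by `activation_onset` (fraction of the
#' beat; used to place atrial contraction late in the cycle).
#'
#' @param e_max end-systolic (peak) elastance (mmHg/mL).
#' @param e_min diastolic elastance (mmHg/mL); `e_max >= e_min > 0`.
#' @param v0 unstressed volume (mL).
#' @param viscoelastic_coefficient resistive viscoelastic coefficient
#'   (mmHg·s/mL), >= 0.
#' @param activation_onset onset of activation as a fraction of the beat.
#' @param tau1_frac,tau2_frac rise/decay time constants as fractions of
#'   the beat period.
#' @param m1,m2 Hill exponents of the rising and falling limbs.
#' @return An object of class `chamber_parameters`.
#' @export
chamber_parameters <- function(e_max, e_min, v0,
                               viscoelastic_coefficient = 0,
                               activation_onset = 0,
                               tau1_frac = 0.269, tau2_frac = 0.452,
                               m1 = 1.32, m2 = 27.4) {
  if (!(e_max >= e_min))
    stop("chamber_parameters: e_max must be >= e_min", call. = FALSE)
  if (!(e_min > 0))
    stop("chamber_parameters: e_min must be > 0", call. = FALSE)
  if (v0 < 0)
    stop("chamber_parameters: v0 must be >= 0", call. = FALSE)
  if (viscoelastic_coefficient < 0)
    stop("chamber_parameters: viscoelastic_coefficient must be >= 0",
         call. = FALSE)
  ch <- list(e_max = e_max, e_min = e_min, v0 = v0,
             viscoelastic_coefficient = viscoelastic_coefficient,
             activation_onset = activation_onset,
             tau1_frac = tau1_frac, tau2_frac = tau2_frac,
             m1 = m1, m2 = m2)
  ch$act_norm <- activation_norm(ch)
  structure(ch, class = "chamber_parameters")
}

# Peak of the un-normalized double-Hill activation over one beat, used to
# normalize the waveform so that E(t) attains e_max exactly once per
# beat.  Evaluated on a fine fixed grid; the same constant is used by the
# R and compiled right-hand sides so both see an identical waveform.
activation_norm <- function(ch) {
  tn <- seq(0, 1, length.out = 4097)
  max(activation_raw(tn, ch))
}

activation_raw <- function(tn, ch) {
  h1 <- (tn / ch$tau1_frac)^ch$m1
  (h1 / (1 + h1)) / (1 + (tn / ch$tau2_frac)^ch$m2)
}

#' Chamber elastance at a time within the beat
#'
#' Evaluates the periodic double-Hill elastance waveform of a chamber.
#' The result lies in \[`e_min`, `e_max`\], is periodic with the beat
#' period, and attains `e_max` once per beat.
#'
#' @param chamber a [chamber_parameters()] object.
#' @param t time (s); values are wrapped into the beat, so any
#'   non-negative time is accepted.
#' @param period beat period (s).
#' @return Elastance (mmHg/mL); vectorized over `t`.
#' @examples
#' ch <- chamber_parameters(e_max = 2.9, e_min = 0.11, v0 = 8)
#' elastance_at(ch, 0, 0.75)            # end-diastole: e_min
#' max(elastance_at(ch, seq(0, 0.75, 1e-3), 0.75))  # e_max
#' @export
elastance_at <- function(chamber, t, period) {
  tn <- ((t / period) - chamber$activation_onset) %% 1
  phi <- activation_raw(tn, chamber) / chamber$act_norm
  chamber$e_min + (chamber$e_max - chamber$e_min) * phi
}

#' Chamber pressure from volume and filling rate
#'
#' P = E(t)·(V − V0) + viscoelastic_coefficient · dV/dt.
#'
#' @param chamber a [chamber_parameters()] object.
#' @param volume chamber volume (mL).
#' @param volume_rate dV/dt (mL/s).
#' @param t time within the beat (s).
#' @param period beat period (s).
#' @return Pressure (mmHg).
#' @examples
#' ch <- chamber_parameters(e_max = 2, e_min = 2, v0 = 10)
#' chamber_pressure(ch, 110, 0, 0, 0.75)  # 2 * (110 - 10) = 200
#' @export
chamber_pressure <- function(chamber, volume, volume_rate, t, period) {
  if (any(volume < 0))
    stop("chamber_pressure: volume must be >= 0", call. = FALSE)
  elastance_at(chamber, t, period) * (volume - chamber$v0) +
    chamber$viscoelastic_coefficient * volume_rate
}

#' Valve parameters
#'
#' A regularized-diode valve: forward flow is Ohmic through
#' `forward_resistance` (asymptotically `(delta_p - w)/R`), reverse flow
#' is `leak_conductance * delta_p` (zero by default), and the open/close
#' transition is a quadratic blend over the pressure width
#' `smoothing_width`, keeping the flow law continuously differentiable
#' for the integrator while remaining monotone in the pressure
#' difference.
#'
#' @param forward_resistance resistance when open (mmHg·s/mL), > 0.
#' @param leak_conductance reverse-leak conductance (mL/s/mmHg), >= 0.
#' @param smoothing_width transition half-width w (mmHg), > 0; the blend
#'   spans `0 <= delta_p <= 2 w`.
#' @return An object of class `valve_parameters`.
#' @export
valve_parameters <- function(forward_resistance, leak_conductance = 0,
                             smoothing_width = 0.05) {
  if (forward_resistance <= 0)
    stop("valve_parameters: forward_resistance must be > 0", call. = FALSE)
  if (leak_conductance < 0)
    stop("valve_parameters: leak_conductance must be >= 0", call. = FALSE)
  if (smoothing_width <= 0)
    stop("valve_parameters: smoothing_width must be > 0", call. = FALSE)
  structure(list(forward_resistance = forward_resistance,
                 leak_conductance = leak_conductance,
                 smoothing_width = smoothing_width),
            class = "valve_parameters")
}

#' Flow through a regularized-diode valve
#'
#' Continuous, continuously differentiable (for zero leak) and monotone
#' in the pressure difference: `(delta_p - w)/R` for `delta_p >= 2 w`,
#' a quadratic blend `delta_p^2/(4 w R)` on `0 < delta_p < 2 w`,
#' `leak_conductance * delta_p` for `delta_p <= 0`, and exactly zero at
#' `delta_p = 0`.
#'
#' @param delta_p pressure difference across the valve (mmHg).
#' @param valve a [valve_parameters()] object.
#' @return Flow (mL/s); vectorized over `delta_p`.
#' @examples
#' v <- valve_parameters(forward_resistance = 0.1)
#' valve_flow(10, v)   # ~100 mL/s (Ohmic limit)
#' valve_flow(-10, v)  # 0 (closed)
#' @export
valve_flow <- function(delta_p, valve) {
  w <- valve$smoothing_width
  R <- valve$forward_resistance
  ifelse(delta_p >= 2 * w, (delta_p - w) / R,
         ifelse(delta_p > 0, delta_p^2 / (4 * w * R),
                valve$leak_conductance * delta_p))
}
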