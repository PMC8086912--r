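#' Timer update rule
#'
#' A timer is a canalized maturation trajectory: it decreases linearly from
#' an initial state 1 to a ground state 0 at rate `1/T` per time step, with a
#' floor at 0. While held (e.g. by the posterior signal) it is pinned to its
#' held value (normally 1).
#'
#' @param tau Current levels in `[0, 1]`.
#' @param held Logical; cells pinned at `held_value`.
#' @param rate_scale Non-negative rate multipliers (feedbacks enter here).
#' @param T Timer duration in time steps (`>= 1`).
#' @param held_value Value(s) held cells are pinned to (default 1).
#' @return Updated levels.
#' @export
timer_update <- function(tau, held, rate_scale = 1, T, held_value = 1) {
  stopifnot(T >= 1, all(rate_scale >= 0))
  out <- pmax(0, tau - rate_scale / T)
  if (any(held)) {
    hv <- rep_len(held_value, length(out))
    out[held] <- hv[held]
  }
  out
}

#' Oscillator output level
#'
#' Converts a phase (in cycles) to a functional output level via
#' `o = (sin(2 pi (phi - 1/4)) + 1) / 2`, so that `o(0) = 0` (trough) and
#' `o(0.5) = 1` (peak). The phase is wrapped internally.
#'
#' @param phase Phase in cycles (any real).
#' @return Output levels in `[0, 1]`.
#' @export
oscillator_output <- function(phase) {
  (sin(2 * pi * (phase - 0.25)) + 1) / 2
}

#' Oscillator phase update
#'
#' The hidden phase advances at rate `f(tau_gate)/P` per step, where `f` is
#' the frequency profile evaluated at the gating maturation state. When the
#' gate is 0 the phase is frozen (the oscillator is expressed only where the
#' gate is positive; freeze-readout models exploit the frozen phase as a
#' permanent record).
#'
#' @param phase Unwrapped phase in cycles.
#' @param tau_gate Gating levels in `[0, 1]` (timer 1 or PI value).
#' @param P Oscillator period in time steps (`>= 1`).
#' @param profile A [frequency_profile()].
#' @return Updated unwrapped phase.
#' @export
oscillator_update <- function(phase, tau_gate, P,
                              profile = frequency_profile("exp2")) {
  stopifnot(P >= 1)
  f <- frequency_scale(tau_gate, profile)
  phase + ifelse(tau_gate > 0, f / P, 0)
}

#' Binary fate from oscillator level
#'
#' Segment-polarity fate read from the final oscillator level as the
#' oscillator turns off: state 1 if `o > 0.5` (strictly), else state 2.
#'
#' @param o Oscillator levels in `[0, 1]`.
#' @return Integer states (1 or 2).
#' @export
fate_from_oscillator <- function(o) {
  stopifnot(all(o >= 0 & o <= 1, na.rm = TRUE))
  ifelse(o > 0.5, 1L, 2L)
}

#' Oscillator-resettable timer (timer 2)
#'
#' Timer 2 measures the time since the oscillator last peaked: when the
#' oscillator level is at its peak (`o >= theta`, inclusive so that a sampled
#' peak of exactly `theta` triggers), timer 2 resets to 1; otherwise it
#' decreases at rate `rate_scale/T2` with a floor at 0. Cells where the
#' module is not expressed are left unchanged.
#'
#' @param tau2 Current levels in `[0, 1]`.
#' @param o Oscillator levels in `[0, 1]`.
#' @param theta Peak threshold in `(0, 1]`.
#' @param T2 Timer duration in steps.
#' @param expressed Logical; where timer 2 is running.
#' @param rate_scale Rate multipliers (by default timer 2 shares the
#'   oscillator's frequency profile, so the two stay phase-locked across the
#'   SAZ).
#' @return Updated levels.
#' @export
timer2_update <- function(tau2, o, theta, T2, expressed = TRUE,
                          rate_scale = 1) {
  stopifnot(T2 >= 1, theta > 0, theta <= 1)
  out <- ifelse(o >= theta, 1, pmax(0, tau2 - rate_scale / T2))
  ifelse(expressed, out, tau2)
}

#' Oscillator gate on elongation
#'
#' Elongation proceeds only while the posterior oscillator level is below
#' 0.5; at or above the threshold elongation is suppressed (the boundary is
#' assigned to suppression).
#'
#' @param o_posterior Oscillator level of the posterior-most cell.
#' @return `TRUE` if elongation is allowed.
#' @export
elongation_gate <- function(o_posterior) {
  o_posterior < 0.5
}

#' Oscillator feedback on timer rate
#'
#' Feedback of the oscillator on the maturation timer: the timer rate is
#' scaled by `exp(-k * o)`, so the timer slows while the local oscillator
#' level is high, producing pulsatile wavefront movement. `k = 0` recovers
#' the feedback-free model exactly.
#'
#' @param o Oscillator levels in `[0, 1]`.
#' @param k Feedback strength (`>= 0`).
#' @return Rate multipliers in `(0, 1]`.
#' @export
timer_rate_feedback <- function(o, k) {
  stopifnot(k >= 0, all(o >= 0 & o <= 1, na.rm = TRUE))
  exp(-k * o)
}

#' Axial timer update (timer 3)
#'
#' Timer 3 represents slow axial maturation (Hox/gap-like dynamics): inside
#' the SAZ (where timer 1 is positive) it decreases at rate `1/T3` with a
#' floor at 0; outside the SAZ it is stable.
#'
#' @param tau3 Current levels in `[0, 1]`.
#' @param in_saz Logical; cells whose timer 3 is running.
#' @param T3 Timer duration in steps.
#' @return Updated levels.
#' @export
timer3_update <- function(tau3, in_saz, T3) {
  stopifnot(T3 >= 1)
  ifelse(in_saz, pmax(0, tau3 - 1 / T3), tau3)
}

#' Timer-3 modulation of timer 1
#'
#' Optional coupling from the axial timer onto the maturation timer, given
#' as a piecewise-linear map from `tau3` to either a timer-1 rate multiplier
#' (`mode = "rate"`; multiplier grows as `tau3` falls, so late cells mature
#' faster) or to the timer-1 value held while signal-positive
#' (`mode = "initial"`; a reduced initial state lowers the posterior
#' oscillation frequency through the frequency profile).
#'
#' @param tau3 Levels in `[0, 1]`.
#' @param mode `"none"`, `"rate"` or `"initial"`.
#' @param map List with numeric vectors `tau3` (ascending) and `value`.
#' @return Multipliers (`rate` mode, `>= 1` expected) or held initial values
#'   (`initial` mode, `<= 1`); 1 for `mode = "none"`.
#' @export
tau1_modulation <- function(tau3, mode = c("none", "rate", "initial"),
                            map = NULL) {
  mode <- match.arg(mode)
  if (mode == "none") return(rep(1, length(tau3)))
  if (is.null(map) || is.null(map$tau3) || is.null(map$value))
    stop("tau1 modulation needs a map with 'tau3' and 'value' control points")
  x <- as.numeric(map$tau3); y <- as.numeric(map$value)
  if (is.unsorted(x, strictly = TRUE))
    stop("modulation map 'tau3' must be strictly increasing")
  out <- stats::approx(x, y, xout = tau3, rule = 2)$y
  if (mode == "rate" && any(out < 0)) stop("rate multipliers must be >= 0")
  if (mode == "initial" && any(out < 0 | out > 1))
    stop("held initial values must lie in [0, 1]")
  out
}

#' Oscillator output as a function of timer 3
#'
#' In the clock-free simultaneous model the oscillator loses its autonomous
#' dynamics and becomes a static periodic function of the axial timer:
#' `o = (sin(2 pi (m tau3 - 1/4)) + 1) / 2`, with `m` output peaks per unit
#' of `tau3`. It reuses the autonomous oscillator waveform with a compressed
#' argument so that downstream peak-triggered machinery (timer-2 resets)
#' operates unchanged.
#'
#' @param tau3 Levels in `[0, 1]`.
#' @param m Integer number of repeats (`>= 1`).
#' @return Output levels in `[0, 1]`.
#' @export
oscillator_as_function <- function(tau3, m) {
  stopifnot(m >= 1, m == as.integer(m),
            all(tau3 >= 0 & tau3 <= 1, na.rm = TRUE))
  (sin(2 * pi * (m * tau3 - 0.25)) + 1) / 2
}
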