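#' Frequency profiles
#'
#' A frequency profile maps the maturation state of a cell (timer-1 level or
#' positional-information value, `tau` in `[0, 1]`) to a multiplicative scaling
#' of a module's intrinsic rate, `f(tau)` in `[0, 1]`. It is the source of
#' kinematic-wave narrowing: cells that are further along their maturation
#' trajectory oscillate more slowly. Profiles must be monotone non-decreasing
#' with `f(1) = 1`.
#'
#' Available forms:
#' * `"exp2"` (default): `f(tau) = (1 - exp(-2 tau)) / (1 - exp(-2))`, a
#'   saturating profile with `f(0) = 0`.
#' * `"uniform"`: `f(tau) = 1` everywhere; all cells share one frequency and
#'   no differential phase accumulates across the SAZ.
#' * `"linear"`: `f(tau) = tau`.
#' * A custom piecewise-linear profile given as a list with numeric vectors
#'   `x` (tau, ascending, spanning `[0, 1]`) and `y` (scale values).
#'
#' @param form `"exp2"`, `"uniform"`, `"linear"`, or a list with elements
#'   `x` and `y` giving piecewise-linear control points.
#' @return An object of class `freq_profile`.
#' @examples
#' fp <- frequency_profile("exp2")
#' frequency_scale(c(0, 0.5, 1), fp)
#' @export
frequency_profile <- function(form = "exp2") {
  if (inherits(form, "freq_profile")) return(form)
  if (is.character(form)) {
    form <- match.arg(form, c("exp2", "uniform", "linear"))
    prof <- structure(list(form = form), class = "freq_profile")
    return(prof)
  }
  if (is.list(form) && !is.null(form$x) && !is.null(form$y)) {
    x <- as.numeric(form$x); y <- as.numeric(form$y)
    if (length(x) < 2L || length(x) != length(y))
      stop("custom frequency profile needs matched 'x' and 'y' vectors (>= 2 points)")
    if (is.unsorted(x, strictly = TRUE))
      stop("frequency profile 'x' must be strictly increasing")
    if (min(x) > 0 || max(x) < 1)
      stop("frequency profile must be defined on all of [0, 1]")
    if (is.unsorted(y))
      stop("frequency profile must be monotone non-decreasing")
    if (any(y < 0) || any(y > 1))
      stop("frequency profile values must lie in [0, 1]")
    y1 <- stats::approx(x, y, xout = 1)$y
    if (abs(y1 - 1) > 1e-12)
      stop("frequency profile must satisfy f(1) = 1")
    return(structure(list(form = "custom", x = x, y = y), class = "freq_profile"))
  }
  stop("unrecognized frequency profile specification")
}

#' Evaluate a frequency profile
#'
#' @param tau Numeric vector of maturation states in `[0, 1]`.
#' @param profile A [frequency_profile()] (or a specification accepted by it).
#' @return Rate multipliers `f(tau)` in `[0, 1]`.
#' @export
frequency_scale <- function(tau, profile = frequency_profile("exp2")) {
  profile <- frequency_profile(profile)
  stopifnot(all(tau >= 0 & tau <= 1, na.rm = TRUE))
  switch(profile$form,
    exp2    = (1 - exp(-2 * tau)) / (1 - exp(-2)),
    uniform = rep(1, length(tau)),
    linear  = tau,
    custom  = stats::approx(profile$x, profile$y, xout = tau, rule = 2)$y
  )
}

#' Growth profiles
#'
#' A growth profile maps the axial timer (timer 3, `tau3` in `[0, 1]`) to an
#' elongation rate `v >= 0` (cells per time step). Its shape sculpts the
#' anteroposterior distribution of segment sizes; it must satisfy `v(0) = 0`,
#' which terminates axis extension when timer 3 is exhausted.
#'
#' @param tau3 Ascending numeric vector of control-point abscissae spanning
#'   `[0, 1]`.
#' @param v Non-negative rates at the control points; `v` at `tau3 = 0`
#'   must be 0.
#' @return An object of class `growth_profile`.
#' @examples
#' gp <- growth_profile(tau3 = c(0, 1), v = c(0, 0.5))
#' growth_rate(c(0, 0.5, 1), gp)
#' @export
growth_profile <- function(tau3 = c(0, 1), v = c(0, 0.2)) {
  if (inherits(tau3, "growth_profile")) return(tau3)
  if (is.list(tau3) && !is.null(tau3$tau3)) {
    v <- as.numeric(tau3$v); tau3 <- as.numeric(tau3$tau3)
  }
  tau3 <- as.numeric(tau3); v <- as.numeric(v)
  if (length(tau3) < 2L || length(tau3) != length(v))
    stop("growth profile needs matched 'tau3' and 'v' vectors (>= 2 points)")
  if (is.unsorted(tau3, strictly = TRUE))
    stop("growth profile 'tau3' must be strictly increasing")
  if (min(tau3) > 0 || max(tau3) < 1)
    stop("growth profile must be defined on all of [0, 1]")
  if (any(v < 0)) stop("growth profile rates must be non-negative")
  if (abs(v[tau3 == 0]) > 0 || tau3[1] != 0)
    stop("growth profile must satisfy v(0) = 0")
  structure(list(tau3 = tau3, v = v), class = "growth_profile")
}

#' Evaluate a growth profile
#'
#' @param tau3 Numeric vector of timer-3 levels in `[0, 1]`.
#' @param profile A [growth_profile()].
#' @return Elongation rates (cells per step).
#' @export
growth_rate <- function(tau3, profile) {
  profile <- growth_profile(profile)
  stopifnot(all(tau3 >= 0 & tau3 <= 1, na.rm = TRUE))
  stats::approx(profile$tau3, profile$v, xout = tau3, rule = 2)$y
}

#' Switch mappings
#'
#' A switch mapping partitions the input domain `[0, 1]` into `n` contiguous
#' half-open intervals `[a, b)` (bin edges belong to the higher-input
#' interval; the top interval is closed at 1), each labelled with a fate in
#' `1..n`. Preset mappings use equal-width bins with states numbered from the
#' top of the input domain downwards, so that a sawtooth input decaying from
#' 1 produces the fate sequence `1, 2, ..., n` along the axis:
#' * `"binary"`: 1 threshold, 2 states (vertebrate-like polarity).
#' * `"three_state"`: 2 thresholds, 3 states (arthropod-like single-segment
#'   polarity).
#' * `"pair_rule"`: 5 thresholds, 6 states (two triplet repeats per
#'   double-segment unit, insect/centipede-like).
#'
#' @param thresholds Strictly increasing thresholds inside `(0, 1)`, or a
#'   preset name.
#' @param states Integer state labels for the bins in ascending input order
#'   (length `length(thresholds) + 1`). Defaults to descending labels
#'   `n, n-1, ..., 1` so the highest input bin is state 1.
#' @return An object of class `switch_mapping` with fields `thresholds`,
#'   `states` and `n`.
#' @examples
#' m <- switch_mapping("three_state")
#' fate_from_mapping(c(0.95, 0.5, 0.1), m)
#' @export
switch_mapping <- function(thresholds = "binary", states = NULL) {
  if (inherits(thresholds, "switch_mapping")) return(thresholds)
  if (is.list(thresholds) && !is.null(thresholds$thresholds)) {
    states <- thresholds$states
    thresholds <- thresholds$thresholds
  }
  if (is.character(thresholds)) {
    name <- match.arg(thresholds, c("binary", "three_state", "pair_rule"))
    n <- switch(name, binary = 2L, three_state = 3L, pair_rule = 6L)
    thresholds <- seq_len(n - 1L) / n
  }
  thresholds <- as.numeric(thresholds)
  n <- length(thresholds) + 1L
  if (n < 1L) stop("mapping needs at least one state")
  if (length(thresholds) &&
      (is.unsorted(thresholds, strictly = TRUE) ||
       min(thresholds) <= 0 || max(thresholds) >= 1))
    stop("mapping thresholds must be strictly increasing within (0, 1)")
  if (is.null(states)) states <- rev(seq_len(n))
  states <- as.integer(states)
  if (length(states) != n || anyDuplicated(states))
    stop("mapping needs one distinct state label per bin")
  structure(list(thresholds = thresholds, states = states, n = n),
            class = "switch_mapping")
}

#' Map a continuous input to a switch state
#'
#' Bin edges belong to the higher-input interval (half-open `[a, b)` bins
#' scanning downward from 1).
#'
#' @param input Numeric vector in `[0, 1]`.
#' @param mapping A [switch_mapping()].
#' @return Integer states.
#' @export
fate_from_mapping <- function(input, mapping) {
  mapping <- switch_mapping(mapping)
  stopifnot(all(input >= 0 & input <= 1, na.rm = TRUE))
  bin <- findInterval(input, mapping$thresholds) + 1L
  mapping$states[bin]
}

#' Positional-information value
#'
#' In spatial model variants the maturation timer is replaced by a
#' positional-information (PI) field read from a cell's distance to the
#' anterior edge of the posterior signal range. Signal-positive cells carry
#' the value 1 (distance 0). The default field is linear,
#' `max(0, 1 - d / lambda)`, mirroring the linear timer; an alternative
#' monotone shape may be supplied as piecewise-linear control points on the
#' scaled distance `u = d / lambda`.
#'
#' @param distance Non-negative distances in cell diameters.
#' @param lam SAZ length scale `lambda > 0` in cell diameters.
#' @param profile Optional list with `x` (scaled distance in `[0, 1]`,
#'   ascending) and `y` (values, non-increasing from 1 to 0).
#' @return PI values in `[0, 1]`.
#' @examples
#' pi_value(c(0, 4, 8, 12), lam = 8)
#' @export
pi_value <- function(distance, lam, profile = NULL) {
  stopifnot(lam > 0, all(distance >= 0))
  u <- distance / lam
  if (is.null(profile)) return(pmax(0, 1 - u))
  x <- as.numeric(profile$x); y <- as.numeric(profile$y)
  if (is.unsorted(x, strictly = TRUE) || x[1] != 0 || x[length(x)] != 1 ||
      y[1] != 1 || y[length(y)] != 0 || is.unsorted(rev(y)))
    stop("PI profile must decrease monotonically from 1 at u = 0 to 0 at u = 1")
  stats::approx(x, y, xout = pmin(u, 1), rule = 2)$y
}
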