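#' Posterior signal mask
#'
#' The posterior signalling centre (PSC) sits behind the posterior-most cell
#' and emits a Boolean signal over the `r` posterior-most cells. Without an
#' active PSC no cell is signal-positive.
#'
#' @param L Number of cells (`>= 1`).
#' @param r Signal range in cell diameters (`>= 1`).
#' @param psc_active Logical.
#' @return Logical vector of length `L` (index 1 = anterior-most cell).
#' @examples
#' signal_mask(10, 3, TRUE)
#' @export
signal_mask <- function(L, r, psc_active = TRUE) {
  stopifnot(L >= 1, r >= 1)
  if (!psc_active) return(rep(FALSE, L))
  seq_len(L) > L - min(L, r)
}

#' Compile a configuration into executable wiring
#'
#' Resolves profiles, mappings and variant-specific couplings into the rule
#' set used by [step_embryo()] and [run_model()]: which modules exist, what
#' gates and rate-scales each one, how fates are handed over, and how the
#' elongation rate is computed.
#'
#' @param config A [seg_config()].
#' @return An internal wiring object (class `seg_wiring`).
#' @export
build_model <- function(config) {
  cfg <- validate_config(config)
  w <- list(
    config = cfg,
    variant = cfg$variant,
    modules = variant_modules(cfg$variant),
    spatial = cfg$saz_mode == "spatial",
    noclock = cfg$variant == "three_timers_no_clock",
    freeze_family = cfg$variant %in% c("freeze", "freeze_elongation_feedback",
                                       "freeze_timer_feedback"),
    fp_osc = frequency_profile(cfg$freq_profile_osc),
    # timer 2 shares the oscillator's profile unless told otherwise, keeping
    # the two modules phase-locked across the SAZ
    fp_tau2 = frequency_profile(
      if (is.null(cfg$freq_profile_tau2)) cfg$freq_profile_osc
      else cfg$freq_profile_tau2),
    gp = if (!is.null(cfg$growth_profile)) growth_profile(cfg$growth_profile),
    mapping = switch_mapping(cfg$mapping),
    mod13 = cfg$tau3_to_tau1,
    clamps = cfg$clamps
  )
  structure(w, class = "seg_wiring")
}

#' Initial embryo state
#'
#' Sequential variants start as a single row of `L0` cells (default 1) held
#' by the posterior signal; the clock-free variant starts at its final length
#' with its initial timer-3 gradient and no PSC.
#'
#' @param config A [seg_config()].
#' @return A `seg_state` list: per-cell vectors (`tau1`, `tau2`, `tau3`,
#'   `phase` (unwrapped, cycles), `osc`, `switch`, `signal`, `born`), the
#'   time counter `t`, growth accumulator `acc`, cell count `L` and
#'   `psc_active`. Modules absent from the variant are `NULL`.
#' @export
init_state <- function(config) {
  cfg <- validate_config(config)
  mods <- variant_modules(cfg$variant)
  if (cfg$variant == "three_timers_no_clock") {
    L <- as.integer(cfg$noclock$L_final)
    tau3 <- seq(cfg$noclock$tau3_anterior, cfg$noclock$tau3_posterior,
                length.out = L)
    st <- list(t = 0L, L = L, acc = 0, psc_active = FALSE,
               born = rep(0L, L),
               tau1 = rep(1, L), tau2 = rep(1, L), tau3 = tau3,
               phase = rep(NA_real_, L),
               osc = oscillator_as_function(tau3, cfg$m_repeats),
               switch = rep(0L, L),
               signal = rep(FALSE, L))
    return(structure(st, class = "seg_state"))
  }
  L <- as.integer(cfg$L0)
  sig <- signal_mask(L, cfg$r, TRUE)
  tau1 <- if (cfg$saz_mode == "spatial") {
    s0 <- L - min(L, cfg$r) + 1L
    val <- pi_value(pmax(0, s0 - seq_len(L)), cfg$lam, cfg$pi_profile)
    val[sig] <- 1
    val
  } else rep(1, L)
  st <- list(t = 0L, L = L, acc = 0, psc_active = TRUE,
             born = rep(0L, L),
             tau1 = tau1,
             tau2 = if (mods[["tau2"]]) rep(1, L),
             tau3 = if (mods[["tau3"]]) rep(1, L),
             phase = rep(0, L),
             osc = rep(oscillator_output(0), L),
             switch = if (mods[["switch"]]) rep(0L, L),
             signal = sig)
  structure(st, class = "seg_state")
}

#' Elongate by posterior-cell duplication
#'
#' Adds `v_effective` to the fractional growth accumulator; while the
#' accumulator is at least 1, the posterior-most cell is duplicated with all
#' its state variables and the accumulator decremented by 1. Each addition
#' displaces the PSC posteriorly by one cell diameter.
#'
#' @param state A `seg_state`.
#' @param v_effective Elongation rate this step (`>= 0`).
#' @return The state, grown as required.
#' @export
elongate <- function(state, v_effective) {
  stopifnot(v_effective >= 0)
  state$acc <- state$acc + v_effective
  # tolerance so that repeated addition of e.g. 0.3 still yields floor(v * N)
  # additions over N steps despite binary floating point
  n_add <- floor(state$acc + 1e-9)
  if (n_add >= 1) {
    state$acc <- max(0, state$acc - n_add)
    L <- state$L
    idx <- c(seq_len(L), rep(L, n_add))
    for (f in c("tau1", "tau2", "tau3", "phase", "osc", "switch", "signal"))
      if (!is.null(state[[f]])) state[[f]] <- state[[f]][idx]
    state$born <- c(state$born, rep(state$t, n_add))
    state$L <- L + as.integer(n_add)
  }
  state
}

# one synchronous update: signal -> module updates from the t_n snapshot ->
# fate handover (using just-updated values) -> elongation
.step_core <- function(st, w) {
  cfg <- w$config
  L <- st$L
  sig <- signal_mask(L, cfg$r, st$psc_active)

  ## --- timer 3 (needed first in the clock-free variant, where it drives o)
  tau3_new <- NULL
  if (w$modules[["tau3"]]) {
    tau3_new <- timer3_update(st$tau3, in_saz = st$tau1 > 0, cfg$T3)
    if (!is.null(w$clamps$tau3)) tau3_new[] <- w$clamps$tau3
  }

  ## --- timer 1 / PI field
  if (w$spatial) {
    if (st$psc_active) {
      s0 <- L - min(L, cfg$r) + 1L
      tau1_new <- pi_value(pmax(0, s0 - seq_len(L)), cfg$lam, cfg$pi_profile)
      tau1_new[sig] <- 1
    } else tau1_new <- st$tau1  # no signal source: field frozen in place
  } else {
    rs1 <- rep(1, L)
    held_value <- 1
    if (w$variant == "freeze_timer_feedback")
      rs1 <- rs1 * timer_rate_feedback(st$osc, cfg$k)
    if (!is.null(w$mod13) && w$mod13$mode == "rate")
      rs1 <- rs1 * tau1_modulation(st$tau3, "rate", w$mod13$map)
    if (!is.null(w$mod13) && w$mod13$mode == "initial")
      held_value <- tau1_modulation(st$tau3, "initial", w$mod13$map)
    tau1_new <- timer_update(st$tau1, held = sig, rate_scale = rs1,
                             T = cfg$T1, held_value = held_value)
  }
  if (!is.null(w$clamps$tau1)) tau1_new[] <- w$clamps$tau1

  ## --- oscillator
  if (w$noclock) {
    phase_new <- st$phase
    expressed <- st$tau1 > 0
    osc_new <- ifelse(expressed,
                      oscillator_as_function(tau3_new, cfg$m_repeats), st$osc)
    # downward crossing of an output peak as tau3 falls
    crossed <- expressed &
      floor(cfg$m_repeats * tau3_new - 0.5) <
      floor(cfg$m_repeats * st$tau3 - 0.5)
  } else {
    gate <- st$tau1
    phase_new <- oscillator_update(st$phase, gate, cfg$P, w$fp_osc)
    crossed <- floor(phase_new - 0.5) > floor(st$phase - 0.5)
    osc_new <- ifelse(gate > 0 | w$freeze_family,
                      oscillator_output(phase_new), 0)
  }
  if (!is.null(w$clamps$oscillator)) {
    osc_new[] <- w$clamps$oscillator
    phase_new <- st$phase
    crossed <- rep(FALSE, L)
  }

  ## --- timer 2 (peak detection sees both the sampled level and whether the
  ##     phase crossed the peak within the step, so fast cells cannot alias
  ##     past the threshold window)
  tau2_new <- NULL
  if (w$modules[["tau2"]]) {
    expressed2 <- st$tau1 > 0
    rs2 <- if (w$noclock) 1 else frequency_scale(st$tau1, w$fp_tau2)
    o_eff <- pmax(osc_new, as.numeric(crossed))
    tau2_new <- timer2_update(st$tau2, o_eff, cfg$theta, cfg$T2,
                              expressed2, rs2)
    if (!is.null(w$clamps$tau2)) tau2_new[] <- w$clamps$tau2
  }

  ## --- fate handover at the determination front
  switch_new <- st$switch
  if (w$modules[["switch"]]) {
    newly <- switch_new == 0L & tau1_new <= 0
    if (any(newly)) {
      switch_new[newly] <-
        if (w$variant == "clock_timer") fate_from_oscillator(osc_new[newly])
        else fate_from_mapping(tau2_new[newly], w$mapping)
    }
  }

  ## --- consistency guard
  rng <- function(x) !is.null(x) && any(x < -1e-12 | x > 1 + 1e-12, na.rm = TRUE)
  if (rng(tau1_new) || rng(tau2_new) || rng(tau3_new) || rng(osc_new))
    stop("state inconsistency: a module level left [0, 1]")

  ## --- PSC extinction: in the temporal three-timer model the signalling
  ##     centre dies with the axial timer, letting the SAZ run out
  psc <- st$psc_active
  if (w$variant == "clock_three_timers" && !w$spatial && psc &&
      tau3_new[L] <= 0)
    psc <- FALSE

  ## --- elongation rate for this step
  v_eff <- 0
  if (psc) {
    v_eff <- if (w$variant == "clock_three_timers")
      growth_rate(tau3_new[L], w$gp) else cfg$v
    if (w$variant == "freeze_elongation_feedback" &&
        !elongation_gate(osc_new[L]))
      v_eff <- 0
  }

  st2 <- st
  st2$t <- st$t + 1L
  st2$tau1 <- tau1_new
  if (!is.null(tau2_new)) st2$tau2 <- tau2_new
  if (!is.null(tau3_new)) st2$tau3 <- tau3_new
  st2$phase <- phase_new
  st2$osc <- osc_new
  st2$switch <- switch_new
  st2$psc_active <- psc
  st2 <- elongate(st2, v_eff)
  st2$signal <- signal_mask(st2$L, cfg$r, psc)
  # the PI field is an instantaneous read of distance-to-signal, so after
  # growth it is re-evaluated at the new geometry (cells duplicated this step
  # would otherwise carry a stale maturation value into the recorded state);
  # cells the moving front just passed hand over now, while their oscillator
  # value is still current
  if (w$spatial && psc && st2$L > L) {
    s0 <- st2$L - min(st2$L, cfg$r) + 1L
    pi_new <- pi_value(pmax(0, s0 - seq_len(st2$L)), cfg$lam, cfg$pi_profile)
    pi_new[st2$signal] <- 1
    if (w$modules[["switch"]]) {
      newly <- st2$switch == 0L & pi_new <= 0
      if (any(newly)) {
        st2$switch[newly] <-
          if (w$variant == "clock_timer") fate_from_oscillator(st2$osc[newly])
          else fate_from_mapping(st2$tau2[newly], w$mapping)
      }
    }
    st2$tau1 <- pi_new
  }
  attr(st2, "v_eff") <- v_eff
  st2
}

#' Advance an embryo one time step
#'
#' All cells are updated synchronously from the current snapshot (signal
#' recomputation, module updates, fate handover, then elongation).
#'
#' @param state A `seg_state`.
#' @param config The matching [seg_config()] (or a prebuilt [build_model()]
#'   wiring).
#' @return The state at the next time step.
#' @export
step_embryo <- function(state, config) {
  w <- if (inherits(config, "seg_wiring")) config else build_model(config)
  .step_core(state, w)
}

#' Run a simulation
#'
#' Runs `config$steps` synchronous updates from the variant's initial
#' conditions and records every state variable at every step.
#'
#' @param config A [seg_config()] or preset name.
#' @param verbose Emit a progress line every 100 steps and a final summary.
#' @return A `seg_history`: a list with element `vars` (one `time x cell`
#'   matrix per variable, rows `t = 0..steps`, columns = final cell indices,
#'   `NA` before a cell's birth), `config`, `born` (birth step per cell),
#'   `t`, `v_eff` (realized elongation rate per step), `term_step` (first
#'   step at which every cell is fated/frozen, or `NA`) and `final` (the
#'   final `seg_state`).
#' @examples
#' h <- run_model(seg_config("clock_timer", steps = 150))
#' dim(h$vars$tau1)
#' @export
run_model <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- preset_config(config)
  w <- build_model(config)
  cfg <- w$config
  st <- init_state(cfg)
  steps <- as.integer(cfg$steps)

  v_hi <- if (w$variant == "clock_three_timers") max(w$gp$v) else cfg$v
  Lmax <- st$L + as.integer(ceiling(v_hi * steps)) + 1L
  vars <- c("tau1", "phase", "osc",
            if (w$modules[["tau2"]]) "tau2",
            if (w$modules[["tau3"]]) "tau3",
            if (w$modules[["switch"]]) "switch", "signal")
  mats <- lapply(vars, function(v) matrix(NA_real_, steps + 1L, Lmax))
  names(mats) <- vars
  rec <- function(row, st) {
    i <- seq_len(st$L)
    for (v in vars) mats[[v]][row, i] <<- as.numeric(st[[v]])
  }
  rec(1L, st)
  v_eff <- numeric(steps)
  term_step <- NA_integer_
  for (s in seq_len(steps)) {
    st <- .step_core(st, w)
    rec(s + 1L, st)
    v_eff[s] <- attr(st, "v_eff")
    if (is.na(term_step)) {
      done <- if (w$modules[["switch"]]) all(st$switch > 0L)
              else all(st$tau1 <= 0)
      if (done) term_step <- st$t
    }
    if (verbose && s %% 100L == 0L)
      message(sprintf("step %d: L = %d, SAZ = %d", s, st$L, saz_length(st)))
  }
  mats <- lapply(mats, function(m) m[, seq_len(st$L), drop = FALSE])
  h <- structure(list(vars = mats, config = cfg, born = st$born,
                      t = 0:steps, v_eff = v_eff, term_step = term_step,
                      final = st),
                 class = "seg_history")
  if (verbose) print(h)
  h
}

#' @export
print.seg_history <- function(x, ...) {
  segs <- tryCatch({
    p <- final_pattern(x)
    if (all(p > 0)) length(segment_lengths(p, flag = FALSE)) else
      length(segment_lengths(p[p > 0], flag = FALSE))
  }, error = function(e) NA_integer_)
  cat("<seg_history>", x$config$variant,
      if (x$config$saz_mode != "none") paste0("(", x$config$saz_mode, ")"), "\n")
  cat("  steps:", max(x$t), " final length:", x$final$L,
      " complete interior segments:", segs,
      " termination step:", x$term_step, "\n")
  invisible(x)
}

#' Final fate pattern of a run
#'
#' For switch-bearing variants, the final switch state per cell (0 =
#' unfated). For freeze-readout variants, an indicator of frozen cells.
#'
#' @param history A `seg_history`.
#' @return Integer vector over cells.
#' @export
final_pattern <- function(history) {
  stopifnot(inherits(history, "seg_history"))
  st <- history$final
  if (!is.null(st$switch)) return(as.integer(st$switch))
  as.integer(st$tau1 <= 0)
}
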