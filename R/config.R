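.variants <- c("clock_timer", "clock_two_timers", "freeze",
               "freeze_elongation_feedback", "freeze_timer_feedback",
               "clock_three_timers", "three_timers_no_clock")

# spatial (PI-field) counterparts exist for these variants only
.spatial_variants <- c("clock_timer", "freeze", "freeze_elongation_feedback",
                       "freeze_timer_feedback", "clock_three_timers")

#' Which dynamical modules a variant carries
#'
#' @param variant Variant name.
#' @return Named logical vector over `tau1`, `oscillator`, `tau2`, `tau3`,
#'   `switch`.
#' @export
variant_modules <- function(variant) {
  variant <- match.arg(variant, .variants)
  c(tau1 = TRUE,
    oscillator = TRUE,
    tau2 = variant %in% c("clock_two_timers", "clock_three_timers",
                          "three_timers_no_clock"),
    tau3 = variant %in% c("clock_three_timers", "three_timers_no_clock"),
    switch = !(variant %in% c("freeze", "freeze_elongation_feedback",
                              "freeze_timer_feedback")))
}

.config_keys <- c("variant", "saz_mode", "L0", "steps",
                  "T1", "T2", "T3", "P", "v", "r", "lam", "theta", "k",
                  "mapping", "freq_profile_osc", "freq_profile_tau2",
                  "growth_profile", "tau3_to_tau1", "pi_profile",
                  "m_repeats", "noclock", "clamps")

#' Build and validate a model configuration
#'
#' Assembles the complete parameter set for one simulation: the model
#' variant, SAZ regulation mode, module durations and couplings, mappings
#' and profiles, clamps ("mutant" overrides), initial length and run length.
#' Unspecified parameters take documented illustrative defaults
#' (`P = 20`, `T1 = 40`, `T2 = 20`, `T3 = 600`, `v = 0.2`, `r = 5`,
#' `theta = 0.995`, `lam = 8`, `k = 2`, `L0 = 1`, `steps = 400`).
#'
#' @param .variant One of `"clock_timer"`, `"clock_two_timers"`, `"freeze"`,
#'   `"freeze_elongation_feedback"`, `"freeze_timer_feedback"`,
#'   `"clock_three_timers"`, `"three_timers_no_clock"`. (Dot-prefixed so that
#'   the short parameter name `v` cannot partially match it; `variant = ` is
#'   also accepted among the `...`.)
#' @param ... Named parameter overrides; unknown names are rejected.
#' @return A validated list of class `seg_config`.
#' @examples
#' cfg <- seg_config("clock_timer", P = 20, v = 0.2, steps = 100)
#' @export
seg_config <- function(.variant = "clock_timer", ...) {
  dots <- list(...)
  if (length(dots) && (is.null(names(dots)) || any(names(dots) == "")))
    stop("all configuration parameters must be named")
  if (is.null(dots$variant)) dots$variant <- .variant
  validate_config(dots)
}

#' Validate a configuration list
#'
#' Checks key set, parameter ranges, variant/mode compatibility and profile
#' well-formedness; fills variant-dependent defaults. Called by
#' [seg_config()] and [load_config()].
#'
#' @param cfg A configuration list.
#' @return The canonicalized `seg_config`.
#' @export
validate_config <- function(cfg) {
  if (inherits(cfg, "seg_config")) cfg <- unclass(cfg)
  unknown <- setdiff(names(cfg), .config_keys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(variant = "clock_timer", saz_mode = NULL, L0 = 1,
                   steps = 400, T1 = 40, T2 = 20, T3 = 600, P = 20, v = 0.2,
                   r = 5, lam = 8, theta = 0.995, k = 2,
                   mapping = "binary",
                   freq_profile_osc = "exp2", freq_profile_tau2 = NULL,
                   growth_profile = NULL, tau3_to_tau1 = NULL,
                   pi_profile = NULL, m_repeats = 1, noclock = NULL,
                   clamps = list())
  cfg <- utils::modifyList(defaults,
                           cfg[!vapply(cfg, is.null, logical(1))],
                           keep.null = TRUE)

  cfg$variant <- match.arg(cfg$variant, .variants)
  noclock <- cfg$variant == "three_timers_no_clock"
  if (is.null(cfg$saz_mode)) cfg$saz_mode <- if (noclock) "none" else "temporal"
  cfg$saz_mode <- match.arg(cfg$saz_mode, c("temporal", "spatial", "none"))
  if (noclock && cfg$saz_mode != "none")
    stop("three_timers_no_clock has no SAZ mode (no PSC); use saz_mode = 'none'")
  if (!noclock && cfg$saz_mode == "none")
    stop("saz_mode 'none' is only meaningful for three_timers_no_clock")
  if (cfg$saz_mode == "spatial" && !(cfg$variant %in% .spatial_variants))
    stop("variant '", cfg$variant, "' is defined only temporally; ",
         "spatial saz_mode is not supported for it")

  num1 <- function(key, lo = -Inf, hi = Inf, lo_open = FALSE) {
    x <- cfg[[key]]
    if (is.null(x) || length(x) != 1L || !is.numeric(x) || is.na(x))
      stop("parameter '", key, "' must be a single number")
    if (x < lo || x > hi || (lo_open && x == lo))
      stop("parameter '", key, "' out of range")
    as.numeric(x)
  }
  cfg$L0 <- num1("L0", 1); cfg$steps <- num1("steps", 0)
  if (cfg$L0 != round(cfg$L0) || cfg$steps != round(cfg$steps))
    stop("'L0' and 'steps' must be whole numbers")
  cfg$T1 <- num1("T1", 1); cfg$T2 <- num1("T2", 1); cfg$T3 <- num1("T3", 1)
  cfg$P <- num1("P", 1); cfg$v <- num1("v", 0); cfg$r <- num1("r", 1)
  cfg$lam <- num1("lam", 0, lo_open = TRUE)
  cfg$theta <- num1("theta", 0, 1, lo_open = TRUE)
  cfg$k <- num1("k", 0)
  cfg$m_repeats <- num1("m_repeats", 1)
  if (cfg$m_repeats != round(cfg$m_repeats))
    stop("'m_repeats' must be a whole number")

  # structured sub-objects: validated by their constructors
  cfg$mapping <- unclass_map(switch_mapping(cfg$mapping))
  cfg$freq_profile_osc <- unclass_fp(frequency_profile(cfg$freq_profile_osc))
  if (!is.null(cfg$freq_profile_tau2))
    cfg$freq_profile_tau2 <- unclass_fp(frequency_profile(cfg$freq_profile_tau2))
  if (!is.null(cfg$growth_profile))
    cfg$growth_profile <- unclass(growth_profile(cfg$growth_profile))
  if (cfg$variant == "clock_three_timers" && is.null(cfg$growth_profile))
    cfg$growth_profile <- unclass(growth_profile(
      tau3 = c(0, 0.05, 1), v = c(0, cfg$v, cfg$v)))
  if (!is.null(cfg$pi_profile))
    pi_value(0, cfg$lam, cfg$pi_profile)  # validates shape
  if (!is.null(cfg$tau3_to_tau1)) {
    mode <- cfg$tau3_to_tau1$mode
    if (is.null(mode) || !mode %in% c("none", "rate", "initial"))
      stop("tau3_to_tau1 mode must be 'none', 'rate' or 'initial'")
    if (mode != "none") {
      if (!(cfg$variant %in% c("clock_three_timers")))
        stop("tau3_to_tau1 modulation requires the clock_three_timers variant")
      tau1_modulation(c(0, 1), mode, cfg$tau3_to_tau1$map)  # validates map
    }
  }

  if (noclock) {
    nc <- cfg$noclock
    if (is.null(nc))
      stop("three_timers_no_clock requires a 'noclock' initial-condition block")
    need <- c("L_final", "tau3_anterior", "tau3_posterior")
    if (!all(need %in% names(nc)))
      stop("'noclock' block needs fields: ", paste(need, collapse = ", "))
    nc$L_final <- as.numeric(nc$L_final)
    if (nc$L_final < 2 || nc$L_final != round(nc$L_final))
      stop("'noclock$L_final' must be a whole number >= 2")
    if (nc$tau3_anterior <= nc$tau3_posterior)
      stop("noclock tau3 gradient must decrease strictly from anterior to posterior")
    if (nc$tau3_anterior > 1 || nc$tau3_posterior < 0)
      stop("noclock tau3 gradient leaves [0, 1]")
    cfg$noclock <- nc[need]
  } else if (!is.null(cfg$noclock)) {
    stop("'noclock' block is only valid for three_timers_no_clock")
  }

  if (!is.null(cfg$clamps) && length(cfg$clamps)) {
    mods <- variant_modules(cfg$variant)
    ok <- names(mods)[mods]
    bad <- setdiff(names(cfg$clamps), setdiff(ok, "switch"))
    if (length(bad))
      stop("clamp on unknown/absent module(s): ", paste(bad, collapse = ", "))
    for (val in cfg$clamps)
      if (!is.numeric(val) || length(val) != 1L || val < 0 || val > 1)
        stop("clamp values must be single numbers in [0, 1]")
  } else cfg$clamps <- list()

  structure(cfg, class = "seg_config")
}

# strip classes so configs stay plain JSON-serializable lists
unclass_map <- function(m) list(thresholds = m$thresholds, states = m$states)
unclass_fp <- function(p) if (p$form == "custom") list(x = p$x, y = p$y) else p$form

#' @export
print.seg_config <- function(x, ...) {
  cat("<seg_config> variant:", x$variant,
      if (x$saz_mode != "none") paste0("(", x$saz_mode, ")"), "\n")
  cat("  T1:", x$T1, " T2:", x$T2, " T3:", x$T3, " P:", x$P,
      " v:", x$v, " r:", x$r, " lam:", x$lam, "\n")
  cat("  theta:", x$theta, " k:", x$k, " L0:", x$L0, " steps:", x$steps, "\n")
  if (length(x$clamps))
    cat("  clamps:", paste(names(x$clamps), unlist(x$clamps), sep = "=",
                           collapse = ", "), "\n")
  invisible(x)
}

#' Clamp a module to a fixed value ("mutant" run)
#'
#' The clamped module returns the fixed value at every step; all other rules
#' are unchanged. Clamping the oscillator also freezes its phase.
#'
#' @param config A [seg_config()].
#' @param module One of `"tau1"`, `"tau2"`, `"tau3"`, `"oscillator"`
#'   (must be present in the variant).
#' @param value Fixed level in `[0, 1]`.
#' @return The modified configuration.
#' @examples
#' cfg <- apply_clamp(preset_config("fig6_timer_feedback"), "oscillator", 0)
#' @export
apply_clamp <- function(config, module, value) {
  config <- validate_config(config)
  clamps <- config$clamps
  clamps[[module]] <- value
  config$clamps <- clamps
  validate_config(config)
}

#' Derive a matched clock-free initial condition
#'
#' Computes the initial timer-3 gradient for the simultaneous
#' (three-timers-no-clock) model so that its frozen pattern's repeat length
#' matches a sequential reference: with `m` oscillator-output peaks per unit
#' of `tau3`, a per-cell gradient slope `s` gives a spatial peak spacing of
#' `(1/m)/s` cells, so `s = 1 / (m * seg_length_target)`. The effective
#' temporal period experienced by each cell is `T3/m` steps, so a reference
#' with oscillator period `P` is matched by choosing `T3 = m * P`.
#'
#' @param seg_length_target Desired repeat length in cells (`>= 2`).
#' @param m Peaks per unit of `tau3` (`>= 1`, integer).
#' @param L_final Number of cells in the pre-grown embryo.
#' @param T1,T2,T3 Timer durations in steps.
#' @return An object of class `noclock_init` with the gradient endpoints,
#'   slope and timer durations.
#' @examples
#' derive_noclock_config(4, m = 4, L_final = 40, T1 = 40, T2 = 20, T3 = 80)
#' @export
derive_noclock_config <- function(seg_length_target, m, L_final,
                                  T1 = 40, T2 = 20, T3 = 20 * m) {
  stopifnot(seg_length_target >= 2, m >= 1, m == as.integer(m),
            L_final >= 2, T1 >= 1, T2 >= 1, T3 >= 1)
  slope <- (1 / m) / seg_length_target
  anterior <- 1
  posterior <- anterior - slope * (L_final - 1)
  if (posterior < 0)
    stop("tau3 gradient leaves [0, 1]: L_final exceeds 1/slope")
  if (posterior - T1 / T3 < 0)
    stop("tau3 gradient leaves [0, 1] during the run: the posterior value ",
         round(posterior, 4), " is depleted by T1/T3 = ", round(T1 / T3, 4))
  structure(list(seg_length_target = seg_length_target, m = m,
                 L_final = L_final, slope = slope,
                 tau3_anterior = anterior, tau3_posterior = posterior,
                 T1 = T1, T2 = T2, T3 = T3),
            class = "noclock_init")
}

#' Turn a `noclock_init` into a full configuration
#'
#' @param init A [derive_noclock_config()] result.
#' @param mapping Switch mapping (preset name or [switch_mapping()] spec).
#' @param steps Run length (default `T1 + 10`; patterning completes at
#'   `t = T1`).
#' @return A `seg_config` for the `three_timers_no_clock` variant.
#' @export
noclock_config <- function(init, mapping = "three_state",
                           steps = init$T1 + 10) {
  stopifnot(inherits(init, "noclock_init"))
  seg_config("three_timers_no_clock",
             T1 = init$T1, T2 = init$T2, T3 = init$T3,
             m_repeats = init$m, L0 = init$L_final, steps = steps,
             mapping = mapping, v = 0,
             noclock = list(L_final = init$L_final,
                            tau3_anterior = init$tau3_anterior,
                            tau3_posterior = init$tau3_posterior))
}

#' Preset configurations
#'
#' Named, fully specified example configurations, one per model family and
#' headline behaviour. Parameter values are illustrative choices (the models
#' are generic); each preset runs to completion and exhibits the behaviour it
#' is named after.
#'
#' @return `presets()` returns the preset names; `preset_config(name)` the
#'   full `seg_config`.
#' @examples
#' presets()
#' preset_config("fig3_temporal")
#' @export
presets <- function() {
  c("fig3_temporal", "fig3_spatial", "fig4_three_state", "fig4_pair_rule",
    "fig6_freeze", "fig6_elongation_feedback", "fig6_timer_feedback",
    "fig7_growth", "fig8_noclock")
}

#' @rdname presets
#' @param name Preset name (see `presets()`).
#' @export
preset_config <- function(name) {
  name <- match.arg(name, presets())
  switch(name,
    fig3_temporal = seg_config("clock_timer", saz_mode = "temporal",
                               steps = 400),
    fig3_spatial  = seg_config("clock_timer", saz_mode = "spatial",
                               steps = 400),
    fig4_three_state = seg_config("clock_two_timers", mapping = "three_state",
                                  v = 0.5, steps = 400),
    fig4_pair_rule = seg_config("clock_two_timers", mapping = "pair_rule",
                                P = 24, T2 = 24, T1 = 48, v = 0.5,
                                steps = 500),
    # P = 23 is coprime with the 5-step elongation rhythm at v = 0.2, so the
    # constant-velocity wavefront samples the whole phase circle instead of
    # phase-locking onto a few residues
    fig6_freeze = seg_config("freeze", P = 23, steps = 400),
    fig6_elongation_feedback = seg_config("freeze_elongation_feedback",
                                          steps = 600),
    fig6_timer_feedback = seg_config("freeze_timer_feedback", P = 23, k = 2,
                                     steps = 400),
    fig7_growth = seg_config("clock_three_timers", mapping = "three_state",
                             v = 0.5, T3 = 600, steps = 900,
                             growth_profile = list(tau3 = c(0, 1),
                                                   v = c(0, 0.5))),
    fig8_noclock = noclock_config(
      derive_noclock_config(seg_length_target = 20, m = 10, L_final = 141,
                            T1 = 40, T2 = 20, T3 = 200),
      mapping = "three_state", steps = 60)
  )
}
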