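#' SAZ length
#'
#' Number of cells with positive maturation state (timer 1 or PI value),
#' excluding signal-positive cells.
#'
#' @param state A `seg_state`.
#' @return Integer cell count.
#' @export
saz_length <- function(state) {
  sum(state$tau1 > 0 & !state$signal)
}

#' Determination-front (wavefront) position
#'
#' 1-based index of the anterior-most cell with positive maturation state,
#' i.e. one past the last fated cell; returns `L + 1` for a fully fated
#' embryo.
#'
#' @param state A `seg_state`.
#' @return Integer cell index.
#' @export
wavefront_position <- function(state) {
  idx <- which(state$tau1 > 0)
  if (!length(idx)) state$L + 1L else min(idx)
}

#' SAZ phase difference
#'
#' Difference in unwrapped oscillator phase (cycles) between the
#' posterior-most non-signal SAZ cell and the anterior-most SAZ cell; it
#' equals the number of kinematic-wave stripes spanning the SAZ. `NA` when
#' the SAZ is empty.
#'
#' @param state A `seg_state`.
#' @return Phase difference in cycles (`>= 0`), or `NA`.
#' @export
saz_phase_difference <- function(state) {
  ant <- which(state$tau1 > 0)
  post <- which(state$tau1 > 0 & !state$signal)
  if (!length(ant) || !length(post)) return(NA_real_)
  state$phase[max(post)] - state$phase[min(ant)]
}

# reconstruct a minimal seg_state from one history row
.row_state <- function(history, row) {
  alive <- !is.na(history$vars$tau1[row, ])
  st <- list(L = sum(alive))
  for (v in names(history$vars)) st[[v]] <- history$vars[[v]][row, alive]
  st$signal <- st$signal > 0
  if (!is.null(st$switch)) st$switch <- as.integer(st$switch)
  structure(st, class = "seg_state")
}

#' Segment lengths from a fate pattern
#'
#' Distances between successive anterior-to-posterior transitions into a
#' designated boundary state. The stretches before the first onset and after
#' the last onset (partial repeats) are excluded.
#'
#' @param pattern Integer fate states per cell, anterior to posterior.
#' @param boundary_state State id(s) whose onsets mark segment boundaries
#'   (default 1).
#' @param flag Warn when fewer than 2 onsets are found (default `TRUE`).
#' @return Integer vector of interior segment lengths (possibly empty).
#' @examples
#' segment_lengths(c(1, 1, 2, 2, 1, 1, 2, 2, 1))
#' @export
segment_lengths <- function(pattern, boundary_state = 1, flag = TRUE) {
  on <- .onsets(pattern, boundary_state)
  if (length(on) < 2L) {
    if (flag) warning("fewer than 2 boundary-state onsets: no complete segment")
    return(integer(0))
  }
  diff(on)
}

# onsets: positions i >= 2 where the pattern enters the boundary state set
.onsets <- function(pattern, boundary_state) {
  inb <- pattern %in% boundary_state
  which(inb & !c(TRUE, inb[-length(inb)]))
}

#' Per-step summary curves
#'
#' Time-resolved observables of a run: embryo length, SAZ length, realized
#' elongation rate, SAZ phase difference, determination-front and
#' posterior-tip positions, and the length of any segment completed at that
#' step.
#'
#' @param history A `seg_history`.
#' @return A data.frame with one row per recorded time point (`t = 0` up to
#'   `steps`) and columns `t`, `L`, `L_SAZ`, `v_eff`, `delta_phase`,
#'   `wavefront`, `tip`, `seg_length`.
#' @export
summary_curves <- function(history) {
  stopifnot(inherits(history, "seg_history"))
  n <- length(history$t)
  out <- data.frame(t = history$t, L = NA_integer_, L_SAZ = NA_integer_,
                    v_eff = c(NA_real_, history$v_eff),
                    delta_phase = NA_real_, wavefront = NA_integer_,
                    tip = NA_integer_, seg_length = NA_real_)
  for (i in seq_len(n)) {
    st <- .row_state(history, i)
    out$L[i] <- st$L
    out$L_SAZ[i] <- saz_length(st)
    out$delta_phase[i] <- saz_phase_difference(st)
    out$wavefront[i] <- wavefront_position(st)
    out$tip[i] <- st$L
  }
  sf <- tryCatch(segment_formation(history), error = function(e) NULL)
  if (!is.null(sf) && nrow(sf))
    out$seg_length[match(sf$t_formed, out$t)] <- sf$length
  out
}

#' Segment formation events
#'
#' For each complete interior segment of the final pattern, the step at which
#' it was completed (the step its posterior boundary cell acquired its fate),
#' its length, and the elongation rate realized at that step.
#'
#' @param history A `seg_history` from a switch-bearing variant.
#' @param boundary_state State id(s) marking segment boundaries (default 1).
#' @return A data.frame with columns `t_formed`, `length`, `v_at_formation`.
#' @export
segment_formation <- function(history, boundary_state = 1) {
  stopifnot(inherits(history, "seg_history"))
  sw <- history$vars$switch
  if (is.null(sw)) stop("variant has no switch module; no segments to time")
  pattern <- final_pattern(history)
  on <- .onsets(pattern, boundary_state)
  if (length(on) < 2L)
    return(data.frame(t_formed = integer(0), length = integer(0),
                      v_at_formation = numeric(0)))
  fate_row <- apply(sw[, on[-1L], drop = FALSE], 2L,
                    function(col) which(!is.na(col) & col > 0)[1L])
  t_formed <- history$t[fate_row]
  data.frame(t_formed = t_formed,
             length = diff(on),
             v_at_formation = history$v_eff[pmax(1L, t_formed)])
}

#' Recorded-phase distribution
#'
#' Histogram of the wrapped oscillator phases frozen into fated cells by a
#' freeze-readout run. With a constant-velocity wavefront all phases are
#' represented about equally; feedback on elongation or on the timer
#' restricts or reweights the recorded range.
#'
#' @param history A `seg_history` from a freeze-family variant.
#' @param bins Number of bins on `[0, 1)` (default 50).
#' @return An object of class `phase_histogram`: list with `breaks`,
#'   `counts` and the raw `phases`.
#' @export
recorded_phase_distribution <- function(history, bins = 50) {
  stopifnot(inherits(history, "seg_history"))
  if (!history$config$variant %in%
      c("freeze", "freeze_elongation_feedback", "freeze_timer_feedback"))
    stop("recorded phases are defined for freeze-readout variants only")
  st <- history$final
  phases <- (st$phase[st$tau1 <= 0]) %% 1
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- if (length(phases))
    tabulate(findInterval(phases, breaks, rightmost.closed = TRUE),
             nbins = bins) else integer(bins)
  structure(list(breaks = breaks, counts = counts, phases = phases),
            class = "phase_histogram")
}

#' Recorded-phase sweep
#'
#' Reruns a freeze-family configuration across a swept parameter and stacks
#' the recorded-phase histograms, one row per value.
#'
#' @param config Base [seg_config()] (freeze family).
#' @param param Name of the swept numeric parameter (e.g. `"T1"`, `"lam"`).
#' @param values Numeric vector of parameter values.
#' @param bins Number of phase bins.
#' @return Matrix `length(values) x bins` with `values` as rownames.
#' @export
recorded_phase_sweep <- function(config, param, values, bins = 50) {
  out <- matrix(0L, length(values), bins,
                dimnames = list(values, NULL))
  for (i in seq_along(values)) {
    cfg <- validate_config(config)
    cfg[[param]] <- values[i]
    out[i, ] <- recorded_phase_distribution(run_model(validate_config(cfg)),
                                            bins)$counts
  }
  out
}

#' Minimal circular span of a set of phases
#'
#' Length of the smallest arc of the unit phase circle containing all the
#' given wrapped phases.
#'
#' @param phases Phases in `[0, 1)`.
#' @return Span in cycles (0 for a single phase; `<= 1`).
#' @export
phase_span <- function(phases) {
  phases <- sort(unique(phases %% 1))
  if (length(phases) <= 1L) return(0)
  gaps <- diff(c(phases, phases[1L] + 1))
  1 - max(gaps)
}

#' Lag scaling of segment length on past SAZ length
#'
#' In runs with a time-varying elongation rate, new-segment length tracks the
#' SAZ length some time *ago* rather than the current one. This finds the lag
#' maximizing the Pearson correlation between segment length at formation
#' time `t` and `L_SAZ(t - lag)`, and reports the zero-lag correlation for
#' contrast.
#'
#' @param history A `seg_history` (switch-bearing variant, non-constant
#'   elongation).
#' @param max_lag Largest lag searched, in steps (must be below the run
#'   length).
#' @return List with `best_lag`, `best_cor`, `cor0` and the full `cors`
#'   vector (index 1 = lag 0).
#' @export
lag_scaling <- function(history, max_lag = 150) {
  stopifnot(inherits(history, "seg_history"))
  if (max_lag >= max(history$t)) stop("lag search window exceeds run length")
  if (stats::sd(history$v_eff) < 1e-12)
    stop("constant elongation rate: lag scaling is uninformative")
  sf <- segment_formation(history)
  if (nrow(sf) < 3L) stop("too few segments for lag analysis")
  curves <- summary_curves(history)
  saz <- curves$L_SAZ
  cors <- vapply(0:max_lag, function(lag) {
    tt <- sf$t_formed - lag
    keep <- tt >= 0
    if (sum(keep) < 3L) return(NA_real_)
    x <- saz[match(tt[keep], curves$t)]
    if (stats::sd(x) < 1e-12 || stats::sd(sf$length[keep]) < 1e-12)
      return(NA_real_)
    stats::cor(x, sf$length[keep])
  }, numeric(1))
  best <- which.max(cors)
  list(best_lag = best - 1L, best_cor = cors[best], cor0 = cors[1L],
       cors = cors)
}

#' Interior repeating unit of a fate pattern
#'
#' Extracts the consensus repeating unit of a fully fated pattern: units are
#' taken between consecutive onsets of the anchor state (the smallest state
#' id present) and the modal unit (by length and content) is returned,
#' making the extraction robust to irregular boundary segments.
#'
#' @param pattern Fully fated integer pattern.
#' @return Integer vector: one repeat, starting at an anchor onset.
#' @export
interior_repeat <- function(pattern) {
  if (any(is.na(pattern)) || any(pattern == 0L))
    stop("pattern contains unfated cells")
  anchor <- min(pattern)
  on <- .onsets(pattern, anchor)
  if (length(on) < 2L) stop("fewer than 2 anchor onsets: no repeating unit")
  units <- lapply(seq_len(length(on) - 1L),
                  function(j) pattern[on[j]:(on[j + 1L] - 1L)])
  keys <- vapply(units, paste, character(1), collapse = ",")
  units[[which(keys == names(which.max(table(keys))))[1L]]]
}

#' Pattern equivalence up to cyclic alignment
#'
#' Two patterns are equivalent when their interior repeating units have the
#' same length and identical state order under some cyclic rotation.
#'
#' @param a,b Fully fated integer patterns.
#' @return List with `equivalent` (logical), `repeat_a`, `repeat_b`, and
#'   `mismatches` (minimal Hamming distance over rotations when lengths
#'   match, else `NA`).
#' @export
pattern_equivalence <- function(a, b) {
  ra <- interior_repeat(a)
  rb <- interior_repeat(b)
  if (length(ra) != length(rb))
    return(list(equivalent = FALSE, repeat_a = ra, repeat_b = rb,
                mismatches = NA_integer_))
  n <- length(ra)
  mism <- min(vapply(seq_len(n) - 1L, function(s) {
    sum(ra != rb[((seq_len(n) - 1L + s) %% n) + 1L])
  }, numeric(1)))
  list(equivalent = mism == 0, repeat_a = ra, repeat_b = rb,
       mismatches = as.integer(mism))
}

#' Time-space transcription by a moving wavefront
#'
#' A stand-alone construction of wavefront readout: synchronous sinusoidal
#' oscillations of period `P` are frozen into a row of cells as a wavefront
#' passes. With `gate = "constant"` the front moves at `v` cells per step and
#' the spatial output is the temporal input scaled by `v`. With
#' `gate = "rising"` (or `"falling"`) the front moves at `multiplier * v`
#' only while the clock output is rising (falling), pausing otherwise, so
#' only half the cycle is transcribed; the mean progression matches the
#' constant case when `multiplier = 2`.
#'
#' @param P Oscillation period (steps).
#' @param v Baseline wavefront velocity (cells per step).
#' @param gate `"constant"`, `"rising"`, or `"falling"`.
#' @param multiplier Speed multiplier applied during the moving half-cycle.
#' @param cycles Number of oscillation cycles simulated.
#' @param warmup_cycles Cycles discarded before measuring the repeat.
#' @return List with `phases` (recorded wrapped phase per cell),
#'   `repeat_length` (cells transcribed per cycle at steady state) and
#'   `cells` (total cells transcribed).
#' @examples
#' transcribe_wavefront(20, 0.2, "rising", multiplier = 2)$repeat_length
#' @export
transcribe_wavefront <- function(P, v, gate = c("constant", "rising",
                                                "falling"),
                                 multiplier = 1, cycles = 30,
                                 warmup_cycles = 5) {
  gate <- match.arg(gate)
  stopifnot(P >= 2, v > 0, multiplier > 0, cycles > warmup_cycles)
  steps <- as.integer(round(cycles * P))
  pos <- 0
  phases <- numeric(0)
  t_rec <- integer(0)
  for (t in seq_len(steps)) {
    phi <- t / P
    moving <- switch(gate,
      constant = TRUE,
      rising  = (phi %% 1) >= 0 && (phi %% 1) < 0.5,
      falling = (phi %% 1) >= 0.5)
    speed <- if (moving) (if (gate == "constant") v else multiplier * v) else 0
    new_pos <- pos + speed
    # same tolerance as the engine accumulator, so repeated fractional
    # addition crosses cell boundaries exactly as rational arithmetic would
    n_new <- floor(new_pos + 1e-9) - floor(pos + 1e-9)
    if (n_new > 0) {
      phases <- c(phases, rep(phi %% 1, n_new))
      t_rec <- c(t_rec, rep(t, n_new))
    }
    pos <- new_pos
  }
  measured <- t_rec > warmup_cycles * P
  rep_len <- sum(measured) / (cycles - warmup_cycles)
  list(phases = phases, repeat_length = rep_len, cells = length(phases))
}

#' Speed multiplier matching a half-cycle wavefront to constant velocity
#'
#' Scans speed multipliers for a wavefront that progresses only during the
#' rising half of each oscillation cycle and returns the multiplier whose
#' recorded spatial repeat length equals that of a constant-velocity
#' wavefront moving at `v`.
#'
#' @param P Oscillation period (steps).
#' @param v Constant-case wavefront velocity.
#' @param multipliers Candidate multipliers.
#' @param cycles Cycles simulated per candidate.
#' @return The matching multiplier (numeric scalar); errors if none matches.
#' @export
matched_speed_multiplier <- function(P = 20, v = 0.2,
                                     multipliers = c(1, 1.5, 2, 2.5, 3),
                                     cycles = 30) {
  ref <- transcribe_wavefront(P, v, "constant", cycles = cycles)$repeat_length
  reps <- vapply(multipliers, function(m)
    transcribe_wavefront(P, v, "rising", multiplier = m,
                         cycles = cycles)$repeat_length, numeric(1))
  hit <- which(abs(reps - ref) < 1e-9)
  if (!length(hit)) stop("no candidate multiplier preserves the repeat length")
  multipliers[hit[1L]]
}
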