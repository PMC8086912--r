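---
title: "Dynamical-module models of segmentation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamical-module models of segmentation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segwave)
```

## The modelling framework

`segwave` simulates a one-dimensional row of largely autonomous cells — an
abstraction of the arthropod segment-addition zone (SAZ) and the vertebrate
presomitic mesoderm — in discrete time with synchronous update: the state of
every cell at $t_{n+1}$ is a function of the full snapshot at $t_n$, under
rules identical for all cells. A posterior signalling centre (PSC) sits
behind the posterior-most cell, emits a Boolean signal over the nearest $r$
cell diameters, and drives elongation: a fractional accumulator gains $v$
cells per step and, each time it exceeds 1, the posterior-most cell is
duplicated with all its state variables. At $v = 0.2$ a cell is added
exactly every 5 steps. The framework contains no randomness whatsoever; two
runs of the same configuration are bit-identical.

Cell state is a vector of **dynamical modules** of three kinds:

* a **timer** $\tau$ decreasing linearly from 1 to 0 at rate $1/T$
  (floored at 0), optionally held at an initial value by the signal;
* an **oscillator** with hidden phase $\phi$ advancing at rate $1/P$ and
  output $o = (\sin(2\pi(\phi - 1/4)) + 1)/2$;
* a **switch** with $n$ mutually exclusive states, written once and then
  immutable.

A **frequency profile** $f(\tau)$ (default
$(1 - e^{-2\tau})/(1 - e^{-2})$) scales the oscillator rate by the local
maturation state, producing anteriorly narrowing kinematic waves. Because a
frequency scaling in discrete time means multiplying per-step increments,
timer 2 shares the oscillator's profile by default; this keeps the two
modules phase-locked across the SAZ, which is what makes the timer-2 state a
faithful proxy of oscillator phase. Divergent profiles may be configured per
module (`freq_profile_osc`, `freq_profile_tau2`), in which case the pattern
acquires a dependence on the timer-1 time scale.

## Model variants

| variant | modules | patterning route |
|---|---|---|
| `clock_timer` | $\tau_1$, $o$, switch | binary fate from final $o$ ($>0.5 \to 1$, else 2) |
| `clock_two_timers` | + $\tau_2$ | switch reads $\tau_2$, reset to 1 at oscillator peaks ($o \ge \theta$) |
| `freeze` family | $\tau_1$, $o$ | oscillator phase frozen at $\tau_1 = 0$: a readout of the transcribed pattern |
| `clock_three_timers` | + $\tau_3$ | growth profile maps $\tau_3$ to $v$; termination at $\tau_3 = 0$ |
| `three_timers_no_clock` | $\tau_1..\tau_3$, static $o(\tau_3)$ | simultaneous patterning from an initial $\tau_3$ gradient |

Every variant with a timer-1 also exists in a **spatial** flavour (except
`clock_two_timers` and the clock-free model), where $\tau_1$ is replaced by
a positional-information (PI) field $\max(0, 1 - d/\lambda)$ read from the
distance $d$ to the anterior edge of the signal range. The temporal and
spatial variants respond differently to the elongation rate: with a timer,
$L_{SAZ} = T_1 v$ and the SAZ phase difference is independent of $v$; with
PI, $L_{SAZ}$ is fixed by $\lambda$ and the phase difference falls as $v$
rises. Both obey $L_{seg} = P v$.

## Parameters

All parameters are dimensionless or measured in time steps / cell diameters.
Defaults (`seg_config()`): $P = 20$, $T_1 = 40$, $T_2 = 20$, $T_3 = 600$,
$v = 0.2$, $r = 5$, $\theta = 0.995$, $\lambda = 8$, $k = 2$, $L_0 = 1$,
400 steps. These are illustrative; every preset documents its own choices
(`presets()`, `preset_config(name)`), and nothing in the package is fitted
to data.

## Numerical choices

**Growth accumulator tolerance.** The accumulator compares against 1 with a
$10^{-9}$ slack, so that repeated addition of binary-inexact rates such as
0.3 produces exactly $\lfloor vN \rfloor$ additions over $N$ steps, as
rational arithmetic would. The same slack is used by the stand-alone
wavefront-transcription construct.

**Peak detection.** Timer-2 resets fire when the sampled output satisfies
$o \ge \theta$ (inclusive, so a sampled value of exactly $\theta$ or an
exact 1.0 triggers) *or* when the unwrapped phase crossed the peak
($\phi \equiv 1/2 \bmod 1$) within the step. The second clause exists
because a discrete trajectory whose per-step phase increment exceeds the
width of the $\theta$ window ($\approx 0.045$ cycles at $\theta = 0.995$)
can otherwise step across a peak without ever sampling it; the crossing test
removes this aliasing without changing where resets occur for
well-resolved trajectories.

**Boundary conventions.** Switch-mapping bins are half-open $[a, b)$ with
edges owned by the higher-input interval (the top bin is closed at 1);
preset bins are equal-width with states numbered from the top of the input
domain downwards, so a decaying sawtooth reads out as $1, 2, \dots, n$
along the axis. The binary fate rule is strict ($o > 0.5 \to$ state 1) and
the elongation gate suppresses growth at $o \ge 0.5$ (allowance is strict,
per "below the threshold elongation proceeds").

**Cell indexing.** R's 1-based indexing is used throughout: cell 1 is the
anterior-most; `wavefront_position()` returns the index of the anterior-most
immature cell and $L + 1$ for a fully fated embryo.

**PSC extinction.** In the temporal three-timer variant the SAZ must run
out after elongation stops, which requires the posterior signal itself to
die; the engine switches the PSC off at the step the posterior cell's
$\tau_3$ reaches 0. In the spatial variant the PSC persists, the PI field
freezes in place, and cells with positive PI never mature — the SAZ
persists indefinitely.

**Spatial field refresh.** The PI value is an instantaneous function of a
cell's current distance to the signal, so after elongation the field is
re-evaluated at the new geometry; cells the front has just passed hand over
immediately, while their oscillator value is still current. Without this,
recorded snapshots would carry one stale cell per growth event and the
measured $L_{SAZ}$ would dither with $v$.

**Oscillator clamps.** A clamp fixes the module's *output*; for the
oscillator it also freezes the hidden phase (a clamped clock has no
dynamics). Clamp a module with `apply_clamp(config, module, value)`.

## Measurement conventions and their quantization limits

**SAZ phase difference** is the unwrapped-phase gap between the
posterior-most non-signal SAZ cell and the anterior-most immature cell — the
number of stripes spanning the SAZ, reported in cycles. Because cells mature
in discrete events spaced $1/v$ steps apart, the sampled anterior endpoint
wanders over roughly $1/(2vP)$ cycles. The claim "$\Delta\phi$ is
independent of $v$ with a timer" is therefore asserted in a regime where the
SAZ holds several stripes ($T_1 = 300$, $\Delta\phi \approx 5$ cycles,
where the sampling term is under 5%); at $T_1 = 40$ ($\Delta\phi < 1$) the
sampling term dominates and no implementation of these endpoints can show
flat curves.

**Segment lengths** are onset-to-onset distances of a designated boundary
state (default 1), excluding the two partial end repeats. Lengths are
integers, so cumulative growth $\int v\,dt$ is floored per boundary: the
"segment sizes mirror the growth profile" property is asserted up to 1-cell
inversions (the same $\pm 1$ tolerance as the scaling laws); the fig7 preset
yields a Spearman correlation of about 0.99 between the elongation rate at
formation time and segment length, not exactly 1.

**Recorded-phase distributions** (freeze-readout variants) histogram the
wrapped frozen phases of matured cells, 50 bins by default. A constant
wavefront whose addition rhythm $1/v$ is commensurate with $P$ phase-locks
onto a few residues (at $P = 20$, $v = 0.2$: four values, 1/4 cycle apart) —
a resonance, not a bug. The `fig6_freeze` and `fig6_timer_feedback` presets
use $P = 23$, coprime with the 5-step rhythm, so the constant-velocity
readout samples the whole circle nearly uniformly, as the idealized argument
expects.

## Preset design notes

* **`fig4_pair_rule`** uses $P = 24$, $v = 0.5$, $T_2 = P$, $T_1 = 2P$: the
  double-segment repeat then spans 12 cells, two per mapping state, and the
  realized repeat `1 1 1 2 2 3 3 4 4 5 5 6` carries all six states with two
  boundary onsets (states 1 and 4) per oscillation period. Shorter repeats
  (e.g. $Pv = 6$) put each state on a single cell, where one-step reset
  quantization can delete a state from the readout.
* **`fig7_growth`** uses a linear growth profile from $v(1) = 0.5$ down to
  $v(0) = 0$ with $T_3 = 600$: segment lengths decline from 10 to 2 along
  the axis and segmentation terminates with SAZ exhaustion around step 640.
* **`fig8_noclock`** is derived with `derive_noclock_config()`: with $m$
  oscillator-output peaks per unit of $\tau_3$ and gradient slope $s$ per
  cell, the frozen repeat spans $(1/m)/s$ cells, and each cell experiences
  an effective period $T_3/m$; a sequential reference with period $P$ and
  repeat $Pv$ is matched by $s = 1/(m \cdot Pv)$ and $T_3 = mP$. The
  matched-equivalence test runs the sequential reference at $v = 1$ with a
  **uniform** frequency profile: the final pattern is profile-independent in
  the continuum limit, and the uniform profile makes both models sample
  timer-2 on the same integer grid, so the interior repeats agree exactly
  rather than up to one bin-edge cell. Patterning completes at $t = T_1$
  (40 steps) versus ~640 steps sequentially.

## What the simulations do and do not establish

These are phenomenological, deterministic, single-file-of-cells models. A
green test establishes that the *logic* of a patterning mechanism produces
the claimed tissue-scale behaviour (scaling laws, wave narrowing, polarity,
termination, sequential/simultaneous equivalence) under exact synchronous
update. It does not establish anything about molecular implementations (the
modules deliberately abstract over gene networks), about robustness to
noise or cell mixing (no stochasticity, no rearrangement, no Notch-style
synchronization is modelled), or about real parameter values (none are
fitted). Cell death, 2-D/3-D morphogenesis and continuous-time dynamics are
out of scope by design.

## A worked example

```{r example}
cfg <- seg_config("clock_timer", P = 20, v = 0.2, T1 = 40, steps = 400)
h <- run_model(cfg)
p <- final_pattern(h)
interior_repeat(p[p > 0])          # 1 1 2 2 : L_seg = P * v = 4
steady_state_metrics(h)            # L_SAZ = T1 * v = 8
```
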