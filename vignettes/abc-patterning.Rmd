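---
title: "Modelling the ABC patterning of the Arabidopsis floral meristem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the ABC patterning of the Arabidopsis floral meristem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcpattern)
```

## The biological question

A young floral meristem starts out with its identity genes expressed
uniformly, yet within hours its L1 cell layer carries the concentric A/B/C
zones that the ABC model of flower development maps onto sepal, petal, stamen
and carpel fates. `abcpattern` implements a minimal dynamical answer: five
protein fields — LFY, AP1, AG, TFL1 and WUSCHEL (WUS) — interacting on a 1D
transect of 15 L1 cells, where a boundary-driven WUS pre-pattern breaks the
initial symmetry and an AG/AP1 mutual-exclusion module converts it into the
zonal pattern. The package is a simulator, not a fitting tool: its inputs are
rate constants and boundary configurations, its outputs trajectories and
pattern summaries.

## The kinetic model

Each cell `j` carries concentrations (µM) evolving as

$$\frac{d\,lfy_j}{dt} = k_1 + k_2\,ap1_j - k_3\,tfl1_j - k_4\,lfy_j
  + \varepsilon\,(lfy_{j+1} - 2\,lfy_j + lfy_{j-1})$$
$$\frac{d\,ap1_j}{dt} = k_5 + k_6\,lfy_j - k_7\,tfl1_j - k_8\,ap1_j$$
$$\frac{d\,ag_j}{dt} = u(t - t_{gate})\,
  \frac{k_9\,wus_j + k_{10}\,lfy_j}{\beta_2 + \beta_3\,ap1_j}
  - k_{11}\,tfl1_j - k_{12}\,ag_j$$
$$\frac{d\,tfl1_j}{dt} = k_{13} - k_{14}\,lfy_j - k_{15}\,ap1_j
  - k_{16}\,tfl1_j$$

with the derived, AG-excluded effective AP1 profile
$ap1_T = ap1\,[1 - ag/(ag+\beta_1)]$: AP1 itself neither moves nor is degraded
by AG, but its activity is masked where AG accumulates, with half-maximal
exclusion at $ag = \beta_1$. Only LFY diffuses between cells; the lattice ends
are no-flux (mirrored ghost cells), so the discrete Laplacian always sums to
zero. The step gate $u$ stands in for upstream flowering-time control and
keeps AG silent for the first `gate_time` = 5 h; it is right-continuous
(equal to 1 at exactly $t = t_{gate}$), an arbitrary but fixed convention.

Defaults for $k_1 \ldots k_{16}$, $\beta_{1..3}$, $\varepsilon = 5\,s^{-1}$
and `gate_time` are the working values of the source study
(`kinetic_params()`); each rate constant also carries a stability interval
(`param_intervals()`) probed by `run_robustness_scan()`.

### Ambiguities made explicit

The AG production law admits several typographic readings, and the package
exposes each as a `model_options()` flag rather than hard-wiring one:

* `gate_scope`: the default gates **all** AG production. Gating only the WUS
  term would let the $k_{10}\,lfy$ term pattern AG immediately, contradicting
  the intended five-hour silence; both readings are available.
* `denominator_scope`: the default shares the noncompetitive AP1 inhibition
  $(\beta_2 + \beta_3\,ap1)$ across the combined activation, the natural
  reading of an inhibition "on the production of AG".
* `ap1_feedback`: "AP1" in the LFY, AG and TFL1 equations denotes the raw
  state variable by default (the literal reading of the equations). The
  alternative — substituting $ap1_T$ — couples those equations to the spatial
  AG pattern and thereby breaks the exact coupling-invariance described
  below; the raw reading makes it exact, which is why it is the default.
* `exclusion_driver`: AG drives the AP1 exclusion by default; WUS is the
  variant probed by `run_wus_exclusion_variant()`.

## The WUS pre-pattern

The repressor subsystem adapts a classic shoot-apical-meristem model: a fixed
binary boundary signal $L$ (cells 1–3 and 13–15 in the wide configuration,
cells 1 and 15 in the narrow one) produces a diffusible repressor $y$, and
WUS is produced through a saturating sigmoid of $u = h_w + T_{wy}\,y$:

$$\frac{d\,wus_j}{dt} = k_{17}\,g(h_w + T_{wy}\,y_j) - d_w\,wus_j,
  \qquad g(u) = \tfrac12\left(1 + u/\sqrt{1+u^2}\right)$$
$$\frac{d\,y_j}{dt} = k_y\,L_j - d_y\,y_j + D_y\,(y_{j+1} - 2y_j + y_{j-1})$$

Three conventions deserve comment, each set once and documented here:

* **Sigmoid form.** The printed production bracket of the source is
  typographically garbled; the package defaults to the saturating sigmoid of
  the original repressor model (`sigmoid_variant = "mjolsness"`). The two
  literal readings, $(1+u)/(1+u^2)$ and $1 + u/(1+u^2)$, are retained behind
  the same flag; with $h_w = 2$, $T_{wy} = -30$ neither is sigmoidal nor
  produces the required on/off contrast.
* **Timescale.** The subsystem's constants ($d_w = 1.75$, $d_y = 2$, …) are
  per *hour* (`time_scale = 3600` s): with per-second rates the pre-pattern
  would form within seconds, while the documented behaviour is emergence
  after about an hour. The integrator still steps everything in seconds.
* **Amplitude.** With the literal $k_{17} = 0.05$ and $d_w = 1.75$ the
  derepressed steady WUS is ≈ 0.03 µM — far too small to trigger the AG
  switch given $k_9 \le 0.5$ and an order of magnitude below the unit initial
  WUS level. The default `amplitude_mode = "normalized"` sets the production
  constant to $d_w$, giving a derepressed steady level $g(h_w) \approx 0.95$,
  commensurate with the rest of the model; `"literal"` is available.
* **y boundary handling.** The stated side condition $y_j = 0$ conflicts with
  the stated initial condition ($y = 1$ at the signal cells). The package
  treats it as the *interior initial* condition: y starts from the boundary
  profile and evolves by its own equation with no-flux ends.

`wus_steady_profile()` solves the linear y steady state directly
(`(d_y I - D_y \Delta) y = k_y L`) and evaluates the WUS profile pointwise;
it is the independent oracle against which the time-stepped subsystem is
tested (agreement to 1e−6 µM).

## Integration

The coupled six-field system is advanced by the fixed-step Euler
predictor–corrector (Heun) scheme: forward-Euler predictor, trapezoidal
corrector, and — because linear inhibition terms can push concentrations
below zero — clipping at zero after each corrector step. Clipping after (not
inside) the step lets the predictor see the raw dynamics and minimises
distortion of the scheme; clip events are counted per field. The reference
conditions are `dt` = 0.05 s for 1,200,000 steps (16.6 h), sampling every
2,000 steps (100 s) with the final state always stored. The WUS subsystem is
integrated with the same `dt`, its rates scaled by `1/time_scale` — no
operator splitting. A pure-R reference engine mirrors the compiled kernel and
the two are required to agree to 1e−12 in the tests; halving `dt` moves the
steady profiles by less than 1e−6. Plain forward Euler is available
(`method = "euler"`) for fidelity comparisons only. No adaptive stepping and
no stiff solver: the scheme *is* part of the modelled procedure.

Degenerate inputs are handled explicitly: non-finite states abort with the
step index (instability diagnostic), `peak_cell()` breaks ties toward the
lowest index, `zone_classify()` returns an explicit "undefined" flag when
both AG and effective AP1 are identically zero (e.g. the t = 0 state), and an
all-zero profile has no half-max width.

## Pattern metrics and the B zone

Zones are classified from the final state by scale-invariant half-max
thresholds: C where $ag \ge \tfrac12 \max ag$, A where not C and
$ap1_T \ge \tfrac12 \max ap1_T$, B otherwise (the fraction is configurable).
The B zone is thus *residual*, matching its biological description as the
region between the AP1- and AG-dominated domains.

Under the default parameters the y → WUS transition is essentially one cell
wide (decay length $\sqrt{D_y/d_y} \approx 0.22$ cells), so AG jumps from
zero (cells 1–3) to near its plateau (cell 4) and the steady labels are
`A A A C C C C C C C C C A A A`: the hard B zone is empty, with the A→C
transition falling between cells 3 and 4. The overlap structure that the ABC
model ascribes to the B region is therefore reported through the soft
per-cell A/C membership matrix attached to the labels rather than through
exclusive labels; the zone-ordering checks in the experiments accept the
pattern `A+ B* C+ B* A+` (B present or empty) and additionally require the C
run to contain the centre cell. Narrowing the boundary signal widens the AG
domain (half-max width 13 vs 9 cells) while preserving this layout.

Two honesty notes on claims the dynamics do **not** honour:

* The narrow-boundary pattern is described in the source as asymmetric about
  cell 8, but the narrow configuration is mirror-symmetric and symmetric
  equations with symmetric initial conditions cannot break symmetry under
  exact arithmetic. The package reproduces the broadening and *flags* the
  symmetry (`symmetry_error` < 1e−10) instead of asserting asymmetry.
* "LFY ≫ TFL1 at all times" fails during the early transient: TFL1 relaxes
  within seconds to ≈ 1.5 while LFY still sits near its initial 1, so at the
  100 s sample min(LFY) < max(TFL1). From 200 s on the dominance holds. The
  acceptance suite asserts the literal claim and documents this failure; the
  unit suite asserts the (true) post-transient dominance.

## Experiments

Each named experiment returns configurations, pattern summaries, named
scalar metrics and booleans traceable to them:

* `run_wildtype()` — central AG (peak at cell 8), exact pre-gate silence,
  zone layout and settling time (zones final from 5.03 h ≤ 16 h).
* `run_narrow_boundary()` — AG broadening with conserved qualitative form.
* `run_epsilon_experiments()` — coupling sweeps (ε ∈ {0, 5, 10}), a redraw
  of ε ~ U[0, 10] every 50 s of simulated time, and independent per-cell
  random ε. Under the default options LFY, AP1 and TFL1 stay spatially
  uniform, the Laplacian of a uniform field is exactly zero in floating
  point, and the trajectories are therefore *bit-identical* for any ε — the
  mechanistic content of "LFY diffusion is not necessary", tested at 1e−10.
  The redraw distribution is uniform on the sweep's printed range [0, 10]
  (no distribution is stated); draws are seeded.
* `run_tfl1_knockout()` — `k13 = 0` with zero initial TFL1 (the plain
  reading of "TFL1 = 0"): AG floods the centre (0.89 vs 0.14 µM) and edge
  effective AP1 collapses (0.43 vs 2.84 µM), while wild-type TFL1 is kept
  low but positive.
* `run_wus_exclusion_variant()` — exclusion driven by WUS instead of AG
  leaves the zone sequence identical and the central $ap1_T$ minimum intact.
* `run_robustness_scan()` — per-parameter ±10% draws or both endpoints of
  every stability interval; the stability verdict is "identical zone-label
  sequence and unchanged AG peak cell", a sharp stand-in for the source's
  qualitative "model output is stable". The printed k5 interval [0.9, 1.5]
  excludes the k5 working value 0.09 and, taken literally, destroys the
  pattern (TFL1 is driven to zero and AG becomes positive everywhere); the
  scan therefore uses the decimally rescaled reading [0.09, 0.15], and the
  printed values remain available via `param_intervals(corrected = FALSE)`.

## Problem sizes and test design

All headline checks run at the reference conditions (15 cells × 6 fields ×
1.2 M steps; a few seconds each with the compiled kernel). The engine
cross-checks, CLI smoke tests and experiment plumbing tests use either short
runs (≤ 2,000 steps) or a 10× coarser step (`dt` = 0.5 s over the same
16.6 h), which the step-halving bound justifies for qualitative verdicts.
There is no external data anywhere: every input is generated from the printed
parameter set, so the tests demonstrate internal consistency and faithfulness
to the stated conditions, not agreement with gene-expression measurements.

## Known limitations

One spatial dimension with static, equally sized cells; no growth, division
or mechanics; LFY exchange with deeper cell layers ignored; the
flowering-time gate imposed, not modelled; no ABC-mutant simulations (they
require the full 15-gene network of which this five-node model is a
subnetwork); and TFL1 is suppressed but never excluded from the pattern — a
known incompleteness of the five-node reduction.
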