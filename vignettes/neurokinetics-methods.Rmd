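---
title: "Models and methods behind neurokinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neurokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurokinetics)
```

neurokinetics quantifies two intertwined aspects of axonal cell biology
from live-cell imaging: how dynamically a microtubule-associated protein
such as tau exchanges on and off the axonal microtubule array, and how
well microtubule-dependent cargo (mitochondria, APP vesicles) moves
through that array. All estimators consume plain tables — per-cell
fluorescence-decay curves, per-frame localization series, long-format
track tables — and every estimator has a matching synthetic generator
with recorded ground truth, so the whole pipeline is testable by
parameter recovery.

## FDAP: photoactivation decay models

In a fluorescence-decay-after-photoactivation (FDAP) experiment a 6 µm
segment in the middle of a thin process is photoactivated and the total
fluorescence in that window is followed over time (here: 1 frame/s, 112
frames). Two forward models are provided.

**Pure diffusion.** For a top-hat initial condition of half-width
$a$ on an infinite line, the window-averaged remaining fraction has the
closed form

$$F(t) = \operatorname{erf}(w) - \frac{1 - e^{-w^2}}{w\sqrt{\pi}},
\qquad w = \frac{a}{\sqrt{D_{\mathrm{eff}}\,t}},$$

implemented in `fdap_model_diffusion()` and verified in the test suite
against adaptive quadrature of the heat-kernel convolution. Fitting this
one-parameter model (`fit_deff()`) yields the effective diffusion
constant $D_\mathrm{eff}$, which for a diffusing-and-binding species in
fast exchange compresses to $D_\mathrm{free}/(1 + k^*_{on}/k_{off})$.

**Reaction–diffusion.** The two-species system

$$\partial_t f = D\,\partial_x^2 f - k^*_{on} f + k_{off} b,
\qquad \partial_t b = k^*_{on} f - k_{off} b$$

describes a free species $f$ diffusing at $D = D_\mathrm{free}$ and a
bound, immobile species $b$; $k^*_{on}$ is pseudo-first-order (it absorbs
the free-site concentration). Activated molecules start uniformly in the
window, partitioned at binding equilibrium (bound fraction
$k^*_{on}/(k^*_{on}+k_{off})$), the steady state of an unperturbed cell.
The same physical model is evaluated by two independent numerical routes:

* `fdap_model_reaction()` solves the system semi-analytically in Fourier
  space. Per wavenumber the $2\times 2$ propagator has eigenvalues
  available in closed form; the window-averaged signal is
  $F(t) = \tfrac{2}{\pi}\int_0^\infty \tfrac{\sin^2 u}{u^2}\,
  g(u/a, t)\,du$ with an overflow-safe evaluation of $g$ and
  Gauss–Legendre panels graded toward $u = 0$ (the integrand develops a
  feature of width $a/\sqrt{Dt}$ there) plus an analytic large-$u$ tail.
  Accuracy is ~1e-6, at ~5 ms per curve — fast enough for multi-start
  least squares.
* `fdap_solve_pde()` integrates the same system by the method of lines
  (deSolve, sparse-Jacobian stiff solver) on a cell-centered
  finite-volume grid with reflecting far ends. The grid spacing is
  chosen as an exact divisor of the window half-width so the top-hat
  edge coincides with a cell boundary; this keeps the scheme
  second-order (a node-centered edge costs a first-order error of
  several 1e-3 in the window average, which matters at fitting
  accuracy). The domain is at least 20 windows long and widens with
  $6\sqrt{D t_\mathrm{max}}$ so the reflecting ends are never felt;
  total mass on the domain is conserved to better than 1e-6 and reported
  with every simulation.

The two routes agree to ~1e-4 on the acquisition grid; the simulator
uses the PDE route, the fitter the Fourier route, so self-consistency
tests are never circular in the numerics.

**Fitting choices.** $\chi^2$ is the plain sum of squared residuals —
single curves provide no per-point variance estimate, so $\chi^2$ is
only ever compared between models on the same curve, never interpreted
absolutely. $D_\mathrm{free}$ is an input (`nk_config()$d_free`), not a
fitted parameter: the decay constrains two effective quantities well, and
fixing $D_\mathrm{free}$ keeps the reaction fit two-dimensional. No
measured value ships with the package; the default 10 µm²/s is a
placeholder of the right order for a free cytosolic protein and must be
set deliberately for quantitative work. Fits are multi-started on log
grids ($D$: 7 starts over $10^{\pm2}$ µm²/s; rates: a $5\times5$ grid
over $10^{\pm2}$/s, with local refinement from the best three grid
points), tie-broken by lowest $\chi^2$ then smallest parameter norm.
Estimates that land on a search bound are flagged `converged = FALSE`.

**Identifiability.** The window sets a diffusion rate scale
$D/a^2 \approx 1.1$/s at the defaults. Rate pairs much faster than this
are in fast exchange: the decay collapses onto an effective-diffusion
curve and only the ratio $k^*_{on}/k_{off}$ remains identifiable, so
replicate fits wander along a $\chi^2$ ridge and the spread of absolute
rates becomes very large even at 2% measurement noise. Recovery tests
therefore target the physiological-dwell regime (defaults
$k^*_{on} = 4$/s, $k_{off} = 1$/s, bound fraction 0.8); users fitting
fast-exchange data should interpret only the bound fraction and
$D_\mathrm{eff}$.

**Degenerate inputs.** A constant curve carries no kinetic information:
`fit_deff()` returns a flagged fit at a search bound. A reaction fit
whose best $\chi^2$ is worse than a configurable multiple (default 2) of
the pure-diffusion $\chi^2$ on the same curve warns about model
mis-specification.

## Single-molecule residence time

Single-molecule tracking of a sparsely labeled protein shows
kiss-and-hop binding: dwells on one microtubule site, then sub-µm hops.
The residence time is estimated by counting how many consecutive frames
a localized molecule stays within a radius (default 50 nm) of the
event's first localization. Design choices:

* **Anchor, not rolling centroid.** "Stays within a radius" is read
  relative to the event's first localization; this is the simplest
  criterion and avoids slow drift being absorbed by a moving reference.
* **Gaps terminate events** (the criterion counts *consecutive*
  frames); the closing frame may anchor the next event.
* **Events touching track ends are kept.** Naive counting slightly
  censors long dwells; with track lengths much longer than the mean
  dwell the bias is small.
* **Minimum two frames**: one frame cannot evidence dwelling.

The duration histogram (zero-count bins inside the observed range
included) is fitted with $A\,e^{-n\,\Delta t/\tau}$ on raw counts by
least squares, initialized from a log-linear regression. With
exponential dwells sampled at frame interval $\Delta t$ the frame counts
are geometric with decay $e^{-\Delta t/\tau}$, so the fit recovers
$\tau$ without bias; the suite verifies this at the ~2000-event scale
with dwell/frame ratios 2–5.

One measurement-physics caveat is deliberate: at 16.7 nm localization
noise the frame-to-frame displacement SD is ~24 nm, so a 50 nm radius is
spuriously exceeded in ~10% of frames, truncating events and biasing
$\tau$ low by roughly a third at a 60 ms dwell and 20 ms frames. The
package implements the printed criterion as stated and documents the
bias; recovery tests use 5 nm noise so the criterion itself — not the
noise — is what is being tested. The camera frame interval has no
canonical value and is a required parameter (simulations and tests use
20 ms, a typical fast-camera setting).

## Mitochondria: mobile / stationary / undefined

A mitochondrion is called mobile when it moved farther than its own
size. Because the apparent diameter fluctuates frame to frame (z-motion,
rotation, fusion/fission), the rule is implemented as a one-sample
t-test of the track's diameter distribution against the track's
displacement:

$$t = \frac{\bar d - \mathrm{disp}}{s_d/\sqrt n},$$

with two-sided p-value on $n-1$ df and confidence $1-p$. Labels: mobile
if confidence > 0.95 and $t < 0$; stationary if confidence > 0.95 and
$t \ge 0$; undefined otherwise. The threshold is expressed on the
confidence scale so the printed value 0.95 applies unchanged.
"Displacement" is the net start-to-end distance by default; maximal
excursion is available (`displacement = "max"`) since either reading is
defensible. Tracks with fewer than 3 diameter observations cannot be
tested and are undefined; zero diameter variance degenerates to the sign
rule with confidence 1 (reported via a message). Classification is
invariant under rigid motions of the track, and — at the simulator's
defaults of 0.5 µm mitochondria moving at ~0.3 µm/s for 8 min —
sensitivity and specificity of the mobile call exceed 95%.

## Vesicle transport

The vesicle pipeline mirrors a spinning-disc acquisition at 5 frames/s
over 60 s, tracked upstream (e.g. by an autoregressive-motion linker
with 0.5 µm search radius and 2-frame gap limit — those tools are
consumed, not re-implemented). Steps, in order:

1. **Duration filter**: keep tracks spanning ≥ 15 frames (3 s),
   inclusive.
2. **Orientation**: arclength is signed so that increasing values point
   away from the axon-hillock reference; anterograde is positive.
3. **Mobility gate**: mobile iff net displacement strictly exceeds
   0.75 µm over the observation window. Tracks shorter than 60 s are
   gated on their own duration with the same threshold (the printed rule
   is fixed, not rescaled).
4. **State segmentation**: for successive observations $i \to j$,
   $ds = (s_j - s_i)/(j - i)$ µm/frame — a step across a 1–2 frame gap
   is normalized by the frames elapsed. $ds > 0.02$ µm/frame is
   anterograde, $ds < -0.02$ retrograde, otherwise a stalling event
   (equality goes to stall: the printed wording assigns movement only to
   *more than* threshold). 0.02 µm/frame at 5 fps is 0.1 µm/s, the
   tracker-level minimum speed. Gaps longer than the limit split a track
   into separately segmented pieces; the spanning step is dropped and
   contributes no state change.
5. **Metrics**: signed velocity (net $\Delta s$/duration); speed (mean
   $|ds|$ per step × fps); max speed; processivity; state changes
   (adjacent step pairs with different states).

**Processivity** is defined here as the mean length (µm) of maximal
uninterrupted anterograde or retrograde runs — the standard
motor-transport meaning of run length, and consistent with processivity
dropping while mean speed barely moves when transport becomes choppier.
A time-based alternative (fraction of step frames in motion) is
available behind `processivity = "time_moving"`. Stall-only tracks
report missing processivity, not zero. Per-cell summaries are unweighted
means over that cell's mobile tracks; cumulative state changes are
reported both as per-track mean and per-cell total, since either reading
of "cumulative" is defensible.

Direction-flip symmetry (relabeling which end is the hillock swaps
anterograde/retrograde totals, negates velocity and leaves speed,
processivity and state-change counts unchanged) holds exactly and is
tested exactly.

## The synthetic generators

Each generator is a pure function of `(params, seed)`.

* **FDAP**: normalized PDE forward solution plus i.i.d. Gaussian noise
  per frame (σ = 0.02 by default). Noise is additive on the normalized
  scale; `read_fdap()` renormalizes measured curves to their first
  sample on ingestion.
* **Kiss-and-hop**: a continuous-time renewal process — exponential
  dwells (60 ms default), instantaneous 300 nm hops in random
  directions, camera sampling every 20 ms with isotropic localization
  noise. Truth records every episode's sampled frame count.
* **Mitochondria**: stationary tracks jitter around a fixed point;
  mobile tracks run-and-pause at ~0.3 µm/s; per-frame lognormal
  diameters (mean 0.5 µm, CV 0.1); 8 min at 0.5 fps.
* **Vesicles**: per-frame 3-state Markov chain (default rates give runs
  of tens of seconds with a slight anterograde bias out of stalls),
  state speeds ~1 µm/s, 60 s at 5 fps, ~20% mobile, i.i.d. frame drops
  capped at the tracker's 2-frame gap limit so tracks stay linkable.

What the generators deliberately do **not** model: photophysics
(blinking, bleaching), 3-D neurite geometry, z-drift, motor attachment
mechanics, spot detection or linking errors beyond simple gaps.
Passing recovery tests therefore demonstrates that the estimators are
correct for data with the assumed statistical structure — not that real
microscopy meets those assumptions.

## Problem sizes and numerical tolerances

The test and acceptance workloads are sized for a laptop-class run:
model cross-checks on a grid of diffusion constants and times (closed
form vs PDE, tolerance 1e-3); noise-free rate recovery to 5%; 100-curve
noisy replicate sets for rate RMSE; ~2000 dwell events for residence
time (10% tolerance); 150–200 synthetic organelle tracks per classifier
check. Seeds are fixed in tests; every simulator records its seed in the
truth table, and the command-line entry points echo config, seed and
package version into a JSON sidecar next to each output table.

## Known limitations

* Infinite-line FDAP geometry: sealed or nearby process ends are not
  modeled (activation is assumed mid-process and short relative to the
  process length).
* Unweighted $\chi^2$; no per-point variance model.
* Absolute rate recovery degrades in the fast-exchange regime
  (identifiability, not implementation — see above).
* The residence-time criterion inherits a noise-dependent truncation
  bias at realistic localization precision.
* Mitochondria z-motion is emulated only through diameter fluctuation;
  no explicit 3-D motion.
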