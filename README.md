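# neurokinetics

Tools for quantifying protein–microtubule binding kinetics and axonal cargo
transport from live-cell imaging, together with seeded synthetic-data
generators so every estimator in the package can be validated against known
ground truth.

The package covers four measurement modalities that are commonly combined
when studying microtubule-associated proteins in neurons:

1. **FDAP** (fluorescence decay after photoactivation): a short axon segment
   (default 6 µm) is photoactivated and the normalized fluorescence remaining
   in the window is followed over time (default 1 frame/s, 112 frames). The
   decay reports both diffusion of the free protein and its exchange with
   microtubule binding sites.
2. **Single-molecule tracking (SMT)**: residence (dwell) times of single
   molecules, defined by a 50 nm consecutive-frame immobility criterion and
   estimated by a mono-exponential fit to the dwell-time histogram.
3. **Mitochondria transport**: a per-track one-sample *t*-test of frame-to-
   frame displacements against the organelle diameter classifies each
   mitochondrion as mobile, stationary, or undefined.
4. **Vesicle transport**: tracks are oriented relative to an axon-hillock
   reference point, filtered (≥ 15 frames ≙ 3 s at 5 frames/s), gated for
   mobility (> 0.75 µm net displacement over 60 s), segmented into
   anterograde / retrograde / stalled states at 0.02 µm/frame (0.1 µm/s),
   and summarized per cell (velocity, speed, processivity, state changes).

## The FDAP model

The activated protein is split between a freely diffusing pool
*f*(*x*, *t*) and a microtubule-bound, immobile pool *b*(*x*, *t*):

```
∂f/∂t = D ∂²f/∂x² − k*on f + koff b
∂b/∂t =             k*on f − koff b
```

with pseudo-first-order association rate *k**on, dissociation rate *k*off,
free diffusion constant *D*, a top-hat initial condition over the activation
window partitioned at binding equilibrium, and the window-averaged total
fluorescence normalized to 1 at *t* = 0. The bound fraction is
*k**on / (*k**on + *k*off); in fast exchange the system behaves as a single
species with *D*eff = *D* / (1 + *k**on/*k*off).

Two independent numerical routes implement the same model: the simulator
integrates the PDE by the method of lines (`fdap_solve_pde()`, deSolve), and
the fitter evaluates the solution semi-analytically in Fourier space
(`fdap_model_reaction()`). The two routes agree to ~10⁻⁴ on the acquisition
grid and the pure-diffusion limit matches the closed form
`fdap_model_diffusion()` to ~10⁻⁶; both checks run in the test suite. See
the methods vignette (`vignettes/neurokinetics-methods.Rmd`) for the
numerics, fitting strategy, and an identifiability analysis of the
fast-exchange regime.

## Worked example

Simulate noisy FDAP curves at known kinetics and fit the reaction–diffusion
model to one cell:

```r
library(neurokinetics)

sim <- simulate_fdap_curves(
  fdap_sim_params(d_free = 10, k_on_star = 4, k_off = 1, noise_sigma = 0.02),
  n_curves = 3, seed = 42)
head(sim$curves, 4)
#> # A tibble: 4 × 3
#>   cell_id     t     F
#>   <chr>   <dbl> <dbl>
#> 1 sim_001     0 1.03
#> 2 sim_001     1 0.789
#> 3 sim_001     2 0.694
#> 4 sim_001     3 0.619

fit <- fit_reaction_diffusion(dplyr::filter(sim$curves, cell_id == "sim_001"),
                              d_free = 10)
fit
#> <kinetic_fit: reaction model, 112 points>
#>   k_on_star       3.2384
#>   k_off           0.81913
#>   bound_fraction  0.79812
#>   chi2            0.04559
#>   converged       TRUE
```

The bound fraction (0.798 vs the generative 0.8) is recovered much more
precisely than the individual rates — the expected behavior when exchange is
fast relative to diffusion across the window (see the vignette). Broom-style
accessors are available: `tidy(fit)`, `glance(fit)`, `predict(fit)`, and
`autoplot(fit)`.

Residence time from single-molecule localizations:

```r
smt <- simulate_smt(smt_sim_params(localization_sigma = 5), seed = 7)
residence_time(smt$localizations, radius = 50, frame_interval = 20)
#> <residence_fit: tau = 59.2 ms from 2089 events (R^2 = 0.993)>
```

Vesicle transport, end to end:

```r
ves <- simulate_vesicle_tracks(cargo_sim_params(n_tracks = 50), seed = 11)
res <- analyze_vesicles(ves$tracks, reference_s = 0)
#> filter_tracks: kept 50 of 50 tracks (span >= 15 frames).
res$summary
#> # A tibble: 10 × 10
#>   cell_id n_tracks frac_mobile n_mobile mean_velocity mean_speed mean_max_speed
#>   <chr>      <int>       <dbl>    <int>         <dbl>      <dbl>          <dbl>
#> 1 cell_01        9       0.111        1        0.612       0.773           1.21
#> 2 cell_02        5       0.4          2        0.292       0.576           1.17
#> ...
```

A command-line front end over the same functions ships at
`inst/scripts/nk.R` (`simulate`, `fit fdap`, `smt dwell`,
`transport mito|vesicle`).

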