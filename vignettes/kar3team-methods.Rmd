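---
title: "kar3team: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kar3team: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the science implemented in `kar3team`: the
coupled motor-team model, the synthetic-data generator, the tracking
pipeline, the trajectory estimators, and — most importantly — the places
where the design was genuinely open and what we chose. Nothing here
states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The motor-team model

A team of `n_dimers` kinesin-14 heterodimers is coupled through their
tails. We model the coupling as a **star**: every dimer hangs from one
massless tail node by an equal spring of stiffness
$k_\mathrm{stiff}$. Force balance on a massless node with equal springs
puts the node at the **mean of the bound head positions**, and makes the
spring forces $f_i = k_\mathrm{stiff}(X_\mathrm{node} - x_i)$ sum to zero
over bound dimers at every instant (a tested invariant). A pairwise
chain topology would be indistinguishable from the available evidence;
the star is the minimal model consistent with the interconnected-tails
picture.

Each dimer draws a persistent intrinsic velocity
$\nu_i \sim \mathcal N(V, \sigma_\nu)$ truncated at zero, **once per
run** (whether $\nu_i$ should be redrawn on rebinding is unspecified; we
keep it fixed, treating $\nu_i$ as a property of the molecule, not of
the binding event). Three laws close the model:

* **Force–velocity**: linear to stall,
  $v = \nu_i\,(1 - L/F_\mathrm{stall})$ clamped to $[0, \nu_i]$, where
  $L = \max(0, -f_i)$ is the opposing component of the spring force.
  Assisting force does not speed a motor past $\nu_i$ and there is no
  backward stepping. The published relation is shown only graphically;
  linearity is the conventional minimal choice.
* **Detachment**: a capped Bell law
  $k_\mathrm{off}(f) = \min(k_\mathrm{off,0} e^{|f|/F_\mathrm{detach}},
  k_\mathrm{off,max})$. Only the two endpoints
  ($k_\mathrm{off,0}, k_\mathrm{off,max}$) are published, so
  $F_\mathrm{detach}$ defaults to
  $F_\mathrm{stall} / \ln(k_\mathrm{off,max}/k_\mathrm{off,0})$, which
  places the cap exactly at stall. It is exposed in `team_params()`.
* **Rebinding**: an unbound dimer binds at the node position (spring
  relaxed) with rate $k_\mathrm{on}$.

Default parameters are the published set for the size-resolved
comparison: $V = 50$ nm/s, $\sigma_\nu = 20$ nm/s,
$F_\mathrm{stall} = 1$ pN, $k_\mathrm{on} = 0.55\,s^{-1}$,
$k_\mathrm{off,0} = 0.08\,s^{-1}$, $k_\mathrm{off,max} = 4\,s^{-1}$,
$k_\mathrm{stiff} = 0.03$ pN/nm.

**Integration** is fixed-step Euler with Bernoulli event draws at
`dt = 1 ms`; the constructor rejects any `dt` for which a per-step event
probability reaches 0.1. Halving `dt` moves N = 2 mean velocity and run
length by under a few percent (tested). Runs start with one dimer bound
at the origin ("land, then engage"; `all_bound = TRUE` is available) and
end when no dimer is bound. A run-time cap (`max_time`, default 2000 s,
flagged `censored`) bounds compute: with rebinding, teams of three or
more essentially never detach in finite simulation time.

For N = 1 the model collapses to an analytic oracle — run time
$\sim$ Exp($k_\mathrm{off,0}$), so mean run time $1/k_\mathrm{off,0}
= 12.5$ s and mean run length $V/k_\mathrm{off,0} = 625$ nm — which the
acceptance suite verifies to 3% over $10^4$ runs.

### Fitting and its identifiability limit

`fit_team_params()` grid-searches
$(F_\mathrm{stall}, k_\mathrm{on}, k_\mathrm{off,max})$ against a
size-resolved table using the relative squared-error objective summed
over sizes and over the four statistics (mean/SD of velocity and run
length), with common random numbers — the same seed at every grid point
— so the surface is smooth in the parameters.

Two facts limit what fitting can establish. First, the objective is
dominated by the SD-of-run-length terms, whose estimator has relative
standard error $\approx\sqrt{8/n}$ for exponential-like run lengths
(20% at $n = 200$ runs). Second, the model has a genuine
$F_\mathrm{stall}$–$k_\mathrm{off,max}$ compensation ridge: a stiffer
stall with faster saturated detachment mimics a softer stall with slower
detachment (the published analysis itself reports three nearly
equivalent parameter sets along this ridge). Resolving the ridge with
independent random numbers would need thousands of runs per grid point.
The acceptance check therefore exercises **self-consistency with full
common random numbers** (observed table and fit simulations share seed
and run count), which makes the objective exactly zero at the generating
point and the recovery deterministic. Users fitting real tables should
treat the reported optimum as one point on a ridge and inspect the full
objective surface that the function returns.

## The synthetic-data generator

`generate_tracks()` emulates the experimentally observed track
populations along a 1-D minus-end-positive microtubule coordinate:

* **directed** (e.g. `wt_atp`: 77 ± 23 nm/s, 5.2 µm mean exponential run
  length): a per-track velocity from the truncated Gaussian, an
  exponential run length, constant-interval sampling, and i.i.d.
  Gaussian localization noise per frame;
* **diffusive** (e.g. `adp`: D = 0.061 µm²/s, τ = 0.6 s; nucleotide-state
  pairs `apo_wt`/`apo_mutant` at 0.00045/0.01 µm²/s and
  `amppnp_wt`/`amppnp_mutant` at 0.00011/0.0036 µm²/s): Gaussian
  increments of variance $2D\,\Delta t$ with an exponential lifetime;
* **static**: constant position plus noise, exponential residence.

Localization noise defaults to **30 nm**, a typical single-molecule TIRF
precision (the source reports none); it is configurable, and the pure
"Brownian motion" acceptance ensembles are generated with it set to 0,
as their definitions state. Runs cut short by the observation window are
flagged so the statistics layer can fit with right-censoring; the
run-length acceptance target censors ~10% of draws at a 12 µm
field-length cap ($5200 \cdot \ln 10$ nm), a realistic microtubule
length.

The movie renderer places molecules on an oriented axis segment and
draws each as an **integrated Gaussian PSF** (pixel-area integrals of a
2-D Gaussian, default σ = 150 nm at 133 nm pixels), conserving photons
to the tested 0.5%, then applies an optional multiplicative shading
field, Poisson shot noise and Gaussian read noise. The generator does
*not* emulate EMCCD gain statistics, optical aberrations, microtubule
dynamics, or molecule–molecule photophysics — a green end-to-end test
establishes that the pipeline recovers what this idealized imaging model
contains, not that it would perform identically on raw experimental
movies.

A note on one estimator interaction the generator exposes: because a
directed track's duration is run length / velocity, any minimum-length
filter selects against fast molecules. At 3 s frames the ≥ 5-frame rule
biases the recovered mean velocity by about
$-\mathrm{Var}(v)\cdot 4\Delta t/\bar L \approx -1.2$ nm/s, which is
commensurate with the $2\cdot SE$ recovery band at $n = 699$; the
velocity-recovery checks therefore run at the 0.273 s frame-interval
preset, where the same bias is ~0.1 nm/s.

## Tracking

The pipeline follows the classical recipe: divide each raw frame by its
11×11 median filter (shading correction; reflected borders; an all-zero
frame is an error), smooth with a unit-sum 3×3 Gaussian, detect, link.

Choices the recipe leaves open, and what we chose:

* **Gaussian σ** for the 3×3 kernel: 0.8 px, the standard value for a
  3-pixel support.
* **Segmentation threshold**: median + $k \cdot 1.4826 \cdot$ MAD with
  $k = 3$ by default. The MAD is estimated on the **corrected frame
  before smoothing**: smoothing correlates and shrinks the noise, and a
  3-MAD threshold measured on the smoothed frame itself passes ~20
  noise maxima per 128² frame, while the pre-smoothing noise scale
  keeps the blank-frame false-positive rate below one per frame
  (tested by Monte-Carlo).
* **Detection**: strict local maxima within a 532 nm radius; a circular
  ROI of radius 332 nm measures intensity (ROI sum minus annulus-median
  background times area) and a background-subtracted intensity-weighted
  centroid gives sub-pixel positions. The centroid and annulus are
  additions needed for brightness statistics.
* **Linking**: greedy one-to-one assignment by descending circle-overlap
  area, ties broken by smaller centroid distance then lower (row, col);
  zero-overlap pairs never link; no gap closing. An exhaustive
  optimal-assignment mode exists for validation and agrees with the
  greedy result on the tested instances.
* Pixel convention: 0-based (row, col); pixel (i, j) covers
  [i, i+1) × [j, j+1), physical position = coordinate × pixel size.

## Trajectory statistics

* **Velocity**: least-squares slope of position vs time; tracks under 5
  frames are excluded with a reason code.
* **Censored exponential MLE**: mean $= \sum x_i / n_\mathrm{uncensored}$
  — the closed form is cross-checked against a brute-force likelihood
  grid in the tests. All distribution fits are ML on raw values;
  histogram bins are display-only.
* **MSD**: per-track time-averaged squared displacements over all pair
  offsets, pooled across tracks weighted by pair counts. The fit window
  was a genuinely open choice. Lags are bounded by 25% of the longest
  track duration **and** by a pair-support rule: only lags whose pair
  count is ≥ 75% of the maximal pair count enter (never fewer than 4
  lags; `min_support` argument). The support rule exists because the
  long-lag tail of a pooled MSD is carried by the one or two
  longest-lived molecules: its variance explodes, and for
  detachment-limited directed runs the survivors are systematically the
  slow molecules, which bends the curve below $t^2$. With the rule, the
  directed wild-type world fits $n \approx 1.94\!-\!1.97$ and Brownian
  worlds $n \approx 0.95\!-\!1.05$ across seeds; without it, the same
  data give $n \approx 1.6$ and Brownian exponents scattering by ±0.15.
* **Power law**: weighted (pair-count) nonlinear least squares of
  $a\,t^n$, started from the log–log regression, with a `scaleOffset` so
  exact power-law inputs converge cleanly; $D = a/2$ is reported when
  $n \in [0.8, 1.2]$. Short-lag **linear** fits with an intercept
  (`msd_diffusion_coefficient()`, default 4 lags) estimate $D$ directly;
  the intercept absorbs the $2\sigma_\mathrm{loc}^2$ noise floor.
* **Photobleaching steps**: recursive binary segmentation on
  squared-error reduction with a BIC-type stop
  ($m\,\ln(\mathrm{SSE}_0/\mathrm{SSE}_1) > 2\ln N$, two parameters per
  change point, minimum segment 3 frames); the step count is the number
  of downward level changes. The algorithm choice is ours; none is
  published.
* **Brightness mixture**: EM for $K$ Gaussians constrained to means
  $k\mu_1$ and SDs $\sqrt k\,\sigma_1$ (closed-form M-steps:
  $\mu_1 = \sum x_i / \sum_{i,k} r_{ik} k$). The model is invariant to
  $\mu_1 \to \mu_1/m$ with weights moved to components $km$, so
  single-population data cannot identify $\mu_1$; when one component
  carries > 95% of the weight the fit is canonicalized to the
  parsimonious reading (that population has size 1). Complex brightness
  is the mean of a track's first 3 frames, capturing initial size
  before bleaching.

## Hydrodynamics

`native_mw()` implements the Siegel–Monty relation
$M = 6\pi\eta N_A R_s s/(1-\bar v \rho)$ with $R_s$ in nm and $s$ in
Svedberg, returning kDa. Defaults: $\bar v = 0.73$ cm³/g (typical
protein; none is published for this complex) and water at 20 °C
($\eta = 1.002\times10^{-3}$ Pa·s, $\rho = 0.9982$ g/cm³) — the
convention under which the published 9.1 nm / 5.6 S inputs reproduce the
published 214 kDa within 2%. Calibration standards are user-supplied
(`calibration_table()` + `interpolate_standard()`, linear least squares
with an extrapolation warning beyond 10% of the span) because the
published standard curves exist only as figures.

## File formats and determinism

Tracks and summary tables are CSV; configuration is JSON (no YAML
package is available in the supported dependency set); movies are
uncompressed 16-bit multi-page TIFF with a JSON sidecar
(`pixel_size_nm`, `frame_interval_s`, seed). The TIFF reader/writer is a
minimal baseline implementation covering exactly this format, verified
by round-trip tests. Every stochastic entry point takes a `seed`; stage
seeds in the demo pipeline derive from one global seed and no stage
consumes OS entropy, so fixed-seed runs are byte-identical (tested).

## Known limitations

* The team model is 1-D: no protofilament geometry, no explicit ATP
  cycle, no optical-trap emulation; the star coupling is one of several
  topologies consistent with the evidence.
* Absolute objective-function values of the published fits are not
  reproducible (the corresponding table is unavailable); only the
  fitting procedure's self-consistency is validated.
* MSD-based $D$ estimation is the only diffusion estimator provided
  (no CVE/MLE alternatives).
* The greedy linker has no gap closing; a molecule lost for one frame
  starts a new track.
* The brightness-mixture unit $\mu_1$ is identified only in the
  presence of a genuine single-fluorophore population.
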