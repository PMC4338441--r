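# kar3team

Single-molecule motility analysis and stochastic modelling of processive
kinesin-14 motor teams.

Budding-yeast Kar3 is a kinesin-14 that becomes a processive, minus-end
directed motor when it heterodimerizes with a non-catalytic partner head
(Cik1 or Vik1). This package re-implements the computational toolchain for
studying such motors with single-molecule TIRF microscopy, as a tested R
package driven entirely by synthetic, ground-truthed data:

* **Motor-team simulator** — N dimers coupled by spring-like tail linkers
  (stiffness *k*<sub>stiff</sub>) to a shared massless node. Each dimer
  carries a persistent intrinsic velocity *ν*<sub>i</sub> ~
  N(*V*, *σ*<sub>ν</sub>) truncated at 0, a linear force–velocity relation
  *v* = *ν*<sub>i</sub>(1 − *L*/*F*<sub>stall</sub>) clamped to
  [0, *ν*<sub>i</sub>], and a capped Bell detachment law
  *k*<sub>off</sub>(*f*) = min(*k*<sub>off,0</sub>
  e<sup>*f*/*F*<sub>detach</sub></sup>, *k*<sub>off,max</sub>). Unbound
  dimers rebind at the node with rate *k*<sub>on</sub>. Fixed-step
  Euler/Bernoulli integration in compiled code; grid fitting of
  (*F*<sub>stall</sub>, *k*<sub>on</sub>, *k*<sub>off,max</sub>) to
  size-resolved motility tables.
* **Synthetic data** — directed / diffusive / static trajectory presets
  (wild-type ATP: 77 ± 23 nm/s, 5.2 µm exponential runs; ADP:
  D = 0.061 µm²/s, τ = 0.6 s; nucleotide-state pairs for mutant vs
  wild-type), quantized photobleaching intensity traces, and rendered
  16-bit TIRF-like TIFF stacks (integrated Gaussian PSF, Poisson + read
  noise, optional shading field).
* **Tracking** — the classic detection-and-linking pipeline: 11×11
  median-filter shading correction (divide raw by filtered), 3×3 Gaussian
  smoothing, local-maximum search within 532 nm, circular 332 nm
  measurement ROIs, and greedy best-overlap frame-to-frame linking.
* **Trajectory statistics** — least-squares track velocities with Gaussian
  ML fits; right-censored exponential MLE for run lengths and dwell times
  (mean = Σ values / n<sub>uncensored</sub>); ensemble MSD with power-law
  fits ⟨x²⟩ = a·t<sup>n</sup> (n = 1 diffusion with a = 2D, n = 2
  transport); photobleaching step counting by binary segmentation with a
  BIC stop; constrained Gaussian-mixture fluorophore counting (component
  k at mean k·µ₁, SD √k·σ₁).
* **Hydrodynamics** — native molecular weight by the Siegel–Monty
  relation M = 6πη·N<sub>A</sub>·R<sub>s</sub>·s / (1 − v̄ρ) from Stokes
  radius and sedimentation coefficient, plus linear standard-curve
  interpolation.

## Worked example

```r
library(kar3team)

## native mass of the heterodimer from its hydrodynamic measurements
native_mw(9.1, 5.6)          # Stokes radius 9.1 nm, 5.6 S
#> 213.6 kDa

## simulate one three-dimer team at the published model parameters
p <- team_params(n_dimers = 3)
simulate_run(p, seed = 1)
#> Team run (N = 3): 2341 nm in 62.0 s (37.5 nm/s)

## size-resolved motility: velocity flat, its SD shrinking, run length
## growing with team size
size_sweep(team_params(), sizes = 1:4, n_runs = 300, seed = 7)
#>   n_dimers mean_velocity sd_velocity mean_run_length sd_run_length n_runs
#> 1        1          48.0        19.4             560           609    300
#> 2        2          47.0        14.8            1491          1797    300
#> 3        3          46.8        11.9            4599          6811    300
#> 4        4          46.3        10.6           10744         14360    300

## recover the wild-type velocity distribution from 699 synthetic tracks
g <- generate_tracks("wt_atp", n_tracks = 699, frame_interval = 0.273,
                     seed = 2)
v <- track_velocities(g$tracks)
fit_gaussian(v$velocity_nm_s[v$included])
#> velocity: 77.1 +/- 23.5 nm/s (n = 692)

## the same ensemble is ballistic by MSD analysis
gm <- generate_tracks("wt_atp", n_tracks = 250, frame_interval = 0.2,
                      seed = 3)
fit_power_law(compute_msd(gm$tracks))
#> MSD power law: a = 6147 nm^2/s^n, n = 1.948 (SE 0.001)
```

The simulated team statistics mirror the experimental observations: mean
velocity is nearly independent of team size (within ~10 % of V = 50 nm/s),
its standard deviation falls with N, and run length rises steeply with N.
The velocity recovery reproduces the 77 ± 23 nm/s generating law, and the
directed ensemble fits ⟨x²⟩ ∝ t<sup>1.95</sup>, close to the ideal
ballistic exponent 2 (the small deficit comes from the localization-noise
floor and detachment-limited track durations).

## Command line

A small CLI ships in `inst/cli/kar3team`:

```sh
kar3team simulate --size 3 --runs 500 --seed 1 --out runs.csv
kar3team track movie.tif --threshold-k 3 --out tracks.csv
kar3team stats tracks.csv --analysis msd
kar3team hydro --rs 9.1 --s 5.6
kar3team demo --seed 1 --out-dir demo_out
```

See `vignettes/kar3team-methods.Rmd` for the model assumptions, estimator
choices, and known limitations.
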