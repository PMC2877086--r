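# tumorcpm

A 3D Glazier–Graner–Hogeweg (Cellular Potts) simulator of avascular tumor
growth in a homogeneous tissue matrix (TM) supplying a single limiting
nutrient, with the morphometric analysis needed to study **front
instabilities and invasiveness**: whether a growing solid tumor keeps a
smooth, noninvasive interface or develops fingers.

It is written for computational-oncology researchers who want a compact,
scriptable, fully reproducible lattice model: tumor cells are spatially
extended *Generalized Cells* evolving by Metropolis boundary-copy dynamics
under the effective energy

> H = Σ J(τ,τ′)·[1 − δ(σ,σ′)] + Σ λ_V (V − V_t)² + Σ λ_S (S − S_t)²,

coupled to three scalar fields on the same lattice — TM density *f*, a
matrix-degrading enzyme *m*, and substrate *c* — integrated by forward
Euler with no-flux boundaries. Cells grow at rate g·c(COM), divide at the
doubling volume along a random plane, and can optionally become quiescent
(reversible) or necrotic (irreversible) below a substrate threshold. Two
control parameters organize the phase diagram:

* **G**, the diffusion-limitation parameter (ratio of maximum substrate
  consumption to maximum transport; here G = k·L²/D_c, so the studied
  uptake range k = 0.05–0.2 maps onto G = 50–200): small G grows compact
  spheroids, large G drives a diffusion-limited fingering instability;
* **γ = J(t,TM) − J(t,t)/2**, the tumor–TM surface tension: high γ gives
  compact/dendritic morphologies, γ → 0 gives DLA-like dispersal.

Morphometrics: sphericity s = π^⅓(6V)^⅔/A and mid-plane section
circularity c = 4π·Area/P² (smoothed marching-tetrahedra / marching-squares
estimators calibrated on digitized balls and disks to within 3%),
26-connected component analysis, boundary-reach and fixed-stage times, and
a quasi-Gaussian fit s(t) = s₀·exp(−(t/τ)²) whose characteristic time τ
measures fingering speed.

## A worked example

Grow a compact tumor (G = 50, γ = 0) on a reduced 50³ lattice to 500 cells
and summarize it:

```r
library(tumorcpm)
cfg <- sim_config(L = 50, k = 0.05, gamma = 0, g = 0.3,
                  seed = 17, snapshot_interval = 400)
run <- run_single(cfg, stop = "cells:500")
summarise_run(run, stage = 500)
```

prints (seed 17):

```
  s_at_stage cbar_at_stage day_at_stage ... day_at_boundary censored_boundary
1  0.7571125     0.6175828            2 ...              NA              TRUE
```

i.e. the tumor reaches 500 Generalized Cells on simulated day 2 (400 MCS =
1 day) with sphericity 0.76 — a slightly grooved spheroid — and has not yet
touched the 3-mm domain wall. Raising the diffusion limitation at the same
stage lowers the sphericity (0.76 → 0.71 → 0.59 across G = 50/100/150,
same seed), while raising the surface tension at G = 100 raises it
(0.71 → 0.89 → 0.93 → 0.95 across γ = 0/2/4/6): competition for substrate
destabilizes the front, adhesion stabilizes it.

The same machinery runs the full-scale (100³, 6 mm) system:

```r
cfg  <- sim_config(L = 100, G = 50, gamma = 0, g = 0.3, seed = 1,
                   snapshot_interval = 400)
run  <- run_single(cfg, stop = "boundary")   # a few minutes
fit_characteristic_time(run$records$day, run$records$sphericity)
```

```
Quasi-Gaussian sphericity fit: s(t) = 0.888 * exp(-(t/11.78 d)^2)  [n = 7, ...]
```

with 1000 cells passed at ~day 2.25 and a boundary-stage mean mid-plane
circularity of 0.539 for this seed.

`sweep_plan()`/`run_sweep()` orchestrate the full G × γ grid with
deterministic per-replicate seeds; every run writes a config, metrics CSV,
per-cell census, label/field TIFF snapshots and a reproducibility manifest.
A thin command-line wrapper ships in `inst/cli/cpm3d.R`
(`run`, `sweep`, `metrics`, `fixture`, `fit-tau` subcommands).

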