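---
title: "Modeling avascular tumor front instabilities with a 3D Cellular Potts simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling avascular tumor front instabilities with a 3D Cellular Potts simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorcpm)
```

## The model

`tumorcpm` simulates a solid, avascular, single-phenotype tumor growing in a
homogeneous tissue matrix (TM) that supplies one limiting nutrient
("substrate"). Tumor cells are *Generalized Cells* of the
Glazier–Graner–Hogeweg (Cellular Potts) model: spatially extended domains of
voxels on a cubic lattice, indexed by a label field $\sigma(\vec x)$. The
entire normal tissue is one additional, unconstrained Generalized Cell. The
configuration evolves by Metropolis boundary-copy dynamics under the
effective energy

$$H = \sum_{\langle \vec x, \vec x'\rangle}
      J\!\left(\tau(\sigma(\vec x)), \tau(\sigma(\vec x'))\right)
      \left[1 - \delta_{\sigma(\vec x), \sigma(\vec x')}\right]
    + \sum_{\sigma} \lambda_V \left(V_\sigma - V_t(\sigma)\right)^2
    + \sum_{\sigma} \lambda_S \left(S_\sigma - S_t(\sigma)\right)^2 ,$$

where the contact sum runs over unordered voxel pairs within the
fourth-order interaction range (32 neighbors per voxel, which reduces
lattice anisotropy), $V_\sigma$ is a cell's voxel count, $S_\sigma$ its
surface, and $\lambda_V, \lambda_S$ the inverse compressibility and inverse
membrane elasticity. The TM cell is exempt from both constraint terms. A
randomly chosen voxel is overwritten by the label of a random fourth-order
neighbor with probability $1$ if the energy change $\Delta H \le 0$ and
$e^{-\Delta H / T_m}$ otherwise; $T_m$ is the intrinsic cell motility. One
Monte Carlo Step (MCS) is $L^3$ such attempts; 400 MCS correspond to one
simulated day, and one voxel to 60 µm (a 100³ domain is 6 mm across, and one
Generalized Cell is a coarse-grained cluster of a few hundred real tumor
cells).

The tumor--TM *surface tension* is
$\gamma = J(t,\mathrm{TM}) - J(t,t)/2$: large $\gamma$ makes tumor cells
cluster into compact masses, $\gamma \to 0$ lets them disperse.

Three scalar fields co-occupy the lattice, normalized to $[0,1]$:

* TM density $f$: non-diffusing, degraded by the matrix-degrading enzyme
  (MDE) as $\partial_t f = -\delta\, m f$; it never regenerates.
* MDE $m$: secreted at rate $\mu$ (capped at 1) at every voxel occupied by a
  proliferating tumor cell, diffusing slowly
  ($\partial_t m = D_m \nabla^2 m + \mu\,\mathbf{1}_{\text{tumor}}$).
* Substrate $c$: $\partial_t c = D_c \nabla^2 c + S\, f\,(1-c)\,\Theta(1-c)
  - k\,\mathbf{1}_{\text{tumor}}$, produced by intact TM up to saturation,
  consumed at rate $k$ at tumor-occupied voxels (floored at 0).

All fields use forward Euler with no-flux (mirrored) boundaries; the
substrate runs at 75 substeps per MCS to satisfy the 3D explicit-Euler
stability bound $D\,\Delta t \le 0.8/6$ at $D_c = 10$, the MDE at its own
(single) substep. TM degradation shares the substrate substep; because $m$
is constant within an MCS, the per-substep factor $(1-\delta m \Delta t)$ is
applied in closed form once per MCS, with production reading the MCS-start
$f$ (the difference is far below the scheme's own Euler error).

Cells grow by raising their target volume at a rate proportional to the
substrate concentration at their center of mass,
$dV_t/dt = g\, c(\vec x_{\mathrm{COM}})$, with the target surface slaved to
$S_t = 6\,V_t^{2/3}$ (anchored by the initial 3×3×3 cell cube: $V_t = 27$,
$S_t = 54$), which keeps cells roughly isotropic as they grow. When a cell's
*actual* volume reaches the doubling volume (54 voxels) it divides along a
uniformly random plane through its center of mass; both daughters inherit
the phenotype and half the parent's target volume. There is no growth
threshold: cells deep inside the tumor see $c \approx 0$ and simply stop
growing, an implicit quiescence.

The *diffusion-limitation parameter* $G$ is the ratio of the maximum
substrate-consumption rate to the maximum transport rate; the package uses
the working form $G = \kappa\, k L^2 / D_c$ with $\kappa = 1$, so the
studied consumption range $k = 0.05$–$0.2$ maps onto $G = 50$–$200$ at
$L = 100$, $D_c = 10$. $G$ selects the morphology: substrate penetration
into the tumor scales as $\ell \approx \sqrt{D_c/k}$ (14 voxels at $G=50$,
7 at $G=200$, versus a cell diameter of ~3.4), so small $G$ grows compact,
near-spherical tumors while large $G$ starves the interior, and the
competition of rim cells for substrate drives a fingering instability.
$\gamma$ then sets the finger character: high tension gives compact,
dendritic branches, low tension DLA-like dispersal.

## Parameters, units, defaults

| parameter | meaning | default | units |
|---|---|---|---|
| `L` | lattice side | 100 | voxels (60 µm each) |
| `mcs_per_day` | time calibration | 400 | MCS/day |
| `J_ttm`, `J_tt` | contact energies | 8, 4 (γ = 6) | energy/boundary area |
| `T_m` | cell motility | 60 | energy |
| `lambda_V`, `lambda_S` | constraint strengths | 20, 0.4 | energy/vol², energy/area² |
| `V_doubling` | mitosis trigger | 54 | voxels |
| `shape_constant` | $S_t/V_t^{2/3}$ | 6 | — |
| `D_c`, `D_m` | diffusion constants | 10, 0.01 | voxel²/MCS |
| `delta` | TM degradation | 0.5 | 1/MCS per unit MDE |
| `mu` | MDE production | 1 | conc./MCS |
| `S_prod` | substrate production | 0.1 | conc./MCS per unit TM |
| `k` (or `G`) | substrate uptake | 0.05 (G = 50) | conc./MCS |
| `g` | growth rate | 0.3 | voxels/MCS per unit c |
| `c_threshold` | quiescence/necrosis threshold | 0.05 | — |
| `g_necrotic` | necrotic shrink rate | −g/2 | voxels/MCS |

The adhesion, motility, constraint, doubling and shape values are the
published study conditions. The field constants and the growth rate are not
uniquely pinned by the published table available to us; the shipped defaults
were fixed once as a set: $D_c = 10$ closes the $G$-mapping at the published
$k \leftrightarrow G$ correspondence, $D_m$ and $\delta$ realize "slow MDE
diffusion" and "strong TM degradation" (MDE saturates and TM vanishes under
the tumor within a few MCS), $S_\mathrm{prod} = 0.1$ restores the far-field
substrate on a ~10-MCS scale, and $g = 0.3$ was calibrated once against the
published milestone of two days to 1000 Generalized Cells at $G = 50$
(giving 2.25 days at snapshot resolution) and then frozen. All of them are
plain configuration keys.

## Design choices on genuinely open points

* **Field coupling.** Secretion and uptake act at *every tumor-occupied
  voxel* (the indicator-function form of the field equations). A
  point-sink/point-source reading at the cell center of mass was
  implemented first and rejected on physical grounds: a point sink of
  magnitude $k \le 0.2$ per MCS cannot measurably deplete a $D_c = 10$
  field, which makes substrate penetration independent of $G$ and
  suppresses the fingering instability entirely — and it contradicts MDE
  saturation beneath the whole tumor footprint. Growth and the phenotype
  rules still *sample* $c$ at the center-of-mass voxel.
* **Surface measure.** A cell's surface $S$ is the count of first-neighbor
  voxel pairs spanning its boundary (faces on the domain wall have no
  partner voxel and do not count). This is the cheapest incrementally
  updatable estimator and is calibrated through `shape_constant`.
* **Copy-attempt convention.** The randomly selected site is the *target*
  whose label is overwritten by a random neighbor's label; same-cell and
  out-of-domain draws count toward the MCS attempt budget as no-ops.
* **Update order.** Within one MCS: Metropolis sweep → field update →
  biology (growth, then mitosis, then phenotype rules). Daughters created
  in an MCS do not divide again within it.
* **Division trigger** is the realized volume (a cell that has physically
  reached the doubling volume divides), with a config switch to trigger on
  target volume instead. Degenerate split planes are redrawn up to ten
  times, then the longest-extent axis is used.
* **Quiescence is reversible, necrosis irreversible**; starved cells resume
  proliferating when substrate returns, necrotic cells never do, and a
  necrotic cell whose volume reaches zero is removed. The two rules are
  enabled one at a time, as they were studied.
* **No connectivity constraint**: all contact energies are positive, which
  discourages fragmentation energetically, but nothing forbids it; at
  $\gamma = 0$ individual cells may detach, as observed.
* **RNG.** One seeded `mt19937_64` stream per simulation with explicit
  bounded-integer and normal derivations, so trajectories are bit-identical
  across platforms for a given seed. Attempt sites are drawn with
  replacement.

## Morphometrics

Sphericity and section circularity are

$$s = \frac{\pi^{1/3} (6V)^{2/3}}{A}, \qquad
  c = \frac{4\pi\,\mathrm{Area}}{P^2},$$

with $V$ and Area the voxel/pixel counts of the *union* of all tumor
components, and $A$, $P$ sub-voxel mesh estimates: the binary occupancy is
smoothed with a separable 1-2-1 binomial kernel and iso-surfaced at level
0.5 by marching tetrahedra (3D) or marching squares with linear
interpolation (2D). Plain face counting is unusable here — it overestimates
a ball's area by ~50% and would cap sphericity at ~0.67 — and meshing the
*unsmoothed* occupancy still overestimates a ball's area by 8–25%
(estimator-dependent). With the shipped estimator, digitized balls of radius
8–16 read $s = 0.993$–$1.009$ and disks $c = 0.979$–$0.990$.

The estimator's known limitation is sharp edges: any smoothing wide enough
to calibrate curved surfaces chamfers a cube's edges, leaving a $+4\%$ bias
at side 32 that decays like the inverse side length. We verified this is a
family-level constraint, not an implementation defect: even projecting the
facets of an unsmoothed mesh onto analytically exact normals cannot recover
the edge area (the bevel is absent from any level-0.5 mesh of binary data).
Simulated tumors have no sharp edges, so the calibration on balls and disks
is the relevant one. Absolute sphericities of *rough* bodies remain
estimator-dependent — our smoothed estimator reads a grooved compact
spheroid higher than an unsmoothed one by ~0.2–0.4 — which should be kept
in mind when comparing absolute values (rather than orderings or trends)
against numbers produced by other codes with unstated estimators.

Mid-plane circularities are taken at plane index $\lfloor L/2 \rfloor$
(0-based) of the XY, XZ and YZ sections; empty sections are excluded from
the mean and flagged. Connectivity is 26-connected in 3D and 8-connected in
2D, so a tumor touching at a voxel vertex still counts as one body — the
U-tube fixture demonstrates the geometric artifact by which 2D sections of
a connected 3D body appear disconnected. Boundary-reach times are reported
at snapshot resolution and *censored* (never zero, never blank) when the
tumor stops before reaching the wall. Sphericity decay curves are fitted by
least squares to the quasi-Gaussian form $s(t) = s_0 e^{-(t/\tau)^2}$
(`minpack.lm`); the characteristic time $\tau$ measures how fast fingers
develop. A $\tau$ larger than 50× the observed window is reported as
unidentified rather than returned as a number.

## Scaled-down study sizes

The test suite and the acceptance script reproduce trends at reduced sizes,
chosen as the package's own study conditions:

* **Trend runs** use a 50³ lattice, three seeds, and a fixed stage of 500
  cells. The consumption rates are kept at their *study-scale* values
  ($k$ from the $L = 100$ mapping, labeled by that $G$): since Generalized
  Cells are not coarsened further on the smaller lattice, keeping $k$ fixed
  preserves the substrate penetration depth *per cell diameter* — the
  quantity that actually controls the instability — whereas re-deriving $k$
  from $G$ at $L = 50$ quadruples the per-voxel uptake and pushes every
  combination into the starved regime (verified: $G = 50$ then fails to
  reach 500 cells in 20 simulated days). The most starved combination
  ($G = 200$) may still censor before the stage within the 7-simulated-day
  cap shared by all trend runs; a
  censored run contributes its final snapshot's sphericity, an upper bound
  on a declining trajectory and therefore conservative against the
  decreasing-with-$G$ trend being tested.
* **Full-scale milestones** use the 100³ lattice at $G = 50$: growth to
  1000 cells takes ~2.25 simulated days (published: 2), and one full run to
  the domain boundary supplies the boundary-stage morphometrics and the
  $\tau$ fit in the acceptance script.

What the synthetic-data generator (the simulator itself, plus the digitized
ball/cube/ellipsoid/U-tube fixtures) does *not* emulate: real tumors have
heterogeneous phenotypes, anisotropic and deformable stroma, vasculature,
and imaging noise. Passing tests therefore validate the model's internal
consistency and its parameter dependencies, not clinical predictive power.

## Numerical notes and limitations

* The energy bookkeeping is exact: the incremental $\Delta H$ of a copy
  equals the difference of global energy recomputations to $10^{-9}$, and
  integer volume/surface ledgers are audited against the lattice.
* Field state is stored in single precision (values live in $[0,1]$; the
  bandwidth-bound stencil loop is the simulation's hot spot); the standalone
  field operators used for numerical verification run in double precision,
  and the diffusion step conserves mass to $10^{-10}$ relative.
* A 100³ MCS costs ~0.1 s on one core (~75 substrate substeps dominate);
  a growth run to 1000 cells is ~1–2 minutes.
* Cubic-lattice anisotropy is mitigated, not removed, by the fourth-order
  interaction range; orientational observables (dendrite directions) should
  not be over-interpreted.
* The $G \leftrightarrow k$ mapping constant and every masked-parameter
  default are config keys, so alternative published values can be
  substituted without code changes.
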