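---
title: "Modelling hormone transport along a file of plant cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling hormone transport along a file of plant cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellfile)
```

## The model

Plant hormones such as gibberellin (GA) move through tissues by crossing
a succession of membranes and cell-wall spaces.  `cellfile` models a
one-dimensional file of `N` cells, each split into a cytoplasm, a
vacuole, and three apoplastic (wall) compartments: the transverse wall
shared with the next cell (`f`), the corner connecting that wall to the
wall running along the file (`g`), and the longitudinal wall strip
alongside the cell (`h`).  A weak-acid hormone exists in a protonated,
membrane-permeant form and an anionic form that needs carrier proteins.
The protonated share in each compartment is `1/(1 + 10^(pH - pK))`, and
carrier fluxes are weighted by the Goldman–Hodgkin–Katz factor
`q(phi) = phi / (exp(phi) - 1)` of the scaled membrane potential.  Both
routes combine into one effective permeability per crossing direction
(`effectivePermeabilities()`); transporter knockouts simply zero the
relevant carrier permeability before combining, so every mutant formula
is the wild-type expression with substituted chemistry rather than
separate code.

Because the compartment capacitances scale with the square of the ratio
of the cell length to the file length (`eps = 1/N`), concentrations
evolve quasi-statically on the file-scale diffusion time: apoplastic and
vacuolar concentrations are slaved to the cytoplasmic one through the
ratios `Pa = P_ca/P_ac` and `Pv = P_cv/P_vc`.  For GA in *Arabidopsis*
roots these are about 0.013 and 3.2 — almost no hormone in the walls and
a threefold accumulation inside the vacuole.

Two levels of description are implemented and cross-checked against each
other:

* the **discrete model** (`simulateDiscrete()`), the full `5N - 2`
  linear ODE system with upstream Dirichlet data (`c_1 = 1`,
  `h_1 = Pa`) and a ghosted no-flux downstream end; and
* the **continuum model** (`solveContinuum()`), the homogenised
  reaction–advection–diffusion equation for the macroscopic cytoplasmic
  concentration, with coefficients `U_eff`, `D_eff`, `Q_eff` given in
  closed form by `effectiveCoefficients()`.

For static identical cells the continuum limit is a pure diffusion
equation whose coefficient (`staticEffectiveDiffusivity()`) splits into
a cell-to-cell membrane pathway, a plasmodesmatal pathway and an
apoplastic pathway.  Growth of identical cells adds an advective
velocity `u = x l'/(l + lambda)` and a dilution sink `V'/V`; spatial
gradients of cell length or vacuolar fraction in a *static* file induce
an effective velocity through the storage asymmetry quantified by the
ratio of cytoplasmic to area-averaged concentration
(`concentrationRatio()`, `inducedVelocity()`).

## Parameters

All presets store dimensional primaries; every dimensionless group is
derived at load time by `nondimensionalize()`.

| quantity | default | unit | meaning |
|---|---|---|---|
| `pK` | 4.2 | – | hormone dissociation constant |
| `pH_apo`, `pH_cyt`, `pH_vac` | 5.3, 7, 5.5 | – | compartment pH |
| `V_mem`, `V_ton` | −120, −30 | mV | membrane/tonoplast potential |
| `P_pass` | 0.333 | µm/s | passive membrane permeability |
| `P_imp` | 0.017 | µm/s | plasma-membrane importer (NPF 2.12-type) |
| `P_exp` | 0.556 | µm/s | tonoplast carrier (NPF 2.14-type) |
| `P_plas` | 0.81 | µm/s | plasmodesmatal permeability |
| `D_apo` | 32 | µm²/s | apoplastic diffusivity |
| `l` | 20 / 200 | µm | short-/long-cell length |
| `w`, `a` | 10, 0.5 | µm | cell width, wall thickness |
| `phi` | 0.1 / 0.91 | – | vacuolar area fraction |
| `N` | 20 | – | cells per file |

Time is non-dimensionalised with `L0^2 / D_apo`, the apoplastic
diffusion time along the whole file; the limit-regime diffusivities for
closed plasmodesmata live on the slow time `t_bar = eps^2 t`, and
`limitDiffusivity()` records which scale applies together with the
dimensional value.

## Numerical choices

* **Stiffness.**  The corner compartments relax on an `eps^2 lambda^2`
  time scale, so the discrete system is integrated with BDF-capable
  solvers; the time-invariant cases supply the exact constant Jacobian
  of the linear operator.  Default tolerances are `rtol = 1e-8`,
  `atol = 1e-10`.
* **Growing files** are advanced in conserved-amount variables
  (capacitance × concentration), which makes dilution exact by the
  product rule; concentrations are recovered views.
* **Continuum discretisation** is a method of lines on 100 grid
  intervals: second-order central differences for diffusion and for the
  (smooth, low-Péclet) advective term.  For static graded files the
  sink `-U' C` cancels against the conservative advection term, and the
  equation is integrated as `C_t = D C_xx + (D' - U) C_x`.
* **Moving domains** (growing and dividing files) are solved on the
  fixed unit interval via `x = xi (l + lambda)/(1 + lambda)`; the
  transform cancels the growth advection, leaving diffusion plus the
  dilution rate `V'/V`.  For dividing files the domain span follows the
  undivided exponential length while the transport coefficients use the
  divided cell length, and the equation is integrated piecewise between
  division instants with the concentration carried across each event.
* **Upstream boundary.**  The initial data are hormone-free while the
  upstream value is 1; the Dirichlet value is imposed from the first
  positive time, matching the separation-of-variables solution
  (`analyticStaticSolution()`), whose truncation error is reported as an
  attribute.
* **Downstream closure.**  The discrete model's default downstream rule
  mirrors the concentration two cells back (`c_{N+1} = c_{N-1}`),
  placing the effective no-flux plane at the centre of the last evolved
  cell; the alternative one-sided rule (`downstream = "copy"`) places it
  at the last wall, which coincides with the continuum's no-flux
  position.  For files of identical cells the two closures differ by
  under 1% away from the far end.  For strongly graded files the end
  cells are long and the half-cell offset of the mirrored rule is
  visible (up to 0.07 in concentration at `N = 20`), so
  discrete-versus-continuum convergence checks use the wall-matched
  one-sided closure.
* **Division events.**  The model text does not specify how the
  apoplastic compartments created between two daughters are initialised.
  Daughters inherit the mother's cytoplasmic, vacuolar and
  longitudinal-wall concentrations, and new wall/corner compartments
  start at the quasi-static level `Pa * c_mother`; the associated mass
  defect is `O(lambda * c)` and the quasi-static ratio is re-established
  within the fast transient.  The closed-form dividing cell length
  conserves file length exactly at the first event and carries a known
  `O(lambda)` bookkeeping defect afterwards; the simulator instead
  applies the exact partition `(l - lambda)/2` at each event, which
  keeps the total span exactly continuous.
* **Linear-file fit.**  `fitLinearFile()` determines the self-consistent
  graded file by a damped fixed-point iteration on the file length
  (damping 0.5, relative tolerance 1e-10, at most 1000 iterations); the
  undamped centre map oscillates with growing amplitude.

## What the comparisons do and do not show

The discrete model is itself the synthetic data generator: every
validation compares an independent solution route against it under the
preset GA conditions (20-cell files, the Table of primaries above, zero
initial hormone).  Agreement of the continuum limit with the discrete
system at `N = 20` (within 0.05 in dimensionless concentration) shows
the homogenisation is implemented consistently, not that real root
tissue behaves this way: real files have asynchronous divisions,
non-prescribed growth mechanics (turgor, wall loosening), hormone
production and degradation, radial escape, and transporter saturation —
all outside this model.  Cell lengths and division times are prescribed
inputs, never emergent.

## Problem sizes

The shipped tests and the acceptance script use the study conditions
throughout: `N = 20` files for static, growing (`kappa = 0.01` and
`0.001`) and graded (20 → 200 µm) runs, continuum grids of 100
intervals, and division runs starting from two 5-µm cells for three
synchronous doublings (coefficient periodicity is checked analytically
out to ten periods, and a six-event run against the continuum solution
in the ten-hour inter-division regime).

## Known limitations

* The induced-velocity sign analysis is pointwise; a file whose ratio
  gradient changes sign is reported pointwise without a global label.
* For dividing files the continuum solution neglects the `O(lambda)`
  mismatch between the per-cell stretching rate and the whole-file
  exponential span; agreement with the discrete run is correspondingly
  limited to about 0.05–0.08 near the upstream boundary cell.
* The ghost-cell downstream closures bracket the true no-flux behaviour;
  neither is exact for strongly graded files at small `N`.
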