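# cellfile

Multiscale modelling of hormone transport along files of plant cells.

Plant hormones such as gibberellin (GA) cross a root tissue by moving
through a chain of cells, each of which is itself a mosaic of
compartments: cytoplasm, vacuole, and the apoplastic wall spaces between
cells.  Only the protonated (uncharged) fraction of a weak-acid hormone
diffuses passively through membranes; the anion is carried by NPF-family
transporters whose flux follows Goldman–Hodgkin–Katz (GHK) kinetics.
`cellfile` is for modellers and quantitative biologists who want to
connect those cell-scale parameters (pH, pK, membrane potentials,
transporter permeabilities, cell geometry) to tissue-scale transport.

The package implements two mutually validating descriptions of a file of
`N` cells:

* the **discrete model** — the full `5N − 2` linear ODE system for the
  per-cell cytoplasmic (`c`), vacuolar (`v`) and apoplastic (`f`, `g`,
  `h`) concentrations, with membrane fluxes
  `J = P_ca c − P_ac f`, GHK-weighted carrier transport, plasmodesmatal
  exchange `P_plas (c_{i+1} − c_i)`, growth, spatially graded cell
  lengths, and synchronous cell division;
* the **continuum limit** — the homogenised
  reaction–advection–diffusion equation
  `C_t + (U_eff C)_x = (D_eff C_x)_x − Q_eff C`
  for the macroscopic cytoplasmic concentration, with closed-form
  coefficients.  For static identical cells

  ```
  D_eff = (1+λ) (ω P_ca/2 + ω P_plas + λ 𝒫_a)
          ───────────────────────────────────────
          (1−φ)ω + φω𝒫_v + λ(1+ω+λ)𝒫_a
  ```

  where `λ`, `ω`, `φ` are the wall, width and vacuole aspect fractions
  and `𝒫_a = P_ca/P_ac`, `𝒫_v = P_cv/P_vc` are the quasi-static
  apoplast:cytoplasm and vacuole:cytoplasm concentration ratios.
  Spatial gradients in cell length or vacuole size induce an effective
  velocity whose sign is governed by the gradient of the cytoplasmic to
  area-averaged concentration ratio — the headline diagnostic for why
  hormone moves faster through files of shrinking cells.

Wild-type and transporter-knockout parameterisations
(`no_cyt_importer`, `no_ton_importer`, `double`) are a flag, not
separate formulas.

## Worked example

Short-cell (meristem-like) GA parameterisation, plasmodesmata closed:

```r
library(cellfile)
params <- gaParams("short", plasmodesmata = FALSE)
params
#> Dimensionless cell-file parameters
#>   eps 0.05  lambda 0.025  omega 0.5  phi 0.1
#>   P_ca 0.000828  P_ac 0.063  P_cv 0.602  P_vc 0.19  P_plas 0
#>   Pa 0.01313  Pv 3.171  (mutant: wild_type, plasmodesmata closed)
#>   time scale 5.25e+03 s, L0 410 um
```

`Pa` and `Pv` say that at quasi-steady state the wall holds ~1.3% of
the cytoplasmic GA concentration while the vacuole accumulates ~3.2×.
The tissue-scale diffusivity and its pathway split:

```r
D <- limitDiffusivity(params, "short_no_plas")
#> D_eff = 0.352 (x eps^2, apoplast units) = 2.8e-02 um^2/s;
#> cell-to-cell share 39%
```

i.e. effective GA diffusion through short cells is ~0.03 µm²/s — a
thousandfold slower than free apoplastic diffusion — with ~40% of it
crossing cell membranes and the rest running along the wall.  The
discrete and continuum solutions agree cell by cell:

```r
tr  <- simulateDiscrete(params, t_eval = 0.5 / params$eps^2)
sol <- solveContinuum(params, staticUniformProfile(0.1),
                      t_eval = 0.5 / params$eps^2)
#> cytoplasmic c at cells 1,5,10,15,20 (t_bar = 0.5): 1 0.743 0.469 0.289 0.227
#> continuum C at the same positions:                 1 0.741 0.463 0.274 0.194
```

Graded, growing and dividing files work the same way through
`fitLinearFile()`, `linearTimeProfile()` and `simulateWithDivision()`;
`inducedVelocity()` and `positiveVelocityThreshold()` analyse the
velocity induced by cell-length gradients.  A thin command-line wrapper
lives in `exec/cellfile` (subcommands `coeffs`, `simulate-discrete`,
`simulate-continuum`, `compare`, `steady-state`, `analyze-velocity`).

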