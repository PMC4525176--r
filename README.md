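# propellr

Chiral molecules with a permanent dipole moment act as microscopic
propellers in a rotating electric field (REF): the field torque spins the
responding fraction of the population, and the hydrodynamic coupling
between rotation about the propeller axis and translation along it —
opposite in sign for the two enantiomers — turns that rotation into
opposite drift velocities for the S and R forms. Exposed to a REF in a
capillary, a racemic sample therefore un-mixes, which can be read out as
enantiomeric excess (ee) in the leading and trailing halves of the sample
slug. `propellr` is for physical chemists and separation scientists who
want to model, simulate and analyse this effect quantitatively.

The core is the factorised propulsion velocity

```
v = L_rev · ν_eff · A_cor · F(E)
```

with

* `x = μE/kT` — dimensionless dipole–field coupling,
* `F(x) = 1 − 2x/(e^{2x} − 1)` — responding fraction of molecules that
  follow the field's rotation,
* `ν_esc = μE/(2πξ)`, `ξ = kT/D_r` — escape frequency of the overdamped
  driven dipole; above it the rotor phase-slips and
  `ν_eff = ν − sqrt(ν² − ν_esc²)`, else `ν_eff = ν`,
* `A_cor ∈ [1/2, 2/π]` — Boltzmann-weighted average projection of the
  propeller axis on the field-rotation axis,
* `L_rev` — signed axial displacement per revolution (Å/rev).

Around the closed-form chain the package provides: an overdamped
rotational Brownian dynamics simulator with the rotational-to-translational
coupling built in (a synthetic stand-in for all-atom MD), estimators that
recover `D_r` (MSAD slope) and `L_rev` (block-sampled increment regression)
from trajectories, the drift–diffusion ee kinetics
`ee(t) = v·sqrt(t/(πD))` with a bounded-chamber finite-difference solver
and the closed-chamber exponential steady state, and chromatogram
synthesis/analysis (FWHM-based diffusion estimation, CD/absorbance ee
calibration, leading/trailing fraction splitting).

## Worked example

The two bundled reference molecules are binaphthyl derivatives: molecule I
(μ = 5.3 D, L_rev = 1.22 Å/rev, D = 8.3×10⁻⁶ cm²/s) and molecule II
(μ = 10.9 D, L_rev = 0.18 Å/rev, D_r = 8.2×10¹² deg²/s, D = 1.4×10⁻⁵
cm²/s), driven at 6×10⁵ V/m and 0.9 MHz in benzene at 293 K:

```r
library(propellr)
propeller_predict(reference_rotor("molecule_I"), reference_field())
#> Propeller-effect prediction: molecule I (S, CW REF)
#>   coupling x = mu E / kT     0.00262214
#>   responding fraction F      0.00261985
#>   rotational friction xi     3.33e-30 J s
#>   escape frequency           0.507 MHz
#>   effective frequency        156.4 kHz
#>   angular correction A_cor   0.5
#>   propulsion velocity        +24.99 nm/s
#>   D / |v|                    3.321 cm
```

Only ~0.26% of molecules respond to the field at this coupling, and above
the 0.507 MHz escape frequency the rotor slips, so the 0.9 MHz drive
yields an effective rotation of only 156 kHz — yet the chain still gives a
25 nm/s drift, which over a 45 h exposure predicts a ~20% ee in each half
of the slug:

```r
100 * ee_vs_time(25e-9, 8.3e-6, 45 * 3600)
#> [1] 19.70532
```

Closing the loop through the simulator — generate a trajectory with known
parameters, then estimate them back:

```r
cfg <- simulation_config(reference_rotor("molecule_I"), field = NULL,
                         dt = 2e-12, n_steps = 4e5, seed = 41)
traj <- simulate_rotor(cfg)
estimate_L_rev(traj, axis = 1)
#> L_rev about I1: 1.281 +/- 0.044 Angstrom per revolution (10 blocks)
```

A command-line wrapper (`inst/exec/propellr`) exposes the same pipeline as
subcommands (`predict`, `simulate-rotor`, `analyze-trajectory`,
`simulate-separation`, `analyze-chromatogram`, `make-fixtures`); see
`?propellr_cli`.

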