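---
title: "The molecular propeller effect: model, simulator and separation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The molecular propeller effect: model, simulator and separation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propellr)
```

## The physical picture

A chiral molecule with a permanent electric dipole moment, dissolved in a
non-polar solvent and exposed to a rotating electric field (REF), behaves as
a microscopic propeller. The field torque makes part of the molecular
population rotate with the field; because the molecule is chiral, rotation
about its propeller axis $I_1$ is hydrodynamically coupled to translation
along that axis. The coupling strength is the signed displacement per full
revolution, $L_{rev}$ (Å/rev), equal in magnitude and opposite in sign for
the two enantiomers. Under a REF the S and R forms therefore drift in
opposite directions along the field-rotation axis, and a racemic plug in a
capillary slowly un-mixes.

`propellr` implements this theory and everything needed to exercise it end
to end: orientation statistics, the driven-rotor frequency response, the
propulsion-velocity chain, a rotational Brownian dynamics generator of
synthetic trajectories, the estimators that read $D_r$ and $L_{rev}$ back
out of trajectories, a 1-D drift–diffusion model of the separation chamber,
and chromatogram synthesis/analysis with CD-based enantiomeric-excess (ee)
readout.

## The closed-form chain

Everything is controlled by the dimensionless dipole–field coupling

$$x = \frac{\mu E}{k T},$$

which is small (≈ $2.6\times10^{-3}$ and $5.4\times10^{-3}$ for the two
reference molecules at $E = 6\times10^5$ V/m, 293 K): the field only weakly
biases the orientation distribution.

**Orientation statistics.** In the co-rotating frame the orientation density
is Boltzmann, $\rho(\alpha) \propto e^{x\cos\alpha}$ with $\alpha$ the
dipole–field angle (`angular_density()`, normalised per steradian). The
*responding fraction* subtracts the isotropic baseline fixed by the density
minimum at $\alpha = \pi$:

$$F(x) = 1 - \frac{2x}{e^{2x} - 1} \approx x - \tfrac{x^2}{3},$$

the average fraction of molecules that follow the field's rotation.
An alternative baseline reading, $F = 1 - e^{-2x} \approx 2x$, is exposed as
`responding_fraction(x, mode = "exponential")`. The two differ by a factor
of ~2 at small coupling and cannot both be consistent with the same
downstream velocity; the default is the form that reproduces the published
velocity chain exactly, and the package never silently mixes the two.

**Frequency response.** An overdamped dipole driven at field frequency
$\nu$ obeys the Adler-type phase equation
$\dot\psi = 2\pi\nu_{esc}\sin(2\pi\nu t - \psi)$ with escape frequency
$\nu_{esc} = \mu E / (2\pi\xi)$ and rotational friction
$\xi = kT/D_r$. Below $\nu_{esc}$ the rotor phase-locks
($\nu_{eff} = \nu$); above it, it slips, with time-average

$$\nu_{eff} = \nu - \sqrt{\nu^2 - \nu_{esc}^2} \;\xrightarrow{\nu \gg \nu_{esc}}\; \frac{\nu_{esc}^2}{2\nu}.$$

`effective_frequency()` is the closed form; `effective_frequency_ode()`
integrates the phase equation directly (fixed-step 4th-order Runge–Kutta,
200 steps per field period via deSolve) and is used as its independent
check. One must integrate over enough periods for the finite-time average
to converge: the bias decays as one slip cycle over the total time, and at
1000 periods the two routes agree to ~0.2% over drive ratios
$\nu/\nu_{esc}$ from 0.5 to 100 — the package tests assert 1%.

**Angular correction.** The field torque rotates molecules about the lab
field-rotation axis, but the propeller axis is not always aligned with it.
Averaging the projection $|\sin\theta\cos\phi|$ of $I_1$ on that axis with
the azimuthally averaged Boltzmann weight $B(x, \theta) = I_0(x\sin\theta)$
gives the correction factor $A_{cor}(x)$, computed by `angular_correction()`
with adaptive quadrature at relative tolerance $10^{-10}$ — fine enough to
resolve $A_{cor} = 0.5000003$ at experimental couplings. The exact limits
are $1/2$ (zero field, uniform axis orientation) and $2/\pi \approx 0.637$
(strong field, axis uniform in the plane perpendicular to the field), with
small-$x$ behaviour $\tfrac12(1 + x^2/48)$. Since the field dependence is
negligible at realistic couplings, the velocity chain defaults to the
constant $1/2$ (`a_cor_mode = "fixed_half"`).

**Propulsion velocity.** The factorised chain is

$$v = L_{rev}\,\nu_{eff}\,A_{cor}\,F(E).$$

Sign conventions: $v$ is reported along the flow axis (injection →
collection); a CW field (viewed along the flow) drives the S enantiomer
($L_{rev} > 0$) toward collection. Mirroring the molecule or reversing the
field sense negates $v$ exactly.

```{r}
pred <- propeller_predict(reference_rotor("molecule_I"), reference_field())
pred
```

The bundled `molecule_I` carries a rotational diffusion coefficient
back-solved from its published 0.507 MHz escape frequency (the source
reports the value only graphically); the fixture JSON flags it as inferred.

## The Brownian dynamics generator

`simulate_rotor()` generates synthetic rigid-rotor trajectories standing in
for all-atom MD. Per step of size $dt$ the body frame (axes $I_1, I_2, I_3$;
dipole along $I_2$) is rotated about each body axis by

$$\Delta\theta_i = \frac{\tau_i}{\xi}\,dt + \sqrt{2 D_r\,dt}\;\mathcal{N}(0,1),$$

where $\tau = \mu I_2 \times E(t)$ is the instantaneous field torque. The
centre of mass advances by $(L_{rev}/2\pi)\,\Delta\theta_1$ along the
pre-rotation $I_1$ — the coupling is put in by construction, so the
generator is a controlled oracle for the estimators — plus isotropic
translational noise $\sqrt{2 D\,dt}$ per coordinate. Numerical choices:

* The rotations are composed in the fixed order $I_1, I_2, I_3$; the
  non-commutativity error is $O(\Delta\theta^2)$ and the configuration
  constructor enforces $dt\,D_r \le 0.01\ \mathrm{rad}^2$, far below the
  stochastic step itself. The triad is re-orthonormalised every 50 steps
  and stays orthonormal to $10^{-8}$.
* A single scalar $D_r$ applies to all three axes by default (the three
  principal values are similar for the study molecules); `d_r_axes` can
  override per axis.
* Any step with $|\Delta\theta| > 0.5$ rad aborts with a step-size error.
* All randomness flows through R's RNG, so a configuration plus seed
  reproduces a trajectory bit for bit.
* `field_at()` provides the ideal circular REF and a `four_phase_square`
  dialect: constant magnitude, direction stepping 90° four times per
  period, the idealisation of the four-pole square-wave electrode drive
  (the brief diagonal states during real phase overlaps are not modelled).

What the generator deliberately does *not* emulate: solvent structure,
force fields, inertia, hydrodynamic memory, or any feedback of translation
on rotation. Passing recovery tests therefore demonstrates that the
estimator pipeline is unbiased for the rigid-rotor model with a linear
coupling — not that the coupling value of a real molecule is correct.

## Trajectory estimators

* `msad()` computes the mean square angular displacement of the unwrapped
  rotation angle over sliding windows; `fit_rotational_diffusion()` takes
  half the fitted slope. The fit window defaults to lags up to 1% of the
  trajectory (hard cap 10%): the relative error of a single-trajectory
  MSAD slope grows roughly as the square root of the lag fraction, and 1%
  keeps recovery within a few percent.
* `estimate_L_rev()` regresses the per-record *increments* of the axial
  displacement (COM increments projected on the instantaneous $I_1$)
  against increments of the rotation angle. With realistic translational
  diffusion, the absolute displacement and angle series are two nearly
  independent random walks whose absolute-vs-absolute regression slope is
  dominated by spurious correlation (tens of Å/rev); the increment
  regression is unbiased with error shrinking as $1/\sqrt{n}$, which is
  the only way slopes of ~1 Å/rev are resolvable at the published
  precision. Uncertainty comes from block sampling (default 10 contiguous
  blocks; s.e. = s.d. of block slopes / $\sqrt{n_{blocks}}$).
* Angles are used unwrapped throughout; nothing is re-wrapped at ±180°.

The core closure property — simulate with known $(D_r, L_{rev})$, then
recover both, including the null $L_{rev} = 0$ axis — is asserted across
five seeds in the test suite, with trajectories of $10^5$–$4\times10^5$
steps at $dt = 2\times10^{-12}$ s (sizes chosen to put the estimator s.e.
comfortably below the tolerances while the whole suite stays quick).

## Separation transport

For two Gaussian plumes drifting apart at $\pm v$ and diffusing with $D$,
splitting the combined profile at its centre gives each half an excess

$$ee(t) = v\sqrt{\frac{t}{\pi D}},$$

the small-drift limit of the exact result $\mathrm{erf}(v\sqrt{t/4D})$; the
package caps it at 1. `split_ee()` of a `gaussian_pair_profile()` matches
the erf value to $10^{-4}$; the $\sqrt{t}$ law tracks it within 1% up to
ee ≈ 0.2 and ~2% by ee ≈ 0.27 (it departs quadratically). Off-centre cuts
toward the leading edge are strictly more enriched, as observed
experimentally. `fit_propulsion_velocity()` inverts the law — a regression
of measured ee on $\sqrt{t/\pi D}$ through the origin — to read a drift
velocity off ee kinetics.

`evolve_bounded()` handles the finite chamber: a conservative explicit
finite-difference scheme (upwind advection, central diffusion, flux form)
on a closed domain, with the drift switched off outside the 10-cm active
region — material that diffuses past the electrodes keeps diffusing but is
no longer driven — and reflecting far boundaries, since the valves are
closed during exposure. Stability requires $D\,dt/\Delta x^2 \le 0.4$ and
an advection Courant number below 0.9; mass is conserved to rounding
(tested at $10^{-6}$). ee is computed on concentrations; absorbance is
taken proportional to concentration at the detection wavelength.

In a closed chamber of length $L$ the drift–diffusion balance ends in the
zero-flux exponential steady state

$$C(x) = C_{ave}\,\frac{(vL/D)\,e^{vx/D}}{e^{vL/D} - 1},$$

mirrored for the opposite enantiomer (`steady_state_profile()`; the
$v \to 0$ limit returns the uniform profile via `expm1`). The scale
$D/|v|$ (`characteristic_length()`, ~3 cm for the reference molecules)
says how strongly drift beats diffusion.

## Chromatography

`profile_to_chromatogram()` maps positions to elution times through the
linear flow velocity (flow rate / capillary cross-section; defaults
0.050 µl/min in a 75 µm ID capillary), with the leading edge eluting
first; absorbance tracks total concentration and the CD channel tracks the
concentration difference. `fwhm()` measures peak widths by linear
interpolation at half maximum and refuses multi-peak traces;
`estimate_D_from_spreading()` turns a series of (wait time, FWHM) pairs
into $D$ via $FWHM^2 = FWHM_0^2 + 16\ln 2\,D\,t$ with a free intercept.
`ee_from_cd()` reads ee from the concentration-independent ratio of
integrated CD to integrated absorbance through a linear calibration
(identity by default, matching the synthetic detector; real calibration
tables load from CSV — the linear form is an assumption, stated here
because the reference procedure does not specify one).
`split_fractions()` cuts at the absorbance centre of mass by default
(peak-maximum cutting is an option) and inserts an interpolated sample at
the cut so the fractions tile the record exactly.

## Design decisions that were genuinely open

* **Responding-fraction form.** Two baseline-subtraction readings exist
  (see above); the default follows the one consistent with the published
  velocity chain, the alternative stays available behind a mode switch,
  and the discrepancy is documented rather than reconciled.
* **Temperature default** is 293 K (the simulation temperature; the
  experimental chamber ran slightly cooler), configurable per
  `field_protocol()`.
* **Units at the boundary:** Debye, deg²/s, Å, cm²/s in all user-facing
  structures (with 1 D = 3.33564×10⁻³⁰ C·m fixed internally); SI and
  radians internally.
* **Molecule I's $D_r$** ships as the back-solved value with an explicit
  "inferred" note, rather than pretending a published number exists.
* **Increment-based coupling regression** (see the estimator section) in
  place of the naive absolute-vs-absolute reading.

## Known limitations

* The factorised velocity treats $F(E)$ and $\nu_{eff}$ as separable;
  near and above $\nu_{esc}$ the orientation distribution is not at
  equilibrium and the chain is an approximation. The BD simulator can
  probe the joint effect, but the package does not force the two routes to
  agree beyond the deterministic limit.
* The transport model is 1-D: no capillary hydrodynamics, convection,
  electro-osmosis or Joule heating.
* Field non-uniformity across the chamber and dielectric corrections are
  ignored; the field magnitude is a configuration constant.
* Detector physics (CD optics, wavelength dependence, recovery losses) is
  reduced to a linear calibration.
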