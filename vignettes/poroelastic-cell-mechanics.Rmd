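---
title: "Poroelastic cell mechanics with poroflow: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poroelastic cell mechanics with poroflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poroflow)
```

# The model

`poroflow` treats the cytoplasm as a linear biphasic (poroelastic)
continuum: a drained elastic skeleton with Young's modulus $E$ and
Poisson ratio $\nu$, saturated by an incompressible interstitial fluid
that moves relative to the skeleton by Darcy flow with hydraulic
permeability $k$. With Biot coefficient 1 and incompressible
constituents, the coupled equations are

$$\nabla\cdot(\sigma' - p\,I) = 0, \qquad
\frac{\partial}{\partial t}(\nabla\cdot u) = \nabla\cdot(k\,\nabla p),$$

with $\sigma' = C : \varepsilon(u)$ the effective stress on the drained
skeleton and $p$ the pore pressure above ambient. Pressure disturbances
spread diffusively with the poroelastic diffusion constant $D$. The
literature on cell poroelasticity usually states only the scaling
$D \sim kE$; this package fixes the convention as the oedometric
(confined-compression) consolidation coefficient

$$D = k\,E\,\frac{1-\nu}{(1+\nu)(1-2\nu)},$$

used identically in both directions (`poro_D_from_k()`,
`poro_k_from_D()`). Every parameter-recovery result in the package is
therefore convention-independent: the same mapping is used when
generating forward data and when inverting it. At $\nu = 0.3$ the
prefactor is about $1.35$, so the distinction from $D = kE$ matters only
if values are compared across conventions.

Internal units are µm, s, Pa and nN throughout; `k_si_to_um2()` /
`k_um2_to_si()` bridge to the SI permeability usually printed in papers
($1\,\mu m^2/(Pa\,s) = 10^{-12}\, m^2/(Pa\,s)$).

## Assumptions and what they exclude

* **Small strains.** The indentation and pressure protocols used for
  parameter work impose strains of order 10%; a geometrically nonlinear
  (porohyperelastic) formulation would shift absolute amplitudes slightly
  but the package's quantitative claims are self-consistency recoveries,
  which are insensitive to that choice. Large-deformation analysis is out
  of scope.
* **No surface tension term.** The cortex enters only as a
  low-permeability elastic layer. The fast (\<0.3 s) phase of the
  experimental bead response, attributed to cortical tension, is
  represented in the synthetic-data generators but not in the continuum
  solver.
* **No osmotic or ion-transport model.** Trans-membrane water exchange is
  represented, where needed, by a fixed-pressure reservoir boundary
  condition (see the depressurisation scenario).

# The solver

The weak form is discretised on structured, graded meshes of 9-node
biquadratic quadrilaterals for displacement sharing corner nodes with a
bilinear pressure field — the Q2–Q1 Taylor–Hood pairing, inf-sup stable
for consolidation problems and equivalent in accuracy class to the
8-node quadratic pore-pressure quads traditional in commercial codes.
All volume integrals carry the axisymmetric measure $2\pi r$; a 3×3
Gauss rule integrates the curved (isoparametric) elements of the
elliptical-cap geometry.

Time integration is backward Euler, unconditionally stable, with uniform
steps through load ramps and geometrically growing steps through hold
phases (`time_grid_ramp_hold()`). A per-increment cap on the pore
pressure change is available (`ptol`) and bisects offending steps; it is
off by default because the scenario time grids are chosen by convergence
checking instead (halving all element sizes and refining the step
schedule changes reported forces and displacements by under 2%).

Two numerical details deserve note:

* **Storage regularisation.** With incompressible constituents and fully
  impermeable, fully fixed boundaries the pressure is determined only up
  to a constant. A tiny specific storage ($10^{-9}\,Pa^{-1}$) keeps this
  mode well-posed; it perturbs transient solutions at the sub-ppm level.
* **Parameter-linear assembly.** The stiffness scales linearly in each
  region's $E$ (at fixed $\nu$) and the mobility in each region's $k$, so
  the element integration is done once per mesh and every solve in a
  fitting loop only rescales cached sparse matrices and refactorises per
  distinct time step.

The solver is validated against the classical one-dimensional
consolidation series solution (`terzaghi_reference()`): a laterally
confined column, step-loaded and drained at the top, matches the series
within 1% relative $L_2$ at the benchmark resolution, reproduces the
undrained ($p = q$) and drained ($p = 0$) limits, and reaches 50% average
consolidation at dimensionless time $T_v \approx 0.197$. A steady
two-pressure column relaxes to an exactly linear profile, and the
discrete continuity residual (fluid balance per step) sits at the
round-off level of the linear solves.

# The three in-silico experiments

**Indentation** (`simulate_indentation()`): a cylindrical disk (default
20 µm radius and thickness, chosen large to keep edge effects away from
the contact) indented by a rigid sphere. The contact is simplified to a
prescribed vertical displacement over the geometric contact patch
$a = \sqrt{R\delta}$, frictionless and impermeable, with the rest of the
top surface drained ($p = 0$); the base is no-slip. The indenter radius
is not fixed by the experimental record; the default $R = 2$ µm matches
a ~4 µm contact diameter at 2 µm depth and is exposed as a parameter.
The solver reproduces the hallmark observations: monotone hold-phase
force relaxation, and a steady surface profile that moves down near the
contact and up further out. In this drained linear model the sign change
sits near the disk rim with a small amplitude; in experiments (and with
cortical tension) it occurs nearer 6 µm — the qualitative pattern, not
its location, is the model's claim.

**Microinjection** (`simulate_injection()`): an elliptical cap (40 µm
footprint diameter, 4.5 µm apex height) attached to a substrate, with a
pipette contact of 1 µm radius at the apex. The effective pressure
$P_{eff} = P_{app} - P_{in}$ is ramped over 2 s at the contact; all other
boundaries are impermeable, since membrane water exchange
(tens-of-seconds scale) is negligible over a 2 s injection. Per-probe
vertical displacements and onset time lags (10%-of-steady-state rule)
are returned. Time lags grow nearly linearly with distance over 3–15 µm
(r² > 0.99 at the default parameters), and doubling $D$ shortens them.
Probes are interpolated at undeformed radii (small-strain consistency).

**Depressurisation** (`simulate_depressurisation()`): the same cap with
a 250-nm low-permeability cortex layer and a 2-µm-diameter sink at the
apex held below the internal pressure. The pipette opening pierces the
membrane–cortex layer, so the sink couples to the cell interior; the
outer cortex boundary away from the sink is held at the internal
pressure, a reservoir standing in for trans-membrane influx. This
reproduces the expected structure without an explicit osmotic model: a
steady intracellular pressure gradient whose length scale is set by the
cortex diffusion constant $D_1$. Sweeping $D_1$ over two decades, the
distance at which the pressure recovers 90% of the drawdown shrinks
monotonically as $D_1$ grows (6.6 → 2.4 → 1.0 µm for
$D_1/D_2 = 0.01, 0.1, 1$ at the default parameters); for very tight
cortices the profile plateaus below full recovery and the 90% length is
reported as missing rather than extrapolated. At steady state the sink
efflux balances the membrane influx to within 1% (boundary integrals of
the Darcy flux).

# Estimators

* `time_lag()` implements both threshold rules in experimental use — a
  fixed 0.1 µm displacement and 10% of the steady-state displacement —
  as an explicit argument, never a silent default, with linear
  interpolation between samples and a distinct "never crosses" result
  (`NA`, not 0).
* `darcy_fit()` reduces $(\Delta x, \delta t, \Delta P)$ records to
  $v = \Delta x/\delta t$ and $g = \Delta P/\Delta x$ and fits the
  through-origin slope $k$ (Darcy's law has no offset); the
  free-intercept r² is reported alongside for comparability with
  published regressions.
* `hyperbolic_lag_fit()` fits $\delta t = c/\Delta P$ and reports the
  relative residual so pressure-independent lags flag as misfits instead
  of fitting silently.
* `tau_p_fit()` fits a single exponential to the slow phase after a
  fixed, explicit phase-split time (default 0.3 s, the empirical bound
  on the fast phase). A fixed split was chosen over automatic changepoint
  detection: the split time is part of the analysis definition, and an
  automatic detector would make the estimator's behaviour
  data-dependent in ways that are hard to audit. The functional form of
  the slow phase is taken as single-exponential; this is a documented
  modelling choice.
* `pore_scaling()` evaluates $\xi/\xi_0 = (\alpha + \phi(\alpha-1))^{1/3}$
  and $t_p/t_{p0} = (\xi/\xi_0)^{-2}$ exactly as printed in the
  literature. Note the convention trap: $\alpha$ is the *remaining*
  volume fraction $V/V_0$, so a 40% volume decrease corresponds to
  $\alpha = 0.6$ — published brackets of 0.72–0.77 for the pore-size
  ratio (hence 1.7–1.9 for the time ratio) match the formula near
  $\alpha = 0.6$ even where the shrinkage magnitude 0.4 is quoted as the
  "$\alpha$" value. The formula is implemented as printed and this
  ambiguity is documented rather than patched.

## A documented bias: the coarse front estimator versus the solver

Applying the experimental reduction $v \sim \Delta x/\delta t$,
$\nabla P \sim P_{eff}/\Delta x$ to the *simulated* injection lags
overestimates the solver's own permeability by roughly a factor of five
at the default conditions. The causes are structural: the lag includes
the 2 s pressure ramp, the flow spreads radially in a thin cap rather
than along a 1D column, and $P_{eff}/\Delta x$ overestimates the local
gradient at the front. The same tension is visible between published
experimental permeabilities ($\sim 0.1\,\mu m^2/(Pa\,s)$) and the
permeabilities implied by FE-fitted $(E, D)$ pairs
($\sim 0.01\,\mu m^2/(Pa\,s)$). The package therefore treats the front
estimator as the order-of-magnitude tool it is; the test suite asserts
the direction and magnitude of the bias rather than pretending it is
absent.

# Inference

`fit_indentation()` and `fit_injection()` recover $(E, D)$ by matching
forward simulations to observations in two stages: a log-spaced
5×5 grid over the parameter bounds (first approximation), then
Nelder–Mead refinement on $\log_{10}$ parameters with out-of-bounds
penalisation. The objective is a sum of per-series normalised squared
residuals — each series (displacement profile, force relaxation, time
lags) is scaled by its own maximum absolute observation, so µm-scale and
s-scale observables mix without manual weights and zero-crossing
profiles cause no division blow-ups. The pipeline is deterministic:
identical inputs give bitwise-identical results.

Identifiability is enforced, not assumed: under displacement-controlled
indentation the steady profile is independent of $E$ (amplitude is
prescribed) and carries no kinetics, so requesting $D$ from a
steady-state profile alone is an explicit error — a force-relaxation
timecourse identifies $D$ through its decay and $E$ through its scale.
Under pressure-controlled injection the displacement amplitude scales as
$P_{eff}/E$, so an error in the assumed $P_{eff}$ propagates almost
proportionally into $E$ (doubling the assumed $P_{eff}$ doubles the
fitted $E$); this covariance is asserted in the tests and should be kept
in mind when $P_{eff}$ comes from an independent measurement.

Fits run on a deliberately coarse mesh (the forward model is the cost);
an optional finer verification solve at the optimum
(`verify_resolution`) warns when discretisation moves the fitted
observables by more than 5%. It is off by default because for
self-consistency work (data generated on the fitting mesh) the warning
would only ever report the mesh difference itself.

# Bead tracking

Defocused fluorescent beads image as concentric rings whose outer radius
reports the bead's distance to the focal plane. `outer_ring_radius()`
takes a horizontal intensity profile through the ring centre, averaged
over a 3-px band (configurable) to reduce noise, finds the first and
last peaks above a noise floor, and fits each with a Gaussian plus a
linear baseline; the radius is half the distance between the fitted
centres. Two details matter for sub-pixel accuracy: the fit window is
capped below the distance to the neighbouring ring, and the linear
baseline absorbs that ring's sloping tail — without these the fitted
centres are pulled inward by up to a pixel. The noise floor is a
background quantile plus the larger of a prominence fraction and a few
noise standard deviations, making detection invariant to global
intensity scaling and offset; ring-free frames raise a typed detection
error, never a silent zero.

`calibrate()` maps radius to z by least squares over a piezo staircase
(locally linear over the calibrated range, per the stepped-stage
procedure), and `track_stack()` converts stacks to baseline-subtracted
traces, carrying failed frames as gaps (never interpolating) and failing
the stack outright beyond 50% losses. On synthetic stacks (0.1 µm
pixels, 0.05 µm/px calibration slope, 5% noise) the end-to-end z-trace
RMSE is a few nanometres, comfortably inside the tens-of-nanometres
regime the technique claims; the radius estimator's RMSE is below 0.2 px
at 10% noise and its bias below 0.05 px across radii 10–40 px.

# Synthetic data

The generators exist so every estimator has a ground-truth round trip:

* `gen_biphasic_traces()`: fast step (complete by 0.2 s) plus slow
  exponential with distance-dependent $\tau_p(r)$ (non-decreasing by
  default), sign switching from downward to upward at 6 µm, 5 nm
  Gaussian noise by default. Amplitude defaults (hundreds of nm,
  decaying over ~15 µm) are order-of-magnitude placeholders, not
  measured values.
* `gen_injection_traces()`: flat until a front-arrival lag, then a
  saturating rise. The default front model is linear in distance
  (constant velocity, the experimental observation); a diffusive
  quadratic alternative supports sensitivity tests.
* `gen_darcy_dataset()`: the default `local_gradient` model sets
  $\delta t = \Delta x^2/(k\Delta P)$ so that `darcy_fit()` recovers $k$
  exactly at zero noise (the defining round-trip property); the
  `constant_velocity` alternative makes lags linear in distance at the
  cost of an only-approximate round trip. Lag noise is multiplicative
  log-normal, 20% by default.
* `gen_metaphase_diameter()`: flat diameter until a hyperbolic onset lag
  $c/\Delta P$, then linear growth at a pressure-proportional rate,
  3 replicate cells per pressure by default. The onset-threshold
  extraction adds exactly `threshold/rate` to the recovered $c$, a bias
  the documentation and tests account for analytically.

All generators require a seed, produce bitwise-identical output under
it, and restore the ambient RNG state.

What the generators deliberately do not emulate: correlated noise between
beads on one cell, drift, photobleaching, non-exponential slow phases, or
camera noise beyond Gaussian/Poisson. Passing round-trip tests therefore
demonstrates estimator correctness under the stated statistical model,
not robustness to every failure mode of real recordings.

# Problem sizes and reproducibility

The shipped tests and the acceptance script run on deliberately coarse
discretisations chosen by convergence checks: fitting meshes of a few
hundred elements (2.5 µm resolution for the disk, 1.5 µm for the cap,
with three-fold refinement near the axis and surface and at least two
element layers through the cortex), 20–40 time steps per transient, and
Monte-Carlo ensembles of 100–200 seeds for estimator calibration (25
seeds scaled to 5 for the full-fit noise-robustness property). The
self-consistency recoveries at the published parameter points
(E = 1.8 kPa, D = 28 µm²/s for indentation; E = 1.2 kPa, D = 13 µm²/s at
P_eff = 500 Pa for injection) land within a fraction of a percent of
truth from ±50% perturbed starts.

# Known limitations

* Linear small-strain theory: absolute amplitudes at 2 µm indentation of
  a 4.5 µm cell carry finite-strain error; ratios and recoveries do not.
* No contact mechanics: the indenter is a prescribed-displacement patch
  of fixed radius $\sqrt{R\delta}$, adequate for far-field surface
  displacement but not for contact-pressure distributions.
* The cortex is purely a transport barrier plus elastic layer; active
  tension, turnover and mechanosensitive fluxes are absent.
* The membrane reservoir boundary condition fixes pressure, not
  chemistry; osmotic transients are outside the model.
* Single-exponential $\tau_p$ extraction and linear radius–z calibration
  are local approximations, valid over the ranges stated above.
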