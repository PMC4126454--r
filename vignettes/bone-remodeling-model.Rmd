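---
title: "A mechanobiological finite-element model of bone remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanobiological finite-element model of bone remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteofem)
```

## The model

`osteofem` simulates load-adaptive remodeling of a 2D plane-stress proximal
femur by coupling three layers, advanced together with a time step of one
day:

1. **Mechanics.** Each gait load case is solved as a linear static
   plane-stress problem on a quadrilateral mesh. The element modulus is
   the density-ash-damage law $E = C\,(1-D)\,\rho^{p}\alpha^{q}$ with
   $p = 3$, $q = 2.74$; stress follows the damaged constitutive relation
   $\sigma = (1-D)\,a\,\varepsilon$.

2. **Mechanotransduction.** The osteocyte-sensed signal per element is the
   strain-damage energy density $S_k = \tfrac12\,\sigma\!:\!\varepsilon$
   (the damage factor enters once, through $\sigma$). The net stimulus is
   the influence-weighted excess over the setpoint,
   $S(x) = N_{oc}\sum_k e^{-d_k/d_0}\,\mu\,(S_k - \bar S_k)$, and the
   setpoint accommodates toward the experienced level,
   $\bar S_k(t) = S_{k0} + (S_k - S_{k0})(1 - e^{-\lambda t})$, so a
   constant habitual load is eventually perceived as neutral. When local
   fatigue damage reaches $D_{crit}$ the stimulus is shut down, which
   hands the failed site to targeted osteoclastic resorption.

3. **Cell dynamics.** Each element hosts one basic multicellular unit
   whose osteoclast/osteoblast populations follow the coupled power-law
   ODEs
   $\dot x_C = \alpha_1 x_C^{g_{11}} x_B^{g_{21}} - \beta_1 x_C$,
   $\dot x_B = \alpha_2 x_C^{g_{12}} x_B^{g_{22}} - \beta_2 x_B$
   with $g_{11} = g_{22} = 0$ and stimulus-dependent paracrine exponents
   $g_{12} = A_1 + B_1 e^{-\gamma_1 S}$,
   $g_{21} = A_2 + B_2 e^{-\gamma_2 S}$. Only cells in excess of the
   steady-state populations
   $\bar x_C, \bar x_B$ (the closed-form fixed point of the ODEs) remodel
   matrix: $d\rho/dt = k_2 X_B - k_1 X_C$ with
   $X_i = \max(x_i - \bar x_i, 0)$, density being carried as a fraction of
   its initial value and the activities $k_1, k_2$ as percent of initial
   mass per active cell per day. An overloaded site ($S > 0$) raises
   $g_{12}$ and lowers $g_{21}$ — stimulatory to osteoblasts, inhibitory
   to osteoclasts — and a disused site does the opposite.

Fatigue damage accumulates from the per-case principal strain amplitudes
through a nonlinear (Chaboche-type) law
$D = 1 - [1 - (N/N_f)^{1/(1-\gamma)}]^{1/(1+\beta)}$ with separate
compressive and tensile strain-life curves
($N_f^c = 1.479\times10^{-21}\Delta\varepsilon^{-10.3}$,
$N_f^t = 3.630\times10^{-32}\Delta\varepsilon^{-14.1}$), is repaired in
proportion to newly formed mass, and degrades the modulus. Mineralization
follows $\alpha(t) = \alpha_{max} + (\alpha_0-\alpha_{max})e^{-k t}$ on
the global tissue clock; porosity is the bookkeeping quantity
$p = 1 - \rho/(1.41 + 1.29\,\alpha)$.

Within a day the stage order is fixed: mechanics, damage accumulation,
stimulus and setpoints, cell/density update, damage repair, mineralization.
The stimulus (hence the paracrine exponents and the steady-state
thresholds) is frozen within each day.

## Parameter choices that required judgment

The reference parameterization contains three internal inconsistencies
that any implementation must resolve. The resolutions below were fixed
before the simulation studies and are exposed as plain configuration
fields, so each alternative reading can be forced.

**Osteoblast removal rate vs. formation activity.** The reference table
pairs $\beta_2 = 0.0017$/day with $k_2 = 0.02$; the source cell-dynamics
model pairs $\beta_2 = 0.02$/day with $k_2 = 0.0017$. The first pairing
implies an osteoblast lifespan of ~590 days — contradicting the stated
biology (osteoblast lifespan about 3 months, about 6 times that of
osteoclasts) — and makes formation overwhelm resorption so strongly that a
zero-stimulus site gains density monotonically until it hits the
fully-mineralized clamp, which is incompatible with heterogeneous
converged density maps and with an adaptation process that *starts with
resorption*. The package therefore defaults to the source pairing
($\beta_2 = 0.02$, $k_2 = 0.0017$, cortical activities 10× lower);
`bmu_params(beta2 = 0.0017, k2 = 0.02)` restores the literal table.

**Initial moduli vs. the modulus coefficient.** The printed coefficients
$C = 4000/8000$ give initial moduli of 440/5415 MPa at the initial
densities and ash fraction, while the printed initial moduli are
2000/17000 MPa. With the 440 MPa reading, physiological gait loads
produce strain amplitudes of several percent and the entire mesh fails by
fatigue within days. The package anchors the law to the printed initial
moduli, $C = E_0/(\rho_0^{p}\alpha_0^{q})$, which keeps the model
coherent; `material_params(C = 4000)` forces the printed-coefficient
reading.

**Effective section thickness.** A coronal femur slice carrying the full
3D joint and abductor forces needs an effective out-of-plane thickness
well above its anatomical slice depth (the slice stands in for the whole
cortical tube; classic 2D femur models use side plates for the same
reason). The default, 120 mm, is calibrated once so that the peak
cortical strain under the normal walking schedule is ~0.10% and under the
overload schedule ~0.14% — inside the measured in-vivo gait strain band
and below the tensile fatigue-runaway threshold for 5 years of 10^4
cycles/day, matching the observation that fatigue damage stays low under
habitual loading. Thinner sections push the shaft-base bending fibers
into a damage-softening runaway (damage lowers $E$, strain rises, $N_f$
falls as $\Delta\varepsilon^{-10..-14}$), i.e. a propagating stress
fracture.

**Stimulus units and sensor discretization.** The reference unit system
(setpoint in J·m⁻³, exponent coefficients in g/J) cannot be made
dimensionally consistent; the package works in MPa energy units (MPa ×
dimensionless strain), where the printed setpoint $S_{k0} = 0.0025$ sits
at the scale of the median element energy density of the initial normal-
walking solve — the operating point is what matters. Each element carries
one aggregate osteocyte sensor at its centroid with weight 1; the
absolute osteocyte count folds into the $\gamma_1,\gamma_2$ scaling, and
`Noc` survives as a relative multiplier so the sensitivity analysis can
perturb sensor density. With the default decay length $d_0 = 0.1$ mm
(read as mm; the printed µm would extinguish all spatial interaction
below any feasible mesh scale) and millimetric elements, sensing is
effectively local. A calibration helper
(`simulation_config(calibrate_setpoint = TRUE)`) can instead pin
$S_{k0}$ to the median element energy of an initial solve.

## Numerical choices

* Cell ODEs: classical Runge-Kutta with 24 sub-steps per day (the
  osteoblast equation is fast when osteoclasts are numerous); density by
  forward Euler accumulated per sub-step. Against an adaptive
  high-accuracy integrator the day-stepping agrees to better than 1e-3
  relative in both populations over 100 days.
* Paracrine exponents are clamped to ±5: under strongly negative
  (disuse) stimulus $g_{21}$ grows exponentially and $x_B^{g_{21}}$ would
  overflow. Cell counts carry a positivity floor of 1e-8; normalized
  density is clamped to [0.01, $\rho_{max}/\rho_0$] with
  $\rho_{max} = 1.74$ g/cm³, and the modulus is floored at 0.01 MPa so
  fully resorbed or failed elements keep a regular stiffness.
* The linear systems are solved by sparse Cholesky after symmetric
  Jacobi scaling (the modulus contrast between intact cortical bone and a
  floored element reaches ~10^6) with iterative refinement; verification
  solves reach ~1e-12 relative residual, and the daily loop aborts above
  1e-6.
* Fatigue under the three daily load cases uses a damage-equivalent-cycle
  rule: current damage is inverted to a cycle ratio at the new amplitude
  before adding $n/N_f$; for constant amplitude this is exactly the
  closed-form law and is independent of cycle partitioning. The per-case
  amplitude is the largest-magnitude principal strain at the element
  centroid; its sign picks the compressive or tensile life curve, with
  pure-shear ties broken to tensile. The three cases' energy densities
  combine into the daily stimulus with cycle weights 6000/2000/2000.
* Unloading increments are not solved (identically zero in linear
  elasticity); they enter only through cycle counting.

## The synthetic femur fixture

No subject geometry is distributed with the package; the reference mesh is
a stylized parametric coronal proximal femur (vertical shaft, circular
bend into a 50° neck, spherical-cap head, lateral trochanter bump),
meshed as a single structured quadrilateral block (~1500 elements at the
default 1.8 mm resolution). The outer shell within 3.5 mm of the
medial/lateral surface is cortical, the interior trabecular; a transverse
neck band is the region of interest over which density change is
summarized (area-weighted mean); the distal edge is fixed and the
head/trochanter arcs receive cosine-distributed consistent loads, so the
applied force totals are preserved exactly. Element Jacobians are checked
positive, optionally under seeded interior-node jitter.

The fixture reproduces the *structure* of the problem — two material
regions, a neck ROI, realistic load paths and lever arms — but not
subject-specific geometry, cortical thickness variation, or the real
acetabular contact (loads are applied directly to the head arc). Passing
the pattern tests on this fixture therefore shows that the coupled
algorithm behaves as described, not that the package reproduces any
particular subject's densitometry.

## What the simulations show

On the fixture under the normal walking schedule the model starts with a
net-resorption transient (the initial cell state has a large osteoclast
excess), reaches its ROI-density minimum after ~3-4 weeks, then recovers
and converges: over the last 100 of 1825 days the ROI density moves by
less than 0.001%. The final state keeps the cortical region denser than
the trabecular region, and the final ROI density is ordered with load
(overload ≥ normal ≥ reduced). A one-factor sensitivity sweep (±50%)
recovers the expected signs — more resorption activity $k_1$ lowers the
neck density, more formation activity $k_2$ raises it, and the Poisson
ratio is negligible (|change| ≪ 1%).

The isolated-site disuse experiment (`disuse_experiment()`) deserves
honest comment. Holding the stimulus at zero and starting the reference
cell state (15 osteoclasts, 1 osteoblast), the site resorbs ~3% within
the first two weeks and then — as the osteoblast population overshoots its
steady state — recovers to a small net *gain* (~3.6%) at its new steady
state, far from the ~60% loss reported for unloaded bone in the source
experiments. That figure is not recoverable from the isolated site model
under any reading of the printed parameters we tested (the literal table
pairing drives the site to the density ceiling instead); in the full
femur it would emerge from the density-stiffness-energy feedback in
chronically low-energy regions, a mechanism the zero-stimulus site run
deliberately excludes.

## Problem sizes used by the test-suite

Unit and property tests run on closed forms, single elements, a
5-element patch, a 40×4 cantilever and coarse fixtures (4-6 mm elements).
The pattern checks run the full default fixture (~1500 elements) for
1825 days under each of the three schedules (~2 minutes each); the
sensitivity checks use a 5 mm fixture for 365 days per run. These sizes
are the package's reference desk-scale configuration; all are plain
arguments, so larger studies only change `elem_size` and `days`.

## Known limitations

Isotropic linear elasticity only (no anisotropy, creep or contact);
remodeling sites evolve synchronously; the 2D plane-stress slice cannot
represent out-of-plane load paths beyond the effective-thickness
calibration; region labels are static (no cortical/trabecular
conversion); and the sensitivity analysis is one-factor-at-a-time by
design, so it measures local main effects only.
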