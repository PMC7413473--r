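---
title: "Modelling catheter-tip hemodynamics and platelet damage with cathflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling catheter-tip hemodynamics and platelet damage with cathflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Hemodialysis withdraws blood through the *arterial* (inflow) lumen of a
dual-lumen catheter placed in a central vein. Side-holes drilled or skived
into the catheter wall near the tip add inflow paths: they keep the
catheter usable when the tip occludes, but they also change the local
velocity and shear-stress field that platelets experience on their way
into the lumen. High shear stress (above roughly 10 Pa) and long
residence times are both implicated in platelet activation, adhesion and
thrombus growth, so side-hole shape, size and arrangement are a genuine
design trade-off.

`cathflow` implements a desk-scale, two-dimensional version of the
standard computational pipeline for comparing such designs:

1. a parameterized planar catheter-tip geometry (vessel channel, catheter
   wall strips, tip opening, zero to two side-holes),
2. a steady laminar finite-volume solve of incompressible flow with
   shear-thinning blood rheology,
3. Lagrangian platelet tracking through the converged field with drag and
   shear-lift forces, and
4. a scoring layer: tip-volume shear statistics, side-hole flow rates,
   residence times and a power-law platelet lysis index (PLI).

Everything is deterministic: a configuration maps to byte-identical
artifacts.

## Blood rheology

Whole blood is shear-thinning. The package uses the asymptotic Carreau
model

$$\mu(\dot\gamma) = \mu_\infty + (\mu_0 - \mu_\infty)
  \left[1 + (\lambda\dot\gamma)^2\right]^{(n-1)/2},$$

with defaults $\mu_0 = 0.025$ Pa s, $\mu_\infty = 0.00345$ Pa s,
$\lambda = 25$ s, $n = 0.25$ — the usual whole-blood constants for
catheter-inflow modelling. The scalar shear rate is
$\dot\gamma = \sqrt{2\,D:D}$ with $D$ the strain-rate tensor, and the
scalar stress reported everywhere is $\tau = \mu(\dot\gamma)\dot\gamma$
(the conventional viscous-stress magnitude for laminar non-Newtonian
reporting; percentage-above-threshold metrics use the 10 Pa
platelet-activation level).

One form of the Carreau prefactor that circulates in the applied
literature, $(\mu_\infty + \mu_0)$, fails its own zero-shear limit
($\mu(0) = 2\mu_\infty + \mu_0 \ne \mu_0$); `cathflow` implements the
standard difference form above, which reproduces both plateaus exactly
(`carreau_viscosity(carreau_parameters(), 0)` returns 0.025).

## The 2D geometric analog

The solver works on a planar analog of a catheter inserted along a vein:

* a channel of width 20 mm (the vena-cava diameter) and length 60 mm;
* the catheter body as two horizontal wall strips (2 mm thick) enclosing
  a 2.5 mm lumen, inserted 24 mm from the inlet plane;
* the tip opening as the open end face plus a 2.5 mm cut-back of the
  upper wall (a skived tip);
* side-holes as openings in the upper wall, either `straight_cut`
  (square edges) or `angled_cut` (linearly chamfered edges, default 45
  degrees), with the distal edge held 16.5 mm from the tip in all
  compared designs so that designs differ only in the opening itself.

Two deliberate choices deserve comment.

**Wall placement.** The catheter lies along the bottom vessel wall
(`wall_offset = 0`), which is both the typical clinical position and a
requirement of the planar analog: a *centered* 2D rod exposes two free
shear layers whose von-Karman street has no steady state (we measured a
persistent residual limit cycle near $10^{-4}$ at fine grids), whereas
the wall-lying layout leaves a single shear layer — a step-down topology
with a steady laminar solution at these Reynolds numbers. The 3D annular
problem has no such vortex street, so suppressing it is the faithful
reduction, not an approximation of convenience. The vessel extends 36 mm
past the tip so the step-recirculation bubble reattaches well upstream
of the outflow plane.

**Flow-rate conversion.** 2D fields carry per-unit-depth fluxes
(m$^2$/s). The 400 mL/min volumetric withdrawal target is mapped through
an effective depth $D_\mathrm{eff} = A_\mathrm{lumen}/h = \pi h/2$ of a
semicircular lumen whose radius equals the planar lumen height
$h = 2.5$ mm. Reported "mL/min (2D-equivalent)" values round-trip this
conversion, so the volumetric scale of the reports is directly
comparable with clinical settings.

## The flow solver

`solve_steady()` is a staggered-grid SIMPLE scheme: first-order upwind
convection, central diffusion, Picard (lagged) Carreau viscosity,
pressure correction by a direct sparse Cholesky solve, under-relaxation
0.7 (momentum) / 0.3 (pressure). Boundary conditions follow the study
conditions: uniform 0.3 m/s vessel inflow, no-slip walls, zero gauge
pressure at the vessel outlet, and a *pressure* boundary at the lumen
outlet whose value is adjusted by a secant iteration between
residual-converged states until the recovered outflow matches the target
within 0.25% (the analog of 400 ± 1 mL/min) — mirroring how the dialysis
pump's suction, not a prescribed velocity profile, sets the flow.

Convergence requires three conditions simultaneously: scaled continuity
residual below $10^{-5}$ (sum of absolute cell imbalances over the inlet
flux), scaled momentum residual below $10^{-5}$ (imbalance over the
$a_P|u|$ scale, the usual segregated-solver normalization), and the
outflow within tolerance. The momentum criterion matters: continuity can
be projected out exactly each iteration while the delicate
diffusion-pressure balance is still settling, and stopping on continuity
alone leaves visible profile errors.

Numerical details that affect accuracy:

* **Walls at half-cell distance.** Cell-centered solid masks put no-slip
  surfaces half a spacing from the first velocity node. Wall shear uses
  the quadratic one-sided gradient $(9u_1 - u_2)/(3h)$ via a deferred
  correction, restoring second-order wall accuracy; with 40 cells across
  a channel the Newtonian solve matches the analytic parabolic profile
  to 0.15%.
* **Wall-aware shear evaluation.** The cell-center shear-rate field used
  for viscosity, stress statistics and export applies the same
  half-distance one-sided gradients at every no-slip surface (domain
  walls and interior wall strips). Differencing naively across a wall
  face underestimates near-wall shear by roughly a factor two at any
  resolution and dominates the grid sensitivity of shear statistics.
* **Rasterization.** Feature edges snap to the nearest grid face, and
  every feature must span at least three cells; chamfered holes become
  stair-steps whose slope matches the requested angle to within one
  cell. Spacings that divide all feature sizes exactly (0.5, 0.25, 1/6,
  0.125 mm for the default designs) rasterize the *identical* geometry,
  which is what the grid-convergence study uses so that level-to-level
  differences measure discretization error alone.
* **Outlet behavior.** The vessel outlet is a pressure boundary with
  zero-gradient velocity; it must lie downstream of the tip
  recirculation (the default geometry provides 36 mm of clearance).

The mesh-independence procedure follows the usual incremental practice:
solve on successively finer grids (each warm-started from the previous
level), evaluate the maximum tip-region speed and average tip-region
shear rate on a fixed probe lattice, and flag the first level at which
both change by less than 0.5% from the previous level.

*What the study shows at desk scale.* On the exact-geometry sequence
0.5, 0.25, 1/6 mm (4.8k, 19.2k, 43.2k cells) the finest-pair changes
are about 1.5% in maximum tip speed and 1.3% in mean tip shear rate —
consistent with the first-order truncation of the upwind scheme. Meeting
the 0.5% criterion at this rate requires spacings near 0.1 mm (over
120k cells), beyond a sensible desk budget; the original 3D studies of
this kind use tens of millions of cells on HPC hardware. A
deferred-correction path to second-order convection is built in
(`convection_blend`), but on the separated tip flow the defect feedback
destabilizes the segregated iteration for blends much above 0.5, so the
robust first-order scheme remains the default and the study's role is
to *quantify* its discretization error rather than certify mesh
independence. Comparative conclusions between designs, which share the
same grid and the same error structure, are far less sensitive than the
absolute metrics.

## Platelet tracking

Platelets are rigid 2 um spheres, neutrally buoyant (both densities
default to 1060 kg/m$^3$; the values are configurable, and buoyancy,
Brownian motion, near-wall corrections and particle-particle interaction
are deliberately excluded — a dilute one-way-coupled model). Forces:

* **Drag**, Schiller-Naumann:
  $C_D = 24(1 + 0.15\,Re^{0.687})/Re$ for $Re \le 1000$, $0.44$ above;
  assembled as $a_D = \frac{18\mu}{\rho_p d_p^2}\frac{C_D Re}{24}(u-u_p)$,
  which reduces to Stokes drag with response time
  $\tau_p = \rho_p d_p^2/(18\mu) \approx 7\times10^{-8}$ s.
* **Shear lift**, generalized Saffman-Mei tensor form
  $a_L = 2K\nu^{1/2}\rho_f\, d_{ij}\,(u-u_p) /
  (\rho_p d_p (d:d)^{1/4})$ with $K = 2.594$; in simple shear this
  reduces exactly to the classical Saffman magnitude (coefficient
  $K\,2^{1/4} = 3.085$ per unit particle mass), which the tests verify.

Because $\tau_p$ is far below any practical time step, drag is
integrated analytically (exponential integrating-factor update per
step); the lift is frozen over each step. Steps are sized to a target
0.5 um spatial increment along the path, the standard step at which the
per-step PLI is defined. Termination is classified as exit through the
lumen outlet, exit through the vessel outlet, the 1 s residence cap, or
stagnation (speed below $10^{-6}$ of the reference speed for $10^4$
consecutive steps, e.g. after persistent wall contact).

Seeding is a uniform deterministic lattice on a plane 1 mm above the
catheter's outer surface spanning each side-hole opening (the tip
opening for a no-hole design). The count per plane defaults to 40 — a
choice balancing ensemble stability against runtime; there is no
canonical value, and the metrics reported are means, not extremes.

## Damage metrics

The per-step platelet lysis index is $A\,\Delta t^{0.77}\tau^{3.075}$
with $A = 3.31\times10^{-6}$; it is summed along each path line and the
per-design value is the arithmetic mean over lines (the per-step
average — grand sum over grand step count — is available as
`mode = "per_step"`). Note that $\sum \Delta t^{0.77}$ is sub-additive
under step refinement, so the 0.5 um step is part of the metric's
definition, not a numerical parameter to be refined away.

Platelet shear statistics (mean stress, % exposure above 10 Pa, mean
shear rate) are exposure-time weighted by default; step-count weighting
is available (`weighting = "step"`) since the two differ wherever speed
varies along the path and neither convention is canonical.

The Eulerian tip volume is a fixed rectangle spanning the lumen interior
from the distal tip 22 mm proximally (past the most proximal default
side-hole), identical across compared designs. Reported per design:
maximum speed, volume-weighted mean stress, % volume above threshold,
per-hole and tip-opening flow rates (integrated exactly over staggered
faces; hole fluxes plus the tip-opening flux reproduce the lumen outflow
to within the continuity tolerance).

## What the synthetic fixtures do and do not show

`make_analytic_field()` provides uniform, Couette, planar/tube
Poiseuille and stagnation fields with closed-form velocities, gradients
and shear rates, written in the same VTK legacy ASCII format as solver
output. Every downstream stage (interpolation, tracking, damage metrics,
report assembly) is exercised against these closed forms without any
solve. Passing those tests demonstrates correct *propagation* — that
path lines follow streamlines, that residence times, PLI sums and flux
integrals are computed exactly as defined. It does not validate the
physical fidelity of the 2D analog itself: absolute magnitudes of
stresses, residence times and PLI in a planar desk-scale domain are not
those of the 3D clinical geometry, and only directional comparisons
between designs are meaningful.

## Problem sizes

The shipped tests and the acceptance script use: channel verification at
40 cells across the gap; toy-design solves at 0.5 mm spacing (120 x 40
cells) in the test suite; a refinement sequence 0.61, 0.5, 0.25 mm
(up to 240 x 80 cells), warm-started level to level, for the
grid-sensitivity report; and tracking ensembles of up to 40 seeds. These sizes were chosen so the
full pipeline runs on a laptop-class single core in minutes while still
resolving every geometric feature by at least three cells.

## Known limitations

* The planar analog cannot represent the circumferential ("parallel")
  dual-hole arrangement; only the axial in-line pair is modeled.
* Only the inflow lumen is modeled. A return-lumen mode would need the
  thin inter-lumen septum, which cannot satisfy the three-cell
  resolution rule at desk-scale spacings.
* First-order upwind convection is robust but diffusive; quantitative
  shear metrics carry its discretization error, which is why the
  mesh-independence study is part of the pipeline rather than an
  afterthought.
* Absolute damage metrics are 2D-equivalent quantities; use them to rank
  designs, not to predict in vivo values.
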