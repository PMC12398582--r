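---
title: "A multiscale closed-loop left-ventricle model with stress-driven fiber remodeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale closed-loop left-ventricle model with stress-driven fiber remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lvfiber` simulates the human left ventricle (LV) as a closed loop of four
coupled components, and uses it to study how heterogeneous cellular
abnormalities of hypertrophic cardiomyopathy (HCM) — hypercontractile or
hypocontractile myocytes and replacement fibrosis — drive myocardial fiber
disarray:

1. an incompressible mixed finite-element (FE) model of an idealized
   ellipsoidal LV,
2. a half-sarcomere cross-bridge model producing active fiber stress at
   every quadrature point,
3. a seven-compartment Windkessel systemic circulation closing the
   hemodynamic loop, and
4. a stress-based fiber reorientation law that incrementally rotates the
   reference fiber direction toward the local traction vector.

This vignette documents the model equations as implemented, the numerical
choices, the parameters a user may want to touch, the calibration of the
package defaults, and the limitations of the scaled-down test problems.

## Circulation

Each of the six vascular compartments (aorta, arteries, arterioles,
capillaries, venules, veins) carries a blood volume $V_i$; its pressure is
$P_i = (V_i - V_{i,\mathrm{slack}})/C_i$.  Flows between adjacent
compartments follow Ohm's law $Q = \Delta P / R$, with one-way valves on
the two ventricular connections (aortic and mitral).  Volumes are updated
explicitly once per global time step with
$\dot V_i = Q_{\mathrm{in},i} - Q_{\mathrm{out},i}$, which conserves total
blood volume to round-off by construction.  The ventricular pressure is
not given by a compliance: it is the Lagrange multiplier of the
cavity-volume constraint in the FE solve, which is what couples the 3-D
model into the loop.

The R/C/slack values are package defaults chosen to put a healthy adult at
a ~120/80 mmHg arterial operating point, a venous filling pressure of
~6.6 mmHg and a total blood volume of 4.5 L; they are listed in
`default_circulation_params()`.

## Passive and active myocardium

All stresses are 2nd Piola–Kirchhoff tensors in the reference
configuration, additively decomposed as
$S = S_a + S_{\mathrm{vol}} + S_{\mathrm{bulk}} + S_{\mathrm{myofiber}}$.

* **Bulk tissue** (collagen/elastin/microvasculature): transversely
  isotropic Guccione law $\Psi = \tfrac{C}{2}(e^Q - 1)$ with
  $Q = b_{ff}E_{ff}^2 + b_{xx}(E_{ss}^2 + E_{nn}^2 + E_{sn}^2 + E_{ns}^2)
  + b_{fs}(E_{fs}^2 + E_{sf}^2 + E_{fn}^2 + E_{nf}^2)$, strain components
  in the local fiber/sheet/sheet-normal frame.  Normal myocardium uses
  $C = 200$ Pa, $b_{ff} = 8$, $b_{xx} = 3.58$, $b_{fs} = 1.63$.
* **Myofiber spring**: tension-only exponential in the fiber stretch
  $\alpha$, $\Psi = C_1 e^{C_2(\alpha-1)^2}$ for $\alpha > 1$, zero
  otherwise ($C_1 = 250$ Pa, $C_2 = 15$).  The printed energy has a
  constant offset at $\alpha = 1$; the stress uses the derivative only, so
  the offset is inert.
* **Incompressibility**: $\Psi_{\mathrm{vol}} = -p(J-1)$ with the
  hydrostatic pressure $p$ a Lagrange-multiplier field.
* **Active stress**: $S_a = F_{\mathrm{active}}\, f_0 \otimes f_0$ with the
  scalar $F_{\mathrm{active}}$ supplied by the sarcomere model.
* **Fibrous (replacement-scar) tissue** uses the isotropic row
  $C = 2720$ Pa, all exponents 4, no myofiber spring and zero cross-bridge
  density, i.e. stiffer, isotropic and non-contractile.

## Half-sarcomere contraction model

Thin-filament sites switch between unavailable ($N_{\mathrm{off}}$) and
available ($N_{\mathrm{on}}$) states with calcium-driven, cooperative
kinetics; myosin heads populate a super-relaxed state
($M_{\mathrm{SRX}}$), a disordered-relaxed state ($M_{\mathrm{DRX}}$) and
an attached force-generating population $M_{\mathrm{FG}}(x)$ resolved on a
cross-bridge strain grid of 21 bins at 1 nm spacing over $-10 \le x \le
10$ nm — 25 ODEs per integration point.  The SRX→DRX flux
$J_1 = k_1 (1 + k_{\mathrm{force}} F_{\mathrm{total}}) M_{\mathrm{SRX}}$
carries the mechanosensitive recruitment that the HCM models perturb
through $k_1$ (baseline $k_1 = 3.7\,\mathrm{s}^{-1}$).  Attachment is
distributed over the strain grid with Boltzmann weights
$e^{-k_{cb}x^2/2k_BT}$ normalized so the summed flux equals the attachment
rate density integrated over the grid; detachment is strain-dependent
through $k_{4,0} + k_{4,1}x^4$.  Active stress is the first moment
$F_{\mathrm{active}} = N_0 k_{cb} \sum_i M_{FG,i}(x_i + x_{ps})$ with the
cross-bridge density $N_0 = 6.96\times10^{16}\,\mathrm{m}^{-2}$.

Numerics: within each global step the 25-ODE system is integrated with
midpoint (RK2) sub-steps of 0.1 ms; filament sliding advects the attached
population along the strain grid by $-\Delta \mathrm{hsl}$ (mass-conserving
linear interpolation; mass advected past the grid ends is forcibly
detached into DRX).  Half-sarcomere length couples to the continuum
through $\mathrm{hsl} = \mathrm{hsl}_{\mathrm{ref}}\,\alpha$ with
$\mathrm{hsl}_{\mathrm{ref}} = 950$ nm; the overlap function defaults to 1.
$F_{\mathrm{total}}$ for the recruitment flux is the myofiber passive plus
active stress along $f_0$, clamped at zero from below.  Conservation of
the thin-filament and myosin sums is enforced to $10^{-8}$ per step — a
violation is an error, never a silent clamp.

The calcium transient is a two-compartment model: a stimulus gate opens
for 20 ms once per 937 ms cycle and releases sarcoplasmic-reticulum
calcium into the myoplasm; first-order re-uptake and a constant leak
return it.  Because the gated system is piecewise linear, the periodic
steady state has a closed form (`calcium_transient()`), with a diastolic
baseline of $10^{-7}$ M and a peak of $\sim 1.9\times10^{-6}$ M.

### Default rate constants and the contractile reserve

The sarcomere and circulation rate constants are model-configuration
choices rather than universal constants, so the package carries its own
defaults, chosen once so that the **baseline** coupled model
reproduces a healthy adult: EDV ≈ 123 mL, ESV ≈ 54 mL, EF ≈ 56%, peak
systolic pressure ≈ 120 mmHg at 64 bpm.  Two structural choices matter
beyond the operating point:

* the twitch must be long enough to sustain ~300 ms of ejection
  (release/uptake rates 200 and 7.5 s⁻¹), and
* the force-dependent recruitment is deep
  ($k_{\mathrm{force}} = 2.5\times10^{-3}\,\mathrm{Pa}^{-1}$), so that at
  systolic stress most of the SRX pool is already mobilized.  This
  saturation is what gives the modest contractile reserve reported for
  the reference model (a 100% increase of $k_1$ in 30% of the wall shifts
  EF by only a few points); with shallow recruitment the same perturbation
  would implausibly shift EF by ~15 points.

## Finite-element ventricle

The wall is a truncated half-ellipsoid (base plane $z = 0$, apex toward
$-z$): outer base-to-apex length 7.3 cm, outer basal diameter 7.2 cm,
basal wall thickness 1.3 cm, apical thickness half of basal.  The enclosed
unloaded cavity volume of this geometry is 73.7 mL (≈75 mL).  The
structured parametric mesh uses quadratic (P2) tetrahedra with midside
nodes placed by parametric midpoints, so surface nodes lie exactly on the
bounding ellipsoids; presets are `mini` (~90 elements), `coarse` (~170)
and `paper` (~1250).  The parametric transmural coordinate $t \in [0,1]$
is carried on every node; for this geometry family it is the monotone
wall-normal coordinate that a Laplace–Dirichlet solve between the tagged
surfaces would produce, and it feeds the fiber rule directly.

Fibers follow the linear transmural helix rule $60° \to -60°$ (endo to
epi) with zero transverse angle, built in the local
circumferential/longitudinal/radial basis derived from $\nabla t$ and the
long axis.  The basis is singular on the axis at the apex; quadrature
points within a small polar cap inherit the nearest well-defined basis.

Unknowns: quadratic displacement $u$, linear pressure $p$ (Taylor–Hood),
the cavity-pressure multiplier $P_{LV}$ enforcing
$V_{LV}(u) = V_{LV}^{\mathrm{target}}$ through the endocardial surface
integral $V = -\tfrac13 \oint x \cdot n\, da$, and three scalar
multipliers removing in-plane rigid translation and rotation about the
long axis.  The basal plane carries $u \cdot n = 0$.  Quadrature is a
degree-4 14-point rule per tetrahedron; all cross-bridge state lives at
these integration points.

Numerical choices that deserve explanation:

* **Augmented-Lagrangian volumetric penalty.**  The linear multiplier
  space enforces incompressibility only element-mean-wise; on coarse
  meshes the pointwise $J$ can oscillate by tens of percent under strong
  active stress.  A penalty modulus of $10^6$ Pa on $(J-1)^2$ is added on
  top of the exact multiplier: the weak constraint stays exactly
  satisfied, and pointwise $|J - 1|$ stays within a few percent.
* **Viscous wall damping.**  The mechanics is integrated with a backward-
  Euler rate term $c\,\dot u$ ($c = 10^5\,\mathrm{N\,s\,m^{-4}}$,
  consistent mass matrix).  Physically this is a small tissue viscosity;
  numerically it regularizes fold points that the quasi-static path of a
  coarse mesh would otherwise hit during rapid force development, and it
  renders the displacement block positive definite.  At the pressures and
  rates of the cardiac cycle its effect on the PV loop is at the sub-mmHg
  level.
* **Newton solver.**  Damped quasi-Newton with the natural
  (affine-invariant) monotonicity test and lazy refactorization: the
  factorized tangent of a nearby state is reused while it contracts, and
  rebuilt otherwise.  The four dense constraint borders are eliminated by
  a small Schur complement around the sparse displacement block
  (supernodal Cholesky with reused symbolic analysis; sparse-LU fallback
  when the block is locally indefinite).  Convergence requires the
  residual to drop to $10^{-4}$ relative (configurable; quasi-static
  analyses use $10^{-9}$) *and* the cavity volume to match its target to
  $10^{-3}$ mL.  Large activation increments fall back to recursive
  bisection of the load (`solve_mechanics_ramp`).
* **Staggered coupling**, once per global step: calcium → cross-bridge
  ODEs (strain and total fiber stress lagged one step) → circulation
  volume update (previous $P_{LV}$) → mechanics solve at the new target
  volume → fiber reorientation.  The global step is 1 ms at protocol
  fidelity; the scaled-down test problems use 5–7.5 ms, which the damped
  formulation tolerates.

## Fiber reorientation

At every integration point the reference fiber direction relaxes toward
the traction direction of the *total* (active + passive) stress:
$\dot f_0 = \kappa^{-1}(S f_0 / \lVert S f_0\rVert - f_0)$, with
$\kappa = 4000$ ms, applied as one explicit step per global time step (a
$dt/\kappa = 2.5\times10^{-4}$ blending fraction at 1 ms) followed by
renormalization.  Fibers are axial (headless) objects: the traction is
taken as $\sigma S f_0$ with $\sigma = \mathrm{sign}(f_0 \cdot S f_0)$,
which makes the update invariant under $f_0 \to -f_0$.  Unloaded points
($\lVert S f_0\rVert$ below $10^{-12}$ of the stress scale) are skipped.
After each update the sheet vector is re-orthogonalized continuously and
the sheet-normal closes the right-handed triad.  Protocol: rule-based
initialization, a hemodynamic run-in with fibers frozen, then remodeling
for the remainder of the run.  $\kappa$ is a numerical time-scale
separator, not a biological rate; in scaled-down runs the remodeling dose
$T_{\mathrm{remodel}}/\kappa$ is preserved by scaling $\kappa$ down with
the simulated duration.

## HCM perturbations

`generate_regions()` seeds spherical foci (diameter ≥ a minimum size;
presets 3 / 2.5 / 2 mm for Distributions 1–3) with centres uniform in the
wall volume and radii uniform in [min/2, 1.5·min/2], accepting foci until
the quadrature-weighted perturbed volume fraction reaches 30% ± 2%.  No
transmural preference is applied.  Labels are a pure function of
(mesh, spec, seed).  Perturbed points then receive either a scaled
$k_1$ — ±20/60/100% for the hyper/hypocontractile models — or the fibrous
material row.

## Metrics

Pumping metrics come from the last complete cycle (EDV = max volume,
ESV = min, SV, EF, peak pressure).  Fiber disarray is quantified by the
helical and transverse angles in the local wall basis and their **angular
deviation** (AD): the quadrature-weighted standard deviation over the
epicardial ($t \ge 0.8$) or endocardial ($t \le 0.2$) 20%-thickness layer,
using the sample (n−1) convention.  The 3-D reorientation angle between
initial and final fiber fields uses the axial convention
$\arccos|f_i \cdot f_f| \in [0°, 90°]$.  Systolic strain uses the
multiplicative decomposition $F_{\mathrm{sys}} = F_{ES}F_{ED}^{-1}$ and
reports Lagrangian strain relative to end-diastole projected on the wall
directions.  Variability across the three focus-size distributions is
summarized by the coefficient of variation (sample SD over mean).

## What the scaled-down problems do and do not show

The reference protocol is 211 cycles of 937 ms at 1 ms steps on the
~1250-element mesh — hours of compute.  The package's test problems run
the same code on the ~90-element mesh with 7.5 ms steps in two families:

* a **fibers-frozen baseline run** (one run-in cycle, one measured cycle)
  for the healthy operating point — at the scaled remodeling dose an
  active reorientation during the single measured cycle would contaminate
  the calibrated baseline; and
* **remodeling runs** (same protocol with reorientation over the second
  cycle, $\kappa = 200$ ms, i.e. a remodeling dose
  $T_{\mathrm{remodel}}/\kappa \approx 4.7$) for the perturbed models'
  PV metrics — the reference protocol reports the final remodeling
  cycle — and for all fiber-disarray metrics.

What these scaled problems reproduce: the healthy operating point, the
direction of every PV-loop change under the three perturbations (and the
magnitude for the fibrous model), disarray clearly above baseline in all
perturbed models, the near-linear AD–$k_1$ trend, and the epicardial
dominance of disarray in the fibrous model.  What they do not: the
*magnitudes* of the contractility-model PV shifts come out stronger than
the reference values — with the recruitment depth of the package defaults
the contractile reserve is larger than the reference model's (see the
ledgered analysis of $k_{\mathrm{force}}$); and the epicardial-over-
endocardial disarray ordering of the contractility models only emerges at
remodeling doses and resolutions beyond desk scale — at this fidelity the
hyper/hypocontractile models remodel predominantly near the endocardium.
Transmural stress profiles at publication resolution, converged disarray
magnitudes, and beat-to-beat convergence over hundreds of cycles are all
beyond the scaled problems; mesh sensitivity of the full model is out of
scope.

## Known limitations

* No volumetric growth; fibrosis is imposed, not grown.
* The calcium model and the circulation/sarcomere constants are package
  defaults calibrated to a generic healthy adult; clinical conclusions
  should re-derive them against data.
* The viscous damping and volumetric penalty are numerical stabilizers
  whose constants were fixed once; very different material regimes may
  need different values.
* Quasi-static mechanics: no inertia, no pericardium, single chamber.
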