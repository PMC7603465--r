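---
title: "A multiscale hypoelastic model of arterial tension-inflation mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale hypoelastic model of arterial tension-inflation mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arterymech)
```

## The problem

Arterial tissue stiffens dramatically and anisotropically as it is loaded,
and most of that behavior is set by the adventitial collagen network: wavy
(crimped) fiber bundles that straighten ("recruit") under load and rotate
toward the loading direction. Phenomenological strain-energy models
reproduce the stress-stretch curves but their parameters have no direct
histological meaning, so they cannot say how a change in collagen content or
crimp morphology — the kind of change seen in connective-tissue disorders —
alters the mechanical response. `arterymech` implements a structural
alternative: every constitutive parameter is a measurable histological or
mechanical quantity (fiber volume fraction, crimp amplitude and period,
fiber radius and modulus, layer thicknesses), and both fiber de-crimping and
*non-affine* fiber rotation emerge from micromechanics rather than being
prescribed.

The package simulates tension-inflation tests on a two-layer hollow cylinder
(media + adventitia) and reports the evolving fiber orientation, the
macroscopic kinematics (diameter, stress, tangent stiffness) and
per-constituent stresses.

## The constitutive model

### Macroscopic balance and hypoelasticity

The structure obeys quasi-static equilibrium with a rate-form
(hypoelastic) constitutive law: the Cauchy stress rate is a linear function
of the Eulerian strain rate through an evolving tangent,
`T_dot = C(x, t) : D`. The medial layer uses a constant isotropic tangent
(`E_M = 0.12` MPa, `nu_M = 0.49`). The adventitial tangent is rebuilt at
every material point after every increment from the current microstructure.

### The adventitial representative volume element

Each adventitial point carries a representative volume element (RVE): an
isotropic soft matrix (ground substance plus elastin, `E_m = 10` kPa,
`nu_m = 0.4`) reinforced by `n` discrete families of infinitely long
cylindrical collagen fibers (default four families, at equal volume-fraction
shares of the total collagen fraction `f_c`). Families are oriented by two
Euler angles (`phi`, `theta`) relative to the local
circumferential/axial/radial frame `(K, T, N)`; `theta = 0` is the axial
direction.

Phase strain rates and spins are estimated by Mori-Tanaka mean-field
homogenization built on the interior Eshelby solution of the infinite
circular cylinder:

* strain-rate concentration: `d_i = A_i : D`, with
  `A_i = A_i_dil : (f_m I + sum_j f_j A_j_dil)^-1` and
  `A_i_dil = [I + S : C_m^-1 : (C_i - C_m)]^-1` (`S` the cylinder Eshelby
  tensor, computed in closed form and cross-checked in the tests against a
  numerical integration of the interior Hill operator);
* spin concentration: the antisymmetric part of the same interior operator
  gives, for a cylinder with axis `c`,
  `omega_i = (1/4 mu_m) [ (c o c) tau_i - tau_i (c o c) ]` with the
  polarization `tau_i = (C_m - C_i) : A_i : D`. This closed form has two
  independent checks in the test suite: for an axial-transverse eigenshear
  the interior displacement gradient of an infinite cylinder must satisfy
  `u_{1,3} = 0` (fields cannot vary along the axis), and in the rigid-fiber
  limit the spin must reach the affine (Jeffery needle) rotation of a
  material line.

Each phase is hypoelastic with a Jaumann (corotational) stress rate, so the
phase stress update contains the convection terms `omega t - t omega`, and
the homogenized tangent assembled from the concentration tensors inherits
spin-convection contributions proportional to the current phase stresses.
At zero phase stress it reduces to `sum_r f_r C_r : A_r` and is then majorly
symmetric; under load it is not, and the solver treats it as a general
(minor-symmetric) operator. The matrix spin is set by the spin average rule
(volume-averaged spin equals the macroscopic spin of the RVE loading, which
is zero under the pure strain-rate boundary condition used here).

### Crimped-fiber recruitment

Within a family, collagen is a planar sinusoidal beam: centerline
`g(s) = h sin(s/ell)` over one period `s in [0, 2 pi ell]`, circular cross
section of radius `r_c`, slope `alpha(s) = (h/ell) cos(s/ell)` (small-slope
beam convention, alpha in radians). Its apparent axial stiffness is the
*chord modulus*

```
E_c = E_f * I <cos a> / ( I <cos^2 a> + A <g^2> ),   A = pi r_c^2,  I = pi r_c^4 / 4
```

with `< >` the curvilinear average along the centerline (arc-length measure
by default; a flat-measure variant, in which the classical Bessel-function
closed forms `<cos a> = J0(h/ell)`, `<cos^2 a> = (1 + J0(2h/ell))/2`,
`<g^2> = h^2/2` are exact, is available for sensitivity checks — the two
measures differ by about 1% at `h/ell = 0.3`). For the reference geometry
(`h = 0.2 ell`, `r_c = 0.04 ell`) the initial chord modulus is about 2% of
the straight-fiber modulus: crimped collagen is bending-dominated and
contributes little until it straightens.

The evolution of the crimp under load is not uniquely fixed by the
quantities above, so the package adopts the simplest kinematic law
consistent with them: the accumulated along-the-chord strain
`eps (increments c . d_i . c)` stretches the period affinely,
`ell = ell0 (1 + eps)`, and the amplitude `h` follows from conservation of
the centerline arc length (an inextensible centerline). When the chord
reaches the initial arc length the fiber is fully recruited: `h = 0`,
`E_c = E_f`, and recruitment is sticky thereafter. This reproduces the two
features the case studies rely on — monotone stiffening with a sharp
plateau, and incomplete recruitment for large initial crimp
(`h0 = 0.3 ell0` fibers are still undulated at stretch 1.6). For the
reference crimp (`h0 = 0.2 ell0`) full recruitment occurs at a chord strain
of about 1%. The law is tabulated once per configuration on a grid
concentrated near the recruitment strain and evaluated by monotone cubic
splines; the finite-element core and the single-point driver share this
code path exactly.

### Frame kinematics

Fiber triads evolve by the explicit normalized update
`a <- (a + (d_i + omega_i) a) / || a + (d_i + omega_i) a ||` applied to each
triad vector independently, with no re-orthogonalization — the model's
explicit normalized update is kept as is, and the accumulated pairwise
orthogonality drift is monitored (warned about beyond 1e-3 per run; in the
bundled case studies it stays at the few-1e-3 level, which perturbs the
reported angles by well under a degree). The local `(K, T, N)` frame is
convected with the incremental deformation gradient: `K` is transported and
normalized, the transported (un-orthogonalized) axial direction is carried
along and Gram-Schmidt-projected to give `T`, and `N = K x T`.

Euler angles are extracted by inverting the triad construction:
`theta = acos(c_N . K)`, `phi = acos(c_perp . T)` with the quadrant branch
taken from the sign of `sin(phi) = -(c_perp . N)`. (The triad definition
fixes these dot products uniquely; the inversion round-trips to 1e-8 over
the full angle range, which the tests sweep.) Reported angles are mapped to
`[0, 90]` degrees from the axial direction.

One interpretation was needed: the incremental loading of the RVE is stated
in terms of the ratio of the incremental deformation gradient to the time
step, which is dimensionally a velocity gradient only after subtracting the
identity. The package therefore uses `L = dF - I` per unit increment, with
`D = sym(L)` driving the RVE. This reading is isolated in a single
function (`velocity_gradient_increment`).

## The finite-element scheme

Space is discretized with full-integration (2x2x2) eight-node hexahedra on
a structured mesh of the two-layer cylinder; the default target edge length
is one twelfth of the outer radius with at least three elements through the
media and two through the adventitia, all overridable for desk-scale runs.
Time is discretized in load increments (default 5 mmHg in pressure, 0.03 in
stretch) under the quasi-static convention of one unit time step per
increment, so rates and increments coincide.

Each increment is solved in a staggered way. The constitutive tangent is
frozen at its start-of-increment value; the incremental displacement is
converged by Newton iterations on the force balance between the follower
pressure (integrated on the trial deformed inner surface) and the internal
force of the trial stress `T_n + C_n : D(dU)` (strain increment measured on
the start geometry). The Jacobian is assembled consistently with that
residual — material block `B_trial' C_n B_0`, the exact geometry-variation
term of the stress divergence, and the follower-load stiffness — and was
verified against finite differences to machine precision. Stretch
increments start from an affine axial ramp as the initial guess. A
backtracking line search guards the iterations, and an increment that still
fails to reach a 1% force balance is redone as two half-increments
(recursively, four levels deep). Setting `max_iter = 1` recovers a single
linear solve per increment — the textbook explicit variant — at the price
of equilibrium drift. After convergence, every Gauss point performs the
staggered microstructural update: macroscopic stress update with the frozen
tangent and the whole increment, local-frame convection, then the internal
variables — phase strain rates and spins, Jaumann-convected phase stress
updates, fiber-frame evolution, chord-strain increments and crimp update —
integrated over `micro_substeps` (default 4) sub-increments of the strain
increment with the concentration tensors rebuilt in between, then angle
extraction and the rebuild of the homogenized tangent for the next
increment. The sub-incrementation refines only the internal-variable
integration (the load-step sizes and the solve are untouched); it is what
brings the load-step sensitivity of the results below the 1% level that
the step-size choice is meant to guarantee — with a single sub-step the
halving test below gives about 2% instead of 0.5%, driven by recruitment
switching inside large steps. The element assembly and the Mori-Tanaka
rebuild run in compiled code (`src/`); the compiled rebuild agrees with the
reference R implementation of the concentration tensors to machine
precision, which the tests assert.

The macroscopic stress update deliberately omits a macroscopic corotational
correction (the microscale Jaumann terms enter through the homogenized
tangent instead); the resulting rigid-rotation error is second order in the
increment size and is controlled by the load-step sizes, which the
refinement experiment (`run_p_test` at halved steps) quantifies at well
under 1% on the final radius. In the bundled protocols the principal
directions barely rotate (inflation and extension of a straight tube), so
the omission is immaterial there.

Boundary conditions: the left cross-section is fully clamped; the right
cross-section is a rigid grip — the full displacement vector is prescribed,
with the axial component ramped and the lateral components held at zero
(options for a free or axial-only grip exist). The grip constraint matters
numerically as well: with only the axial component prescribed, the
near-zero-torsion-stiffness twist mode of the soft wall combined with the
non-conservative follower pressure renders the tangent indefinite.

Near-incompressibility of the media (`nu_M = 0.49`) with full integration
implies some volumetric locking on coarse meshes; a mean-dilatation (B-bar)
variant is available behind the `bbar` configuration flag, off by default.
Pressures are entered in mmHg (1 mmHg = 133.322 Pa) and converted to MPa
internally; lengths are in mm, moduli in MPa, reported stresses in kPa.

## Case studies and readouts

`generate_fixture()` returns the two reference parameter sets (the
tension-test and inflation-test columns: geometry, layer thicknesses,
collagen fraction, family angles, crimp geometry and moduli) plus a
desk-scale `tiny` variant. `run_s_test()` ramps pressure then stretch;
`run_p_test()` ramps stretch then pressure; `run_disorder_sweep()` varies
`f_c` or `h0` under the tension protocol (20 mmHg, stretch to 1.6);
`shear_stiffness_series()` tracks the axial-circumferential shear component
of the adventitial tangent. All summaries are averaged over the central
region — elements whose centroid lies in the axial span of length L/4 at
mid-length — to avoid the clamped-end boundary layers, and are returned as
tibbles (one row per increment) with `tidy()`, `glance()` and `autoplot()`
methods.

Two reading conventions were fixed where the readouts are not uniquely
defined: the "axial stiffness of the tissue" is the incremental tangent
`d sigma_TT / d lambda` of the central-region-averaged axial Cauchy stress,
computed by finite differences along the stretch-controlled part of a
series; the "fiber stress" is the along-fiber component `c . t_i . c` of
the collagen-phase Cauchy stress, volume-weighted over all families. The
phase average is used (rather than the main +/-60-degree pair alone)
because under axial stretching the near-axial families carry an order of
magnitude more stress than the steep pair and dominate any phase-level
measurement; a von-Mises variant would be a one-line change and is
deliberately not exposed.

## What the desk-scale runs do and do not show

The bundled tests and the acceptance script run on coarsened meshes (6-12
circumferential, 4-8 axial, 3-5 radial divisions; 72-480 elements — the
collagen-fraction sweep uses the finest of these, where its readouts are
close to mesh-converged) with the reference load-step sizes, completing a
full protocol in one to a few minutes. At this resolution the hoop direction is resolved by a polygon
(about 1-3% surface-area error), the clamped-end boundary layers span a
larger fraction of the length than at the default mesh, and medial locking
slightly stiffens the radial response. Ratio- and trend-type readouts (fold
changes between configurations, reorientation orderings, monotonicity of
the shear stiffness, step-refinement differences) are robust to this;
absolute diameters and stresses shift by a few percent relative to the
default mesh (the refinement spot-check in the tests bounds the shift at
one load level). The Lame thick-cylinder verification runs on a finer
radial discretization (6 radial divisions, 16 circumferential) in the
linear regime, where the hoop-stress profile is reproduced within 3%.

## Known limitations

* No residual stresses or opening angle: the unloaded configuration is
  stress-free.
* The media is homogeneous and isotropic; its lamellar microstructure is
  not modeled.
* No damage, viscosity or active (smooth muscle) response; loading is
  quasi-static and rate-independent.
* Fiber orientation is represented by discrete families, not a continuous
  distribution; crimp is planar-sinusoidal, not helical.
* The de-crimping evolution law (inextensible centerline, affine period
  stretch) is the package's own closure of an under-determined model
  component; alternatives (e.g. force-balance-driven period evolution)
  would change the recruitment sharpness but not the plateau.
* Full recruitment is a hard switch at `h = 0`; a family-level waviness
  distribution would smooth it.
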