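# arterymech

Multiscale hypoelastic finite-element simulation of arterial
tension-inflation tests.

## The problem

The passive mechanics of an artery is set by its microstructure: the outer
layer (adventitia) is a soft ground-substance matrix reinforced by wavy
(crimped) collagen fiber bundles that straighten under load and rotate —
*non-affinely*, i.e. not simply following the macroscopic deformation —
toward the loading direction. Models whose parameters are directly
measurable histological quantities make it possible to ask how a change in
collagen content or crimp morphology (as in collagen-related disorders)
changes the mechanical response of the vessel. `arterymech` is such a
model, for researchers in vascular biomechanics: a structural constitutive
description embedded in a nonlinear finite-element solver for
tension-inflation testing of arterial segments.

## The model

A two-layer hollow cylinder (media + adventitia) is loaded by an inner
follower pressure and an axial grip displacement under quasi-static,
rate-independent hypoelasticity, `T_dot = C : D`.

* **Media**: homogeneous isotropic tangent (E_M, nu_M).
* **Adventitia**: every material point carries a representative volume
  element — an isotropic matrix with n discrete families of infinitely long
  cylindrical collagen fibers. Mori–Tanaka mean-field homogenization on the
  interior Eshelby solution of the circular cylinder gives per-family
  strain-rate and spin concentration tensors

      d_i = A_i : D,   omega_i = R_i : D,
      A_i = A_i_dil [ f_m I + sum_j f_j A_j_dil ]^-1,
      A_i_dil = [ I + S : C_m^-1 : (C_i - C_m) ]^-1,

  with the spin built from the antisymmetric interior operator of the
  cylinder, `omega_i = (1/4 mu_m)[(c⊗c) tau_i - tau_i (c⊗c)]`,
  `tau_i = (C_m - C_i) : A_i : D`. Phase stresses follow Jaumann-rate
  hypoelasticity; the homogenized tangent inherits the spin-convection
  terms.
* **Collagen recruitment**: each family is a sinusoidal crimped beam
  (amplitude h, period parameter ell, radius r_c) with chord modulus

      E_c = E_f I <cos a> / ( I <cos^2 a> + A <g^2> ),

  `< >` the curvilinear average along the centerline. The accumulated
  along-the-chord strain stretches the period affinely and the amplitude
  follows from arc-length conservation (inextensible centerline); at full
  straightening `E_c = E_f`.
* **Kinematics**: fiber triads evolve by the explicit normalized update
  `a <- (a + (d_i + omega_i) a)/||...||`; the local
  circumferential/axial/radial frame is convected with the incremental
  deformation gradient; Euler angles are extracted by inverting the triad
  construction.
* **Solver**: explicit incremental (staggered) scheme on full-integration
  hex8 meshes — the constitutive tangent is frozen over each load increment
  (default 5 mmHg / 0.03 stretch), the incremental displacement is
  converged by Newton iterations with a consistent Jacobian and follower
  pressure on the deformed inner surface, and the microstructure at every
  Gauss point is advanced once per increment (with sub-incremental
  integration of the internal variables).

See the methods vignette (`vignettes/arterial-multiscale-model.Rmd`) for
the full account, including every numerical choice.

## Worked example

A desk-scale tension test at constant 20 mmHg (coarse mesh, reference
parameter set of the tension protocol):

```r
library(arterymech)
cfg <- coarsen(generate_fixture("s_test"))     # 8x6x3-division mesh
ser <- run_s_test(cfg, pressure = 20, stretch_max = 1.6)
subset(tidy(ser), increment %in% c(0, 4, 10, 16, 24),
       select = c(phase, P_mmHg, lambda, rel_diameter, theta1_deg,
                  axial_stress_kPa, fiber_stress_kPa))
glance(ser)
```

```
#>      phase P_mmHg lambda rel_diameter theta1_deg axial_stress_kPa fiber_stress_kPa
#> 1  initial      0   1.00       1.0000      60.00            0.000              0.0
#> 2 pressure     20   1.00       1.0513      61.50            4.441            547.1
#> 3  stretch     20   1.18       0.9758      54.09          216.868           5014.6
#> 4  stretch     20   1.36       0.8829      45.96          457.490           9710.8
#> 5  stretch     20   1.60       0.7454      34.64          795.580          16482.3
#>
#> # A tibble: 1 x 7
#>   increments P_mmHg lambda mean_radius rel_diameter theta1_deg axial_stress_kPa
#> 1         24     20    1.6       0.760        0.745       34.6             796.
```

Reading: the 20 mmHg pressure ramp dilates the central region by ~5% and
recruits the hoop-leaning fibers (the collagen-phase stress jumps to
~0.55 MPa while the tissue-level axial stress is still ~4 kPa); the
stretch phase then thins the tube (relative diameter falls to 0.75),
rotates the main collagen family from 60 degrees toward the axis
(34.6 degrees at stretch 1.6) and stiffens the wall — the axial tissue
stress reaches ~0.8 MPa with the collagen phase near 16 MPa.
`theta1_deg` is the central-region average angle of the first family
measured from the axial direction; stresses are central-region Cauchy
averages; `fiber_stress_kPa` is the volume-weighted along-fiber stress of
the whole collagen phase.

`autoplot(ser)` plots any summary column against the increment;
`write_series_csv()` and `write_vtk()` export the summary table and the
deformed fields. A command-line front end is installed as `artery-sim`
(see `exec/artery-sim`).

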