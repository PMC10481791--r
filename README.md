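# coremag

Charge-based boundary-element magnetostatics for transcranial magnetic
stimulation (TMS) coils with magnetic cores.

Magnetic cores can focus the stimulation field and cut the energy a TMS
device needs, but they magnetize nonlinearly and saturate at typical TMS
field strengths. Predicting what a given core does to the coil — the induced
electric field that actually stimulates tissue, and the coil inductance that
sets the pulse dynamics — requires solving a nonlinear magnetostatic problem
for the coil–core pair. `coremag` solves that problem for coil designers and
TMS modelers: the coil–core combination is solved once, and the resulting
magnetization and charges then give fields anywhere, for any current rate,
with the assembly moved or rotated at will.

## The model

* **Coils** are wire grids of short straight filaments carrying fractional
  currents (Litz-wire uniform-current model, optional bundle twist). Free
  space fields come from Biot–Savart sums,
  `B^p(r) = (mu0/4pi) * sum_m I0 w_m s_m x (r - r_m)/|r - r_m|^3`,
  the induced electric field from the quasistatic relation
  `E = -(dI/dt) A(r)/I0`, and the free-space inductance `L^p` from the
  Neumann double filament sum with the singular `m = n` terms omitted.
* **Cores** are tetrahedral meshes. On *every* face — boundary and inner — a
  fictitious magnetic surface-charge density `rho_s` (units T) represents
  the magnetized material. It satisfies a Fredholm second-kind equation

  ```
  rho(r)/2 - K(r) n(r) . (1/4pi) int (r - r')/|r - r'|^3 rho(r') dS' = K(r) n(r) . B^p(r)
  ```

  with the permeability contrast `K = (mu+ - mu-)/(mu+ + mu-)` across each
  face (`mu- = mu0` on the boundary), solved matrix-free with GMRES over a
  precomputed dense influence operator with analytic near-field triangle
  integrals.
* **Nonlinearity**: each tet carries `mu_r(|H|)` from an anhysteretic B–H
  curve — an arctangent model `mu0 mu_r = a1 atan(a2|H|)/|H| + mu0` or
  Froelich's equation `mu0 mu_r = 1/(a1 + a2|H|) + mu0` — and the solver
  iterates field evaluation, permeability update (with optional neighbor
  smoothing), contrast update and charge re-solve (successive substitution)
  until the relative deviations `e1` (charges) and `e2` (permeabilities)
  are small.
* **Outputs**: per-tet magnetization `M = chi(|H|) H`, the core inductance
  correction `L^s = 2U^s/I0^2` with `U^s = 1/2 int M . B^p dV`, the total
  induced electric field `E = -(dI/dt)[A^p + A^s]/I0`, and exterior
  secondary fields from the stored charges.

## Worked example

A solid cylindrical core (radius 15 mm, height 40 mm) sits inside a
one-turn Litz loop (radius 30 mm) driven at 20 kA — strong enough to
saturate the generic high-saturation material #1:

```r
library(coremag)

cfg <- make_fixture("loop_cylinder")    # coil + core + material #1 + 20 kA
rep <- run_solve(cfg)
rep$summary
#> # A tibble: 1 x 12
#>   kind      n_faces n_tets    I0     L_p     L_s L_total mean_mu_r iterations       e1      e2 converged
#>   <chr>       <int>  <int> <dbl>   <dbl>   <dbl>   <dbl>     <dbl>      <int>    <dbl>   <dbl> <lgl>
#> 1 nonlinear    1440    648 20000 9.36e-8 4.83e-8 1.42e-7      19.1          9 0.000726 0.00299 TRUE
```

The core has saturated: its average relative permeability has collapsed
from the small-signal value 634 to about 19, and it adds `L_s = 48 nH` to
the 94 nH free-space inductance. At 1 mA the same config reports
`mean_mu_r = 634` and a larger `L_s` — the saturation trend a designer
cares about. The induced electric field at any probe point and current
rate follows without re-solving:

```r
total_E(rep$solution, c(0, 0, 0.05), dIdt = 1e8)
#> # A tibble: 1 x 6
#>       x     y     z    Ex     Ey       Ez
#> 1     0     0  0.05 0.304 -0.304 7.35e-17
```

Material curves are available as presets (`preset_material(1:3)`), from
coefficients (`bh_curve("froelich", a1 = 80, a2 = 0.82)`), or fitted to
datasheet hysteresis-locus points (`fit_bh_curve()`). `autoplot()` shows a
curve or a solve's convergence history; `tidy()`/`glance()` give per-tet
and one-row summaries.

A thin command-line front end is installed with the package
(`system.file("cli", "coremag", package = "coremag")`) with verbs `solve`,
`inductance`, `probe`, `fixtures` and `material-info` over YAML configs.

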