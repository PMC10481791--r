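---
title: "Modeling TMS coils with magnetic cores: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling TMS coils with magnetic cores: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(coremag)
```

# The physical problem

A TMS coil drives a pulsed current $I(t)$ through a winding; in the
quasistatic regime the current separates as
$\mathbf{j}(\mathbf{r},t) = I(t)\,\mathbf{j}(\mathbf{r})$ and the induced
electric field — the dosimetric quantity — is
$\mathbf{E} = -\frac{dI}{dt}\,\mathbf{A}(\mathbf{r})/I_0$ with
$\mathbf{A}$ the magnetic vector potential at unit terminal current. A soft
magnetic core inside the winding magnetizes, adds a secondary potential
$\mathbf{A}^s$, reshapes $\mathbf{E}$, and raises the coil inductance
$L$ (which in turn slows the pulse). Because TMS flux densities reach the
tesla range, the core operates on the nonlinear part of its magnetization
curve and may saturate, so both effects are current-dependent.

`coremag` solves the coil–core magnetostatic problem once, stores the core
magnetization $\mathbf{M}$ and the fictitious magnetic surface charges, and
evaluates fields afterwards for any probe points, any current rate, and any
rigid placement of the assembly.

# The solver

## Primary coil fields

Conductors are replaced by a *wire grid*: short straight filaments with
fractional current weights. A Litz conductor of $n$ strands becomes $n$
parallel filament paths of weight $1/n$ filling the cross-section on
concentric rings (annulus-area-proportional counts), optionally twisted
about the bundle axis with a given twist pitch. Per segment the package
uses the midpoint (point-moment) rule; the loop field at the center of a
512-segment circle is within 0.1% of $\mu_0 I/2R$, and refinement is
controlled by the segments-per-turn parameter (default 64). The free-space
inductance is the Neumann double filament sum with the $m=n$ terms set to
zero; it converges only when the conductor cross-section is filled with
filaments (an infinitely thin loop diverges logarithmically with segment
count, and the package warns in that case). The filament-bundle loop
(R = 10 mm, a = 1 mm, 37 filaments) reproduces the uniform-current
thick-loop formula $\mu_0 R(\ln(8R/a) - 1.75)$ within ~1%.

## The surface-charge equation on all faces

The core is a tetrahedral mesh with constant permeability per tet. Every
face — inner and boundary — carries a magnetic surface-charge density
$\rho_s$ (units T) so that the secondary field is the single-layer
gradient
$\mathbf{H}^s(\mathbf{r}) = \frac{1}{4\pi\mu_0}\int \rho_s(\mathbf{r}')
\frac{\mathbf{r}-\mathbf{r}'}{|\mathbf{r}-\mathbf{r}'|^3}\,dS'$.
Enforcing continuity of the normal flux across each face yields the
second-kind equation with the differential contrast
$K = (\mu^+-\mu^-)/(\mu^++\mu^-)$ of the two adjacent tets ($\mu^-=\mu_0$
on the boundary). Faces are oriented from an (arbitrarily chosen) plus tet
to its minus tet — the package uses the lower tet index, and the solution
is invariant under relabeling (tested).

Discretization is piecewise-constant collocation at face centers. The
influence operator is assembled once as a dense matrix: sources within 3
face-radii of an observation point use closed-form constant-density
triangle integrals (in-plane edge-log terms plus the signed solid angle via
van Oosterom–Strackee; the observation point on the face plane yields the
principal value, so the self entry has no normal component), farther
sources use the one-point centroid rule. The linear systems are solved
with a matrix-free GMRES (no restart, relative tolerance $10^{-8}$, max
300 iterations) — second-kind systems with $|K| \le 1$ converge in
typically 10–20 iterations, and nonlinear steps warm-start from the
previous charges.

## Successive substitution

For a field-dependent curve the solver loops: (1) $\mathbf{H}^s$ per tet
from the current charges; (2) $\mu_r(|\mathbf{H}^p+\mathbf{H}^s|)$ from the
curve, optionally smoothed over face-neighbors,
$\mu \leftarrow \alpha\mu + \frac{1-\alpha}{4}\sum_{nb}\mu_{nb}$ (boundary
tets keep the missing weight); (3) contrasts $K$ per face; (4) GMRES
re-solve. Iteration stops when the relative deviations
$e_1 = \|\rho^n-\rho^{n-1}\|/\|\rho^n\|$ and
$e_2 = \|\mu^n-\mu^{n-1}\|/\|\mu^n\|$ drop below their tolerances
(defaults $10^{-3}$ and $5\times10^{-3}$, max 30 iterations). If either
deviation grows five iterations in a row the run is declared divergent and
retried once with the face-averaging stabilizer: the per-tet field is
blended with the mean of the four just-inside face-center values
(principal value plus the $\mp\rho/2\mu_0$ jump), weight $\beta = 0.25$.
The stabilizer is off by default; it damps the iteration for very steep
curves at the cost of choppier interior fields. On the bundled
cylinder-in-loop fixture at 20 kA all three preset materials converge
monotonically (after a 2–3 iteration transient) to $e_1 \le 10^{-3}$,
$e_2 \le 6\times10^{-3}$ in 15–17 iterations at ~5000-tet resolution.

Defaults: $\alpha = 0.7$, $\beta = 0$. The smoothing weight and stabilizer
blend are exposed because no universal values exist; steeper curves (the
maximum of $|d(\mu_0\mu_r)/d|H||$ is the stability indicator — 0.12, 304
and 126 µH/A for the three presets) may need smaller $\alpha$ or positive
$\beta$.

# Material models

Two single-valued anhysteretic forms are built in, both with the physically
required vacuum term $+\mu_0$ so that $\mu_r \ge 1$ deep in saturation:

| model | $\mu_0\mu_r(|H|)$ | saturation of $B-\mu_0H$ | small-signal $\mu_{r0}$ |
|---|---|---|---|
| arctan | $a_1\arctan(a_2|H|)/|H| + \mu_0$ | $a_1\pi/2$ | $(a_1a_2+\mu_0)/\mu_0$ |
| Froelich | $1/(a_1+a_2|H|) + \mu_0$ | $1/a_2$ | $(1/a_1+\mu_0)/\mu_0$ |

Presets: (1) a generic high-saturation material (arctan, $a_1 = 5/\pi$ T,
$a_2 = 5\times10^{-4}$ m/A, $\mu_{r0} \approx 634$, saturating at 2.5 T);
(2) M3 grain-oriented silicon steel at 2 kHz (Froelich, $a_1 = 40$ m/H,
$a_2 = 0.50$ 1/T, $\mu_{r0} \approx 19900$); (3) METGLAS 2605-SA1 foil
(Froelich, $a_1 = 80$ m/H, $a_2 = 0.82$ 1/T, $\mu_{r0} \approx 9950$,
saturating near 1.2 T). These simple forms do not reproduce the
sub-300 A/m permeability peak of real silicon-steel datasheets; that
matters little at TMS flux densities. Hysteresis, coercivity and loss
models are out of scope.

`fit_bh_curve()` estimates $(a_1, a_2)$ from datasheet hysteresis-cycle
locus points $(H_\max, B_\max)$. Because loci span decades in $H$, the
least squares uses relative residuals (weights $1/B^2$) with positive
parameters, Levenberg–Marquardt refined from closed-form starts (the
Froelich model linearizes exactly as $H/(B-\mu_0H) = a_1 + a_2H$).
Noiseless samples of any preset are recovered to $\le 0.1$%, 1%
multiplicative noise to $\le 5$% (tested at fixed seed).

The maximum permeability variation rate of the arctan model is found on a
2000-point log grid over $[10^{-2}, 10^7]$ A/m refined by golden-section
search (the maximum is interior, at $a_2|H| \approx 0.83$); the Froelich
maximum is $a_2/a_1^2$ at $H = 0$ analytically.

# Meshes

Built-in generators produce structured, watertight tet meshes: a cuboid
(6-tet Kuhn split per cell, conforming across the grid), a cylinder (a
square-section grid mapped radially onto the disc, so the boundary is an
$8n$-gon prism), a C-shaped frame (cell masking of a cuboid grid), and a
ball for validation (spherified-cube mapping). STL import (binary/ASCII,
mm-to-m by default) merges facet vertices, checks watertightness (open
edges are reported explicitly), and fills the surface with interior voxels
split into tets — a staircase approximation intended for quick CAD
imports, not boundary-accurate solves; externally generated tet meshes
(TetGen-style `.node`/`.ele`) are accepted as-is. Results export to legacy
ASCII VTK with per-cell attributes. The face topology satisfies
$4T = 2F_\mathrm{inner} + F_\mathrm{boundary}$ and closed-boundary
$\sum \mathbf{n}A = 0$ on every generated mesh (tested).

# Numerical accuracy: what is well resolved and what is not

Validation against closed forms (all in the test suite): the magnetized
sphere at $\mu_r = 3$ reproduces $|\mathbf{M}| = 1.2|\mathbf{H}_0|$ within
1% and the exterior point dipole within 2% at 4800 boundary faces; the
charged-disc on-axis field matches its closed form to 0.5%; charge
neutrality holds to machine precision; matrix-free and densely assembled
operators agree to $10^{-10}$; a field-independent curve reduces the
all-faces solver to the boundary-only linear solver to $10^{-6}$.

Two accuracy limitations of piecewise-constant collocation deserve
explicit statement, because they shaped the design:

* **Interior fields at high permeability.** The interior total field of a
  strongly permeable core is a small difference of nearly cancelling
  primary and secondary fields; its direct evaluation carries a noise
  floor of a few percent of the *surface-charge field scale* (first order
  in the mesh size), which the constitutive relation multiplies by
  $\mu_r - 1$. The package therefore: (a) reconstructs the interior
  magnetization of *linear* cores above `mu_switch = 8` from the boundary
  charges alone ($\mathbf{M}$ is then curl- and divergence-free with exact
  flux $\mathbf{n}\cdot\mathbf{M} = \rho/\mu_0$, an interior Neumann solve
  on the same operator), and computes the core energy by the equivalent
  boundary functional
  $U^s = -\tfrac12\oint \varphi\, \mathbf{B}^p\!\cdot\mathbf{n}\, dS$;
  (b) reconstructs high-$\mu$ tets of nonlinear states from their face
  jump conditions; and (c) evaluates the final magnetization
  curve-consistently as $\chi(|\mathbf{H}|)\mathbf{H}$, which enforces the
  material's saturation ceiling exactly. Nonlinear states whose
  permeability is effectively uniform (weak drives on the flat part of the
  curve) are detected and routed through the linear reconstruction.
* **Spurious high-contrast resonances.** On faceted surfaces the
  collocation operator's spectrum can extend slightly past the continuum
  bound, producing isolated mesh-dependent contrasts ($K \gtrsim 0.997$,
  i.e. $\mu_r$ of several hundred) at which the charge solve is amplified.
  Saturated TMS operating points ($\mu_r$ of order 10–100) and the
  small-signal limit (handled by the linear path) avoid the affected
  regime; pointwise interior fields of partially saturated states in
  between should be treated as qualitative at desk-scale resolutions.

A practical consequence: saturation *trends* (the monotone drop of the
average core $\mu_r$ with drive current; the saturated inductance lying
between the no-core and small-signal values) are robust, while the
saturated-vs-small-signal inductance *gap* for weakly saturating loose
configurations can be smaller than the interior-energy discretization
error at a few thousand tets — the bundled acceptance test asserts the
strict ordering on the strongly saturating METGLAS-like preset, where the
gap (~17%) is well resolved.

# Fixtures and problem sizes

The test suite builds everything programmatically. `make_fixture()`
provides three configurations whose dimensions are this package's own
reference values: `loop_cylinder` (one-turn loop R = 30 mm, conductor
radius 3 mm; coaxial solid cylinder r = 15 mm, h = 40 mm; material #1;
20 kA, chosen to drive the core well into its nonlinear region), at 648
tets by default and 5184 tets at `resolution = "fine"`; `sphere_uniform`
(r = 10 mm ball in a Helmholtz pair of radius 100 mm — applied-field
nonuniformity across the sphere below 0.01%) for closed-form validation;
and `rat_coil_like`, a small-animal TMS coil with two skewed (15 degrees)
20-turn helical spirals of radii 9 mm and 16 mm and 110 mm total length
with an optional 6-turn booster over a 12 x 12 x 120 mm silicon-steel bar.
The spirals' per-turn pitch profile is a linear taper summing to the coil
length — a documented stand-in, since only the total length and radii are
fixed by the design. Default sizes keep every fixture solve within
seconds and the full suite within minutes on one CPU; the solver scales to
larger meshes with the same code path (the dense operator costs
$O(F^2)$ memory — about 1 GB at 11000 faces).

# Known limitations

* Isotropic permeability only; no hysteresis, coercivity, eddy-current or
  anomalous losses (the core is assumed non-conducting).
* Piecewise-constant collocation accuracy is first order; see above for
  the high-permeability interior-field consequences.
* The voxel tetrahedralizer is a staircase filler; import an externally
  generated boundary-conforming tet mesh for accurate curved CAD cores.
* Skin-effect current redistribution in solid conductors is not modeled
  (the Litz uniform-current model is).
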