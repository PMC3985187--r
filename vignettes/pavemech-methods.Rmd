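---
title: "Pavement-cell wall mechanics and its cytoskeletal readouts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pavement-cell wall mechanics and its cytoskeletal readouts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavemech)
```

# The scientific setting

Leaf epidermal pavement cells are jigsaw-shaped: their anticlinal walls
alternate between lobes (outgrowths) and necks (indentations). Turgor
pressure puts the thin outer (periclinal) wall under tension, and the
geometry of the cell outlines shapes that tension field: stress concentrates
in necks, and its maximal principal direction bridges indentations. Cortical
microtubules — and with them cellulose microfibrils — tend to align with the
maximal tensile stress direction, closing a feedback loop between shape,
stress and wall anisotropy. `pavemech` implements the computational side of
that picture: a membrane finite-element model of the pressurized outer wall,
perturbation experiments (ablation, laceration, plate compression), and the
quantification tools used on the microscopy side (nematic anisotropy scores,
AFM force-curve fits, severing statistics), all exercisable on synthetic
inputs with known ground truth.

# The mechanical model

## Kinematics and material

The outer wall is a curved membrane discretized with constant-strain
triangles. Each element carries a 3x2 deformation gradient $F$ mapping its
2D reference tangent plane to deformed space, the Green–Lagrange strain
$E = \tfrac12(F^\top F - I)$, and a plane-stress Saint Venant–Kirchhoff
matrix energy

$$W_m = \tfrac{\lambda}{2}\,\mathrm{tr}(E)^2 + \mu\,\mathrm{tr}(E^2),$$

with $\lambda,\mu$ the plane-stress Lamé coefficients of the matrix
(`E_matrix` = 40 MPa by default). Cellulose-microfibril reinforcement is the
standard transversely isotropic augmentation

$$W_f = \tfrac{\zeta}{2}\,(a^\top E\, a)^2,$$

where $a$ is the per-element fiber axis. The model source states only that
the fiber phase is "five times stiffer" than the matrix without fixing the
energy form, so the package pins the calibration operationally:
$\zeta$ (see `fiber_zeta()`) is chosen so that the small-strain uniaxial
(laterally free) stiffness *along* the fiber is exactly `fiber_ratio` times
the stiffness *across* it. The closed form follows from the Voigt tangent
$D + \zeta v v^\top$; for the defaults ($E$ = 40 MPa, $\nu$ = 0.3, ratio 5)
this gives $\zeta \approx 176$ MPa. An alternative convention — along-fiber
stiffness equal to five times the *matrix* stiffness — gives an along/cross
ratio of about 4.6 rather than 5; we prefer the ratio-exact calibration
because the anisotropy ratio is the quantity the model is sensitive to, and
it is what the test suite asserts.

The matrix Poisson ratio is not specified for the tissue model (0.5 appears
only in the AFM analysis); the default is 0.3 and configurable — plane-stress
SVK becomes ill-conditioned as $\nu \to 0.5$.

## Loads, constraints and the pressure potential

Templates start flat. The outer template boundary is prescribed a 1% radial
in-plane expansion about the template centroid (epidermal pre-tension); all
cell-boundary vertices are fixed in $z$ (the anticlinal walls tether the
outer wall); turgor (0.2 MPa) pushes on every cell surface. Anticlinal walls
additionally contribute axial bar ("beam") elements along the boundary
polylines with the matrix modulus and thickness $t/5$; their cross-section
is taken as (beam thickness) x (wall thickness) = 0.2 um^2, a choice the
source leaves open.

Pressure is a follower load implemented through conservative potentials
$-P V$, which keeps the solver a true energy minimization:

* open flat templates use the $z$-projected volume
  $V = \sum_e \bar z_e A^{xy}_e$ per cell. Because cell-boundary vertices
  are held at $z = 0$, this is exactly the enclosed volume of the inflated
  cell, and its gradient is the consistent follower-pressure force. In-plane
  pressure on shared anticlinal walls cancels between equally pressurized
  neighbors and is not modeled; after ablation the small unbalanced in-plane
  push on wound walls is neglected (the dominant effect, loss of the wound
  cells' surface pressure and stiffness, is modeled).
* closed surfaces (sphere, capsule, compressed cap) use the divergence-
  theorem volume $V = \tfrac16\sum_e x_1\cdot(x_2\times x_3)$.

## Solver

Equilibrium minimizes total potential energy by Newton iteration with the
analytic sparse tangent (assembled in C++), Armijo backtracking, and a
Levenberg-style diagonal shift whenever the tangent is indefinite — a flat
membrane has no out-of-plane stiffness until tension builds, so the first
steps from a flat start are always shifted. Two further stabilizers: turgor
is ramped in steps (default 0.3/0.6/1.0 of the target), and flat open
templates receive a deterministic micro-lift of the free vertices (0.1 of
the mean edge length per interior graph hop, capped at 5 hops) so the first
tangent sees nonzero curvature. Convergence is declared at a residual below
$10^{-8}$ of the initial (or an absolute floor), with an energy-decrement
fallback; `max_iter` = 200. These tolerances are package choices — the model
source states none.

Membrane-only vs full shell: the validated outputs are in-plane principal
stresses, which are membrane quantities; no bending term is included. The
Laplace-law tests (below) guard this reduction.

## Stresses

`principal_stress()` pushes the 2nd Piola–Kirchhoff stress forward to the
deformed tangent plane, divides by the current thickness (plane-stress
thickness stretch), and eigen-decomposes: $\sigma_1 \ge \sigma_2$, tension
positive, directions defined up to sign. Elements with
$\sigma_1-\sigma_2 < 10^{-6}|\sigma_1|$ are flagged degenerate and excluded
from direction-based scores; during feedback iterations they keep their
previous fiber, which avoids noise-driven fiber flips.

A note on validation tolerances: at the default parameters a pressurized
R = 20 um sphere stretches ~3.5%, so the textbook reference $PR/2t$ = 2 MPa
(reference configuration) differs from the true deformed-state Laplace value
by several percent. The acceptance test therefore evaluates $PR/2t$ with the
*deformed* radius and current thickness, so that the measured error reflects
discretization, not finite-strain bookkeeping. Observed errors are ~0.8%
at 320 elements, falling monotonically under refinement.

## Feedback, perturbations

`feedback_align()` alternates solving with setting each element's fiber to
its previous $\sigma_1$ direction, until the median per-element rotation
drops below 1 degree (or an oscillation guard returns the best iterate). On
jigsaw templates the loop settles in a handful of iterations and the final
directions stay close to the isotropic baseline (median cosine ~0.97,
comfortably above the 0.9 criterion) — geometry, not wall anisotropy,
dominates the stress pattern.

`ablate()` implements wounding as loss of turgor plus wall softening
(x 0.1 by default; the source gives no number, and 10x softening makes the
wound passive while keeping the stiffness matrix well-conditioned). Beams
interior to the wound are softened; wound-edge beams are not, since the
surviving neighbor's anticlinal wall is intact. `circumferential_alignment()`
scores the area-weighted mean $\cos^2$ between $\sigma_1$ and the local
wound tangent over an annulus (default: one mean cell diameter). The
laceration-versus-single-cell ordering reproduces only when the wound is
local relative to the tissue — on a 25-cell template a 3-cell central cut
scores above a single-cell ablation, which scores above baseline; on very
small templates the prescribed outer boundary contaminates the annulus and
the ordering degrades. The acceptance test fixes the 25-cell configuration.

`compress()` squeezes a closed pressurized cap under a frictionless rigid
plane (penalty on vertex height only, so tangential forces vanish). The
conserved quantity is the *unconfined pressurized* volume — the cell's water
content — held within 1% by secant iteration on the internal pressure. A
plate above the free apex reproduces the unconfined solution exactly; as
the gap closes, pressure and mean stress in the contact-free region rise
monotonically.

# Synthetic data: the stated world

The generators default to the conditions of the modeled system, and where
the source is silent the choices below were made once:

* **Jigsaw tissues** (`make_jigsaw_cells()`): Voronoi partition of a square
  domain (jittered-grid seeds, half-plane clipping) with each interior wall
  displaced by a sinusoid windowed by $\sin(\pi s)$ so junctions stay put
  and the tiling stays exact. Defaults: 100 um domain, lobe wavelength
  15 um, amplitude 3 um — typical cotyledon pavement-cell scales; the source
  reports no lobe statistics, so these are realistic knobs, not fits. Wall
  extrema are exported as lobe/neck landmarks with the indentation axis,
  giving the stress tests their ground truth. Self-intersection triggers
  amplitude damping (x0.6, logged) and regeneration.
* **Filament textures** (`make_filament_image()`): anti-aliased Gaussian-
  profile chords whose axial angles are wrapped-normal on the doubled angle,
  so the target order parameter is hit exactly in expectation
  ($S = e^{-\sigma^2/2} \Rightarrow \sigma = \sqrt{-2\ln S}$). Additive
  Gaussian noise, 8- or 16-bit quantization. What a green test establishes:
  the estimator tracks $S$ on clean line textures; it says nothing about
  out-of-focus light, bundling, or wall autofluorescence. One practical
  caveat surfaced during development: the total gradient energy of a random
  line texture varies strongly between seeds (clumping), so a *balanced*
  two-orientation pattern is built by superposing one realization with its
  own 90-degree rotation (matrix transpose), not two independent seeds.
* **Force-curve grids** (`make_force_curves()`): exact forward Hertz-cone /
  DMT-sphere contact forces (128x128 default scan), an exponential adhesion
  tail on the DMT retract whose minimum is exactly $-F_{adh}$, per-pixel
  topography offsets, and additive or multiplicative force noise.
* **Severing series** (`make_severing_series()`): homogeneous Poisson events
  per cell with intensity rate x area x duration, uniform positions/times.

All generators are seed-deterministic and restore the caller's RNG state.

# Quantification choices

**Anisotropy.** Local orientation comes from Gaussian-derivative gradients
($\sigma$ = 1.5 px), orientation = perpendicular to the gradient, weighted by
squared gradient magnitude; the ROI is shrunk by the kernel radius so border
gradients do not leak in. The printed score definition ("eigenvalue
difference over the trace") bounds the orientation-tensor score to [0, 1],
yet the modified convention is stated to reach 2; the package reconciles the
two by reading the modified numerator as the eigenvalue difference of the
traceless nematic tensor $Q = 2T - I$, giving exactly
`score_v2 = 2 * score_v1` and both printed bounds. The anticlinal-wall
exclusion is an inward ROI erosion (3 px default).

**AFM.** The printed model equations are typographically corrupted in the
source text; the package implements the canonical forms they cite: Sneddon
cone $F = \tfrac{2}{\pi}\tan(\alpha)\,\tfrac{E}{1-\nu^2}\,\delta^2$ on the
approach, DMT $F - F_{adh} = \tfrac43 E^* \sqrt{R}\,(d-d_0)^{3/2}$ on the
retract, with the standard $E^* = E/(1-\nu^2)$ (the printed Eq. 3 inverts
this; the conversion is exposed so either convention can be reported).
Contact points are found by piecewise (flat baseline + power law) grid
search with two refinement rounds — the source does not describe its
procedure. Defaults: half-angle 18 degrees, R = 6 nm (middle of the
manufacturer range), $\nu$ = 0.5. Under 5% multiplicative force noise both
fits are unbiased to better than 2% over 200 replicates.

**Statistics.** Severing rates are summarized mean +/- SD across cells and
anisotropy scores mean +/- SE, following the respective reporting
conventions. Percent change between crossover-density means is rounded to
the nearest integer — that convention reproduces the printed "+9%" from
means 11.0 and 12; note it yields -67% for means 15 and 5, where the source
prints "65%" (presumably from unrounded means). Mann–Whitney U is exact for
combined n <= 20 without ties, normal-approximated with tie correction
otherwise, delegated to `stats::wilcox.test()`; the exact value for
{1,2,3} vs {4,5,6} (p = 0.1) is verified in the tests against exhaustive
enumeration.

# Numerical and degenerate-input policy

* Vertex snapping tolerance: 1e-6 of the bounding-box diagonal; T-junctions
  from independently clipped Voronoi cells are repaired by splitting edges
  at snapped vertices.
* Meshing: boundary polylines resampled at most at `target_h` (shared walls
  once, so neighbors match vertex-for-vertex), hexagonal interior lattice
  with a 0.72 h boundary clearance, Bowyer–Watson triangulation, boundary
  conformity repaired by wall-segment subdivision (<= 4 rounds), two guarded
  Laplacian smoothing passes. Meshing is deterministic.
* Degenerate principal directions are flagged, excluded from direction
  scores, and frozen during feedback.
* Zero-gradient images, empty scoring annuli, all-zero force curves,
  ablation of every cell, and infeasible volume constraints are errors, not
  silent results.

# Known limitations

* No growth, viscoplasticity, or turgor re-equilibration after wounding;
  the wound response is the instantaneous elastic stress redistribution.
* The anticlinal walls are approximated by z-restriction plus axial beams,
  not resolved 3D solids; the source reports this approximation to be
  quantitatively consistent with a full 3D variant it does not fully
  specify.
* The model's large-turgor instability boundary is not reproduced (the
  source names the phenomenon but no threshold).
* Image anisotropy is validated on synthetic line textures only; absolute
  score values on real micrographs depend on acquisition details the
  generator does not emulate.
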