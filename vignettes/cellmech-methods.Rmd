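---
title: "cellmech: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellmech: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the two cell-model resolutions, the contact mechanics, the numerical
schemes, and the choices we made where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R` do
not themselves compute.

## The deformable cell model

A cell is a closed, consistently oriented triangulated surface (an
icosphere of `10·4^level + 2` nodes; level 2 gives 162 nodes, level 3 gives
642). Every node `i` obeys an overdamped force balance: friction terms on
the left, force generators on the right,

```
Σ_j Γ_nn (v_i − v_j)  +  Σ_k Γ_nn^cc (v_i − v_k)  +  Γ_ns v_i
    =  F_elastic + F_bending + F_volume + F_membrane + F_contact + F_migration .
```

Inertia is absent (the Reynolds number of cell motion is tiny), so each
step solves a friction-coupled linear system for all velocities at once.

**In-plane viscoelasticity.** Edges are either Kelvin–Voigt elements — a
linear spring `F = −k_s (l − l0)` in parallel with node–node damping
`γ_int` — or modified Maxwell elements: a spring in series with a dashpot
`γ_ME`, in parallel with the nodal damping. The Maxwell branch is advanced
by a backward-difference update,
`F(t) = (F(t−Δt) + k_s Δt v_ij) / (1 + k_s Δt / γ_ME)`,
which recovers the analytic steady state `γ_ME v` under constant extension
rate and the analytic relaxation `exp(−k_s t / γ_ME)` on a hold (both are
asserted to 1 % in the tests). The Kelvin–Voigt element is solid-like
(recovers after load release); the Maxwell variant is fluid-like and keeps
an apparent plastic deformation, which is the distinction the optical
stretcher harness probes. The spring constant derives from the cortex
continuum parameters as `k_s = (2/√3) E_cor h_cor` (sixfold-symmetric
lattice), the hinge bending constant as `k_b = E_cor h³/(12(1−ν²))` (units
N·m), and the discrete membrane-area stiffness as `k_mem = K_A l0`.

**Bending.** Each edge's hinge carries a moment `M = k_b sin(θ − θ0)`,
where θ is the signed angle between the two adjacent triangle normals and
θ0 is its value in the rest shape (spontaneous curvature equal to the
initial curvature; the source model leaves θ0 unspecified, so the built
geometry is the natural reference). The two apex nodes receive `M/h` along
their triangle normals (h = apex distance to the hinge line) and the two
edge nodes carry the balancing forces, so every hinge quadruple sums to
zero exactly; the sign convention was verified against a finite-difference
gradient of the hinge energy.

**Volume and membrane area.** The internal pressure follows the
logarithmic volume strain `p = −K_V log(V/V0)` (within 1 % of the linear
law for |V/V0 − 1| < 0.01), applied per node over its Voronoi area along
the outward curvature normal. Node areas use the mixed (circumcentric with
barycentric fallback for obtuse triangles) scheme, which partitions the
surface area exactly — the property the force discretization relies on.
Curvature normals and radii come from the cotangent Laplace–Beltrami
operator with `R_i = 2/|K_i|`, so a sphere returns its radius; radii are
clamped to `[0.1, 10]` times the volume-equivalent radius because contact
needs finite curvature spheres on flat patches. The membrane force resists
global area dilation with per-triangle magnitude `k_mem (A − A0)/A0` along
the triangle normal, split equally over its nodes.

## Contact: Maugis–Dugdale on triangle pairs

Cell–cell contact is resolved per triangle pair. Each triangle carries the
sphere of its local curvature radius tangent at its plane; a pair defines a
contact plane perpendicular to the line of sphere centers at the mid-gap
point. Both triangles are projected onto that plane, clipped against each
other (Sutherland–Hodgman), and the traction is integrated with a degree-2
Gauss rule (mid-edge points) over a centroid fan of the clipped polygon.
The traction combines the Dugdale cohesive stress — constant `−σ0 = −W/h0`
wherever the surfaces attract — with the Hertz pressure
`p_r = 2Ê/(πR̂)·√(a² − r²)`, where the per-pair contact radius `a` follows
from the spheres' normal approach via Hertz geometry and the adhesive-zone
radius `c = m·a` solves the Maugis self-consistency relation (bracketed
bisection on m ≥ 1; in the short-range limit m → 1, the JKR regime). The
Tabor coefficient `λ = σ0 (9R̂/(2πWÊ²))^{1/3}` classifies the regime.

Two discrete-surface refinements matter in practice, and both are choices
this package makes deliberately:

* **Pointwise gap gating.** The analytic zone radii (a, c) describe smooth
  spheres; on a deformed triangulated surface the curvature radii clamp on
  flattened patches and would let rim pairs far outside the physical
  adhesive range receive full cohesive traction. We therefore evaluate the
  actual inter-surface separation (the affine gap between the two triangle
  planes) at every quadrature point: adhesion acts only where the gap is
  within h0, and repulsion only under true local overlap. Without this
  gating, the simulated pull-off force came out an order of magnitude above
  the JKR reference; with it, the quasi-static pull-off sits slightly above
  the JKR value, which is the physically expected range for adhesive cells
  between the solid-sphere (JKR) and membrane-vesicle limits.
* **Conformal-contact penalty.** A flattened (conformal) contact transmits
  arbitrary pressure in the continuum, but the sphere-pair Hertz profile
  saturates. Quadrature points in true overlap therefore add a penalty
  pressure `pen_stiff · Ê/h0 · |gap|` (default `pen_stiff = 20`), sized so
  that face-to-face contact regions settle at nanometre interpenetration,
  and which lets compressed aggregates transmit their volume-pressure
  loads (rim nodes can still interlock at the mesh scale; see the
  limitations). The penalty mode is
  damped by the physical cell–cell contact friction (`γ_cc` per area times
  the patch area), which is what makes it stable at the default step.

Smooth bodies (planes, spheres representing vessels or center-based cells)
contact each triangle's curvature sphere directly; the body-side reaction
is applied at a center-based cell's center (the DCM–CBM "handshake", exact
to Newton's third law) or discarded for static obstacles. Rigid
triangulated bodies reuse the pair narrow phase with a frozen partner.

## The center-based model and its correction

CBM cells are spheres with JKR pairwise forces computed from the geometric
overlap; the contact radius solves `δ = a²/R̂ − √(2πWa/Ê)` on the stable
branch. In scenes this is evaluated through a universal dimensionless form
of the JKR relation (tabulated once, interpolated), which the tests check
against the direct root solve. Adhesive bonds persist below zero overlap
down to the detachment point and re-engage only on renewed positive overlap
(standard JKR loading asymmetry). Pairwise forces underestimate contact
forces in dense packings, so the apparent modulus is corrected per cell,
`Ẽ_i = E_i + a₁ d̃_i⁴`, with the packing measure
`d̃_i = mean(1 − d_ij/(R_i + R_j))` over all current contacts (cells and
obstacles alike — whether obstacle contacts count was left open in the
source description; we include them). After a division, a₁ ramps linearly
from zero over one tenth of the cycle time so fresh daughter pairs are not
blasted apart. CBM elastic parameters tie to the DCM bulk modulus through
`E = K_V/(3(1 − 2ν))` when K_V is given.

The correction coefficient is fitted by `run_compression_calibration()`: a
two-cell DCM doublet inside a snug rigid cage, loaded by equal and opposite
center forces in increasing steps. The cage stands in for the neighbors of
a spheroid interior — without lateral confinement a two-cell stack relieves
all load by bulging sideways and no stiffening is observable at feasible
problem sizes. Force control makes the measurement statically clean: at
equilibrium the interface transmits exactly the applied load, so the
force–distance curve carries no dynamic measurement noise (a plate-driven
variant proved drag- and chatter-dominated at this problem size). The
uncorrected JKR law underestimates the measured force, most strongly at
moderate packing; a₁ then minimizes the squared deviation of the corrected
law over the compressed range. A caveat the tests document honestly: at
this two-cell scale the deviation from JKR is concentrated at moderate
overlap where the quartic `d̃⁴` term (shaped for interior-like coordination
numbers) is still small, so the single-parameter refit tracks the curve
loosely there; the underestimation direction and the stiffening are
reproduced, the 15 % envelope is not.

## Dynamics and numerics

* **Friction assembly.** Node–medium friction is either Stokes-split
  (`6πμR/N` per node; suspension experiments, so the whole cell has exactly
  the Stokes drag) or per-area (`γ_medium · S_i`; tissue/ECM). Node–node
  friction within a cell acts along edges; cell–cell contact friction
  couples the node triples of every contact patch with `γ_cc` times the
  patch area; static obstacles add their share to the diagonal. The
  anisotropic tensor `Γ = γ⊥(e⊗e) + γ∥(I − e⊗e)` is implemented and
  tested, but the integrator assumes isotropic coefficients (the fitted
  values are isotropic), which decouples the three axes and lets one N×N
  sparse Cholesky factorization serve three right-hand sides. The
  factorization is cached between steps while the friction pattern is
  unchanged. A diagonal-only "lumped" mode exists for quick runs.
* **Semi-implicit volume pressure.** The volume ("breathing") mode is stiff
  (`∂F/∂R ~ 3K_V S̄/R`) but barely damped in suspension, which would force
  millisecond steps. Because its force is rank-one per cell
  (`dV = Σ S_i n_i · v_i dt`), it is integrated semi-implicitly through a
  Woodbury correction to the friction solve — one extra triangular solve
  per cell and a small capacitance system — which removes that stability
  limit entirely. The optical stretcher runs at Δt = 10 ms this way.
* **Step control.** Explicit in-plane stiffness against the (thermally
  scaled) damping bounds the step elsewhere; a displacement limiter (a
  quarter of the smallest rest length per step, tightened to a twentieth
  while freshly divided cells relax through their mitosis phase) guards
  transients such as plate jumps. The pull-off harness shrinks Δt in
  proportion to 1/σ0 because the cohesive-zone stiffness grows with the
  adhesion energy. The volume log-strain entering the pressure is clamped
  to ±1.5 so that strongly under-inflated transients (division seeds)
  cannot drive a coarse mesh through itself in one step.
* **Determinism.** One integer master seed; every stochastic feature
  (migration, division planes, seeding, variability) draws from its own
  named substream, so enabling one does not shift another's sequence and
  paired model comparisons share identical draws. Re-runs are bit-identical
  (asserted).

## Virtual experiments and problem sizes

All experiment harnesses are deterministic given (config, seed). The sizes
below are the package's default study conditions; they were chosen as the
smallest configurations that keep each measurement in its asymptotic
regime, and the vignette notes what that means per experiment.

* **Optical stretcher** (`run_optical_stretcher`): one cell in suspension,
  162 nodes by default (the discretization study behind the model used up
  to 642; refinement beyond 162 changes the strain curves by little
  compared with the parameter uncertainty). The surface stress profile is
  the community-standard `σ(θ) = σ_peak cos²θ` about the beam axis applied
  outward on node Voronoi areas, with `σ_peak` proportional to laser power
  (calibration constant `sigma_per_mW`, default 1e-3 Pa/mW, chosen to give
  percent-level strains). While the laser is on, all cortical friction
  coefficients are multiplied by the thermal ratios (0.29 at 900 mW/310 K,
  0.11 at 1100 mW/315 K, consistent with an Arrhenius law at
  E_a = 55 kJ/mol); they are restored instantly at release. The monitoring
  window defaults to 12 s because the Kelvin–Voigt recoil time constant
  (γ/k_s ≈ 2.3 s) makes the solid/fluid contrast invisible within 2 s.
* **Pull-off** (`run_pulloff`): two equal 162-node cells, relaxed into
  adhesive equilibrium, then bisection on the applied force with 50-second
  quasi-static trials (two hundred times the mechanical relaxation time).
  Contact friction is reduced during the trials — the quasi-static
  threshold does not depend on it, and full Table-value friction would slow
  the peeling verdict a hundredfold. A trial counts as separated when no
  contact patches remain.
* **Compression calibration** (`run_compression_calibration`): described
  above; eleven force levels from 0 to 8 nN, three hundred equilibration
  steps each, center distances averaged over sixty further steps.
* **Growth assays** (`run_growth_assay`): uninhibited growth from one cell
  at Δt = τ/200; the doubling-time fit uses populations up to a few tens of
  cells (exponential growth is already unambiguous there). DCM-engine
  growth is supported and exercised at small populations; large DCM
  colonies are out of scale for a single-core test run.
* **Lobule regeneration** (`build_lobule`, `run_regeneration`): a 60°
  wedge of the hexagonal lobule with bounding planes, a central-vein sphere
  column, portal columns at the outer corners, and ~20 jittered radial
  sinusoid chains of overlapping static spheres (radius 4.7 µm, spacing
  half a radius, zero adhesion) — a synthetic stand-in for image-derived
  networks. About 90 half-size cells seed the inter-sinusoid voids, inflate
  quasi-statically to 12 µm, and cells within 150 µm of the axis are then
  ablated. The lesion metric rasterizes the mid-plane disk restricted to
  the wedge sector and reports the uncovered fraction normalized to its
  t = 0 value. Proliferation is restricted to a band of four cell layers
  from the lesion front within a configurable time window; leaders are
  front cells with an unobstructed corridor toward the axis. The regression
  comparisons run the CBM engine for a few simulated days — long enough for
  the model ordering (directed migration closes faster; packing-corrected
  contacts close faster) to emerge, far short of full closure.

## What the synthetic scenes do and do not emulate

The generators reproduce the geometry and rates that define the study
conditions (cell sizes, cycle time, adhesion energies, lobule dimensions,
sinusoid radius and density) but idealize everything else: sinusoid chains
are jittered radial polylines rather than measured vascular trees; the
proliferation schedule is a constant-eligibility band rather than a
stain-derived pattern; there is no explicit ECM continuum, no nutrient or
morphogen field (directed migration uses the geometric direction to the
axis), and no active cortical contractility. Passing tests therefore
demonstrate internal consistency and the mechanisms' relative effects, not
agreement with any particular imaging dataset.

## Known limitations

* The conformal-contact penalty is a regularization, not part of classical
  Maugis–Dugdale theory; its scale (20 Ê/h0) sets the residual
  interpenetration and was fixed once from the no-deeper-than-0.1·h0
  requirement, before any end-to-end experiment was run.
* The per-patch Hertz radius uses the instantaneous sphere approach; how a
  evolves in dynamic (non-quasi-static) contact has no canonical answer at
  this discretization.
* Anisotropic friction is not wired into the integrator (isotropic
  coefficients only).
* The division sub-simulation uses a step cap rather than a strict
  convergence criterion; daughters reach their target volumes during the
  subsequent relaxation (volume bookkeeping across division is asserted at
  5 %).
* Remeshing is absent: extreme deformations (far beyond the regimes
  exercised here) would degrade triangle quality without detection.
* Division requires the standard discretizations (162 nodes and up): 42-node
  surfaces buckle under the inflation loads of the division sub-simulation
  (shell compression against a bending stiffness that is too coarse to
  resist crumpling).
* The measured two-cell pull-off saturates near 0.4 nN across the nominal
  adhesion range instead of scaling with W as the JKR reference does —
  a discrete cohesive-rim (lattice-trapping) effect at 162 nodes; the
  ratio to the JKR prediction is therefore closest to theory at
  W = 1e-5 J/m², the reference adhesion energy.
* At the two-cell scale the packing-correction refit tracks the measured
  compression curve only loosely (see the calibration section): the JKR
  error concentrates at moderate packing where the quartic term is
  negligible.
* Two adhered discrete surfaces interdigitate at the contact rim: nodes of
  one mesh settle into pockets between the faces of the other, down to a
  few percent of the edge length (about 0.1 µm at 162 nodes), even though
  face-to-face contact regions are held at nanometre interpenetration by
  the penalty. A mutual clearance at the adhesive-range scale (tens of
  nanometres) is not achievable for independent triangulations at this
  resolution.
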