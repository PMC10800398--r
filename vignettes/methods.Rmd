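---
title: "Methods: phantom construction, osteotomy Booleans and the finite-element model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom construction, osteotomy Booleans and the finite-element model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lumbosim` simulates two linked analyses on a synthetic L3–L5 lumbar
segment: (1) the bone volume removed by a trephine advanced towards the
L4/5 interspace at entry angles of 20–70° with 7/8/9 mm tools and one or
two attempts, and (2) the biomechanical consequences of representative
resections — range of motion (ROM) and maximum von Mises stress of the
motion segment under a 400 N follower load and 10 Nm pure moments in six
directions.  This vignette documents the models, every tunable parameter
that matters, the numerical machinery and its verification, and what the
phantom does and does not capture about real patients.

## 1. The parametric phantom

Patient CT reconstructions are replaced by a seeded parametric phantom.
Each vertebral body is an extruded superellipse
(`|x/a|^n + |y/b|^n = 1`, exponent 2.4) with a 1.0 mm cortical shell
surrounding cancellous bone.  The discs are wedge-shaped slabs spanning
the endplate planes of the adjacent bodies, composed of cartilage
endplates (0.8 mm), an annulus ring and a nucleus.  The disc cross-section
is scaled so that annulus + nucleus + endplates occupy 95% of the
vertebral cross-section; the nucleus is a scaled copy of the disc boundary
holding 40% of the disc area, positioned so that the ratio of the
anterior to the posterior annulus-edge-to-nucleus-centroid distance along
the mid-sagittal line is 1.62.  These three quantities are *construction
targets* that the package verifies by slicing the generated meshes
(`measure_area_fractions()`), not by echoing inputs.

Posterior elements are constructive-solid-geometry blocks: pedicles,
a swept posterior arch whose interlaminar margin rises towards the
midline (the arched interlaminar window), a spinous process, and
articular processes forming cartilage-capped facet joints.  The articular
processes are rounded superelliptic prisms trimmed flat at the joint
space; the superior articular process (SAP) merges anteromedially into
the pedicle and carries a posterolateral lip that cups the inferior
process — the axial-section curvature of real lumbar joints.  This
curvature is what makes a trajectory that rakes along the joint line
(≈50° from the posterior mid-sagittal axis in this geometry) remove the
most bone, while more lateral trajectories clip progressively less of the
process.

Dimensional defaults come from adult lumbar morphometry (body
46 × 33 × 28 mm; disc space 10 mm; pedicles 10 × 13 × 9 mm; laminae 5 mm
thick; facet centres 15 mm lateral and 13 mm behind the posterior body
wall; articular planes 45° to the sagittal plane; facet gap 0.4 mm with
0.8 mm cartilage per side; segmental lordosis 6°/8°).  They are design
inputs exposed in `subject_params()`; the analyses depend on relative
geometry rather than patient realism.  Cohorts draw each dimensional
parameter independently from a truncated normal (±2.5 SD) around these
defaults with a default 5% coefficient of variation — the simplest
defensible model of inter-subject variability.  The generator is fully
deterministic: identical parameters give bit-identical output.

What the phantom does *not* emulate: cortical/cancellous density
variation, degenerative disc geometry, asymmetric or tropistic facets,
osteophytes, and the soft-tissue envelope.  Passing tests therefore
demonstrate internal consistency of the pipeline and the geometric logic
of the approach corridors, not patient-level predictions.

## 2. Solids, Booleans and the volume oracle

Every region exists in two linked representations: a continuous signed
field (negative inside) with a finite bounding box, and a watertight
triangulated surface.  Booleans are field compositions (`max`/`min`);
boundary surfaces are recovered by marching tetrahedra on a uniform
lattice, with each crossing edge located by bisection (10 iterations, so
surface points are accurate to ~10⁻³ of the lattice pitch), and volumes
follow from the divergence theorem on the extracted surface.  Extrusion
regions (bodies, discs, endplates) also carry analytic lofted meshes that
match their fields exactly.

Resected volume is the sum over disjoint attribution groups (posterior
arch, L4 inferior processes, L5 superior processes, vertebral bodies,
facet cartilage) of the volume of `group ∩ tool`.  The independent oracle
is Monte Carlo point classification over the tool's bounding box with a
binomial standard error; the acceptance suite requires agreement within
three standard errors for all 36 plan configurations at 10⁶ samples.
Default pitches: 0.3 mm for single volumes, 0.5–0.6 mm for the 900-row
cohort factorial (chosen so the lattice error stays well below the Monte
Carlo uncertainty at these sample sizes).

A note on exactness: the environment provides no exact-arithmetic mesh
Boolean, so the CSG/marching-tetrahedra engine *is* the Boolean backend,
with the Monte Carlo oracle as its independent check.  User-supplied
watertight STL meshes are supported through a ray-cast containment
predicate (`anatomy_from_meshes()`); the finite-element mesher, which
needs the parametric structure, accepts generated phantoms only.

## 3. Puncture planning

The planner mirrors the clinical workflow: least-squares planes through
the L4 inferior and L5 superior endplate meshes; the interspace centre C
as the midpoint of the two posterior-edge midpoints; a reference plane
through C parallel to the L5 superior endplate; and a fan of axes in that
plane at 20–70° from the posterior mid-sagittal axis, opening towards
the approach side (right).  The second attempt is the same axis rotated a
further 5° outward about C — pivoting at the target keeps both attempts
aimed at the lesion, which matches the clinical intent of removing
residual bone around the target; a pivot at the skin entry point is the
other reading and is not implemented.  Tools are right circular cylinders
(default 120 mm long) whose tip advances 5 mm past C; the sign convention
(angles open laterally on the approach side) and the left/right symmetry
of the construction are covered by tests.

## 4. The finite-element model

**Meshing.**  No tetrahedral mesher is available in the environment, so
`tetrahedralize()` builds a structured multi-block mesh: a boundary-fitted
ray grid for the spine column (radial rings fitted per angular sector to
the nucleus, cortical-inner, disc-outer and body-outer boundaries,
extruded through axial stations that follow the lordotic level frames), a
swept arch band whose root columns reuse column-surface nodes, lofted
spinous processes, and articular-process lofts five columns wide — wide
enough that a trephine corridor through a process leaves an annular bone
remnant, as it does in the continuum.  Hexahedral cells split into six
tetrahedra (Freudenthal); collapsed core cells degenerate gracefully.
Region interfaces share nodes by construction; across independently
generated blocks the shared-node contract holds while face diagonals may
differ, which is accounted for in the connectivity analysis (components
over shared faces, merged when blocks share three or more nodes).

**Materials.**  Linear elasticity with the standard lumbar card:
cortical 12 000 MPa/0.3, cancellous 100/0.2, endplate 23.8/0.4, cartilage
10/0.4, annulus matrix 4.2/0.45, nucleus 0.4/0.499, and truss ligaments
(annulus fibres 455 MPa/1.35 mm²; ALL/PLL/LF/ISL/SSL/ITL/CL with their
respective moduli and areas).  Posterior bone uses cortical properties (a
common single-material simplification when only two bone materials are
given).  The nucleus at ν = 0.499 locks constant-strain tetrahedra; the
default caps it at 0.495 (`material_table(nucleus_nu_cap=)`), the
documented near-incompressibility treatment.

**Ligaments.**  Each anatomical band is discretised into trusses anchored
to the nearest mesh nodes (attachments farther than 5 mm are an error).
Four capsular trusses span each facet joint; since truss section areas
apply per element, each carries the full 30 mm² capsular area.  Capsular
fibres anchor on bone and cross the joint line obliquely (higher on the
inferior process, lower on the superior), so the capsule resists both
facet distraction and cranio-caudal gliding.  Annulus fibres form two
criss-crossing diagonal families on the outer annulus wall.  Ligaments
are linear (tension and compression) as a Table-level simplification.

**Facet contact.**  Opposing cartilage surface nodes are paired along the
joint normal tilted 25° caudally — a linearisation of the curved
articular surface that lets the joint carry load in extension (caudal
gliding) as well as rotation and bending.  Contact is compression-only
and solved *exactly* within the linear kinematics as a small linear
complementarity problem on the contact Schur complement (projected
Gauss–Seidel; gap ≥ 0, force ≥ 0, complementary), with the pairs' finite
stiffness (2500 N/mm) adding surface compliance in series with the
cartilage solids.  An earlier one-pass penalty spring scheme chattered
(oscillating active sets with millimetre penetrations) and was replaced
by the LCP, which is unconditionally stable here.

**Loads and outputs.**  The L5 inferior surface is fixed.  The follower
load (400 N) is distributed over the L3 superior surface along the
segment's local axis; each 10 Nm moment is applied as the minimum-norm
nodal force system on the same surface (exact zero net force, exact
moment).  ROM is the total rotation angle of the least-squares rigid
transform (Kabsch) fitted to each vertebra's cortical nodes, reported for
the cranial vertebra relative to the caudal one; stresses are constant
per tetrahedron with per-region maxima for the L4/5 annulus and the
adjacent endplates.

**Surgical variants.**  M1 is intact.  M2 (8 mm, 60°, 1 attempt, ¼
capsule), M3 (8 mm, 30°, right flavum), M4 (8 mm, 50°, ½ capsule),
M5 (8 mm, 50°, 2 attempts, ½ capsule), M6 (9 mm, 50°, ¾ capsule,
extensive cartilage removal).  Resection removes every bone/cartilage
element whose centroid lies in the tool (voxel-style), drops small
disconnected slivers (they come out with the core), re-anchors ligaments
whose attachment bone was destroyed to the nearest surviving bone within
5 mm, removes capsular trusses nearest the tool axis first, and for M6
extends cartilage removal to the whole operated joint, per its
"extensive" designation.  Cartilage-removal *extent* is otherwise the
actual Boolean footprint, which reproduces the ordinal relations among
the variants (M6 > M5 ≥ M4 > M2 in removed cartilage elements).

## 5. Verification and numerical choices

The analytic suite (`run_validation()`, `analysis/05_validation.R`)
replaces cadaveric corroboration at desk scale: an axial bar against
FL/EA (consistent tributary-area tractions; <1%), the patch test (exact
reproduction of a linear field on a distorted mesh, ~10⁻¹⁶), a slender
cantilever against Euler–Bernoulli theory with first-order shear
correction (<10% at 0.375 mm lattice), the truss bar formula (exact), and
global equilibrium (reactions balance applied loads to 10⁻⁶ relative).
The intact phantom's flexion ROM falls in the 2–10° physiological
corridor reported for L4–L5 in the validation literature, and flexion ROM
changes by under 5% between 3 mm and 2 mm meshes.

Problem sizes used by the shipped analyses: the cohort factorial runs 25
subjects × 36 plans at 0.5–0.6 mm pitch; the biomechanical study solves
6 variants × 6 directions on a ~3 mm mesh (≈50 000 tetrahedra, ≈30 000
degrees of freedom) with one sparse Cholesky factorisation per variant.

## 6. Known limitations

* The phantom is symmetric and non-degenerate; cohort variability is
  independent per-parameter jitter, not a statistical shape model.
* Discs are single-phase linear elastic (no poroelasticity, no large
  rotations); ligaments are linear rather than tension-only.
* The facet articulation is a flat patch with a tilted-normal contact
  linearisation; real joints are curved with varying congruence.  One
  consequence observed in this phantom: the 60° single-attempt corridor
  (M2) passes through the body of the superior articular process and can
  destabilise axial rotation more than the larger-diameter 50° corridor
  (M6), whereas anatomies whose joint line sits further posterior retain
  more of the articulation at 60°.  Relatedly, because contact makes the
  load path configuration-dependent, the total-rotation angle of one level
  is not strictly monotone in global compliance and an intact model can
  marginally (≈1%) exceed a resected one in a single coupled direction.
  The shipped trend checks treat trend statements with a 1% equivalence
  band and report these deviations where they occur.
* Exact element/node counts of CT-based models, patient demographics and
  skin-entry planning are out of scope.
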