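---
title: "Methods: calvarial suture mechanics from labeled volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calvarial suture mechanics from labeled volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model

`suturemech` analyses the mechanics of the developing skull roof from
labeled voxel volumes: bones are integer labels on a 3-D grid with a
physical voxel size in micrometres, and everything downstream — suture
synthesis, endocast extraction, meshing, finite elements, strain
estimation, gap statistics and inverse calibration — is driven by the
label *roles* (`bone`, `suture`, `endocast`, `cover`, `constraint`).

The mechanical model is small-strain isotropic linear elasticity
throughout. That is a deliberate simplification: sutures are fibrous,
nearly incompressible soft tissues with rate- and history-dependent
behaviour, and the brain is strongly hyperelastic. Linear elasticity keeps
the inverse problem well-posed and cheap, at the price of absolute
accuracy at the large strains (order 1 and above) that neonatal sutures
actually experience. Every result of the package should be read with that
limitation in mind; the calibration module exists precisely because
literature moduli combined with a linear model mispredict observed suture
deformation by orders of magnitude.

Axis convention, fixed once and used everywhere: axis 1 mediolateral,
axis 2 dorsoventral (larger index = dorsal), axis 3 anteroposterior
(larger index = anterior). Voxel-corner origin; physical coordinates are
`index * voxel_size`. Units: volumes µm, meshes mm, moduli MPa, forces N —
a consistent mm–N–MPa system, so displacements are mm and strains
dimensionless.

# The synthetic phantom

No public micro-CT data accompany the problem this package addresses, so
the phantom module *is* the study-condition generator, not a test
convenience. `generate_phantom()` voxelises a thin spherical shell
partitioned into `n_plates` wedge plates by half-planes that contain the
dorsoventral axis, separated by planar gaps of exactly `gap_width`.
Default conditions (`phantom_spec()`): a 4 mm dome (outer radius 2000 µm),
250 µm shell, 120 µm gaps at 30 µm voxels — i.e. four-voxel suture gaps on
a grid of about 140³, the same gap-to-voxel ratio regime as a neonatal
mouse calvaria imaged at 9.5 µm (where unloaded gaps span roughly 9–19
voxels, and the phantom's gap sits deliberately at the harder, thinner end).

Two constraint patches are carved out of the shell as reserved labels:
an anterior cap (the incisor-contact analogue) and a *ventral polar cap*
(the cranial-base analogue). Two design points matter here:

* The patches are **solid bone** — suture gaps do not cut through them.
  The cranial base is a continuous ossification; cutting the gap planes
  through the ventral cap would also leave a through-hole at the pole
  where all plates meet a single label and no contact (hence no suture)
  can form.
* The ventral cap **grounds every plate**. A plate anchored only through
  its sutures floats quasi-rigidly on them, and the force each suture
  carries is then fixed by statics — the suture strain becomes almost
  independent of the bone modulus. Real calvarial bones are anchored
  through the skull base, deform under load, and impose that deformation
  on the soft sutures, which is what makes the bone modulus identifiable.
  The ventral cap reproduces this topology; with it, phantom suture
  strains scale essentially as 1/E_bone across the whole 10–7000 MPa
  sweep range.

`generate_loaded_pair()` applies per-bone proper rigid transforms (µm,
about the physical origin; `rigid_transform()` builds pivoted rotations)
to the extracted bone surfaces, preserving per-bone vertex order so the
ground truth closes to machine precision. `generate_gap_stack()` builds
two flat slabs whose dorsal-edge separation follows a per-slice profile,
quantised to the voxel grid (minimum measurable separation two voxels;
zero means face-contact, i.e. a fused slice).

What the phantom does *not* emulate: anatomical plate shapes, interdigitated
suture geometry, spatially varying bone thickness or mineralisation, and
image noise or segmentation error. Tests passing on the phantom therefore
validate the algorithms and their contracts, not performance on real scans.

# Suture synthesis

`synthesize_sutures()` implements the morphological recipe with
`morph_params()` defaults 5 / 5 / 9 / 1 / 9:

1. bones expand by `bone_expand` voxels — *n* synchronous rounds of unit
   dilation with the 3×3×3 (Chebyshev) structuring element. A background
   voxel claimed by two or more distinct labels in the same round is
   assigned to neither and becomes a permanent *tie* voxel — these are
   the contact voxels;
2. contacts = ties plus voxels on a face between two distinct expanded
   labels (fronts meeting exactly across an even gap leave no tie);
3. the contact set expands by `suture_expand` voxels, clipped to original
   background (the suture never extrudes over bone);
4. one smooth / grow / smooth pass (`smooth_a`, `grow`, `smooth_b`) on the
   suture segment only; bones are then restored to their original extent.

Numerical choices worth stating explicitly:

* **Smoothing counts are kernel sizes, not radii.** "Smoothing of 9
  voxels" filters over the 9×9×9 window (radius 4), matching the kernel
  convention of interactive segmentation tools. A radius-9 (19³) majority
  filter would annihilate any suture narrower than ten voxels.
* **Smoothing votes solid against open space.** The majority filter
  counts suture ∪ bone against background. A suture slab pinned between
  bone faces is a minority of any window wider than the gap, so a plain
  suture-vs-everything vote would carve out exactly the voxels the recipe
  is meant to keep; voting the solid phase preserves the bounded gap fill
  while still trimming flares that protrude into free space.
* **The suture is confined to the skull hull** — the Chebyshev closing of
  the bone mask with radius `bone_expand + suture_expand + grow`. Without
  this, contact sheets flare along the open ends of each gap into the
  cranial cavity and the exterior.
* **Constraint patches count as bone** during expansion and contact
  detection (they are bone tissue reserved for fixation), so gaps flanked
  by a patch are bridged like any other.
* The single smooth–grow–smooth pass is fixed, not iterated to a visual
  criterion: reproducibility beats faithfulness to an interactive
  stopping rule.
* Bones that start in direct face contact leave no background to host a
  suture; `carve_contact = TRUE` reassigns the facing voxel layers to the
  suture, trading strict bone preservation for a representable joint.
  The default is `FALSE` (disarticulated inputs are the norm).

`split_sutures()` attributes every suture voxel to the pair of bones whose
breadth-first fronts reach it first (seeded at bone and constraint voxels,
26-connectivity, deterministic FIFO order) and relabels the suture per
pair. Junction slivers — pairs covering under 1% of the suture volume,
and any self-pair — are merged into the neighbouring suture whose front
arrives first. Only bone-to-bone pairs are *investigated sutures*;
bone-to-patch joints keep suture material in the mesh but are excluded
from strain reports and calibration objectives.

# Endocast, covers, meshing

`extract_endocast()` closes the non-background mask with a Chebyshev ball
(radius default: twice the suture gap in voxels), flood-fills the exterior
from the volume border, and labels the largest enclosed original-background
component as endocast. A solid block, or an opening wider than twice the
closing radius, raises "cavity not closable". `generate_covers()`
repeatedly flood-fills the exterior and converts every exterior voxel
face-adjacent to the endocast into cover material until the exterior can
no longer touch the endocast; covers inherit the suture modulus.

`extract_surface()` produces the exact voxel boundary surface per region
(optionally majority-presmoothed), with all regions sharing one corner
lattice so interfaces conform. `decimate_surface()` first merges coplanar
faces into maximal rectangles — lossless: identical geometry and area —
and only clusters vertices (approximate) if the budget is still exceeded.

`tetrahedralize()` splits every labeled voxel into six tetrahedra around
the cube's main diagonal (Freudenthal/Kuhn), which conforms across voxels
and across region interfaces by construction and conserves region volume
exactly. The lattice is refined by an integer factor when `max_size`
demands it; `coarsen_volume()` goes the other way for FE-scale meshes,
aggregating blocks with role priority (cover and suture outrank bone,
bone outranks endocast) so one-cell-wide soft joints survive coarsening.
Adaptive per-region sizing is not supported — a uniform lattice cannot
express it; the per-region *target* interface is honoured by meshing at
the smallest requested size.

# Finite elements

Standard 4-node constant-strain tetrahedra; per-material unit-modulus
stiffness blocks are cached so a modulus sweep re-forms the matrix without
re-assembly, and the sweep reuses the symbolic (supernodal) Cholesky
factorisation across grid points. The element stiffness uses the
closed-form isotropic expression in the shape-function gradients and is
verified in the tests against an explicit B-matrix oracle to 1e-12.

Loading follows the experimental protocol: the total force (default
0.1 N, the 10 g weight) is split equally over the disc of *bone* surface
nodes within `disc_diameter/2` (default 1 mm) of the load axis — bone
only, because the experiments press on bone; a disc overlapping a 30 kPa
suture would measure local soft-tissue indentation instead of skull
mechanics. The posterior-ventral patch is fixed in all degrees of
freedom; the anterior patch in the load-direction component only (full
fixation is an option — the experimental contact constraint is not fully
specified, so both are exposed).

Strain measures: von Mises equivalent strain is fixed as
`sqrt(2/3 * e_dev : e_dev)` (commercial codes offer effective-Poisson
variants; this convention is used consistently everywhere), principal
strains are the ordered eigenvalues (analytic trigonometric solver), and
per-suture summaries are tet-volume-weighted means (element-count means
are a config option nowhere needed by the tests).

The analytic verification suite pins: uniaxial σ/E and −νσ/E to 1e-10,
the patch test to 1e-10, reaction equilibrium to 1e-8 N, and a slender
cantilever (L/h = 10) within 15% of PL³/3EI at the default refinement of
six linear elements through the thickness, with the error decreasing
under refinement — constant-strain tets are stiff in bending, which is
why the refinement rule (at least two elements through bone, three across
a suture) is part of the meshing contract.

# Strain estimation from surface pairs

`align_bone()` is point-to-point ICP: nearest neighbours via a k-d tree,
closed-form SVD rigid fit, convergence when the RMS changes by less than
1e-6 mm (cap 200 iterations). Staircase voxel surfaces give ICP a
lattice of local minima half a voxel apart, so the iteration is seeded
with a principal-axes initialisation — centroid shift plus covariance
eigenvectors over the *full* vertex sets, with the eigenvector sign
ambiguity (all eight combinations, proper rotations only) resolved by
nearest-neighbour RMS. On exactly corresponding surfaces this
initialisation is already exact, and ICP merely polishes.

`estimate_suture_strain()` reconstructs each suture's interior field from
the rigid bone motions: the suture region is tetrahedralized on its voxel
lattice, a mesh node inherits a bone's displacement if any of its eight
incident voxels carries that bone, and the interior solves linear
elasticity with those Dirichlet data (unit modulus — a pure Dirichlet
problem's strain field is modulus-independent). Each suture is solved in
the frame of its first flanking bone, i.e. with relative transforms
A_a⁻¹A_c, which cancels any rigid motion shared by all bones exactly —
the report is invariant to it by construction, not approximately.

The default strain measure is **infinitesimal**, not Green–Lagrange,
although openings up to four gap widths are supported. The package's own
recovery contracts fix this choice: a prescribed normal opening Δ across
width w must report e1 ≈ Δ/w for Δ/w ∈ {0.3, 1, 4}, and a tangential
slide γ must report e1 ≈ γ/2 — both hold exactly only for the engineering
measure (Green–Lagrange gives λ + λ²/2, i.e. 12 at Δ/w = 4, and 0.618 vs
0.5 for shear at γ = 1). The finite measure remains available as
`measure = "green"` for users who want frame-invariant large-strain
values; it reports systematically larger tensile numbers. For
FE comparisons the infinitesimal measure also matches the solver's own
strain definition.

The closing-the-loop validation (estimate from FE-deformed surfaces vs
the FE's own suture averages, bones 10⁴× stiffer than sutures) is run on
a slab fixture, where bone motion is genuinely rigid. On the grounded
dome phantom the loaded plate bends locally under the disc — that bending
is real deformation a rigid fit cannot represent, and the two estimates
legitimately diverge near the load; this is a property of rigid
alignment, not a defect of either solver.

# Gap analysis

`measure_gap()` samples every `stride`-th mediolateral slice (default 10,
over ranges of 200 slices). In a slice, each bone's most dorsal voxel
within ±20 voxels (anteroposterior) of the inter-bone interface is
located, ties broken toward the interface, and the gap is the in-slice
2-D Euclidean distance between the two voxel centres. Slices where the
bones touch (in-slice 4-adjacency) yield no measurement and are counted,
so sampled = measured + excluded always. `compare_states()` reports the
relative gap change, classic one-way ANOVA (for two groups F equals the
squared pooled t statistic), the Brown–Forsythe (median-centred) Levene
test, and Welch's ANOVA alongside whenever Levene rejects at 0.05 — both
are reported rather than silently switching. Stars follow the
0.05 / 0.01 / 0.001 convention.

# Inverse calibration

`calibrate_modulus()` is the package's fitted-model interface: given a
strain predictor `function(E_bone)` (built efficiently by
`fem_strain_fn()`), an experimental per-suture strain vector, and a grid
(default 25 log-spaced points, 10–7000 MPa — log spacing because the
response spans orders of magnitude), it records per-suture
`100·|comp − exp|/exp`, minimises the unweighted mean across sutures, and
returns a classed object with `coef`, `print`, `summary` and `plot`
methods. Failed grid points are skipped and flagged. Pairs with zero
experimental strain are flagged as undefined, not computed.

Agreement statistics use Lin's concordance correlation coefficient with
population (1/n) moments — the original definition; the sample-moment
variant is an argument — plus the OLS best-fit line and R². CCC ≤ |r|
always, and a pure location shift already drives CCC below 1, which is
what makes it the right agreement measure here.

Identifiability deserves a note: with the suture fixed at 30 kPa, the
bone modulus is identifiable only where bone deformation contributes
measurably to suture strain. On the grounded phantom the response is
essentially proportional to 1/E_bone over the whole grid, so on-grid
self-consistency is exact and recovery under 5% multiplicative noise
stays within one grid step in well over 90% of replicates at 20, 200 and
2000 MPa alike. On a floating-plate geometry (no base anchoring) the same
sweep would be flat and the optimum meaningless — worth checking before
trusting a calibration on new geometry (`plot()` of the curves makes it
obvious).

# Problem sizes and tolerances

The shipped tests run the full-resolution morphological phantom at ~140³
voxels (four-voxel gaps, default parameters), FE fixtures of
1–13k tets for the analytic suite, and a ~29k-tet four-plate dome (75 µm
build, 150 µm mesh lattice) for the loading study and the 25-point sweep;
these sizes keep the complete suite around two minutes on one CPU while
staying inside every contract's tolerance with margin. Key tolerances:
1e-10 relative for analytic FE identities, 1e-8 N equilibrium, 3% endocast
volume against the analytic ball, one voxel for gap measurements, ±10%
for Δ/w strain recovery, 1e-6 for shared-motion invariance, and exact
(integer) equality for all morphology-versus-oracle comparisons.

# Known limitations

Linear elasticity for tissues that are not; rigid per-bone alignment
(local bone bending is invisible to it — the posterior loading sites bend
real neonatal bone appreciably); uniform-lattice meshing without adaptive
sizing; voxel (staircase) surface geometry rather than smooth remeshing;
phantoms that are geometric, not anatomical; and strain estimation that
requires patent sutures — fused joints leave nothing to align across.
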