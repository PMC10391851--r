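---
title: "Methods: static FE comparison of anterior cervical constructs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: static FE comparison of anterior cervical constructs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`cervifem` compares the static axial-load mechanics of three anterior
cervical fusion constructs — ACDF (discectomy + interbody cage + two-level
plate), ACCF (corpectomy + titanium mesh + three-level plate), and a
modified ACDF that adds a partial rectangular osteotomy of the diseased
vertebra — across three bone-quality conditions (normal bone mass,
osteopenia, osteoporosis) and three axial preloads (100, 150, 200 N).
The quantity of clinical interest is the stress and displacement pattern
on the superior surface of the vertebra that supports the implant (C5
for the two-level constructs, C6 for ACCF), a proxy for implant
subsidence and vertebral collapse risk.

The mechanical model is deliberately the simplest one that supports
those comparisons: small-strain, isotropic, linear elasticity, solved as
a single static load step. There is no contact, no material or geometric
nonlinearity, no failure criterion, and no flexion/extension/rotation
load case; the model answers questions about *relative* stiffness and
stress localization of the constructs, not about absolute failure loads.

## Idealized geometry instead of patient CT

Patient-specific models of this kind are normally segmented from CT.
No such geometry ships with this package; instead the geometry module
generates an idealized, fully parametric stand-in on a regular voxel
grid (default 1 mm):

* vertebral bodies: rectangular cross-section, 24 mm (ML) x 16 mm (AP)
  x 12 mm tall by default, as a 1-voxel cortical shell around a
  cancellous core, capped by 1-voxel bony endplates;
* discs: 5 mm tall, a 1-voxel cartilaginous endplate above and below an
  annulus ring with a central nucleus occupying about 40 % of the
  cross-section (the rectangle is parity-adjusted so the model stays
  mirror-symmetric about the mid-sagittal plane);
* posterior elements (laminae, pedicles, facets) are omitted: the load
  path studied is the axial column through the body and implant, and
  the monitored surface lies on the body. The `articular_cartilage`
  role exists for configured variants but is unused by default.

Surgical edits are boolean operations on the label grid, using the
catalogue implant dimensions: PEEK cage 5 x 14 x 16 mm; titanium mesh
outer/inner diameter 10/8 mm; corpectomy channel 15 mm; osteotomy notch
8 mm (ML) x 9 mm (AP); plates 1 x 20 x 16 mm and 1 x 22 x 16 mm; four
4 x 14 mm screws; 1 mm anterior clearance for cage and mesh. Every
centred feature is rasterized symmetrically (voxel centres within the
half-width, ties included), which bounds the rasterization error of any
implant dimension by one voxel but can round an odd width (the 15 mm
channel) up by one voxel on the even-width default grid.

Three geometric decisions deserve emphasis because the catalogue
dimensions cannot all be realised literally on any C4–C6 segment:

* **Mesh length.** The catalogue titanium mesh length (50 mm) exceeds
  the C4–C6 defect (~22 mm here); the cylinder is truncated to span the
  C6 superior to C4 inferior endplates, which is how such a mesh is cut
  to length intraoperatively.
* **Three-level plate length.** A 22 mm plate cannot physically reach
  screw anchors in both C4 and C6 across a ~46 mm stack. The plate keeps
  its printed width and thickness but is extended cranio-caudally so its
  end screws (inset 3 mm from the plate ends) land in the anchor
  vertebrae's cancellous cores. The two-level 20 mm plate fits as
  printed.
* **ACCF disc resection corridor.** Removing both discs entirely would
  leave the residual lateral C5 columns attached to nothing — a
  mechanism the static model cannot represent (and a configuration the
  mesher rightly rejects as disconnected). Disc resection is therefore
  limited to the ML width of the decompression corridor, which is also
  what the anterior surgical access permits; the lateral disc tissue
  keeps the lateral columns load-bearing.

Two further defaults that no catalogue or convention dictates: the
osteotomy notch
opens through the posterior wall (that is the access corridor to a
retro-vertebral ossified mass) and reaches half the body height; both
are configurable (`notch_depth`, `osteotomy_notch`). Screws are placed
symmetrically 4.5 mm off the midline; because a buried screw replaces
the bone along its track, the default Mod ACDF screws graze the notch
margin over a few voxels, which we accept rather than move hardware
away from its clinical position.

The titanium mesh annulus is rasterized by *coverage* (a voxel is
titanium if its cross-section box intersects the open ring
`4 < r < 5` mm): at 1 mm voxels a centre-in-ring rule leaves the 1 mm
wall corner-connected in places, i.e. locally hinged.

## Finite elements and numerics

One 8-node trilinear hexahedron per non-air voxel, full 2 x 2 x 2 Gauss
quadrature, no reduced integration (aspect ratios are 1, so locking and
hourglassing are not concerns at these Poisson ratios). Because all
elements are identical axis-aligned cubes, one element matrix per
material suffices and assembly is a vectorized scatter-add into a
sparse symmetric matrix.

* **Tied interfaces.** Adjacent voxels share nodes, so *every*
  interface — bone–implant included — is perfectly bonded. This
  replaces frictionless sliding contact and is the principal fidelity
  gap of the model: it stiffens the constructs and suppresses
  micromotion, so absolute displacements are underestimates.
* **Materials.** Isotropic linear elasticity from the tissue table
  (cortical 12 000 MPa/0.30, cancellous 450/0.25, bony endplate as
  cortical, cartilaginous endplate 25/0.4, annulus 4.2/0.45, nucleus
  1 MPa, titanium 110 000/0.36, PEEK 3 600/0.30). The nucleus Poisson
  ratio of 0.50 is singular for a displacement formulation and is
  clamped to 0.499, preserving near-incompressibility without a mixed
  element. Bone quality degrades only the bone moduli: osteopenia
  retains 67 % (cortical, endplate, cancellous), osteoporosis retains
  67 % of cortical/endplate and 33 % of cancellous stiffness; the
  stored values are the tabulated integers and the round-half-up rule
  `floor(E * factor + 0.5)` reproduces each of them (8 040, 302, 149).
* **Boundary conditions.** All nodes of the caudal vertebra's lower
  surface are fixed in all directions; the preload is applied in −z on
  the superior surface of C4 by area-tributary lumping (corner : edge :
  interior weights 1 : 2 : 4), which conserves the resultant exactly.
* **Solver.** Constraints are eliminated (not penalized), so reactions
  are exact; the reduced SPD system is factorized by supernodal sparse
  Cholesky (CHOLMOD through the Matrix package) and polished by
  iterative refinement until the relative residual is at or below
  1e-10 — one refinement step is typically needed because the material
  contrast (titanium : nucleus ≈ 1e5) inflates the first residual.
  Stresses are recovered at element centroids; monitored-point values
  are therefore element values, avoiding nodal extrapolation artifacts
  exactly where the monitored points sit (material interfaces).
* **Verification.** The element passes the patch test (affine fields
  exact to 1e-10), carries exactly six rigid-body modes, matches the
  closed-form uniaxial bar (`delta = FL/EA`, `sigma = F/A`) and the
  two-material springs-in-series bar to well below 0.5 %, and the
  affine bar solution is mesh-size independent. Reactions balance the
  applied load to better than 1e-8 relative in every grid cell.

## Monitored points

Clinical FE reports of this kind mark a handful of extreme points on
the monitored surface by hand, without coordinates. To make that
reproducible, the package selects the
monitored surface (the topmost bone element of each (x, y) column of
the monitored vertebra, so the osteotomy floor is included) and takes
the top-16 elements by Von Mises stress and, separately, the top-16 by
displacement magnitude, with ties broken in lexicographic (z, y, x)
centroid order. Both channels are kept (`k = 16` each) rather than
splitting one set of 16 across them. No claim is made that these
coincide with any hand-picked figure points; they are the algorithmic
analogue.

## Experiment grid and statistics

`run_grid()` runs the 27-cell factorial. Within a surgery x quality
family the stiffness matrix is load-independent, so its factorization
is computed once and reused across the three loads — a
correctness-preserving optimization that also makes the exact 1.5x / 2x
load-linearity of the solution a structural property worth asserting
(to 1e-10) rather than an approximation.

The comparison layer follows the conventional clinical analysis plan:
Shapiro-Wilk
normality per group at alpha = 0.05 gates one-way ANOVA versus
Kruskal-Wallis; pairwise post-hocs (Welch t or two-group
Kruskal-Wallis) are Bonferroni-adjusted, Bonferroni being our choice
of multiplicity correction. The Kruskal-Wallis p-value is exact
(full enumeration of distinct group assignments) whenever the
assignment count is at most 1e5, and chi-square otherwise; the Monte
Carlo seed default is 20230801. Treating the 16 monitored points of a
deterministic field as a statistical sample is pseudo-replication;
every generated report carries that caveat and all p-values are
descriptive only.

## What the synthetic geometry does and does not show

The generator reproduces the *topology* of the surgical constructs and
the layered tissue architecture, which is what drives the qualitative
results: the displacement ordering ACDF < Mod ACDF < ACCF in all nine
quality x load conditions, displacement growth with bone loss, peak
stress at the posterior osteotomy notch corners for Mod ACDF, and peak
stress on the posterior half of the C6 surface for ACCF (the anterior
plate and anteriorly placed mesh shift the load path so the eccentric
load tips onto the posterior mesh rim). It does not reproduce
patient-specific anatomy: curved endplates, the uncinate processes,
posterior elements, ligaments, lordotic alignment, or CT-calibrated
density maps. Consequently absolute magnitudes (stress in MPa,
displacement in um) and any statistic/p-value computed from them are
*not* comparable to a patient-derived model, and the package makes no
such claim anywhere; only orderings and localizations are meaningful,
and those are what the test suite asserts.

## Problem sizes and defaults

Default voxel size 1 mm gives ~10 700 elements (two-level constructs)
to ~13 900 (ACCF), i.e. 37 000–52 000 degrees of freedom per family;
the full 27-cell grid solves in well under a minute on one core, and
halving the voxel size (8x elements) remains desk-scale. Units are mm,
N and MPa throughout; displacements are reported in micrometres
(1 mm = 1000 um). Loads outside {100, 150, 200} N, other level counts,
notch sizes, and all implant dimensions are plain arguments to
`segment_spec()` / `surgical_plan()`.

## Known limitations

* Tied interfaces (no contact, no friction, no fusion-gap micromotion);
  consequently no cage subsidence *mechanism*, only its elastic
  precursor (surface displacement).
* Isotropic, homogeneous tissues; no density-mapped cancellous bone,
  no strain-rate or damage behaviour, no destructive load search.
* Axial compression only; bending, torsion and physiologic motion are
  out of scope.
* Rectangular body cross-sections; an elliptical option would change
  magnitudes but not the construct orderings the model is built to
  compare.
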