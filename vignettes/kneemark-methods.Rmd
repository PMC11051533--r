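---
title: "Automated knee landmarking and morphometry: models, parameters and design"
author: "kneemark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated knee landmarking and morphometry: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Morphometric characterization of the knee — implant sizing, meniscal
allograft matching, morphological risk-factor studies — rests on a small set
of named anatomical landmarks on the distal femur and proximal tibia, from
which linear sizes of the medial and lateral compartments are derived.
Manual annotation of these landmarks on 3D bone+cartilage surface meshes is
slow and shows substantial intra- and inter-observer scatter. `kneemark`
implements a fully automated alternative: dense anatomical correspondences
are established by deforming a template mesh onto every subject; expert
annotations are pooled through those correspondences onto a cohort mean
shape; mean landmark positions are propagated back to each subject; and
landmarks defined as locally extreme points are refined to the exact
extremal mesh vertex. Linear measurements are then axis projections in a
reference frame anchored on the femoral posterior condylar line, and a full
agreement-statistics toolbox (quartiles with the 1.5 IQR outlier rule,
two-way ANOVA intraclass correlation, Bland–Altman limits, success-rate
curves) quantifies intra-observer, inter-observer and manual-vs-automated
variability.

No clinical meshes ship with the package. A synthetic phantom generator
produces condyle-like surfaces with analytic ground truth, so every stage —
registration, propagation, refinement, measurement, statistics — is
exercised and validated end to end by the test suite.

## Surface representation and mesh machinery

Surfaces are triangle meshes (`triangle_mesh`): an n×3 vertex matrix in
millimetres and an m×3 face matrix of 1-based indices. Readers exist for
PLY (ascii and binary little-endian), STL (ascii and binary; STL stores no
shared vertices, so soups are always welded) and OBJ `v`/`f` records.
Duplicate vertices within 1e-6 mm are welded on load; meshes that remain
disconnected keep their largest component with a warning, since a
single-bone scan segmentation should be one surface. Coordinates are
treated as millimetres throughout; no unit conversion is attempted.

Geodesic quantities are approximated by shortest paths on the edge graph
with Euclidean edge weights. This underestimates true polyhedral geodesic
distances by at most a small factor on near-isotropic meshes and is entirely
sufficient for its one job here: bounding the search region of landmark
refinement. The approximation is monotone in the radius by construction,
which the refinement inherits.

Isotropic remeshing (template preparation) uses the classical cycle — split
edges longer than 4/3 of the target, collapse edges shorter than 4/5,
valence-equalizing flips, tangential smoothing with back-projection onto
the input surface. Boundary rims of cropped scans are never collapsed,
flipped or smoothed. The vertex count is approximate by design; mesh
resolution, not an exact count, is the quantity that matters downstream.

## Registration

**Rigid stage.** Iterative closest point with point-to-surface
correspondences (exact point-to-triangle projection, grid-accelerated) and
a closed-form Kabsch update. Projection-based ICP can stall with purely
tangential residuals, so a short Gauss–Newton polish on the linearized
point-to-plane objective finishes the alignment; on clean data this
recovers a known pose essentially to machine precision.

**Elastic stage.** The template is deformed by a per-vertex displacement
field `d` minimizing

$$\sum_i w_i\,\lVert v_i + d_i - c_i\rVert^2
  \;+\; \alpha \sum_{(i,j)\in E} \lVert d_i - d_j\rVert^2 ,$$

where `c_i` is the closest compatible point on the target surface and the
second sum runs over template edges (graph-Laplacian stiffness). A
correspondence is rejected (`w_i = 0`) when it is farther than
`max_corr_distance` (default 10 mm), when the target normal deviates from
the deforming template's vertex normal by more than
`normal_compat_threshold` (default 60°), or when a template boundary vertex
matches the target's boundary rim — open rims come from field-of-view
cropping and carry no anatomical correspondence. A symmetric data term
additionally pulls the barycentric footprint of each target vertex on the
deforming template toward that target vertex; one-way closest-point terms
cannot observe tangential sliding over gently curved regions, and the
symmetric term counteracts it. The stiffness `α` is relaxed over 8 steps,
halving from 100 to about 0.8, so global alignment happens first and local
detail last; each step runs up to 3 match/solve sweeps of the sparse
(Cholesky) normal equations and stops early when the maximum vertex motion
falls below `convergence_tol` (default 0.01 mm). The recorded objective
(data + symmetric + smoothness) is non-increasing within a stiffness level
as long as no correspondences are gated in or out, which the test suite
checks on closed surfaces.

The deformed template *is* the corresponded mesh: vertex `i` denotes the
same anatomical location on every subject. Correspondence quality is
monitored by the per-vertex residual distance to the target (a warning
fires when fewer than 95% of vertices land within `max_corr_distance`) and
by a triangle-distortion report: the condition number of the 2D affine map
from each template triangle to its deformed image, which is 1 exactly for
similarity transforms and flags badly sheared triangles (default threshold
5).

**Two-pass scheme.** An arbitrary subject (by default the first) is
remeshed isotropically and registered to every subject; the vertex-wise
mean of the deformed meshes is the cohort mean shape; the mean shape is
then re-registered to every subject, and those second-pass correspondences
are the working set. The mean template is closer to every cohort member
than an arbitrary subject is, so pass-2 residuals are at least as good on
average — asserted in the tests rather than assumed.

## Landmarks

The catalog holds 23 named landmarks (15 femoral, 8 tibial). Each entry
is either *extremum-defined* — it carries a reference-frame axis and sense,
e.g. the posterior condyle points are minima of the anteroposterior
coordinate — or a *construction* (`refine_axis = "none"`) defined on
specific image views or by fractions of the notch depth; constructions are
propagated through correspondences without refinement, because only
genuinely extremal positions can be re-optimized from geometry alone.

Two catalog choices deserve their rationale spelled out:

* **Epicondyles (FME/FLE).** Their textual definition names an anterodistal
  prominence on the medial/lateral aspect. On a convex femoral flank the
  anterior coordinate has no local extremum: a bounded anterior argmax
  drifts to the search-radius rim, and an unbounded one walks onto the
  trochlea, destroying the landmark's identity. The prominence itself *is*
  a mediolateral extremum, so the catalog refines FME/FLE along x (medial /
  lateral sense), with the anterior coordinate as the tie-break axis. This
  also protects the femoral mediolateral size fML, which projects exactly
  onto x.
* **Femoral notch apex.** "Most anterior point in the middle of the notch"
  is a view-constrained construction: in 3D the anterior coordinate
  restricted to the notch surface increases monotonically out of the notch
  toward the trochlea, so a coordinate argmax cannot stay inside the
  notch. The Notch landmark is therefore propagate-only.

**Propagation.** A landmark on one corresponded surface is expressed as
barycentric coordinates in its nearest triangle and evaluated in the same
triangle of any other surface with the template topology. Landmarks farther
than 5 mm from their surface trigger a warning and are projected first.

**Observer pooling.** Expert mean landmarks average each observer's repeats
first and then average across observers, so a three-repeat observer weighs
exactly as much as a single-repeat one.

**Seeding and refinement.** The pooled mean landmark is snapped to its
nearest mean-shape vertex (ties broken by lowest index, for determinism);
through the shared topology that vertex index *is* the seed on every
subject. Extremum-defined landmarks are then refined to the vertex with the
most extreme frame coordinate within a geodesic radius of the seed
(default 10 mm). The search is bounded deliberately: an unbounded "most
distal point" would jump to the other condyle on some subjects. Candidate
positions are restricted to mesh vertices — the automated landmark is
always a vertex of the subject mesh — so landmark precision is coupled to
mesh resolution. Within the search region the refinement is an exact
argmax, which makes it idempotent, monotone in the radius, and never less
extreme than its seed; these properties are tested against an independent
Dijkstra-based exhaustive-search oracle.

**Leave-one-out protocol.** When validating against manual annotations, the
seeds for a subject are built exclusively from the *other* subjects'
annotations, so the automated result is independent of the subject's own
manual labels.

## Reference frame and measurements

The scanner's proximodistal direction is taken as the mesh file's +z axis
(patients are assumed correctly positioned on the table, leaving only axial
rotation to correct). The mediolateral x axis is the unit projection of the
posterior condylar line FMCP→FLCP onto the axial plane; +x points
medial→lateral, a right-knee convention (mirror left knees to the canonical
side before templating, or set `medial_to_lateral = FALSE`). y = z × x is
anteroposterior, and the origin is the condylar midpoint. Femur and tibia
of one subject share the femur-derived frame, as the tibial side-point
definitions require. Landmark sets carry a RAW/ALIGNED flag and refuse to
be aligned twice.

Each of the 15 measurements is the absolute difference of two landmark
coordinates along one axis; the anteroposterior notch size is the mean of
its two condylar pairings, which are near-equal by construction in the
aligned frame. Every measurement is therefore bounded by the Euclidean
distance of its landmarks (projection contraction) and invariant under any
rigid motion applied before frame construction, both of which are tested.
The mediolateral notch size is computed but flagged `validated = FALSE`:
the landmark studies this catalog descends from report no reference values
for it. In validation mode the frame comes from the expert mean condylar
landmarks; a fully automated run can instead derive it from the automated
FMCP/FLCP (`frame_mode = "auto"`).

## Agreement statistics

Three comparison designs share one error definition. INTRA: each repeat of
one observer against the mean of the repeats. INTER: each observer's
(repeat-averaged) annotation against the across-observer mean. METHOD: the
automated result against the expert mean. Landmark errors are Euclidean
distances; measurement errors are absolute differences.

Quartiles use linear interpolation of order statistics (`quantile`
type 7 — the convention is stated because the outlier rule depends on it),
and observations outside [Q1 − 1.5 IQR, Q3 + 1.5 IQR] are flagged;
outlier counts are reported per subject and comparison as a robustness
diagnostic. Reliability is ICC(A,1) — absolute agreement, single rater —
from the two-way ANOVA mean squares:

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}
 {MS_R + (k-1) MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

with rows = subjects, columns = raters. The two-way *mixed* model (repeats
of one observer: raters fixed) and the two-way *random* model (different
observers or methods: raters sampled) share this point estimate for
absolute agreement; the model choice is carried as a label, and confidence
intervals (where the models diverge) are deliberately out of scope. An
all-equal table is degenerate for the ANOVA decomposition and is reported
as ICC 1 with an explicit flag. Bland–Altman limits are bias ± 1.96 SD of
the per-subject differences. Success curves are the empirical CDF of the
errors on tolerance grids of 0.5–6 mm (landmarks) and 0.25–3 mm
(measurements).

A caveat worth stating: ICC is a variance ratio. On cohorts with little
between-subject size variation — such as a small phantom cohort deformed by
only a few millimetres — even sub-millimetre method errors can yield low or
negative ICCs for individual measurements while the absolute agreement is
excellent. ICC values should always be read next to the absolute-difference
summaries.

## The synthetic phantom

Each phantom is a star-shaped surface: a base ellipsoid (semi-axes around
36 × 28 × 28 mm for the femur-like and 37 × 26 × 30 mm for the tibia-like
shape) plus smooth radial Gaussian lobes — two posterior condyles, two
distal condyles, two trochlear lobes and two epicondylar prominences with a
negative intercondylar carve for the femur; plateau eminences, posterior
rims and side prominences for the tibia — cropped by a shaft plane to
emulate a limited scan field of view. Every extremum-type landmark is
realized as a local extremum of the *continuous* surface near its lobe,
located by numerical optimization on the sphere of directions and verified
at generation time (an interior critical point, better than a surrounding
ring of directions); the generator refuses geometries whose lobes merge.
Construction landmarks sit at fixed surface directions chosen so that the
mediolateral wall points (the notch ML landmarks) lie on steep,
mediolaterally facing walls, as their anatomical counterparts do — this is
what keeps their measured x coordinates stable under tangential
correspondence scatter. Ground-truth measurements are evaluated in closed
form from the analytic landmarks in the frame of the condylar anchors; the
tibia-like phantom carries the corresponding femoral condyle points as
anchors so both bones share one frame.

Inter-subject variation is a band-limited random displacement field (a
superposition of 12 isotropic Gaussian kernels, default width 20 mm,
rescaled to an exact RMS vertex displacement, default 2 mm) applied jointly
to both bones of a knee; truth landmarks and anchors ride along with the
field. A consequence worth knowing: the displaced truth point and the
deformed surface's own coordinate extremum differ by a small tangential
offset proportional to the field gradient times the lobe curvature radius —
the same landmark-slides-but-measurement-holds dissociation seen between
human annotators on smooth bone regions. The rigid deformation mode applies
an axial rotation plus translation, the one rigid freedom a correctly
positioned knee has on the scanner table, and leaves all measurements
unchanged exactly.

Observer simulation draws, per observer, a persistent tangent-plane bias
with per-component SD `sigma_inter` (default 1.5 mm) and adds per-repeat
tangent jitter with SD `sigma_intra` (default 1.0 mm); annotations are
projected back onto the mesh, as real annotations are surface points. With
the default three-observer panel (the first observer annotating three
times) these component SDs reproduce inter- and intra-observer mean error
magnitudes in the ~1.5 mm and ~1 mm ranges reported for manual knee
landmarking. Tangent-plane noise is a deliberate simplification: real
observers also disagree systematically about landmark *definitions*, a
component no isotropic noise model captures, so passing phantom tests
bounds algorithmic error, not clinical inter-observer psychology.

## Study conditions and problem sizes

The rehearsal used by the test suite and the acceptance script runs 6
deformed subjects (deformation 2 mm RMS at 20 mm smoothness), observer
sigmas 1.0/1.5 mm, base seed 42, and phantoms at 2.5 mm target edge length
(about 2,000 vertices per bone after cropping). These sizes keep a full
two-bone, two-pass, leave-one-out rehearsal around a minute on one CPU
while staying in the regime where landmark candidates being mesh vertices
is a visible (realistic) error term.

Mesh resolution is the single most consequential parameter of the whole
pipeline, and it trades the two headline behaviours against each other.
Finer templates make the refined landmarks more precise — at roughly 2 mm
edges the automated method becomes *more* accurate than the simulated
inter-observer spread, at which point the classical ordering
INTRA < INTER < METHOD inverts for landmarks; coarser templates preserve
that ordering but fatten the tangential tails of vertex-snapped extremum
landmarks, which surface as occasional >2 mm errors in the mediolateral
measurements (the posterior condylar line is the most exposed, since it
reads the x coordinate of two anteroposterior extrema). At the default
resolution both behaviours hold simultaneously on the default conditions,
with a slim margin on the ordering — the margin itself is informative: it
is exactly the regime the method operates in on clinical data.

## Numerical choices and degenerate inputs

* Determinism: every stochastic component (phantom deformation, observer
  simulation, rehearsal) takes an explicit seed and restores the caller's
  RNG state; equal seeds give bit-identical output on a fixed platform.
* Ties: nearest-vertex snapping and extremum refinement break exact ties by
  the secondary catalog axis, then by lowest vertex index.
* Frames must be orthonormal and right-handed to 1e-8; a condylar line
  parallel to the table axis is a degenerate-frame error, as is re-aligning
  an ALIGNED landmark set.
* Degenerate deformed triangles get distortion ∞ and are flagged rather
  than crashing the report; all-equal ICC tables return 1 with a
  `degenerate` flag; empty error vectors are errors, not NaNs.
* Remeshing refuses targets larger than half the bounding-box diagonal
  (the mesh would degenerate) and collapses are rejected when they would
  violate the link condition or create over-long edges.

## Known limitations

* Phantoms are stylized, not anatomically exact: smooth, star-shaped,
  single-material surfaces. Passing the phantom rehearsal demonstrates
  correct mechanics and parameter recovery under controlled conditions; it
  does not certify accuracy on clinical MRI segmentations, whose
  resolution, surface noise and anatomical ambiguity are harsher.
* Landmark candidates are mesh vertices; sub-vertex refinement (e.g.
  generalized barycentric interpolation) is out of scope, so accuracy is
  bounded by edge length.
* The elastic model is a translation field with graph-Laplacian stiffness —
  adequate for few-millimetre shape differences, but large pose or shape
  changes would need a richer (per-vertex affine) model.
* No statistical shape model is built; correspondences are the product,
  not PCA of them.
* ICC confidence intervals and hypothesis tests are not computed.
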