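---
title: "Curvature-based local analysis of cortical surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-based local analysis of cortical surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corticurv)
```

## The problem

The cerebral cortex is a folded sheet: outward ridges (gyri) and inward
fissures (sulci) carry most of the anatomically and functionally meaningful
landmarks, but their shape varies strongly across individuals.  A standard
way to parcellate a cortical surface objectively is to (1) segment the
gray/white-matter interface from a T1-weighted volume, (2) triangulate it,
(3) simplify the triangulation so that only the main folds remain, and
(4) classify every vertex by its local differential geometry — convex
elliptic points lie on gyral crests, concave elliptic points in sulcal
fundi, and hyperbolic (saddle) points on the walls between them.
`corticurv` implements this chain end to end, together with synthetic
phantoms whose geometry is known analytically, so that every stage can be
verified quantitatively on a desk machine without any imaging data.

## Segmentation: the level-set model

The interface is found as the zero set of a scalar field $\psi$ (positive
inside by our convention) evolving under

$$\frac{\partial \psi}{\partial t}
  = \bigl[\alpha_r F_{\mathrm{region}}(I) + \alpha_b F_{\mathrm{boundary}}(I)\bigr]\,
    \lvert\nabla\psi\rvert .$$

The region speed is a tent function of the image intensity $I$,

$$F_{\mathrm{region}}(I) =
  \begin{cases} I - (m_T - \epsilon_T), & I < m_T\\
                (m_T + \epsilon_T) - I, & \text{otherwise,}\end{cases}$$

positive exactly inside the intensity band
$(m_T-\epsilon_T,\, m_T+\epsilon_T)$ of the target tissue ($m_T$ = mean
target intensity, $\epsilon_T$ = band half-width, both in intensity
units), so the front grows into the band and retreats elsewhere.  The
boundary speed
$\pm\,(c + k)/(1 + \lvert\nabla I\rvert)$ anchors the front at image
edges — its magnitude vanishes where the image gradient is large — with the
sign $+1$ wherever $F_{\mathrm{region}} < 0$ and $-1$ otherwise, so it
always opposes region-term overshoot.  Here $k$ is the mean curvature of
the moving front, $k = \nabla\!\cdot\!\bigl(\nabla\psi/\lvert\nabla\psi\rvert\bigr)$,
acting as a regularizer, and $c$ a constant advection speed.  The printed
form of this speed in the source literature is typographically ambiguous;
we adopt the $(c+k)/(1+\lvert\nabla I\rvert)$ reading, which is the
standard geodesic-active-contour factorization, and keep the whole term in
one function (`boundary_speed()`) so an alternative reading could be
swapped in at a single site.

Numerical choices, all of which matter for reproducibility:

* explicit Euler stepping with Godunov upwinding of
  $\lvert\nabla\psi\rvert$ and central differences for $k$;
* $\psi$ initialized as the signed distance transform of a
  band-threshold-plus-largest-component mask (`threshold_init_mask()`),
  optionally eroded so the front starts strictly inside the tissue;
* time step `dt = 0.1 * min(spacing)` and re-initialization of $\psi$ to a
  signed distance every 5 iterations.  The region term makes
  characteristics collide at the band boundary, which steepens
  $\lvert\nabla\psi\rvert$ without bound; re-initializing this often keeps
  the explicit step inside the stability region.  The front-curvature
  regularizer is clamped at $1/\text{voxel}$ — anything sharper is
  discretization noise.  A step that would move the field by more than
  half a voxel raises an error naming `dt` rather than silently clamping;
* convergence is declared when the mean front movement between
  re-initializations falls below $10^{-3}$ voxels;
* with $\alpha_r = \alpha_b = 0$ the front is returned frozen — a useful
  null case in tests.

## Surface extraction

`extract_isosurface()` triangulates an isosurface of the voxel grid by
splitting every cell into six tetrahedra that all share the cell's main
diagonal (the Kuhn decomposition).  Because the split is
translation-invariant, the triangulated faces of neighbouring cells match
exactly and the output is watertight and consistently oriented by
construction, with no ambiguous configurations to resolve — the reason we
chose the tetrahedral variant of the classic cube-table isosurface
algorithm.  Triangle orientation points from the above-isovalue side to
the below-isovalue side, which for a level-set field (positive inside)
extracted at 0 is the outward orientation.  Vertices are placed by linear
interpolation along crossing edges and reported in world millimetres
(`origin + 0-based index * spacing`, grid vertex at the voxel centre), so
all curvatures downstream come out in physical units (1/mm).

Segmentation debris is removed with `remove_small_components()` (the
pipeline default keeps only the largest component — the cortex interface
is one closed surface), and voxelization staircase is smoothed by
`smooth_mesh()`, a two-factor shrink/inflate (Taubin-style) smoother with
defaults 0.5/−0.53.  The factors nearly cancel at low spatial frequency,
so the enclosed volume and area are almost preserved while the
grid-frequency staircase is annihilated; connectivity is never touched.
One caveat the tests make explicit: the *area* of a surface tessellated
directly from two-level (binary) data overestimates the true area by tens
of percent regardless of the extraction algorithm — that is a property of
voxelization, not of the mesh generator — and only after anti-alias
smoothing (or when extracting from a smooth field such as a signed
distance) is the analytic area recovered to within a few percent.
Smoothing is applied before decimation in the pipeline; the order is
configurable.

## Decimation: quadric edge collapse

`quadric_decimate()` simplifies by repeated edge collapse ordered by a
priority queue of quadric error costs.  Every face contributes the
area-weighted plane quadric $Q_f = A_f\, p\,p^{\mathsf T}$ with
$p = (n, -n\cdot x)$; a vertex carries the sum over its incident faces;
and after a collapse the merged vertex inherits $Q_a + Q_b$ (the additive
rule — quadrics are never re-accumulated from the simplified geometry).
The collapse point minimizes the combined quadric by solving its 3×3
normal equations, falling back to the best of the two endpoints and the
midpoint when the system is ill-conditioned (`rcond < 1e-10`, e.g. on
perfectly flat patches).

Bookkeeping decisions:

* lazy deletion with per-vertex version counters — a popped queue entry is
  discarded if either endpoint's version has moved on;
* exact ties in cost are broken by the (min index, max index) vertex pair,
  which makes the collapse sequence fully reproducible (the test suite
  compares it step by step against an independent brute-force
  implementation that rescans every edge at every step);
* the topology guard is the standard link condition — the one-rings of the
  endpoints may intersect in exactly the two vertices opposite the edge,
  and those two vertices must not close a tetrahedron-like pocket with
  both endpoints.  With the guard on, the Euler characteristic and the
  component count are invariant, and meshes as small as the tetrahedron
  are (correctly) irreducible.  With the guard off, collapses proceed
  regardless, which a user may want to simplify uninteresting subareas
  aggressively;
* a rejected edge can become collapsible again after a nearby collapse
  without its endpoints' versions changing, so when the queue drains
  before the target is reached the decimator re-seeds the queue from the
  surviving edges (a bounded number of times) before declaring the
  reduction blocked;
* "reduction" is the fraction of *faces* removed — the convention of the
  decimation literature; the log also reports the resulting vertex
  fraction since published figures do not always say which is meant.

## Curvature: discrete differential geometry

For a vertex $x_i$ with one-ring neighbours $x_j$, mixed area $A_M$
(Voronoi corner areas, with the $T/2$–$T/4$ split for obtuse triangles so
that the areas still tile the surface exactly):

$$\mathbf{K}(x_i) = \frac{1}{2A_M}\sum_{j}
   (\cot\alpha_{ij} + \cot\beta_{ij})\,(x_i - x_j),
   \qquad K_H = \tfrac12\lVert\mathbf{K}\rVert,$$

$$K_G(x_i) = \frac{2\pi - \sum_j \theta_j}{A_M},$$

with $\alpha_{ij}, \beta_{ij}$ the angles opposite the edge $(i,j)$ in its
two faces and $\theta_j$ the incident face angles.  Principal curvatures
follow as $k_{\max,\min} = K_H \pm \Delta$,
$\Delta = \sqrt{\max(K_H^2 - K_G,\, 0)}$ (the clamp handles the discrete
case $K_H^2 < K_G$, where both are set to $K_H$), and the shape index is

$$SI = -\frac{2}{\pi}\arctan
  \frac{k_{\max} + k_{\min}}{k_{\max} - k_{\min}} \in [-1, 1],$$

with the umbilic limit $SI = -\operatorname{sign}(k_{\max})$ and flat
points ($k_{\max} = k_{\min} = 0$) marked undefined rather than raising an
error.  A published variant of the $\Delta$ term
($\max(K_H^2 - K_G^2, 0)$, without the square root) circulates in the
literature; it is dimensionally inconsistent (1/mm² vs 1/mm) and is
available only behind `printed_delta = TRUE` for comparability — the
corrected form is the default.

**Sign convention.**  The cotangent formula yields a curvature *magnitude*;
the classification table needs a sign.  We fix it by projecting the
mean-curvature vector on the outward vertex normal such that a convex
closed surface (a gyral crest seen from outside) has $K_H < 0$ and
$SI = +1$, concave regions $K_H > 0$ and $SI = -1$.  This is the only
convention under which the leading minus sign of the shape-index formula,
the class table below, and the verbal rule "negative shape-index values
are concave" are simultaneously consistent.

Numerical safeguards: cotangents are computed as $\cos/\sin$ with the sine
floored at $10^{-12}$; triangles with aspect ratio above $10^5$ trigger a
mesh-quality warning; zero-area faces are an error naming the face.
Boundary vertices of open meshes get `NA` differentials and a flag — the
pipeline's meshes are closed, so this never triggers there.

Verified invariants (all in the test suite): mixed areas sum exactly to
the surface area; $\sum_i K_G A_M = 2\pi\chi$ to floating-point accuracy
on every closed fixture (sphere $\chi=2$, torus $\chi=0$); rigid motions
change nothing to $10^{-9}$; scaling by $s$ scales $K_H$ by $1/s$, $K_G$
by $1/s^2$ and leaves $SI$ untouched; on icospheres of radius 5 mm the
operators recover $K_H = 0.2\,\mathrm{mm}^{-1}$ and
$K_G = 0.04\,\mathrm{mm}^{-2}$ within 2% at subdivision 4, with errors
shrinking monotonically under refinement.

## Classification

Each defined vertex is assigned one of four classes from the signs of
$K_H$ and $K_G$, optionally gated by the shape-index interval
(`mode = "strict"`):

| class            | sign $K_H$ | sign $K_G$ | $SI$ interval        | color | anatomy        |
|------------------|-----------|-----------|----------------------|-------|----------------|
| ELLIPTIC_GREEN   | −         | +         | $[3/8,\,1]$          | green | gyral crest    |
| HYPERBOLIC_CYAN  | −         | −         | $[1/8,\,3/8]$        | cyan  | gyral saddle   |
| HYPERBOLIC_BLUE  | +         | −         | $[-3/8,\,-1/8]$      | blue  | sulcal wall    |
| ELLIPTIC_RED     | +         | +         | $[-1,\,-5/8]$        | red   | sulcal fundus  |

Design points that were genuinely open and how we resolved them:

* the class/color table above is taken as canonical; the narrative color
  assignments that accompany such tables in the literature contradict one
  another, and only the tabular form is complete;
* the fourth $SI$ interval is printed reversed in the source literature
  ("[−5/8, −1]"); we read it as $[-1, -5/8]$;
* the $SI$ gaps $(-5/8, -3/8)$ and $(-1/8, 1/8)$ are mapped to
  `UNCLASSIFIED` in strict mode — nothing prescribes a class there;
* curvature magnitudes below `zero_tol` (default
  $10^{-6}/\bar{\ell}$ with $\bar{\ell}$ the mean edge length, i.e. scale
  aware) are treated as sign zero and left unclassified: the sign of a
  near-zero curvature is numerical noise;
* the default mode is `sign_only` (robust); `strict` reproduces the
  table faithfully.  A per-vertex `consistent` flag records whether the
  two modes agree, and the labeling reports both the class histogram and
  mixed-area-weighted area fractions.

`multires_label_agreement()` quantifies how well a parcellation survives
simplification: each coarse vertex is matched to its nearest
full-resolution vertex and the fraction of class-equal pairs is reported
(unclassified pairs are excluded and counted separately).  On the folded
phantom, agreement stays above 0.9 at 50% reduction and both elliptic
classes and the crest/fundus landmark majorities survive 70% reduction —
the quantitative form of the qualitative claim that the main folds remain
identifiable on strongly simplified meshes.

## The phantoms, and what they do not show

`sphere_volume()` (two-intensity ball, optional seeded Gaussian noise),
`icosphere_mesh()` (analytic curvature oracle), `torus_mesh()` (mixed-sign
Gaussian curvature, genus 1), `folded_phantom_mesh()` (sphere with radial
displacement $A\sin f\theta\,\sin f\varphi$, crest/fundus landmark sets
thresholded at $\pm 0.8A$ of the analytic displacement) and
`folded_phantom_volume()` (its voxelization) define the study conditions
for every test: default base radius 10 mm, fold frequency 6, amplitude
2 mm, subdivisions 4 (5120 faces) — folds of roughly 5 mm wavelength on a
brain-scale ball, comfortably resolved by the ~0.66 mm mesh edge length.
Noise, when requested, is additive Gaussian and seeded: the simplest
stationary corruption consistent with MRI-like testing.

What passing on phantoms does and does not show: the operators, the
simplifier and the pipeline plumbing are correct on closed, smooth,
noise-controlled geometry with known ground truth.  Real MR volumes add
bias fields, partial-volume voxels, topology defects and much thinner,
branching sulci; none of these are emulated (deliberately — see
Non-goals), so quantitative behaviour on clinical data is *not* implied.
One empirical subtlety the phantom study surfaced: the elliptic-green
(gyral) *area fraction* is not monotone in fold amplitude — deepening the
folds steepens crests but also grows the saddle walls — whereas the mean
$\lvert K_H\rvert$ over the crest landmarks is monotone, and that is the
quantity the tests pin down.

## Problem sizes and runtimes

The test and acceptance workloads were sized for a single desk-class CPU
core: segmentation grids of $25^3$–$29^3$ voxels, meshes of 20–11 000
faces, decimation from 5120 faces, shape-index grids of $4\times 10^4$
pairs.  The complete suite runs in about a minute; the acceptance script
in well under one.

## Indexing and file formats

Meshes are 1-based inside the package — the natural indexing of R, matching
how every matrix subscript in the code reads — and the PLY/OFF/VTK writers
and readers translate to the formats' 0-based indices at the boundary.
Volumes travel as NIfTI (spacing in `pixdim`, origin in the qform offset),
labelings as CSV plus colored PLY, summaries and provenance as JSON.  Mesh
coordinates are written with 17 significant digits, so geometry
round-trips bit-faithfully for doubles.

## Known limitations

* The segmenter is single-phase and needs a usable intensity band; it does
  not correct topology, so a noisy segmentation can yield a genus > 0
  surface (the extraction and classification still work; only the
  sphere-specific checks assume genus 0).
* `quadric_decimate()` is pure R; it simplifies 5120 faces by 50% in a few
  seconds, which is fine for the intended mesh sizes but far from the
  throughput of compiled implementations.
* Nearest-vertex label transfer across resolutions is a point match, not a
  surface projection; on extremely coarse meshes it under-estimates
  agreement near class boundaries.
* Connected sulcal/gyral *region* extraction (grouping same-class
  vertices into named structures) is out of scope.
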