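# corticurv

Curvature-based local analysis of cortical surfaces in R.

The cerebral cortex is a folded sheet whose ridges (gyri) and fissures
(sulci) are the landmarks of brain mapping, but delineating them by hand is
slow and irreproducible. `corticurv` automates the standard
differential-geometry route for neuroimaging researchers and method
developers: segment the gray/white-matter interface from an intensity
volume with a level-set model, triangulate it, simplify the triangulation
into a multiresolution hierarchy so only the main folds remain, and
classify every vertex by its local curvature into gyral/sulcal surface
types. Synthetic phantoms with analytic ground truth make the whole chain
quantitatively testable without any imaging data.

## The model in brief

**Segmentation.** The interface is the zero set of a field ψ (positive
inside) evolving by
∂ψ/∂t = [α_r F_region(I) + α_b F_boundary(I)] |∇ψ|, where
F_region(I) = I − (m_T − ε_T) for I < m_T and (m_T + ε_T) − I otherwise
(positive exactly in the target intensity band), and
F_boundary = ±(c + k)/(1 + |∇I|) anchors the front at image edges, with k
the front mean curvature and the sign +1 wherever F_region < 0.

**Curvature.** At each vertex, the cotangent one-ring operator gives the
mean curvature K_H = ||Σ_j (cot α_ij + cot β_ij)(x_i − x_j)|| / (4 A_M),
the angle deficit gives the Gaussian curvature
K_G = (2π − Σ_j θ_j)/A_M (A_M = mixed Voronoi area), principal curvatures
are k_max,min = K_H ± √(max(K_H² − K_G, 0)), and the shape index
SI = −(2/π)·arctan((k_max + k_min)/(k_max − k_min)) ∈ [−1, 1] is
translation-, rotation- and scale-invariant. Convention: convex (gyral)
regions have K_H < 0 and SI → +1; concave (sulcal) regions K_H > 0 and
SI → −1.

**Classification.** Sign pairs (K_H, K_G) map to four classes —
(−,+) elliptic/green (crest), (−,−) hyperbolic/cyan, (+,−) hyperbolic/blue,
(+,+) elliptic/red (fundus) — optionally gated by the SI intervals
[3/8, 1], [1/8, 3/8], [−3/8, −1/8], [−1, −5/8] in strict mode.

**Simplification.** Quadric-error-metric edge collapse with a lazy priority
queue, deterministic tie-breaking, and the link condition as an optional
topology guard, producing the 0% / 50% / 70% hierarchy on which labels are
compared across resolutions.

## Worked example

Generate a folded "cortex-like" phantom, compute its per-vertex
differentials, classify it, then check that the parcellation survives a
50% decimation:

```r
library(corticurv)

phantom <- folded_phantom_mesh(base_radius = 10, fold_frequency = 6,
                               fold_amplitude = 2, subdivisions = 3)
phantom
#> <triangle_mesh: 642 vertices, 1280 faces, chi = 2>

diffs <- vertex_differentials(phantom)
print(diffs, n = 3)
#> # A tibble: 642 × 11
#>   vertex   a_m k_h_mag k_h_signed    k_g k_max  k_min delta    si boundary flat
#>    <int> <dbl>   <dbl>      <dbl>  <dbl> <dbl>  <dbl> <dbl> <dbl> <lgl>    <lgl>
#> 1      1  2.11   0.109     -0.109 -0.192 0.342 -0.561 0.451 0.151 FALSE    FALSE
#> 2      2  2.11   0.109     -0.109 -0.192 0.342 -0.561 0.451 0.151 FALSE    FALSE
#> 3      3  2.11   0.109     -0.109 -0.192 0.342 -0.561 0.451 0.151 FALSE    FALSE

labeling <- label_surface(phantom, diffs)
labeling
#> <surface_labeling: 642 vertices, mode = sign_only>
#>   ELLIPTIC_GREEN      204 ( 33.9% area)
#>   HYPERBOLIC_CYAN     234 ( 38.7% area)
#>   HYPERBOLIC_BLUE     100 ( 14.5% area)
#>   ELLIPTIC_RED        104 ( 12.9% area)
#>   UNCLASSIFIED          0 (  0.0% area)

coarse <- quadric_decimate(phantom, target_reduction = 0.5)
coarse
#> <triangle_mesh: 322 vertices, 640 faces, chi = 2>

lab_coarse <- label_surface(coarse, vertex_differentials(coarse))
multires_label_agreement(labeling, phantom, lab_coarse, coarse)
#> # A tibble: 1 × 4
#>   agreement n_compared n_unclassified_pairs n_coarse
#>       <dbl>      <int>                <int>    <int>
#> 1     0.894        322                    0      322
```

Reading the numbers: row 1 of the differentials is a saddle vertex
(K_G < 0, SI ≈ 0.15, i.e. a gyral-side saddle); the labeling splits the
phantom into the four surface types with no unclassified vertices; the
decimated mesh keeps exactly half the triangles with the Euler
characteristic (χ = 2, a topological sphere) intact; and 89% of coarse
vertices keep the class of their nearest full-resolution counterpart.

The same stages are scriptable from a shell via `exec/corticurv`
(`phantom`, `segment`, `extract`, `decimate`, `curvature`, `classify`,
`pipeline` subcommands), and `run_pipeline()` drives volume → labeled
multiresolution meshes end to end from a single YAML config, writing
label CSVs, colored PLYs, summaries and a provenance record.

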