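---
title: "Methods: turntable visual-hull seed phenotyping and germplasm statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: turntable visual-hull seed phenotyping and germplasm statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedhull)
```

seedhull implements a complete image-to-genetics pathway for wheat seed
phenomics: a single fixed camera photographs a seed held tip-down on a
suction nozzle while a stepper motor rotates it in 9-degree increments (40
views per revolution); a checkerboard sequence captured once on the same
rig calibrates the geometry; silhouettes carved against the calibrated
views yield a 3D model from which nine morphometric traits are measured;
and a statistics layer turns per-seed trait tables into germplasm-level
variation summaries. This vignette records the model assumptions, the
tunable parameters, the numerical choices, and what the synthetic test
battery does and does not establish about real data.

## Camera model and rig calibration

The camera is a distortion-free pinhole with skew. World points $X_w$ (mm)
map to pixels through the $3\times4$ projection matrix

$$ P = K\,[R \mid T], \qquad
K = \begin{pmatrix} \alpha_u & s_{uv} & u_0 \\ 0 & \alpha_v & v_0 \\ 0 & 0 & 1 \end{pmatrix}, $$

with $\alpha_u = f/d_x$, $\alpha_v = f/d_y$ the focal length in pixels and
$(u_0, v_0)$ the principal point. Homogeneous projection gives
$(z_C u, z_C v, z_C)$; division by the camera depth $z_C$ yields the pixel.
No radial or tangential lens distortion is modeled: the reference rig uses
a fixed-focus industrial macro lens at a single working distance, where a
skewed pinhole is an adequate description, and the calibration target
(interior 9 × 9 corner grid, 0.5 mm pitch) is too small to constrain a
distortion field reliably anyway.

Calibration proceeds in four sequential stages.

1. **Corner detection** (`detect_corners`). Interior checkerboard corners
   are point-symmetric: $I(c+v) + I(c-v)$ is constant around a corner $c$,
   so the saddle point of the Gaussian-blurred image coincides with the
   true corner regardless of blur scale. The detector finds saddle
   candidates via the Hessian response $I_{xy}^2 - I_{xx}I_{yy}$,
   discards non-checkerboard saddles with a ring test (on a small sampling
   circle a true corner's intensity carries a dominant *second* angular
   harmonic, dark-light-dark-light; board-edge corners against the
   background carry a first harmonic), refines each survivor by solving
   for the stationary point of a local quadratic fit, and recovers the
   grid topology through a four-corner homography. The blur scale (default
   `sigma = 2` px) and the quadratic window (5 × 5) were chosen on
   rendered boards: heavier blur suppresses anti-aliasing noise without
   moving the saddle (symmetry pins it), and the small window keeps the
   quadratic model valid. On rendered fixtures the detector is accurate to
   about 0.1 px (worst case < 0.2 px).

   The canonical per-image ordering (row-major from the corner nearest the
   image top-left) is deterministic per view but *not* stable across a
   rotating sequence; `align_corner_orderings` therefore relabels each
   view by the dihedral grid symmetry that minimizes displacement to the
   previous view. Without this step corner identities scramble mid-sequence
   and the axis fit fails catastrophically — it is applied automatically in
   `calibrate_rig`.

2. **Intrinsics** (`calibrate_intrinsics`). Classic plane-based
   calibration: per-view homographies constrain the image of the absolute
   conic, solved in closed form for the five intrinsics, then jointly
   refined with all poses by Levenberg–Marquardt on the reprojection
   residuals. A known limitation of this rig is that all board poses
   differ only by rotation about one axis, a weakly conditioned
   configuration for planar calibration; the principal point and skew
   absorb most of the uncertainty. The axis estimate downstream is robust
   to this because it depends on the *consistency* of the per-view poses,
   not on their absolute accuracy.

3. **Rotation axis** (`fit_trajectory_center`, `fit_rotation_axis`). Each
   corner traces a circular arc in the camera frame; the circle centers
   all lie on the rotation axis. A direct least-squares sphere fit is rank
   deficient for coplanar circular points (any center translated along the
   axis fits equally well), so each trajectory is reduced to its
   total-least-squares plane, a 2D circle is fitted there (algebraic
   initialization, geometric Gauss–Newton refinement), and the center is
   lifted back to 3D — the same downstream quantity, without the
   degeneracy. The axis is then the total-least-squares line through the
   centers: centroid plus dominant eigenvector of their scatter matrix.
   The direction sign is fixed against the camera up direction
   $(0, -1, 0)$ (image $v$ points down), with ties broken toward $+z$ then
   $+x$; a warning of class `seedhull_ill_conditioned` fires when the
   second eigenvalue exceeds 25% of the first (centers nearly isotropic).
   Axis and poses are fitted sequentially, not bundle-adjusted jointly:
   the sequential scheme is simpler to validate stage by stage, and on
   rendered fixtures it recovers the axis to ~0.2 degrees end-to-end
   (exactly, from noiseless corners), which is already far below the
   voxel resolution downstream.

4. **Virtual views** (`generate_virtual_views`). The object rotates while
   the camera is fixed, so view $k$ composes the base pose with a rotation
   by $k \cdot 9^\circ$ about the fitted axis; equivalently a virtual
   camera orbits the seed. Any world point on the axis projects to the
   same pixel in all 40 views, and the sequence closes exactly after
   $360^\circ$.

## Silhouettes

`binarize` thresholds each frame (Otsu's bimodal-histogram threshold by
default, polarity chosen so the smaller class is foreground), fills holes
and keeps the largest connected component — carving requires one solid
silhouette. The suction nozzle enters from the top edge as a
near-constant-width bar; `remove_nozzle` scans row-wise white-pixel counts
from that edge and cuts at the first row whose count changes by at least
`change_fraction` (default 0.30) relative to the previous row. The
row-to-row reading is the only one that produces a horizontal intersection
line per image; an optional cross-view consensus applies the median
intersection row over all views of a seed. The 0.30 default is a tunable,
not a measured constant: the nozzle/seed width ratio on any real rig
should comfortably exceed it, and the function flags (rather than guesses)
when no such row exists.

## Visual hull, voxel states and meshing

`carve` realizes shape-from-silhouette: a voxel is occupied iff its
*center* projects inside the silhouette in every view (nearest-pixel
lookup of the binary mask — bilinear sampling would invent gray values).
The default grid is cubic at resolution 128 along the largest extent,
auto-sized from the back-projected silhouette extents with a 5% margin.
Occupied voxels are partitioned into *surface* (at least one face-adjacent
outside neighbor) and *inside* states. The visual hull always contains the
true solid, so carved volume is an upper bound that tightens as views are
added — both properties are asserted in the test suite.

`mesh_from_grid` extracts the iso-0.5 surface by marching cubes with
linear edge interpolation. Two implementation choices deserve record:

* **The case table is derived, not transcribed.** For each of the 256
  corner configurations, every cube face contributes 2D marching-squares
  segments; ambiguous faces (diagonal patterns) follow a fixed rule —
  occupied corners are never connected — which depends only on the four
  shared face values, so adjacent cubes always agree and the mesh is
  watertight by construction. Segments are chained into loops and
  fan-triangulated; vertices are welded by exact global edge identity
  rather than coordinate rounding. Watertightness and Euler characteristic
  2 are asserted on every meshed fixture.

* **The occupancy field is box-filtered (3³) before extraction, by
  default.** On a raw binary field every marching-cubes vertex sits at an
  edge midpoint and the resulting staircase inflates surface area by
  roughly 9% (measured on a voxelized ellipsoid at 128³) — well outside
  the accuracy the traits need. The filtered field tracks the true
  surface to a fraction of a voxel (area error ~0.3% on the same
  fixture). The filter slightly smooths sub-voxel detail, which is the
  right trade-off for area measurement; volume and all grid-derived
  traits never see it. If the filtered field has no iso-crossing at all
  (a one-voxel grid, say), extraction falls back to the raw field
  automatically.

## Traits

All nine traits are measured in a canonical seed frame: principal axes of
the occupied voxel centers ordered by decreasing spread (x = length,
y = width, z = thickness), origin at the centroid, signs fixed by making
the third central moment along each axis non-negative (falling back to a
positive dominant component for symmetric solids, with handedness restored
on the least-skewed axis). On this rig the seed's long axis approximately
coincides with the rotation axis, but nothing depends on that.

| trait | definition |
|---|---|
| L, W, D | per-axis voxel extent (`max - min` of centers plus one spacing) |
| S | Heron's formula summed over mesh triangles |
| V | trapezoidal integration of cross-section areas along the length axis |
| A | area of the orthographic shadow along the thickness axis |
| R | isoperimetric ratio $4\pi A_{outline}/P^2$ of the shadow outline |
| A&#95;C | maximum cross-section area transverse to the length axis |
| J | $A_C / (W \cdot D)$ |

Three readings fixed here were left open by the quantities' printed
definitions. The projection area $A$ is the *shadow* along the thickness
axis, not a planar slice — at study scale $A \approx \tfrac{\pi}{4} L W$,
which matches the printed magnitudes (16.45 vs 6.67 × 3.23 mm). The
cardioid-derived area $A_C$ is the *maximum transverse slice* — the
heart-shaped outline of a creased grain — consistent with
$A_C \approx 0.8\,W D$ at study scale (7.29 vs 3.23 × 2.83 mm). The
printed roundness formula is literally a closed-polygon perimeter, yet the
reported values are dimensionless in (0, 1]; the only standard
normalization with those properties is the isoperimetric ratio, so
roundness is $4\pi A / P^2$ with the printed sum as the $P$ term.
Slice counts for $V$ and $A_C$ default to one slab per voxel layer
("sufficiently small intervals"); the trapezoid rule is exact for constant
profiles and second-order otherwise, and on carved fixtures the slice
volume, the voxel-count volume and the mesh divergence-theorem volume
agree pairwise within a few percent.

The shadow outline for roundness is traced by subpixel marching squares
(same construction as the 3D case) and lightly smoothed by a cyclic
(1, 2, 1)/4 moving average (3 passes): the half-pixel staircase of a
binary contour otherwise biases the perimeter of a smooth shape upward by
several percent. With smoothing, a rasterized circle of radius 50 px has
its perimeter recovered to 0.4%.

## Germplasm statistics

The statistics layer consumes a trait table (one row per seed with variety
and group labels) and mirrors the study design: 2 parent varieties and 13
offspring in 2 batches, 30 seeds each.

* **PCV** — $100\,\sigma/\mu$ per trait, sample SD ($n-1$): the usual
  convention for summary tables.
* **Nested ANOVA** — definitional sums of squares for seeds within
  varieties within germplasm groups:
  $SS_{among} = \sum_g n_g(\bar y_g - \bar y)^2$,
  $SS_{within} = \sum_v n_v(\bar y_v - \bar y_{g(v)})^2$,
  $SS_{error} = \sum_i (y_i - \bar y_{v(i)})^2$; the partition identity
  is exact and both F ratios use the residual mean square. The
  implementation is definitional on purpose — the test suite cross-checks
  it against `stats::aov` as an independent oracle, which a delegating
  implementation could not do. No multiple-testing correction is applied;
  significance is flagged at $P < 0.01$.
* **GVF** — the genetic variation factor per offspring variety and trait:
  $$\mathrm{GVF} = 100\cdot\frac{\sqrt{\left|D(P_1) + D(P_2) - D(F_i)\right|}}{E(P_1) + E(P_2)}$$
  with $D$ the population variance (the $1/N$ is absorbed into the
  operator), $D(P_1 + P_2)$ read as the variance of a sum of independent
  parental samples, and $E$ the summed expectation. Phenotypic variance
  decomposes into genetic plus environmental parts; under an unchanged
  environment the environmental term cancels in the parent-offspring
  difference, so the factor tracks the genetic component. The absolute
  value guards the square root against sampling noise. This operator
  placement is one of several readings of the printed formula; it is the
  one that lands GVF in the printed few-percent range when fed study-scale
  inputs, and it makes GVF scale-invariant under common rescaling of all
  three samples (asserted in the tests). The hand-checkable case
  $P_1 = \{9,10,11\}$, $P_2 = \{19,20,21\}$, $F_i = \{15,15,15\}$ gives
  $\sqrt{4/3}/30 = 3.85\%$.
* **Clustering** (`cluster_and_score`) — k-means, Ward hierarchical and a
  minimal DBSCAN on standardized traits, scored as precision against the
  known batch labels after optimal cluster-to-label matching. This is
  evaluation plumbing, not an inferential method; it delegates to
  `stats::kmeans`/`stats::hclust` where possible (no DBSCAN implementation
  is available among the package's dependencies, so a ~30-line one is
  included).

## Synthetic fixtures: what they emulate, and what they do not

Every pipeline input can be generated with analytic ground truth:

* **Seed solids** — superellipsoids $|x/a|^p + |y/b|^p + |z/c|^p \le 1$
  (single exponent; closed-form volume
  $8abc\,\Gamma(1+1/p)^3/\Gamma(1+3/p)$) with an optional ventral crease: a
  cylinder subtracted along the length axis, emulating the groove that
  makes a wheat grain's transverse section heart-shaped. Creased reference
  volumes subtract a high-resolution numeric integral of the grooved
  material. Default semi-axes (3.3, 1.6, 1.4) mm match study-scale grain
  dimensions.
* **Silhouette rendering** — per-pixel ray marching against the inside
  predicate (96 steps across the bounding sphere), accurate to about one
  pixel at the default image scale; a warning fires if a silhouette
  touches the image border, since carving would silently truncate the
  hull.
* **Checkerboards** — plane-intersection rendering with 3 × 3
  supersampling and exact ground-truth corner projections.
* **Germplasm tables** — independent Gaussian draws per seed.
  `default_germplasm_spec()` reproduces the study's shape: 15 varieties ×
  30 seeds, pooled trait means and SDs at the published scale (pooled
  volume PCV ≈ 22%), a between-variety component of 0.6 pooled SD as
  fixed offsets, parent within-variety SDs solved so the pooled variance
  recomposes exactly, and per-offspring variance shifts
  $D(F_i) = (D(P_1)+D(P_2))(1+s_i)$. The default shifts make one variety
  (F1, $s = 1.0$) roughly an order of magnitude more divergent than the
  rest ($s \le 0.12$), so the designed GVF ranking is statistically
  unambiguous at $n = 30$ while the resulting GVF values stay in the
  realistic few-percent range.

Limits worth stating plainly. The renderer is geometric: no lighting,
texture, specularity, shadows or sensor noise, so passing tests establish
the geometry and numerics of the pipeline, not robustness to real
photographic nuisance. The Gaussian trait model has no inter-trait
correlation by default (real seed traits are strongly correlated;
a covariance input is the extension point). And the visual hull is
intrinsically blind to concavities: the ventral crease is bridged almost
entirely by the hull (per transverse slice, silhouette information can
only recover the convex hull of the section), which is why the
creased-fixture trait tests voxelize the solid directly and why real-rig
cardioid areas should be read as upper bounds near the groove.

## Numerical choices and degenerate inputs

* Circle fits refine algebraic (Kåsa) initializations by
  Levenberg–Marquardt on radial residuals; collinear or < 3-point
  trajectories raise `seedhull_degenerate_trajectory`.
* `estimate_board_pose` requires ≥ 4 non-collinear correspondences
  (`seedhull_degenerate_configuration` otherwise) and refines a
  homography-decomposition initialization by LM on reprojection residuals.
* Carving with any empty silhouette raises `seedhull_empty_hull` (after a
  warning); voxels projecting outside any image are outside.
* Marching-cubes interpolation weights are clamped away from 0/1 so welded
  vertices are never exactly coincident; degenerate faces are dropped.
* A sphere has no preferred canonical frame: PCA returns an arbitrary
  orthonormal basis and the traits satisfy L = W = D regardless — the
  tie-break is documented rather than forced.
* All RNG use is local: `simulate_germplasm` and k-means restarts seed a
  local stream and restore the caller's RNG state.

## Problem sizes used by the test battery

The shipped tests run the full pipeline at the working scale: 40 rendered
views at 280 × 320 px carved at 128³ for the end-to-end ellipsoid check
(trait errors: extents within two voxel spacings, volume and surface area
within a few percent, projection and transverse areas within 3%), 9-view
checkerboard sequences at 400 × 400 px for calibration, 500-replicate
Monte Carlo for the circle-center estimator, 200 replicates each for the
nested-ANOVA expected mean squares and the GVF ranking. The whole suite
completes in about two minutes on one CPU; the sizes were chosen as the
smallest at which the asserted tolerances are comfortably diagnostic.
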