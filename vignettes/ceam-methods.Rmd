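---
title: "Continuous edge angle measurement: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous edge angle measurement: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Bifacial stone tools (handaxes) are bounded by one long, continuous
intersection between two flaked faces. The functional character of that
edge — where it is sharp enough to cut, where it is blunt enough to hold —
varies around the perimeter, and any single protractor-style measurement at
an analyst-chosen spot understates that variability and injects observer
bias. This package measures the edge angle *continuously*, at every one of
1000 coordinates around an automatically detected 3D perimeter, and then
segments the perimeter into discrete edges wherever the angle shifts, all
without user input.

The pipeline is: mesh normalization → outline detection → continuous edge
angle measurement (CEAM) → change-point segmentation → per-segment metrics
(length, sharpness, transverse asymmetry, surface concavity, refinement).

## Normalization

Every artifact is brought into a common frame before measurement:

* **Orientation.** If a rotation matrix is supplied (for instance exported
  from an external positioning step), it is applied verbatim. Otherwise
  principal-axes alignment maps the longest axis to y, the second to x,
  and the thinnest to z. Signs are fixed deterministically: the y half
  with the smaller mean plan width (the tip) points to +y; the z sign
  follows the third moment of the z projection; x completes a
  right-handed frame. When the covariance is already diagonal in this
  convention the axes are left untouched, which makes orientation
  idempotent. Near-isotropic meshes (adjacent principal standard
  deviations within 1%) are flagged `ambiguous` rather than rejected.
* **Resolution.** Scan resolution biases the three-point angle (sparser
  meshes read slightly higher), so every mesh is brought to the same
  vertex count, 50,000 by default: midpoint subdivision upward (planar,
  shape-preserving), vertex-clustering decimation downward, with the grid
  cell bisected until the count lands within 2%.
* **Scale.** Uniform rescaling to length 1 (y extent), so arc lengths and
  perimeter percentages are comparable across artifacts.

## Outline detection

The closed 3D perimeter dividing the two faces is found in plan view: the
mesh vertices are projected to x–y and bounded by the alpha shape of the
projected points (Delaunay triangles with circumradius at most alpha;
boundary of the kept complex). Because no alpha value is universal, the
package chooses the smallest alpha on a geometric grid (factor 1.3 steps
up from the mean projected nearest-neighbor spacing) whose *outer boundary
loop* closes, contains every projected point (to within half a spacing),
and whose perimeter is stable to within 0.2% against the next alpha step.
Perimeter stability is the operative criterion: an alpha below the surface
resolution threads a zigzag loop through sub-surface points (inflating the
perimeter), while an oversized alpha cuts across genuinely concave
stretches of outline. Interior holes and degenerate slivers in the
triangulation are tolerated — only the outer loop matters — which keeps the
selection robust on meshes with near-vertical walls whose projections
collapse into dense point columns.

Boundary points are lifted to 3D with the z of their source vertex. Where
the perimeter surface is near-vertical (face normals within 20 degrees of
the x–y plane, averaged over the 50 nearest faces), the lifted z
fluctuates wildly between the top and bottom of the blunt wall; those
coordinates are flagged and their z replaced by the mean z of the 50
plan-view-nearest mesh vertices, which for a vertical band is its
mid-height. x and y are never modified. The corrected outline is
resampled to exactly 1000 coordinates at uniform 3D arc spacing by linear
interpolation, re-indexed to start at the tip (maximum y), and ordered
counter-clockwise in plan view.

## CEAM

The edge angle at a mesh vertex $v$ uses three points: $v$ itself, the
vertex $o$ on the opposing face closest to $v$ in x–y, and the nearest
point $e$ on the outline. The angle is

$$\theta(v) = \operatorname{atan2}\!\big(\lVert (v-e) \times (o-e) \rVert,\; (v-e) \cdot (o-e)\big).$$

Faces are labeled by comparing each vertex's z with the z of its plan-view
nearest outline coordinate (with a topological fallback — cutting the mesh
along the outline and taking the two largest components — for faces that
dip below the rim plane, such as bowl-shaped surfaces). Vertices within
$10^{-3}$ length units of the outline are labeled `boundary` and excluded:
their difference vectors are numerically unstable.

$e$ is taken on the outline *polyline* rather than snapped to the nearest
of the 1000 discrete coordinates. The discrete snap displaces the apex of
the measured angle by up to half an outline spacing along the rim, which
corrupts precisely the near-edge vertices that carry the most accurate
angles; with the continuous foot the octahedron benchmark (below) is
recovered to 0.03 degrees instead of ~0.25.

Only vertices in the outer band of the surface are aggregated — by
default the outer 20% of surface area by distance to the outline, the
region that belongs to the edge rather than the faces. Per outline
coordinate, the angles of the 100 nearest band vertices are summarized by
the mode of a Gaussian kernel density estimate on a 0.1-degree grid over
0–180 degrees (Silverman's bandwidth with a 1-degree floor; ties resolve
to the lowest angle). The mode — "the most frequent angle" — is what makes
the measurement robust to the near-180-degree outliers that arise at the
extreme periphery of real scans from rounding, beveling, and scanner
resolution limits; the suite verifies that salting neighborhoods with 1%
outliers at 180 degrees moves the profile by less than half a degree.
`band_convergence()` reruns the profile across band fractions 1–25%; on
constant-angle solids the mean plateaus once the band exceeds about 10%,
so the 20% default sits on a flat region of the parameter.

### Accuracy and its limits

Two synthetic families provide closed-form truth:

* a regular octahedron (equatorial dihedral exactly
  $\arccos(-1/3) = 109.4712°$), meshed as planar subdivided faces so the
  dihedral survives any resolution; and
* biconvex lenses — two spherical caps (radii $R_{up}$, $R_{down}$)
  sharing a rim circle of radius $a$ — whose rim dihedral is
  $\arcsin(a/R_{up}) + \arcsin(a/R_{down})$, with per-face half-angles and
  their min/max ratio (transverse asymmetry) equally in closed form.

The octahedron is recovered essentially exactly (mean 109.50°, SD 0 at
50,000 vertices). The lenses expose a genuine limit of the three-point
method on *curved* surfaces: the measured vectors are chords, not
tangents, so a vertex at arc distance $s$ from the rim reads low by about
$s/R$ radians. At 50,000 vertices the 100-vertex neighborhoods span
$s \approx 0.04$ length units, giving a downward bias that grows with cap
curvature: measured maximum profile errors are about 0.7° at a 52° edge,
1.4° at 91°, 2.3° at 120°, and several degrees at 145° (where the caps are
steep and tightly curved). The bias vanishes on planar surfaces — the
octahedron, and the near-planar flake scars of real knapped stone — and
shrinks with mesh density. It is a resolution floor of the measurement
itself, not an estimator artifact; no admissible neighborhood size removes
it on the bluntest lenses, and the validation suite reports those cases as
failures rather than hiding them.

## Segmentation

The 1000-point angle profile, plotted against arc length from the tip, is
segmented by change points that minimize the total squared deviation from
segment means. The optimum is computed exactly by dynamic programming over
all placements with a minimum segment length of 25 coordinates (2.5% of
perimeter; forbids one-point segments), for every change-point count
K = 0..10; ties resolve to the lexicographically smallest breakpoint set.
The suite proves the program exact against exhaustive enumeration on
signals up to length 30.

K is selected at the elbow of the residual curve: after scaling both axes
to [0, 1], the K with the largest perpendicular distance below the chord
joining the curve's endpoints. Three guards return K = 0: a residual that
is already negligible; a total relative drop below 8%, calibrated against
the null distribution of its own statistic — optimally placed change
points remove 4–6% of the squared residual from pure noise at this signal
length — so structureless profiles are not segmented; and segment means
that all lie within 5 degrees of one another. The last guard exists
because a *relative* drop cannot protect near-constant profiles: a
constant-angle artifact has a tiny total variance, and the spatially
correlated wiggle left by neighborhood aggregation clears any relative
floor while being archaeologically meaningless. Five degrees is the same
separation below which the report flags first and last segments as
effectively one edge. Note
a structural property of any chord-distance elbow: a change point
contributing less than 1/kmax of the total drop cannot be selected, so
monotone staircases of many unequal steps are under-segmented. The
recovery experiment therefore uses alternating-sign shifts of comparable
magnitude — the sharp/blunt alternation actually seen around biface
perimeters — and recovers the true K in 99 of 100 seeded runs (shifts at
least 5 noise SDs, segments at least 50 coordinates).

The profile is treated as a linear sequence starting at the tip, exactly
as plotted; a segment spanning the start may be split in two, and reports
flag artifacts whose first and last segment means are within 5 degrees.

## Segment metrics

* **Length**: sum of consecutive 3D gaps; each inter-coordinate gap is
  assigned to the segment owning its first coordinate, so segment lengths
  partition the perimeter exactly.
* **Sharpness**: a segment is sharp when its mean angle is strictly below
  the threshold (120 degrees by default, kept fixed for cross-assemblage
  comparability). The data-driven alternative is also computed: a KDE
  (Silverman bandwidth, 2-degree floor) of all pooled segment means,
  taking the density minimum between the two highest genuine modes (at
  least 15 degrees apart, each at least 10% of the peak density —
  without the prominence requirement, tail wiggles of a unimodal sample
  register as spurious second modes), floored to a multiple of 10.
  Unimodal assemblages fall back to 120 with a flag.
* **Transverse asymmetry**: at each band vertex the edge angle is split by
  the horizontal vector from the outline foot toward the plan centroid;
  the min/max ratio of the two half-angles (1 = symmetric section,
  → 0 = plano-convex) is aggregated per coordinate by the same KDE-mode
  estimator on a 0–1 grid. The plan centroid is a single per-artifact
  reference (the outline polygon centroid); a per-cross-section center
  would be a plausible alternative but needs an arbitrary sectioning rule.
* **Surface concavity**: for each vertex, the 20 outermost of its 60
  nearest neighbors are compared through
  $s = (p_j - p_i)\cdot(n_j - n_i)$ with area-weighted vertex normals:
  $s > \varepsilon$ counts convex, $s < -\varepsilon$ concave, otherwise
  planar ($\varepsilon = 10^{-4}$ absorbs exact planarity, mapping a plane
  to 0.5). The value is (convex + planar/2)/20, i.e. 0 = fully concave,
  1 = fully convex. When face labels are supplied, neighborhoods are
  restricted to the vertex's own face: near the edge an unrestricted
  neighborhood mixes both faces across the sharp crest and a genuinely
  concave face would read planar. Per-face outline profiles aggregate
  band-vertex values by KDE mode; the pair is labeled with cutoffs 0.4
  and 0.6 (concave / planar / convex) and reported in face-order-free
  sorted form ("concave-planar", never "planar-concave").
* **Refinement**: width/thickness (x extent over z extent), scale-free.

## Synthetic data: what it does and does not show

The generators (`make_lens`, `make_blunt_lens`, `make_plano_convex`,
`make_bowl_top`, `make_cylinder`, `make_octahedron`, `make_sphere`,
`make_piecewise_signal`) are deterministic given their parameters. Lens
caps are sampled quasi-uniformly by area with a Halton sequence and
triangulated, emulating the irregular vertex placement of structured-light
scans; a perfect revolution grid would quantize neighbor distances into
equal-count rings and visibly distort the mode estimator. The blunt lens
replaces the rim over a contiguous arc (fraction `f`, centered at the
base) with a vertical wall of height `band_height` (default 0.06 length
units, symmetric about the rim plane), blended over a 2%-of-perimeter
linear taper inside each end of the arc so the modified arc spans exactly
`f`; solid-of-revolution generators carry a sub-resolution deterministic
stagger that breaks exact cocircularity (real scans are never perfectly
cocircular, and exact point batteries destabilize Delaunay computation).

What these fixtures do not emulate: flake scars (real edges undulate at
the centimeter scale), cortex, surface noise, holes or non-watertight
scans, and post-depositional rounding. Passing the synthetic suite
demonstrates the geometry and the estimators are correct, not that any
particular archaeological threshold (such as the 120-degree sharp/blunt
cut) is appropriate for a given assemblage.

## Numerical choices and degenerate inputs

* All angles are in degrees; all coordinates dimensionless after rescale.
* KDE grids: 0.1 degrees for angles, 0.001 for ratios; bandwidth floors
  1 degree and 0.01.
* Delaunay input is deterministically jittered by 5% of the mean point
  spacing (the triangulation library's own degeneracy fallback is
  RNG-dependent, which would break reproducibility); the returned
  boundary always carries unjittered coordinates, and all combinatorial
  decisions (windings, walks) are made consistently in the jittered
  embedding. Projected point clusters tighter than a quarter of the
  median spacing are collapsed to their first member before
  triangulation.
* Zero-area faces, duplicate vertices and faces, and disconnected
  fragments are removed on load; meshes with fewer than 4 vertices, open
  outlines, or self-intersecting plan projections are rejected with
  specific errors. A flat patch, whose faces cannot be separated by the
  outline, errors in face assignment.
* Outline coordinates at the plan centroid (undefined asymmetry
  direction) are skipped and logged; outline coordinates with fewer than
  5 usable band vertices fall back to a plain median and are logged.

## Problem sizes used in the validation suite

Benchmarks that assert analytic values (octahedron, the lens family, the
blunt band, asymmetry) run at the full 50,000-vertex operating point;
invariance and orchestration tests use 6,000–20,000 vertices, where every
property tested is scale-free. The change-point oracle comparison covers
all signals up to length 30 with up to 3 change points across 100 seeds,
and elbow recovery uses 100 seeded 1000-point profiles.

## Known limitations

* The chord bias on strongly curved, obtuse edges (above ~120 degrees at
  default resolution) described above.
* The elbow rule's insensitivity to change points contributing less than
  1/kmax of the residual drop.
* The outline is linearized at the tip: a single edge segment spanning
  the tip is reported as two.
* Orientation of near-isotropic pieces is arbitrary (flagged
  `ambiguous`); supply a rotation matrix for such artifacts.
* Blunt-region z correction assumes the blunt wall is roughly symmetric
  about the true perimeter; a strongly beveled wall would bias the
  corrected outline toward the longer face.
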