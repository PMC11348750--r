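---
title: "Whorl and soil-line detection on root-crown skeletons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whorl and soil-line detection on root-crown skeletons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootwhorl)
```

# The problem

Excavated maize root crowns imaged by X-ray CT can be skeletonized into a
spatial graph whose vertices carry a thickness measure.  Two pieces of
information that breeders and physiologists want are not directly present
in that graph: where the *whorls* are (the rings of nodal roots along the
stem, and how many roots each carries), and where the *soil line* was
before excavation (it separates brace whorls from crown whorls, and
above-ground from below-ground traits).  Both are confounded by a
systematic artifact: nodal roots growing steeply downward press against
the stem, and skeletonization then fabricates short "bridge" curves that
connect those roots to the stem far from any true emergence point.
Treated naively, every bridge looks like a root emergence and produces
phantom whorls.

`rootwhorl` addresses both tasks on the skeleton alone, which makes it
fast (graph-sized, not volume-sized) and independent of the upstream
segmentation tool.

# Candidate paths and their score

The stem path is given (skeletonization identifies it by thickness; the
package also ships `infer_stem_path()`, a maximal-thickness fallback used
only for synthetic inputs).  A vertex is **inside the stem** if it lies
within 1.2 times the thickness of its nearest stem vertex — the
comparison is inclusive, so a vertex at exactly the multiplier distance
counts as inside.  Edges with exactly one inside endpoint form the **stem
boundary**: every root emergence, true or spurious, must cross it.

For every junction on the stem (degree ≥ 3), Dijkstra's algorithm finds
shortest paths to each inside vertex incident to a boundary edge.  Stem
edges and fully-outside edges are unusable; this forces the paths to
describe how a branch leaves the stem, not where it wanders afterwards.
Each path is extended by its boundary edge and simplified with
Ramer–Douglas–Peucker.  RDP here always performs its first split — the
farthest input point from the end-to-end chord is always retained — so
the simplified path has at least three vertices and a measurable interior
angle even when the path is nearly straight.  Paths that still have fewer
than three distinct points (a boundary edge incident to the junction
itself) carry no angle information and are discarded with a warning.

The **turning point** is the simplified path's interior vertex of largest
direction change (ties: closest to the stem), and the score is

$$S(P) = \exp\!\left(-\frac{2\alpha_P}{\pi} -
  \frac{10 - \mathrm{clamp}(|v - v_P| - r_v,\, 0,\, 10)}{10}\right)$$

with the turning-point distance expressed in voxels.  Both penalties are
bounded, so $S \in [e^{-3}, 1]$.  A real nodal root bends gently
(small $\alpha_P$) and far from the stem (large clamp term): $S$ near 1.
A clinging-root bridge bends sharply at the stem surface: $S$ near
$e^{-3}$.  When several junctions reach the same boundary edge, only the
best-scoring path survives (ties: shorter path, then lexicographic vertex
sequence, so the result is deterministic).

## Parameters and units

All geometry is in mm.  Constants that are naturally voxel-denominated
are converted through the skeleton's voxel pitch (default 0.44 mm, i.e.
a 109 µm scan downsampled 4×):

| parameter | default | meaning |
|---|---|---|
| `stem_multiplier` | 1.2 | inside-stem thickness multiplier |
| `rdp_epsilon_voxels` | 3 (= 1.32 mm) | RDP tolerance |
| `clamp_voxels` | 10 (= 4.4 mm) | score distance clamp |
| `bandwidth_mm` | 10 | mean-shift bandwidth along the stem |
| `bin_width_mm` | 2 | depth-profile bin width |
| `sigma_factor` | 2 | soil line = b − sigma_factor · c |

# Threshold-persistent clustering into whorls

Thresholding the scores at a fixed δ and clustering the surviving start
positions is brittle: the right δ differs per sample.  Instead, for every
δ in the ascending list of candidate scores, the package clusters the
start-arc positions of all paths scoring ≥ δ and asks how long each
clustering *persists*: two clusterings are the same when they have the
same number of clusters and matched clusters share the same lowest and
highest member.  The clustering persisting over the most consecutive
thresholds wins; ties go to the run at larger thresholds, where the
low-scoring false connections have already dropped out.  Finally, every
candidate path — regardless of score — whose start arc falls inside a
winning cluster's member range becomes a nodal root of that whorl, since
false connections are rare immediately at a true whorl.

The clustering itself is a one-dimensional mean shift with a flat kernel.
No installed package provides mean shift, and the sweep needs full
control of determinism, so it is implemented here directly: each point is
iterated to the mean of its `bandwidth`-neighbourhood, and converged
modes closer than half a bandwidth are merged.  The bandwidth default of
10 mm is well below typical internode distances (30–40 mm) and above the
arc scatter of emergences within one whorl (a few mm); it is exposed in
`run_config()`.  Everything is deterministic for fixed input.

A consequence of the membership rule worth knowing: if the arc-extreme
path of a whorl has a low score, the selected clustering may not include
it, and the member range then excludes that root — per-whorl counts can
miss an extreme root.  This is inherent to the design, which prefers
losing an outlying root to absorbing false connections.

# Pruning, cycles, hierarchy

Stem-attached paths that represent no nodal root are traced from their
stem junction through degree-2 vertices to the next junction or leaf and
removed (end vertices kept; traces that would touch a nodal path or stem
edge abort).  This deletes most clinging-root bridges and with them the
cycles they created.  Remaining cycles are broken per component by a
spanning tree that maximizes retained thickness (minimum spanning tree on
the negated mean endpoint thickness, stem edges pinned), so cycles break
at their thinnest edge.

Hierarchy labels follow: stem = 0, every branch leaving the stem = 1, and
at each junction the child that continues straightest keeps its parent's
label while the others get label + 1.  One refinement proved necessary:
continuation candidates are first restricted to children at least 0.7×
as thick as the thickest child.  With pure direction, a thin lateral that
happens to align with the (noisy) axis of a thick nodal root captures its
label, relabeling the rest of the root as lateral and contaminating the
lateral-density profile; thickness is exactly the cue skeletons carry to
prevent this, and the full upstream hierarchy machinery this rule stands
in for is itself thickness-driven.  At 0.7 the rule never interferes with
same-caliber forks, where direction alone decides.

# Soil-line detection

Lateral roots (label ≥ 2) proliferate below ground.  The package bins
lateral *length* by top-down depth (2 mm bins; each edge apportioned
pro-rata over the bins its endpoints span) and fits
$f(x) = a\,e^{-(x-b)^2/(2c^2)}$ by Levenberg–Marquardt
(`minpack.lm::nlsLM`; initialized at the profile maximum and moment
standard deviation; relative RSS tolerance 1e-10, ≤ 500 iterations).
The soil line is $b - 2c$ — the depth where the density starts rising.
Length was chosen over branch counts as the density measure because it is
robust to fragmented laterals and consistent with the RLD traits; a
degenerate profile (fewer than 3 nonzero bins) raises an error rather
than a spurious line, and a fitted line above the stem top clamps to 0
with a warning.

# Traits

Whorl locations are the mean start arcs of their nodal paths; internode
distances are consecutive differences with whorls ordered youngest first
(smallest arc from the top, i.e. highest on the stalk).  Whorl 0 is the
deepest whorl at or above the soil line; indices decrease with gravity.
Per whorl and hierarchy level the package reports count, total/average
length, tortuosity (arc length over chord), thickness, mean child count,
and emergence/midpoint/tip angles measured between a 5 mm local tangent
window and the downward vertical.  Above/below-ground aggregates sum
counts and weight averaged traits by count.  Root length density uses a
virtual soil core: a cylinder around the best-fit stem axis whose radius
defaults to the 95th percentile of root radial distances, binned per
centimeter of depth below the soil line; RLD = root length (cm) per bin
volume (cm³).  The evaluation metric
$E_k = \sum_{i\le k} |c_i - m_i| / \sum_{i\le k} m_i$ compares computed
against measured internode distances from the youngest whorl down.

# The synthetic generator

`generate_crown()` builds crowns with known ground truth: a noisy
vertical stem tapering from 6 mm thickness; whorls at 30–40 mm internodes
carrying 6–10 nodal roots that leave radially (10–40° below horizontal)
and bend smoothly downward at 1.2°/mm; 15% of above-ground roots
"cling" — they hug the stem just outside its surface and are re-attached
to a lower stem junction by a two-edge bridge that bends ≥ 100° within
one voxel of the stem surface, creating both a false boundary crossing
and a cycle; laterals attach to nodal roots with acceptance probability
proportional to a Gaussian in depth whose peak sits $2c$ below the
nominal soil line ($c$ = 12 mm), at saturation probability 1 per 2 mm
vertex near the peak (~130 laterals per crown — conservative against
field-grown maize, which carries 5–20 laterals per cm of below-ground
nodal root); 12% of laterals carry a second-order lateral, so hierarchy
depth reaches 3.  All positions are jittered by 0.12 mm.  Everything is
deterministic per seed.

What the generator does **not** emulate: skeletonization dropouts (broken
or merged roots), soil remnants, root-to-root fusions away from the stem,
non-vertical stems, whorl-to-whorl azimuthal phyllotaxis, or the strong
compression of internodes near the seed.  Passing recovery tests
therefore demonstrates the pipeline's correctness under clean but
adversarial geometry (clinging bridges, score outliers, cycles), not its
accuracy on damaged real skeletons.

`measure_recovery()` runs the full pipeline over seeds and reports
whorl-count accuracy, $E_1$/$E_k$ against ground-truth internodes
(with $k$ the number of comparable internodes), the youngest-whorl
nodal-count correlation, and soil-line error quantiles.  On the reference
configuration (50 crowns of ~2 200 vertices each, sizes chosen so the
whole suite runs in minutes) the pipeline recovers the whorl count in
≥ 98% of crowns, internode errors stay below 1%, the soil line lands
within 5 mm in ~90% of crowns with a small shallow bias of ~2.4 mm
(the realized lateral sample of a single crown is finite, so its
empirical width wanders around the nominal $c$), and the youngest-whorl
count correlation is ~0.87 — imperfect because clinging-root bridges
occasionally survive scoring, an accepted property of the design.

# Numerical conventions and edge cases

* Vertical axis: volume Z; "top" is the stem path's first vertex; depth
  is measured top-down from it, negative above it.  `--flip-stem`
  reverses files recorded bottom-to-top.
* Ties: RDP split and turning point break toward the smallest index;
  dedup breaks score ties by length then vertex sequence; mean-shift
  cluster order follows ascending centers; persistence ties prefer the
  higher-threshold run.
* Degenerate inputs: empty candidate sets raise a `no_paths` error;
  zero-length candidate paths are dropped with a warning; an all-zero
  lateral profile refuses to fit; whorl sets entirely below the soil line
  are indexed −1, −2, … and flagged.
* Tortuosity guards a zero chord with a 1e-9 floor; arc interpolation
  clamps to the polyline's arc range.

# Limitations

Whorls tightly packed near the seed (internodes below the mean-shift
bandwidth) merge; scores cannot separate a steeply diving true root from
a bridge when both bend sharply at the surface; the hierarchy is a
declared simplification of full thickness-driven labeling; and the soil
line inherits any bias in the lateral-density profile, e.g. from
systematically missing fine laterals.  These mirror the failure modes
expected on real CT skeletons.
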