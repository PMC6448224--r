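---
title: "Annotating 3D-segmented shoot apical meristems: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating 3D-segmented shoot apical meristems: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meristem3d)
library(dplyr)
```

## The problem

The shoot apical meristem (SAM) is the dome-shaped stem-cell tissue at a
plant shoot tip. Confocal stacks of living SAMs are now routinely segmented
into individual cells, yielding a labeled 3D volume in which every voxel
carries an integer cell identifier. Those segmentations are rich but
anonymous: to compare cells across samples, genotypes or species, each cell
must first be annotated with its tissue context — its clonal layer (L1
epidermis, sub-epidermal L2, inner L3), membership of the organizing centre
(the *WUSCHEL*-expressing stem-cell niche), and whether it belongs to an
emerging organ primordium, to the boundary crease around it, or to the
central dome.

`meristem3d` performs this annotation geometrically, from the segmentation
alone, and computes the downstream cellular morphometrics that such
annotations unlock: volumes, PCA shape anisotropy, cell-adjacency networks
and shared cell-wall interface areas.

## Layer detection by cone peeling

For every cell $i$ we compute the centroid $x_c^i$ of its voxel centres and
the nearest point $x_t^i$ on the tissue surface mesh, obtained by exact
point-to-triangle projection (nearest-vertex approximations bias the
direction on coarse meshes). The surface vector

$$t^i = x_c^i - x_t^i$$

points from the surface into the cell. It anchors an unbounded cone with
vertex $x_c^i$, axis aimed at the surface (direction $-t^i$) and semi-cone
angle $\theta$ (default $60^\circ$). A cell is epidermal exactly when no
other cell lies between it and the surface, which the cone formalises: L1
cells are the cells whose cones contain no other centroid. Removing the L1
set and repeating yields L2; every remaining cell is L3, deeper strata
sharing one identity.

Three details are deliberate conventions:

* **Cone orientation.** Membership is the angle between $x_c^j - x_c^i$
  and the direction *toward the surface* being strictly less than
  $\theta$. Taken literally with the inward vector $t^i$, the inequality
  $\cos(\cdot) < \cos\theta$ would select the complement of this cone and
  invert the L1 criterion; we implement the geometry the cone description
  requires. The literal variant remains available via
  `convention = "literal"` for comparison.
* **Unbounded cones.** Cones are not truncated at the mesh. No centroids
  exist outside the tissue, and truncation would couple the test to
  mesh-fit error.
* **Strict inequality.** Points exactly on the cone boundary are outside,
  a deterministic tie-break.

$\theta$ trades sensitivity for robustness: small angles miss occluders in
curved regions (deep cells leak into L1), large angles let lateral
neighbours occlude (L1 erodes). $60^\circ$ is a good default for
meristem-scale curvature; cell size differences between species or mutants
are accommodated by adjusting it. A `min_cell_volume` threshold (default
0 µm³) excludes segmentation debris: sub-threshold cells are reported
`unassigned` and do not occlude any cone. A cell whose centroid falls
exactly on the mesh has no axis; it is assigned L1 with a warning, since it
sits at the surface.

## The organizing centre

The niche is marked from a user-chosen apex cell (the cell at the top of
the dome; the CLI's `inspect` prints a suggestion, but the choice is the
user's, replacing the interactive click). From the apex cell's surface
point $a$ and inward unit normal $n$, the niche centre is $c = a + d\,n$
for a user depth $d$; the organizing centre is every **L3** cell whose
centroid lies within the user radius $r$ of $c$ — a Euclidean ball,
matching the radius-around-a-deep-centre picture, and restricted to the L3
stratum so the niche is carved out of L3 rather than overwriting shallower
layers. Cells in the axial cylinder of radius $r$ between the surface and
depth $d$ keep their stratum but are renamed `L1_above_OC` /
`L2_above_OC` / `L3_above_OC`. The cylinder is our formalisation of the
"column above the niche": no formula exists for it in the method's
description, and the axial cylinder is the simplest construction consistent
with the depicted geometry. Whether the radius should act as a ball or
laterally was genuinely open; we use the ball for the OC and the cylinder
for the column, and document both as conventions.

## Primordium delineation by weighted Voronoi ratio

Each primordium is delineated from three user-selected cells: the SAM peak
($x_{SAM}$), the primordium peak ($x_p$) and the saddle cell in the crease
between them ($x_b$). With $d_p = \lVert x_p - x_b\rVert$ and
$d_{SAM} = \lVert x_{SAM} - x_b\rVert$, the reference ratio is
$r = d_p / d_{SAM}$, and for every cell $i$,
$\rho_i = \lVert x_i - x_p \rVert / \lVert x_i - x_{SAM} \rVert$:

$$P = \{\,i : \rho_i < r - \delta\,\}, \qquad
  B = \{\,i : r - \delta \le \rho_i \le r + \delta\,\}, \qquad
  S = \text{the rest.}$$

$\delta$ (the ratio half-width, dimensionless, default 0) sets how thick
the boundary band is. The absolute-distance parameter caps how far the
boundary reaches: it is applied as a Euclidean ball of that radius around
the saddle centroid, only to $B$ membership; band cells beyond the cap fall
back to the $\delta = 0$ rule. The cap is not part of the printed set
algebra — limiting it to $B$ is the minimal reading of "how deep the
boundary region is". Two limits are pinned by intent rather than
arithmetic: the SAM-peak cell itself ($\rho \to \infty$) is always $S$, the
primordium-peak cell ($\rho = 0$) always $P$.

Sequential selections annotate several primordia; earlier P/B assignments
are frozen (first selection wins — deterministic and order-documented), and
primordium cells keep their layer stratum (`primordium_L1` etc.) so layers
remain analysable inside organs. `same_label = TRUE` collapses all
selections onto one index.

## Surface meshes

When no mesh is supplied, the foreground is binarised, smoothed with a
separable Gaussian (`sigma`, default 2 µm — about half a cell diameter;
enough to remove voxel staircase without rounding the dome), and
triangulated by a marching-tetrahedra isosurface at `iso = 0.5`. Marching
tetrahedra was chosen over classic marching cubes because its per-tetrahedron
cases are unambiguous, giving a watertight, consistently oriented mesh
without lookup-table repair. Degenerate triangles are dropped and only the
largest connected component kept. For dome-shaped samples mounted on a
slide, `cut_base = TRUE` removes the flat cap on the volume's lower z face
(triangles entirely below half a voxel above the base plane), so nearest
surface queries see only the biological surface; deep cells near the base
then project to the dome flank, which is what the layer logic expects.
Point-to-mesh queries are exact per-triangle projections accelerated by
bounding-sphere culling seeded from a nearest-vertex pass; results are
identical to the exhaustive scan.

## Morphometrics

**Anisotropy.** A cell's shape is abstracted into three principal vectors:
the square roots of the eigenvalues of the population covariance
(divide-by-$N$) of its voxel-centre coordinates, in physical units. Each
magnitude is divided by their sum; the maximum is the anisotropy, so values
range from $1/3$ (isotropic, three equal magnitudes) to $1$ (rod-like).
Single-voxel cells have no extent and report `NA` with a warning.

**Networks and interfaces.** Two cells are adjacent iff they share at
least one voxel face (6-connectivity); the edge weight is the accumulated
physical face area, so corner and edge contacts — which carry zero area —
create no edge. Voxel faces, not sub-voxel triangulated walls, are the
areal unit; this makes a sharp conservation law testable: for every cell,
edge areas plus background-facing area equal its total boundary face area
exactly. Summaries per zone (counts, volume and anisotropy moments) and
per zone pair (interface counts and areas, within- and between-layer) are
emitted as CSV; hypothesis testing on those summaries is left to the user's
statistical environment.

## The synthetic phantom

All validation runs on generated phantoms with known truth, because no
segmented meristem stacks are distributed with the package. The phantom is
a solid hemisphere (default radius 40 µm, about a floral meristem) resting
on $z = 0$, partitioned into cells by nearest-seed (Voronoi) labelling:
seeds sit on concentric shells at depths $(s - \tfrac12)h$ for shell
thickness $h$ (default 5 µm, a typical meristematic cell diameter), spread
near-uniformly by a Fibonacci hemisphere lattice, with a deeper lattice
filling the core. Gaussian bumps added to the radial surface emulate
primordia. Seed counts scale with shell area so cells stay roughly
isotropic; the `layer_volume_profile` makes deeper cells larger
(`"increasing"`, the *Arabidopsis*-like gradient) or smaller
(`"decreasing"`, tomato-like). Jitter displaces each seed by a fraction of
its local spacing (default 0.1 — visible irregularity while keeping shells
distinct; validation uses 0 and 0.2); displaced seeds are clamped inside
the tissue so no cell vanishes. Voronoi labelling was chosen over a growth
simulation deliberately: it mimics the *input class* (watershed-style
convex-ish cells with watertight walls), not SAM biology.

What the phantom does not emulate: anisotropic real cell shapes, wall
curvature, segmentation errors (merged/split cells), imaging anisotropy and
surface noise. Perfect layer recovery on phantoms therefore demonstrates
correctness of the geometry, not expected accuracy on microscopy data,
which depends on segmentation and mesh quality.

## Problem sizes and numerical choices

Validation uses the default 40 µm phantom (~1000 cells, ~300k voxels) and a
16 µm phantom for exhaustive voxel-level checks; both complete in seconds.
Tolerances: nearest-point queries are verified to 1e-9 µm against the
exhaustive oracle; rigid-rotation invariance of surface distances to 1e-6
relative; mesh-volume agreement to 15% (voxel staircase); everything
discrete (partitions, layer labels, interface conservation) is exact.
Determinism is by construction — no stage uses randomness outside the
phantom generator, which consumes a single integer seed and restores the
caller's RNG state.

## Worked example

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_spec(jitter = 0, seed = 0))
atlas <- annotate_meristem(ph$volume, cut_base = TRUE,
                           apex_cell = ph$truth$apex_cell,
                           oc_depth = 12, oc_radius = 8)
glance(atlas)
autoplot(atlas)

net <- build_cell_network(ph$volume)
aniso <- cell_anisotropy(ph$volume)
zone_summaries(atlas$cells, atlas$annotation, net = net, anisotropy = aniso)
```

## Known limitations

* Segmentation quality is assumed; merged or split cells shift centroids
  and can misplace a layer locally.
* The method targets dome-shaped meristems; strongly concave tissue would
  break the "nearest surface point is outward" premise.
* Boundary zones are geometric; a genetic marker is the arbiter of real
  boundary identity, which geometry alone cannot provide.
* Interface areas are voxel-face sums and overestimate oblique walls by up
  to the usual staircase factor; comparisons across zones within one
  volume are unaffected.
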