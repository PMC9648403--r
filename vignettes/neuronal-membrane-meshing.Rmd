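---
title: "Progressive convolution-surface meshing of neuronal morphologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progressive convolution-surface meshing of neuronal morphologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurosculpt)
```

## The problem

Reconstructed neurons are distributed as *point-and-diameter* skeletons
(SWC files): a rooted tree of 3D points, each with a radius, the soma at
the root. Reaction–diffusion simulation in full 3D, tetrahedral meshing
(TetGen), and high-quality visualization all need something those files do
not provide: a closed, watertight, 2-manifold triangular membrane surface
with well-shaped triangles. Building that surface robustly is hard mainly
at branches, where naive tube-joining produces self-intersections and
cracks.

`neurosculpt` builds the membrane by *digital sculpting*: an icosphere is
placed at the soma and progressively deformed while a growth front marches
along the neuronal tree. Because the mesh only ever changes through local
operators that preserve connectivity invariants, the surface is a closed
2-manifold with Euler characteristic 2 at *every* stage of the evolution —
robustness is structural, not something repaired afterwards.

## The target shape: a finite-support convolution surface

The target geometry is the level set of a scalar field obtained by
convolving a kernel along the skeleton's line segments. For segment $i$
the field at point $p$ is

$$F_i(p) = \lambda_i \int_{V_i} f\big(\lVert p - q\rVert\big)\, dq,
\qquad
f(r) = \begin{cases}\left(1 - r^2/R_i^2\right)^2 & r \le R_i\\ 0 & r > R_i,\end{cases}$$

a fourth-degree (quartic) polynomial kernel with *finite support* $R_i$:
a segment influences only a capsule of radius $R_i$ around it, which makes
field evaluation local and cheap. The membrane is the iso-surface
$\sum_i F_i(p) = T$.

For an infinitely long straight segment the field at perpendicular
distance $x$ has the closed form
$16\lambda (R^2 - x^2)^{5/2} / (15 R^4)$, so requiring the iso-surface to
pass exactly at the neurite radius $d_i$ fixes the weight analytically:

$$\lambda_i = \frac{15\,T\,R_i^4}{16\,(R_i^2 - d_i^2)^{5/2}}.$$

Per segment, $d_i$ is the mean of the two endpoint SWC radii and
$R_i = 2 d_i$ (a configurable multiplier). Summation makes adjacent and
branching segments blend smoothly with no stitching. The closed form also
serves as an independent oracle in the test suite: the 16-point
Gauss–Legendre quadrature used for finite segments (internally subdivided
into pieces no longer than $R_i$) matches it to 0.1% at segment length
$50R$.

Two printed conventions in the field literature deserve a note. First, we
integrate the quartic kernel itself; the weight formula above only follows
from that form, which our symbolic re-derivation and numeric quadrature
cross-checks confirm. Second, the textbook projection update
$p \leftarrow p + \mathrm{sign}(F(p)-T)\cdot l_{step}\cdot \nabla F/\lVert\nabla F\rVert$
moves points *away* from the surface under the convention that $F$
decreases with distance from the skeleton ($\nabla F$ points inward); we
therefore step along $-\mathrm{sign}(F-T)\,\nabla F/\lVert\nabla F\rVert$,
so that $|F - T|$ decreases monotonically. Each projection starts with
step length half the shortest incident edge, halves the step whenever
$F-T$ changes sign (a bisection safeguard) or a trial fails to improve,
and stops at $|F-T| \le 10^{-4}T$ or 30 iterations. The gradient is
evaluated by central differences with step $10^{-4}\min_i d_i$; both field
and gradient are identically zero outside all support capsules.

## Growth, binding, and the soma

Growth is depth-first from the soma (children in ascending node id, for
determinism). The front segment participates in the field *truncated* at
the current arc length, so the surface extends continuously instead of
popping per segment. Each step advances the front by the local *marching
step* (half the local target edge length), queries the region of
influence, projects those vertices, and remeshes the region.

A vertex engages the surface *from inside*: it is projected only once the
field underneath it exceeds the iso-value (the growing tube pushes it
outward); after first reaching the iso-surface it is *bound* and tracks
the surface in both directions. Vertices the field never reaches — the
far side of the initial soma sphere — stay exactly where they are. This
is what realizes "no special soma processing": near the root the
superposed fields of the root-incident segments plump and blend the
sphere where they reach it, and the untouched spherical cap closes the
cell body. Without the binding rule, a weak early front field (below $T$
everywhere) would pull the whole sphere inward toward its maximum and the
mesh would implode; the rule is the operational reading of sculpting as
material *addition*.

## Quasi-uniform remeshing

The mesh quality invariant is *quasi-uniformity*: every edge length stays
within a band $(d, l_T)$. The remesher runs, per region and iteration:

1. **Split** edges longer than $\beta\,l(x)$ at their midpoint
   (queue-driven, longest edge first, new edges re-enqueued).
2. **Collapse** edges shorter than $\alpha\,l(x)$ to their midpoint,
   subject to legality (below).
3. **Equalize valences**: flip an edge exactly when it strictly decreases
   $\sum (\mathrm{valence} - 6)^2$ over the four affected vertices.
4. **Tangential relaxation**: move each vertex toward the barycenter of
   its one-ring weighted by the neighbours' barycentric (one-third) areas,
   $g_i = \sum_j A(p_j) p_j / \sum_j A(p_j)$, with the displacement
   projected into the tangent plane,
   $p_i \leftarrow p_i + \lambda_{damp} (I - n_i n_i^T)(g_i - p_i)$,
   from a per-pass position snapshot (Jacobi style, order-independent).
5. **Project** the region back onto the iso-surface.

$\alpha = 4/5$ and $\beta = 4/3$ are the classical incremental-remeshing
ratios that keep splitting and collapsing from fighting;
$\lambda_{damp} = 1$ because the projection after every pass already
suppresses the oscillation damping guards against. All thresholds are
evaluated at edge midpoints.

Collapse legality combines the combinatorial *link condition* (the
endpoint one-rings share exactly the two opposite vertices; additionally
the opposite vertices must not already be capped by both endpoint
triangles, which rejects the tetrahedron and fold cases, and $V > 4$)
with a geometric surrogate for "producing intersected triangles": the
collapse is refused if any surviving incident triangle's normal would
reverse. Edge flips are refused when they would duplicate an existing
edge. Split, collapse and flip change $(V, E, F)$ by $(+1,+3,+2)$,
$(-1,-3,-2)$ and $(0,0,0)$ respectively, so the Euler characteristic — and
with the legality rules, closedness and orientability — are invariant by
construction.

Two robustness rules matter in practice at crumpled fold regions (nearly
parallel or crossing branches, where the blended iso-surface folds and
triangle shape degenerates):

* a **split progress rule**: splitting a needle triangle's long edge can
  create a cross edge as long as the edge being split, re-feeding the
  queue indefinitely; a split is refused when either cross edge would
  exceed 95% of the split edge's length (equilateral triangles sit at
  87%, so ordinary splits are unaffected), and
* a **desperate-collapse path** for edges below the global floor $d$:
  these must disappear to keep the band, so their collapse may create
  edges up to $l_T$ (instead of $\beta\,l$ locally), skips the
  normal-reversal surrogate (meaningless inside an already-folded sliver;
  the link condition still protects topology), and, when blocked, retries
  after collapsing a sibling edge of the needle, flipping an incident
  edge, or splitting an over-stretched incident edge.

## Adaptive vertex density

The target edge length $l(x)$ adapts to two drivers:

* **Radius.** The base target is radius-proportional:
  $l_{max}(x) = l_{soma} \cdot r(x)/r_{soma}$, where $l_{soma}$ is the
  measured mean edge length of the initial icosphere and $r(x)$ the radius
  linearly interpolated along the nearest skeleton segment. Thin neurites
  automatically get proportionally denser vertices.
* **Branch curvature.** At a bifurcation with branch angle $\theta$ the
  two daughter tubes separate at the point $t$ on the child-direction
  bisector whose perpendicular distance to each child axis equals the
  support radius $R$; trigonometry places it at distance $R/\sin(\theta/2)$
  from the branch node with projection feet at $R/\tan(\theta/2)$ along
  each axis. Curvature peaks there, so within the interpolation radius
  $\rho = R$ of $t$ the target blends linearly down to
  $l_{min} = \kappa\, l_{max}$, reaching it at $t$. $\kappa = 0.25$ by
  default (the ratio is a free parameter of the method; 4:1 gives a
  visible density contrast without an edge-count explosion). Nodes with
  more than two children are handled pairwise, the smallest target
  winning. The marching step, being $l(x)/2$, automatically slows the
  front near separating points.

The global band is reported as $d = \tfrac{1}{2}\min_x l(x)$ and
$l_T = \beta\, l_{soma}$. An earlier design coupled them rigidly as
$d = l_T/2$; at soma scale that would forbid edges shorter than about
$0.67\,l_{soma}$, while meshing a neurite of radius $r \ll r_{soma}$
needs edges of order $r$ (a tube's circumference is only $2\pi r$), so
the band is instead anchored to the emitted target range. The stated
invariants ($d \le l_T/2$, all emitted targets within $[d, l_T]$) still
hold.

The initial icosphere level is chosen so its mean edge is about
$0.3\,r_{soma}$ (level 2, 162 vertices, for any soma radius under the
ratio rule); the *measured* mean edge then defines $l_{soma}$.

## The skeletal mapping

Every live mesh vertex is owned by exactly one skeleton node — the
endpoint nearest its closest-point projection among active segments, ties
to the lower node id. The per-node collections partition the live vertex
set; splits, collapses and flips rebind ownership automatically. ROI
queries prefilter candidate vertices through owners of nearby nodes
(radius plus a slack that provably bounds the vertex-to-owner distance)
before the exact Euclidean test, so the mapped route returns *identically*
the brute-force scan's answer — `brute_force_roi = TRUE` is a built-in
correctness oracle, and the pipeline's output is byte-identical either
way.

## What the synthetic generator emulates — and what it does not

`synth_morphology()` produces straight cables (uniform radius by
default), Y-bifurcations with a controlled branch angle, and random
binary trees with tapering radii (taper 0.92 per segment in the standard
batch, radius floor 0.4 of the neurite radius, segment length 5 µm, soma
radius 2–5 µm). These cover the geometric regimes the method must handle:
long tubes, branch blending at shallow and wide angles, and irregular
trees with thin distal segments. They do *not* emulate several features
of real reconstructions: spatially correlated tortuosity, spines,
multi-stem somata with measured contours, or annotation artifacts beyond
short trivial segments. Passing the test batch therefore demonstrates the
meshing machinery (topology, band, blending, adaptivity), not fidelity to
any particular biological archive. Random trees may also cross their own
branches — something real neurites rarely do — which is deliberately
retained: it stress-tests the fold-handling rules, at the cost of locally
crumpled (though still closed and manifold) geometry and a small number
of non-converged vertices reported for such meshes.

Preconditioning removes *trivial segments*: degree-2 nodes closer than
$\epsilon \cdot R_{neuro}$ to their parent (shortest first, until none
remains), with $\epsilon = 0.1$ and $R_{neuro}$ the soma radius —
both configurable, since neither constant is standardized; segments
shorter than the marching step would otherwise stall the front. Branch
points and tips are never removed, so tree topology is preserved exactly,
and the operation is idempotent.

## Numerical choices and degenerate inputs

* Quadrature: 16-point Gauss–Legendre per sub-segment piece; pieces no
  longer than $R_i$.
* Projection: tolerance $10^{-4} T$, 30 iterations, initial step
  $\tfrac12 l_e$; zero-gradient points are returned unchanged and
  flagged; the report counts non-converged vertices.
* Culling: a uniform hash grid with cell size $\max_i R_i$; sources are
  inserted in every cell their capsule's bounding box touches, so a
  point's own cell lists every source that can influence it.
* Collinear children (branch angle 180°) have no separating point;
  coincident parent–child nodes are removed by preconditioning
  (zero-length segments otherwise carry no direction).
* Ties (vertex equidistant from two nodes, collapse owner choice) always
  resolve toward the lower node id; all queues and passes iterate in
  index order — the entire pipeline is deterministic, and identical runs
  produce byte-identical OBJ files.
* A soma-only tree (no segments) yields the bare icosphere.

## Problem sizes

The standard validation batch (20 morphologies, seeds 1–20: five cables
of 9–13 nodes, six Y-bifurcations at 45°/90°/135°, nine random binary
trees of 19–93 nodes) produces meshes of roughly 1,300–30,000 vertices
and completes, with all quality checks, in under ten minutes on one CPU;
a single 10-node cable takes about two seconds. These sizes were chosen
as the smallest that exercise every regime — multi-segment tubes, all
three branch angles, deep random trees with radius taper — while keeping
the full batch comfortably interactive.

## Known limitations

* Self-intersection is handled locally (normal-reversal surrogate, fold
  cleanup), not globally: heavily overlapping branches produce meshes
  that are closed and 2-manifold but can interpenetrate geometrically.
* The soma is the field-blended remnant of the initial sphere, not a
  contour-fitted cell body.
* The iso-surface of a truncated growing segment is slightly narrower
  than the final tube near the front; the surface settles as the front
  passes, so transient mid-growth geometry should not be measured.
* Meshes are genus 0 by construction; morphologies whose membrane would
  genuinely require handles (touching, fused branches) are approximated
  by a genus-0 surface.
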