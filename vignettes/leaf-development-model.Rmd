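---
title: "A self-organizing model of leaf development: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A self-organizing model of leaf development: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 6)
library(leafdev)
```

## The model

`leafdev` simulates the development of a two-dimensional leaf as a
deterministic feedback loop among three coupled processes:

1. **Margin patterning.** The leaf margin (the marginal blastozone) is an
   open polyline of attributed sample points. New *convergence points* —
   abstractions of the PIN1 convergence points that position serrations,
   lobes and leaflets — appear wherever a permitted margin interval exceeds
   a threshold arc length λ from the nearest pre-existing convergence point
   or the leaf base. This is a Hofmeister-type spacing rule transplanted
   from phyllotaxis to the margin: new organs form where enough free space
   has opened up.

2. **Vein insertion.** Each new convergence point induces a vein connecting
   it to the existing vasculature. The attachment point P minimizes the
   total transport resistance
   τ = *b*·|CP − P| + *v*·|P − B|,
   where |CP − P| is the Euclidean length of the new vein, |P − B| the
   arc-length path from P to the leaf base B along the veins, and
   *b* ≥ *v* > 0 are per-unit-length resistances in the blade and along
   veins. On the interior of a straight vein the minimizer has a closed
   form: the new vein meets the old one at the constant branching angle
   θ = arccos(*v*/*b*), or it attaches at a branching point. A second
   heuristic clamps the angle between the new vein and the outward margin
   normal to ±σ_max, preventing grazing attachments.

3. **Vein-driven growth.** Veins elongate according to a *relative
   elementary growth rate* (RERG) profile: the local relative elongation
   rate as a piecewise-linear function of arc distance from the base, so a
   finite segment elongates by the line integral of the profile over its
   arc-length extent (evaluated analytically as trapezoid areas). Uniform
   profiles give exponential, self-similar expansion; basipetal profiles
   (a growth zone confined near the base) give oblong and ovate forms.
   Vein tips additionally advance by a fixed increment per step (additive
   marginal growth), the whole blade may expand isotropically, and the
   margin itself propagates outward along its normals. Margin points are
   carried by the vasculature: each point is associated with one vein,
   projected orthogonally onto it, and displaced by its projection's
   displacement.

Finally, **webbing** — geometric fairing of the margin — expresses the
lamina's resistance to stretching and bending, smoothing the contour between
the pinned convergence points. Strong webbing yields an entire margin; weak
webbing lets teeth and sinuses develop.

Abstract named **morphogens** modulate every process locally. A morphogen is
a per-point strength in [0, 1] (presets use crisp 0/1 flags), with a rule
declaring what it does: permit or block convergence points, rescale the
arc-length measure, weaken webbing (deepening sinuses), suppress marginal
growth (petiole, rachis), or act as an interval *barrier* behind which
distances are measured independently (separating the leaflets of a compound
leaf). Rules may also rewrite morphogens when a convergence point is
inserted: an exclusion radius ρ_r clears the morphogen around the new point
and an open band (ρ_bmin, ρ_bmax) introduces it at a distance — this is how
sinus identities propagate as the margin patterns itself recursively.

## Anatomy of a step

Each simulation step applies, in order: vein elongation and tip extension;
vein-driven margin transport; isotropic expansion; marginal growth by normal
propagation; Hofmeister-rule insertion of convergence points (iterated to a
fixpoint, with morphogen bookkeeping) and resistance-minimizing vein
attachment; webbing; margin resampling; and mesh maintenance. The loop
closes itself: growth widens the margin intervals, intervals trigger
convergence points, convergence points seed veins, and veins redirect
growth.

All state is checked each step: the margin must remain a simple polygon
(closed by the base edge), the vein tree connected, acyclic and planar, and
every vein terminal coincident with its convergence point.

## Parameters that matter

| Parameter | Meaning | Default |
|---|---|---|
| `dt` | time step (model time per step) | 0.02 |
| `lambda` | spacing threshold for new convergence points (length) | 1.5 |
| `delta` | margin radius associated with a new vein (length) | 0.3 |
| `tip_growth` | length added at each vein tip per step | 0.012 |
| `rerg` | piecewise-linear elongation-rate profile (1/time) | uniform 1 |
| `iso_rate` | isotropic blade expansion rate (1/time) | 0 |
| `margin_rate` | outward normal propagation speed (length/time) | 0.15 |
| `b`, `v` | blade and vein transport resistance (per length) | 2, 1 |
| `sigma_max` | clamp half-angle on the vein–normal angle (degrees) | 75 |
| `webbing` | stretch/bend weights, iterations, asymmetry, relax | see below |
| `competence` | max base distance and age for insertion | unlimited |

All lengths are dimensionless model units with the leaf base at the origin
and the midvein initially along +y; only ratios matter (for instance λ
relative to the primordium size sets when the first lateral veins appear).
The ratio *v*/*b* fixes the branching angle: *v*/*b* = 0.5 gives θ = 60°.

## The webbing functional and how it is minimized

Fairing minimizes the discrete contour energy

E = Σ_edges k_e (|e| − r_e)² + Σ_points k_b |p_{i−1} − 2p_i + p_{i+1}|²,

a stretching term against per-edge rest lengths r_e plus a bending term on
second differences. Convergence points, barrier points and the base
endpoints are pinned; per-point morphogen `webbing_factor`s rescale the
local weights, and the `asym` ratio multiplies the stretch weight on the
proximal (base-ward) side of each convergence point, which skews teeth into
serrations with a consistent lean.

Two numerical choices deserve note:

* **Majorize–minimize iterations.** Each iteration replaces the stretch
  term by its spring-form majorizer |e − r û₀|² (û₀ the current edge
  direction; by the triangle inequality this bounds the true term from
  above with equality at the current state), adds a unit inertia anchoring
  the current positions, and solves the resulting sparse quadratic exactly.
  The true energy is therefore nonincreasing, the motion per iteration
  scales with the webbing weights (which is what makes "webbing strength" a
  meaningful dial), and long-wavelength smoothing is not bottlenecked the
  way an explicitly stepped gradient descent would be.
* **Rest lengths track the current geometry.** r_e is recomputed each
  iteration as (1 − relax)·|e|, so every edge stays under tension. With
  fixed rest lengths a compressed edge pushes, and the contour can settle
  into buckled zigzag equilibria; with tension everywhere the only
  stationary contours between pins are taut, and with the bending term off
  the fairing limit is exactly the polyline of straight chords between
  pinned points.

A sweep that would make the margin self-intersect or drag it across a vein
is rejected and restarted with increased inertia, so fairing preserves all
geometric invariants by construction.

## Collisions and degenerate geometry

Outward normal offsetting at a concave corner can locally fold the margin
(the classic swallowtail of offset curves), and strongly indented margins
can press against neighbouring veins. A deterministic repair pass resolves
these: the points spanned by each crossing pair of margin edges are relaxed
toward their neighbour midpoints, wiggles across a vein are straightened
onto the chord between their unaffected neighbours, and all crossings are
treated simultaneously so mirror-symmetric states stay exactly symmetric.
Convergence points are moved only as a last resort, and vein tips are
re-synchronized to their convergence points whenever that happens.

Deeply indented faces also complicate vein routing: the resistance optimum
can lie behind a sinus, where a straight vein would exit the blade. The
attachment search therefore discards candidates occluded by the margin and
falls back to the inward-normal direction if everything is occluded.

## Patterning details

* The candidate site is the *weighted midpoint* of the largest permitted
  sub-interval, and a new sample point is created exactly there
  (attributes interpolated). Inserting the exact midpoint keeps the λ/2
  spacing guarantee exact and — unlike snapping to the nearest existing
  sample — cannot break mirror symmetry through tie-breaking.
* All qualifying sites of a patterning round are inserted **before** any
  insertion-triggered morphogen rules run, and rule zones are applied as
  order-independent unions with exclusion taking precedence. Otherwise the
  band painted around the first of a mirror pair of sites can block its
  twin, which breaks symmetry systematically.
* The patterning stage loops to a fixpoint, so an interval that grew far
  beyond λ (for example at initialization) is subdivided recursively until
  no permitted interval exceeds λ.
* Distances are weighted by morphogen metric factors; an edge is rescaled
  to the extent the morphogen is present on **both** its endpoints
  (`1 + min(s_i, s_j)(f − 1)` per rule), which reproduces crisp-flag
  semantics on 0/1 fields.
* Crisp 0/1 morphogen fields do not diffuse: a resampling split midpoint of
  a 0/1 edge carries the morphogen only if both endpoints do, and points on
  a morphogen boundary are never merged away. Without these two rules,
  repeated split/merge cycles measurably smear morphogen regions along the
  margin (the boundary drifts by one sample per merge), which corrupts
  long simulations.
* The competence window for insertion (maximum distance from the base,
  maximum leaf age) is global in `Params`; each morphogen rule additionally
  carries its own optional `max_age` gating its introduction band. This
  per-process reading lets a sinus-defining morphogen act only in early
  development while later convergence points still form.
* Since a candidate has no vein yet, its competence distance is the
  Euclidean distance from the leaf base — a proxy for the eventual
  path length along the vasculature.

## The blade mesh

The lamina is a conforming triangle mesh: every margin point, the base and
every vein junction are vertices, and every margin and vein edge is a mesh
edge. Because the vein tree's terminals lie on the margin, the tree
partitions the closed margin polygon into simple faces, and each face is
triangulated by ear clipping — no external triangulation library is needed,
and the face decomposition doubles as the routing query for the vein
segments bordering a new convergence point's lamina region.

Refinement bisects edges longer than a target. A triangle standing on a
constraint edge of length L forces interior edges of at least L/2, so
over-long constraint edges (long vein segments) are subdivided collinearly
first; this changes no margin or vein geometry. Passive deformation snaps
margin and vein vertices to their new positions and places interior
vertices by a cotangent-Laplacian harmonic solve, which reproduces affine
maps exactly; if any triangle inverts, the domain is retriangulated from
scratch. By default the mesh is rebuilt from the current margin and veins
when requested (`mesh_every`), since the simulation itself never reads
forces from it.

## What the presets emulate — and what they do not

The five presets span the qualitative repertoire: `simple-cordate` (an
entire-margined simple leaf with hierarchically branching venation),
`compound-teeth` (isotropic expansion re-opens patterned intervals, so
intercalary convergence points appear between older ones), `palmate-lobed`
(a sinus morphogen blocks insertion and weakens webbing in the
indentations, producing lobes), `palmate-simple-lobes` (the sinus
morphogen's competence window closes early, so no higher-order lobes
initiate), and `pinnate-compound` (a barrier morphogen partitions the
margin into leaflet intervals that pattern independently along a rachis).

Preset parameter values are this package's own calibration, chosen once so
that each preset robustly reproduces its qualitative morphology at desk
scale; sweep designs (the tested ranges of tip growth, branching angle,
webbing strength and growth-zone extent) are likewise fixed study
conditions. Two sweep-design choices are deliberate: growth-zone extents
are taken within the leaf's realized size so the restriction actually
binds, and the sinus-depth sweep spans webbing strengths at which the
convergence-point count stays constant, because weakening webbing further
triggers new convergence points whose protrusions cap and reset the very
sinuses being measured (the model's own re-patterning feedback).

The simulator is a caricature in the ways the underlying model is: there is
no molecular dynamics (morphogens are abstract flags, not auxin/PIN1/CUC
fields), no third dimension, folding or curvature, no closed (reticulate)
venation, no curved veins, and no cellular resolution or tissue mechanics.
Passing tests therefore certify the geometry and logic of the patterning
feedback, not any molecular mechanism.

## Problem sizes

The test-suite and acceptance runs use desk-scale problems chosen as the
package's study conditions: preset trajectories of 130–200 steps with
margins of a few hundred sample points, 50–100 randomized routing instances
against a 10⁵-point brute-force resistance scan, 1000 random growth
profiles against adaptive quadrature, and four- to five-point parameter
sweeps of full runs.

## Known limitations

* The fairing operator is one admissible realization of "resistance to
  stretching and bending"; its exact original form is not specified by the
  model, and different discrete operators would shift the tooth-shape
  boundary between sinuate and dentate margins.
* Collision repair is a geometric regularization, not a mechanical contact
  model; in extreme parameter regimes (very weak webbing with very fast
  growth) repair can fail, and the simulator then aborts with the failing
  stage named rather than continuing from an inconsistent state.
* Margin association is per-vein and transport is a per-step map, so
  material identity on the margin is only approximate where associations
  change.
* The floating-point mirror symmetry of symmetric presets is exact only up
  to accumulated rounding (observed ~10⁻¹⁴ over 200 steps), because the
  left and right margins sum arc lengths in opposite orders.

## A worked example

```{r example, eval = FALSE}
run <- simulate_leaf(preset = "simple-cordate")
fin <- run$states[[length(run$states)]]
fin
plot(fin)
aspect_ratio(fin$margin)
branching_angles(fin$veins)
```
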