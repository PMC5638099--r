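# leafdev

`leafdev` is a deterministic planar simulator of leaf development for
computational developmental biology: it grows a leaf from a small primordium
by iterating a self-organizing feedback loop among margin patterning, vein
insertion and vein-driven growth, and it reproduces the classic qualitative
repertoire of leaf forms — simple, toothed, lobed, palmate and pinnately
compound — from a single mechanism with different parameters.

## The model in brief

A leaf is an open polygon of attributed sample points (the margin, ending at
the two petiole-base endpoints), a rooted tree of straight vein segments
whose terminals lie on the margin, and a conforming triangle mesh of the
blade. Three processes close a feedback loop each time step:

* **Hofmeister-rule patterning.** A new *convergence point* (the abstraction
  of a PIN1 convergence point) forms at the weighted midpoint of any
  permitted margin interval whose arc length exceeds a threshold λ, measured
  from the nearest existing convergence point or the leaf base. Abstract
  morphogens on the margin (petiole, sinus, rachis, …) locally permit or
  block insertion, rescale the distance measure, weaken the webbing, freeze
  growth, or act as barriers that split the margin into independently
  patterned leaflet intervals.

* **Resistance-minimizing vein insertion.** Each new convergence point CP is
  connected to the vasculature at the point P minimizing the total transport
  resistance

  τ = b·|CP − P| + v·|P − B|,

  with b ≥ v > 0 the per-length resistances in the blade and along veins and
  |P − B| the path length to the leaf base. The interior optimum meets an
  existing vein at the constant branching angle θ = arccos(v/b); otherwise
  the vein attaches at a branching point. The angle to the outward margin
  normal is clamped to ±σ_max.

* **Vein-driven growth.** Veins elongate by the line integral of a
  piecewise-linear relative elementary growth rate (RERG) profile over their
  arc-length extent, tips extend by a fixed increment, the blade may expand
  isotropically, the margin propagates outward along its normals, and every
  margin point is carried by the displacement of its orthogonal projection
  onto its vein. Geometric fairing ("webbing") smooths the margin between
  the pinned convergence points.

## A worked example

```r
library(leafdev)

run <- simulate_leaf(preset = "simple-cordate")
fin <- run$states[[length(run$states)]]
fin
#> <leaf_state> step 200 (age 3): 643 margin points, 75 convergence points, 142 vein segments

round(aspect_ratio(fin$margin), 3)
#> [1] 0.824
round(median(branching_angles(fin$veins)), 1)
#> [1] 60
plot(fin)
```

Starting from a 1-unit primordium with a single apical convergence point,
200 steps of growth produce a heart-shaped simple leaf: 75 convergence
points have appeared as the margin outgrew the spacing threshold λ = 1.5,
each seeding a lateral vein. The aspect ratio (width : length ≈ 0.82) and
the median branching angle, exactly the resistance-law value
θ = arccos(v/b) = 60°, are emergent — neither is prescribed anywhere in the
configuration (individual angles vary where the σ_max clamp or a branch-point
attachment overrides the interior optimum).

Other presets: `"compound-teeth"`, `"palmate-lobed"`,
`"palmate-simple-lobes"`, `"pinnate-compound"`. A thin command-line wrapper
is installed under `inst/scripts/leafdev`:

```sh
Rscript inst/scripts/leafdev run --preset palmate-lobed --out lobed.svg
Rscript inst/scripts/leafdev sweep --preset simple-cordate \
    --param tip_growth --values 0.004,0.012,0.02 --steps 130 --out sweep.csv
```

See the methods vignette (`vignettes/leaf-development-model.Rmd`) for the
model's assumptions, the fairing functional, numerical choices and known
limitations.

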