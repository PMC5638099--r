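#' Declare a morphogen rule
#'
#' A morphogen is an abstract named attribute carried by margin sample points
#' (strength in \[0,1\]); it is not a diffusing concentration field. A rule
#' states how the presence of the morphogen modulates the developmental
#' processes acting at a point, and what happens to the morphogen when a new
#' convergence point is inserted nearby.
#'
#' Graded strengths enter all factors linearly: the effective factor at a
#' point with strength \eqn{s} is \eqn{1 + s (f - 1)}, so strength 0 leaves
#' the process unchanged and strength 1 applies the full factor. Boolean
#' effects (`blocks_cp`, `permits_cp`, `is_barrier`) treat a morphogen as
#' active when its strength exceeds 0.5.
#'
#' @param name Morphogen name. The presets use the reserved names
#'   `"petiole"`, `"sinus"`, `"rachis"` and `"leaflet-base"`.
#' @param blocks_cp If `TRUE`, no convergence point may form where the
#'   morphogen is active.
#' @param permits_cp If `TRUE`, convergence points may form *only* where some
#'   permitting morphogen is active (when any rule in the set has
#'   `permits_cp = TRUE`).
#' @param webbing_factor Multiplier (>= 0) on the local fairing (webbing)
#'   weights; values < 1 weaken webbing and deepen sinuses.
#' @param metric_factor Multiplier (> 0) on the arc-length measure used for
#'   all margin distances (spacing threshold, assignment radii).
#' @param growth_factor Multiplier (>= 0) on the local marginal (normal
#'   propagation) growth rate; 0 freezes the point, as for a petiole.
#' @param is_barrier If `TRUE`, points carrying the morphogen become interval
#'   barriers: margin distances are measured independently within the
#'   intervals they delimit and no patterning operation crosses them.
#' @param rho_r Exclusion radius: on insertion of a new convergence point the
#'   morphogen is removed from points at weighted arc distance < `rho_r`.
#' @param rho_bmin,rho_bmax Introduction band: on insertion the morphogen is
#'   set (strength 1) at points with weighted arc distance strictly between
#'   `rho_bmin` and `rho_bmax`. Requires `rho_bmin <= rho_bmax`.
#' @param max_age Optional competence limit for the introduction band: the
#'   band is applied only while the leaf age is at most `max_age` (`Inf`
#'   disables the limit).
#' @return An object of class `morphogen_rule`.
#' @export
morphogen_rule <- function(name,
                           blocks_cp = FALSE,
                           permits_cp = FALSE,
                           webbing_factor = 1,
                           metric_factor = 1,
                           growth_factor = 1,
                           is_barrier = FALSE,
                           rho_r = 0,
                           rho_bmin = 0,
                           rho_bmax = 0,
                           max_age = Inf) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (webbing_factor < 0) stop("webbing_factor must be >= 0")
  if (metric_factor <= 0) stop("metric_factor must be > 0")
  if (growth_factor < 0) stop("growth_factor must be >= 0")
  if (rho_r < 0) stop("rho_r must be >= 0")
  if (rho_bmin > rho_bmax) stop("rho_bmin must be <= rho_bmax")
  structure(list(
    name = name,
    blocks_cp = isTRUE(blocks_cp),
    permits_cp = isTRUE(permits_cp),
    webbing_factor = webbing_factor,
    metric_factor = metric_factor,
    growth_factor = growth_factor,
    is_barrier = isTRUE(is_barrier),
    rho_r = rho_r,
    rho_bmin = rho_bmin,
    rho_bmax = rho_bmax,
    max_age = max_age
  ), class = "morphogen_rule")
}

#' Simulation parameter set
#'
#' Collects every tunable of the simulator: time step, Hofmeister spacing
#' threshold, vein growth, transport resistances, webbing weights, competence
#' window and margin sampling density. All lengths are in dimensionless model
#' units (the leaf base sits at the origin and the midvein initially points
#' along +y); rates are per unit model time.
#'
#' @param dt Time step (model time units per simulation step).
#' @param lambda Hofmeister spacing threshold: a new convergence point forms
#'   in any permitted margin interval whose weighted arc length exceeds
#'   `lambda`.
#' @param delta Segment radius: margin points within weighted arc distance
#'   `delta` of a new convergence point become associated with its vein.
#' @param tip_growth Length added at each vein tip per step (additive marginal
#'   growth).
#' @param rerg Relative elementary growth rate profile for vein elongation;
#'   see [rerg_profile()].
#' @param iso_rate Isotropic blade expansion rate (relative, per time unit).
#' @param margin_rate Base outward normal-propagation speed of the margin
#'   (length per time unit), modulated per point by morphogen
#'   `growth_factor`s.
#' @param b,v Transport resistance per unit length in the blade (`b`) and
#'   along veins (`v`); requires `b >= v > 0`. The resistance-minimizing
#'   attachment yields branching angle `acos(v/b)`.
#' @param sigma_max Clamp half-angle in degrees (0, 90]: the angle between a
#'   new vein and the outward margin normal at its convergence point is
#'   restricted to `[-sigma_max, sigma_max]`.
#' @param webbing List with elements `stretch`, `bend` (energy weights >= 0),
#'   `iterations` (descent iterations per step), `asym` (proximal/distal
#'   stretch asymmetry ratio; 1 = symmetric) and `relax` (fractional rest
#'   length deficit in (0,1) driving the margin taut between pinned points).
#' @param competence List with `max_base_distance` (maximum distance from the
#'   leaf base at which a convergence point may still be inserted) and
#'   `max_age` (maximum leaf age for insertion); `Inf` disables either.
#' @param rules List of [morphogen_rule()] objects (possibly empty).
#' @param h_max,h_min Margin resampling bounds: edges longer than `h_max` are
#'   split, edges shorter than `h_min` merged. Defaults `lambda/10` and
#'   `h_max/4`.
#' @param n_steps Default number of simulation steps for [simulate_leaf()].
#' @param mesh_every Rebuild the blade mesh every `mesh_every` steps (0 =
#'   only on demand / at the end of a run).
#' @return An object of class `leaf_params`.
#' @export
leaf_params <- function(dt = 0.02,
                        lambda = 1.5,
                        delta = 0.3,
                        tip_growth = 0.012,
                        rerg = rerg_profile(0, 1),
                        iso_rate = 0,
                        margin_rate = 0.15,
                        b = 2,
                        v = 1,
                        sigma_max = 75,
                        webbing = list(),
                        competence = list(),
                        rules = list(),
                        h_max = lambda / 10,
                        h_min = h_max / 4,
                        n_steps = 200,
                        mesh_every = 0) {
  web_def <- list(stretch = 1, bend = 0.2, iterations = 10, asym = 1, relax = 0.15)
  web_def[names(webbing)] <- webbing
  comp_def <- list(max_base_distance = Inf, max_age = Inf)
  comp_def[names(competence)] <- competence
  if (!is.null(names(rules)) && any(nzchar(names(rules)))) names(rules) <- NULL
  for (r in rules) {
    if (!inherits(r, "morphogen_rule")) stop("each element of 'rules' must be a morphogen_rule")
  }
  names(rules) <- vapply(rules, `[[`, "", "name")
  if (anyDuplicated(names(rules))) stop("duplicate morphogen rule names")
  p <- structure(list(
    dt = dt, lambda = lambda, delta = delta,
    tip_growth = tip_growth, rerg = rerg, iso_rate = iso_rate,
    margin_rate = margin_rate, b = b, v = v, sigma_max = sigma_max,
    webbing = web_def, competence = comp_def, rules = rules,
    h_max = h_max, h_min = h_min, n_steps = n_steps,
    mesh_every = mesh_every
  ), class = "leaf_params")
  validate_params(p)
  p
}

validate_params <- function(p) {
  with(p, {
    if (!(b >= v && v > 0)) stop("need b >= v > 0")
    if (!(lambda > 0)) stop("need lambda > 0")
    if (!(sigma_max > 0 && sigma_max <= 90)) stop("sigma_max must be in (0, 90] degrees")
    if (!(dt > 0)) stop("dt must be > 0")
    if (delta < 0) stop("delta must be >= 0")
    if (tip_growth < 0 || iso_rate < 0 || margin_rate < 0) {
      stop("tip_growth, iso_rate and margin_rate must be >= 0")
    }
    if (h_min >= h_max) stop("need h_min < h_max")
    stopifnot(webbing$stretch >= 0, webbing$bend >= 0, webbing$iterations >= 0,
              webbing$asym > 0, webbing$relax >= 0, webbing$relax < 1)
  })
  invisible(p)
}

#' @export
print.leaf_params <- function(x, ...) {
  cat("<leaf_params>\n")
  cat(sprintf("  dt = %g, n_steps = %d, lambda = %g, delta = %g\n",
              x$dt, x$n_steps, x$lambda, x$delta))
  cat(sprintf("  tip_growth = %g, iso_rate = %g, margin_rate = %g\n",
              x$tip_growth, x$iso_rate, x$margin_rate))
  cat(sprintf("  b = %g, v = %g (theta = %.1f deg), sigma_max = %g deg\n",
              x$b, x$v, 180 / pi * acos(x$v / x$b), x$sigma_max))
  cat(sprintf("  webbing: stretch %g, bend %g, %d iter, asym %g, relax %g\n",
              x$webbing$stretch, x$webbing$bend, x$webbing$iterations,
              x$webbing$asym, x$webbing$relax))
  if (length(x$rules)) {
    cat("  morphogens:", paste(names(x$rules), collapse = ", "), "\n")
  }
  invisible(x)
}
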