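# The per-step feedback loop: growth -> margin transport -> patterning ->
# vein insertion -> webbing -> resampling -> meshing. The model is fully
# deterministic.

#' Advance the simulation by one step
#'
#' Stage order: (1) vein elongation and tip extension, (2) vein-driven margin
#' transport, (3) isotropic expansion, (4) marginal growth by normal
#' propagation, (5) Hofmeister-rule insertion of convergence points with
#' their morphogen rules, iterated to a fixpoint, (6) vein attachment for
#' each new convergence point, (7) webbing (fairing), (8) margin resampling,
#' (9) mesh maintenance. Invariants (margin simplicity, vein-tree validity,
#' terminal coincidence, strengths in \[0,1\]) are asserted; a violation
#' aborts with the failing stage named.
#'
#' @param state A `leaf_state`.
#' @param params A [leaf_params()].
#' @return The advanced `leaf_state`.
#' @export
leaf_step <- function(state, params) {
  margin <- state$margin
  veins0 <- state$veins
  stage <- function(name, ok) if (!isTRUE(ok)) {
    stop(sprintf("invariant violation at step %d, stage '%s'", state$step + 1L, name))
  }
  # (1) growth of the vasculature
  veins1 <- elongate_veins(veins0, params$rerg, params$dt)
  # (2) margin transported by its veins
  margin <- transport_margin(margin, veins0, veins1)
  et <- extend_tips(veins1, margin, params$tip_growth)
  state$veins <- et$veins
  state$margin <- et$margin
  # (3) isotropic expansion
  state <- isotropic_expand(state, params$iso_rate, params$dt)
  # (4) marginal growth; convergence points ride their vein tips instead
  rates <- params$margin_rate * point_factor(state$margin, params$rules, "growth_factor")
  rates[state$margin$is_cp] <- 0
  state$margin <- normal_propagation(state$margin, rates, params$dt)
  state <- resolve_collisions(state)
  stage("growth", margin_is_simple(state$margin))
  # (5)+(6) patterning and vein insertion, to a fixpoint. All sites of a
  # round are inserted before any morphogen rules are applied, so that
  # mirror-image sites are treated identically (a band painted around the
  # first of a mirror pair must not block the second).
  guard <- 0L
  repeat {
    sites <- find_insertion_sites(state$margin, state$veins, params, state$age)
    if (!length(sites)) break
    guard <- guard + 1L
    if (guard > 100L) stop("patterning failed to reach a fixpoint")
    # splice in all new sample points, descending edge order so earlier
    # insertions leave later edges valid; remember each new CP's index
    ord <- order(-vapply(sites, `[[`, 0, "edge"))
    new_cps <- integer(0)
    for (s in sites[ord]) {
      n_before <- margin_n(state$margin)
      ins <- insert_convergence_point(state$margin, s, params,
                                      vein_id = state$next_vein,
                                      step = state$step + 1L)
      state$margin <- ins$margin
      state$next_vein <- state$next_vein + 1L
      if (margin_n(state$margin) > n_before) {
        new_cps[new_cps > ins$cp] <- new_cps[new_cps > ins$cp] + 1L
      }
      new_cps <- c(new_cps, ins$cp)
    }
    state$margin <- apply_insertion_rules(state$margin, sort(new_cps),
                                          params$rules, state$age)
    for (cp in sort(new_cps)) {
      region <- candidate_region(state, cp)
      nrm <- margin_normals(state$margin)[cp, ]
      att <- optimal_attachment(state$margin$pos[cp, ], region,
                                params$b, params$v, params$sigma_max, nrm,
                                margin = state$margin)
      state <- attach_vein(state, cp, att)
    }
  }
  stage("patterning", margin_is_simple(state$margin))
  stage("vein insertion", vein_tree_valid(state$veins))
  # (7) webbing
  state$margin <- fair_margin(state$margin, params$webbing$stretch,
                              params$webbing$bend, params$webbing$iterations,
                              params$webbing$asym, params$webbing$relax,
                              params$rules, veins = state$veins)
  # (8) resampling
  state$margin <- resample_margin(state$margin, params$h_max, params$h_min,
                                  step = state$step + 1L)
  stage("webbing/resampling", margin_is_simple(state$margin))
  stage("morphogen range", all(state$margin$morph >= 0 & state$margin$morph <= 1))
  stage("terminal coincidence", terminals_coincide(state))
  state$step <- state$step + 1L
  state$age <- state$age + params$dt
  # (9) mesh maintenance
  if (params$mesh_every > 0 && state$step %% params$mesh_every == 0) {
    state$mesh <- triangulate_blade(state$margin, state$veins)
    stage("meshing", mesh_conforms(state$mesh))
  }
  state
}

# Collision handling: resolve margin self-crossings and margin-vein
# crossings, re-synchronizing vein tips whenever a convergence point is
# displaced so the vein geometry the crossing tests see is current.
resolve_collisions <- function(state, max_pass = 60L) {
  eps <- eps_geom(state$margin$pos)
  for (pass in seq_len(max_pass)) {
    out <- fold_repair_pass(state$margin, state$veins, pass, eps)
    state$margin <- out$margin
    state <- sync_vein_tips(state)
    if (out$clean) return(state)
  }
  out <- fold_repair_pass(state$margin, state$veins, max_pass + 1L, eps)
  if (!out$clean) stop("margin fold-over could not be resolved")
  state$margin <- out$margin
  sync_vein_tips(state)
}

# snap each vein's terminal segment to its (possibly collision-displaced)
# convergence point
sync_vein_tips <- function(state) {
  segs <- state$veins$segs
  changed <- FALSE
  for (w in unique(segs$vein)) {
    i <- which(state$margin$is_cp & !is.na(state$margin$vein_id) &
                 state$margin$vein_id == w)
    if (length(i) != 1L) next
    ch <- vein_chain(state$veins, w)
    k <- match(ch$id[nrow(ch)], segs$id)
    tip <- c(segs$x1[k], segs$y1[k])
    cp <- state$margin$pos[i, ]
    if (sqrt(sum((tip - cp)^2)) > 0) {
      segs$x1[k] <- cp[1]; segs$y1[k] <- cp[2]
      segs$s1[k] <- segs$s0[k] + sqrt((cp[1] - segs$x0[k])^2 + (cp[2] - segs$y0[k])^2)
      changed <- TRUE
    }
  }
  if (changed) state$veins <- new_vein_tree(segs, state$veins$base)
  state
}

# every vein tip coincides with its convergence point on the margin
terminals_coincide <- function(state) {
  eps <- 1e-6 * max(1, max(state$veins$segs$s1))
  for (w in unique(state$veins$segs$vein)) {
    i <- which(state$margin$is_cp & !is.na(state$margin$vein_id) &
                 state$margin$vein_id == w)
    if (length(i) != 1L) return(FALSE)
    if (sqrt(sum((state$margin$pos[i, ] - vein_tip(state$veins, w))^2)) > eps) {
      return(FALSE)
    }
  }
  TRUE
}

#' Run a full simulation
#'
#' Repeats [leaf_step()] from an initial primordium, keeping snapshots at a
#' configurable cadence. Identical inputs give identical trajectories (the
#' model is deterministic).
#'
#' @param params A [leaf_params()].
#' @param preset A primordium description (see [make_primordium()]) or a
#'   packaged preset name (see [leaf_preset()]); a preset name also supplies
#'   its parameters unless `params` is given explicitly.
#' @param n_steps Number of steps (default `params$n_steps`).
#' @param snapshot_every Keep every k-th state (0 = first and last only).
#' @return A `leaf_run`: list with `states` (snapshots; the last element is
#'   the final state), `steps` (their step numbers) and `params`.
#' @export
simulate_leaf <- function(params = NULL, preset = primordium_outline(),
                          n_steps = NULL, snapshot_every = 0) {
  if (is.character(preset)) {
    pr <- leaf_preset(preset)
    if (is.null(params)) params <- pr$params
    preset <- pr$primordium
  }
  if (is.null(params)) params <- leaf_params()
  if (is.null(n_steps)) n_steps <- params$n_steps
  state <- make_primordium(params, preset)
  states <- list(state)
  steps <- 0L
  for (k in seq_len(n_steps)) {
    state <- leaf_step(state, params)
    if (snapshot_every > 0 && state$step %% snapshot_every == 0 && k < n_steps) {
      states <- c(states, list(state))
      steps <- c(steps, state$step)
    }
  }
  if (params$mesh_every == 0) state$mesh <- triangulate_blade(state$margin, state$veins)
  states <- c(states, list(state))
  steps <- c(steps, state$step)
  structure(list(states = states, steps = steps, params = params),
            class = "leaf_run")
}

#' @export
print.leaf_run <- function(x, ...) {
  fin <- x$states[[length(x$states)]]
  cat(sprintf("<leaf_run> %d steps, %d snapshots; final: %d convergence points, %d vein segments, aspect %.3f\n",
              fin$step, length(x$states), sum(fin$margin$is_cp),
              nrow(fin$veins$segs), aspect_ratio(fin$margin)))
  invisible(x)
}

#' @export
plot.leaf_run <- function(x, which = length(x$states), ...) {
  plot(x$states[[which]], ...)
}

final_state <- function(run) run$states[[length(run$states)]]
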