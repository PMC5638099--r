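# Vein elongation via a piecewise-linear relative elementary growth rate
# (RERG) profile over arc distance from the leaf base, tip extension,
# isotropic blade expansion, and vein-driven transport of the margin.

#' Piecewise-linear RERG profile
#'
#' The relative elementary rate of growth is the local relative elongation
#' rate of an infinitesimal vein element, expressed as a function of the
#' arc-length distance `s` from the leaf base measured along the vasculature.
#' Between breakpoints the rate interpolates linearly; beyond the last
#' breakpoint it stays at the last value (use a trailing 0 for a basipetal
#' growth zone confined to the leaf base).
#'
#' @param breakpoints Strictly ascending arc distances from the base. A single
#'   breakpoint gives a uniform (constant-rate) profile.
#' @param rates Nonnegative RERG values (1/time) at the breakpoints.
#' @return An object of class `rerg_profile`.
#' @examples
#' rerg_profile(0, 1)            # uniform, rate 1
#' rerg_profile(c(0, 2), c(1, 0)) # basipetal growth zone of extent 2
#' @export
rerg_profile <- function(breakpoints, rates) {
  stopifnot(length(breakpoints) == length(rates), length(rates) >= 1)
  if (is.unsorted(breakpoints, strictly = TRUE)) stop("breakpoints must be strictly ascending")
  if (any(rates < 0)) stop("rates must be >= 0")
  structure(list(breakpoints = as.numeric(breakpoints), rates = as.numeric(rates)),
            class = "rerg_profile")
}

#' Evaluate a RERG profile
#'
#' @param profile A [rerg_profile()].
#' @param s Arc distances from the base (>= 0); vectorized.
#' @return Rates at `s`: linear interpolation inside the breakpoint range,
#'   constant extrapolation outside it.
#' @export
rerg_at <- function(profile, s) {
  b <- profile$breakpoints; r <- profile$rates
  if (length(b) == 1L) return(rep(r, length(s)))
  stats::approx(b, r, xout = s, rule = 2)$y
}

#' Elongation of a finite vein segment over one time step
#'
#' Returns `dt` times the line integral of the RERG profile over the
#' arc-length interval `[s1, s2]`, evaluated analytically per linear piece
#' (exact trapezoid areas).
#'
#' @param profile A [rerg_profile()].
#' @param s1,s2 Arc-length bounds, `0 <= s1 <= s2`.
#' @param dt Time step.
#' @return Added length.
#' @export
segment_elongation <- function(profile, s1, s2, dt) {
  stopifnot(s1 >= 0, s2 >= s1)
  if (s2 == s1) return(0)
  b <- profile$breakpoints
  knots <- sort(unique(c(s1, s2, b[b > s1 & b < s2])))
  y <- rerg_at(profile, knots)
  dt * sum(diff(knots) * (y[-length(y)] + y[-1]) / 2)
}

#' Elongate all vein segments according to the RERG profile
#'
#' Each segment gains `segment_elongation(profile, s0, s1, dt)` in length
#' while keeping its direction; positions propagate root-to-leaf so that a
#' subtree whose own segments do not grow is rigidly translated by the
#' displacement of its attachment point. Arc-length coordinates are
#' recomputed.
#'
#' @param veins A vein tree.
#' @param profile A [rerg_profile()].
#' @param dt Time step.
#' @return The elongated vein tree.
#' @export
elongate_veins <- function(veins, profile, dt) {
  segs <- veins$segs
  n <- nrow(segs)
  if (!n) return(veins)
  grow <- vapply(seq_len(n), function(k) {
    segment_elongation(profile, segs$s0[k], segs$s1[k], dt)
  }, 0)
  # process in topological (ascending s0) order so parents are updated first
  ord <- order(segs$s0)
  newsegs <- segs
  for (k in ord) {
    if (segs$parent[k] == 0L) {
      start <- veins$base
      s0 <- 0
    } else {
      pk <- match(segs$parent[k], newsegs$id)
      start <- c(newsegs$x1[pk], newsegs$y1[pk])
      s0 <- newsegs$s1[pk]
    }
    L <- segs$s1[k] - segs$s0[k]
    dir <- c(segs$x1[k] - segs$x0[k], segs$y1[k] - segs$y0[k])
    nd <- sqrt(sum(dir^2))
    dir <- if (nd > 0) dir / nd else c(0, 1)
    Lnew <- L + grow[k]
    newsegs$x0[k] <- start[1]; newsegs$y0[k] <- start[2]
    newsegs$x1[k] <- start[1] + dir[1] * Lnew
    newsegs$y1[k] <- start[2] + dir[2] * Lnew
    newsegs$s0[k] <- s0; newsegs$s1[k] <- s0 + Lnew
  }
  new_vein_tree(newsegs, veins$base)
}

#' Extend vein tips by a fixed length
#'
#' Advances the terminal point of every vein along its current direction by
#' `tip_growth` and moves each vein's convergence point on the margin with
#' its tip.
#'
#' @param veins A vein tree.
#' @param margin The margin, or `NULL` to update veins only.
#' @param tip_growth Length added at each tip.
#' @return A list with elements `veins` and `margin`.
#' @export
extend_tips <- function(veins, margin = NULL, tip_growth) {
  if (tip_growth == 0) return(list(veins = veins, margin = margin))
  segs <- veins$segs
  for (w in unique(segs$vein)) {
    ch <- vein_chain(veins, w)
    k <- match(ch$id[nrow(ch)], segs$id)
    dir <- c(segs$x1[k] - segs$x0[k], segs$y1[k] - segs$y0[k])
    nd <- sqrt(sum(dir^2))
    dir <- if (nd > 0) dir / nd else c(0, 1)
    old_tip <- c(segs$x1[k], segs$y1[k])
    segs$x1[k] <- segs$x1[k] + dir[1] * tip_growth
    segs$y1[k] <- segs$y1[k] + dir[2] * tip_growth
    segs$s1[k] <- segs$s1[k] + tip_growth
    if (!is.null(margin)) {
      cp <- which(margin$is_cp & !is.na(margin$vein_id) & margin$vein_id == w)
      for (i in cp) {
        # move the CP that rides this tip
        if (sqrt(sum((margin$pos[i, ] - old_tip)^2)) <= 1e-6 * max(1, segs$s1[k])) {
          margin$pos[i, ] <- c(segs$x1[k], segs$y1[k])
        }
      }
    }
  }
  list(veins = new_vein_tree(segs, veins$base), margin = margin)
}

# project point p onto the straight line through a vein's chain; returns the
# clamped arc parameter t in [0, Ltot] along the vein
vein_project_t <- function(chain, p) {
  a <- as.numeric(chain[1, c("x0", "y0")])
  b <- as.numeric(chain[nrow(chain), c("x1", "y1")])
  L <- sqrt(sum((b - a)^2))
  if (L == 0) return(0)
  u <- sum((p - a) * (b - a)) / L
  min(max(u, 0), L)
}

# position at arc parameter t along a vein's chain (t past the tip clamps)
vein_point_at <- function(chain, t) {
  lens <- chain$s1 - chain$s0
  cum <- cumsum(lens)
  k <- which(t <= cum + 1e-12)[1]
  if (is.na(k)) k <- nrow(chain)
  t0 <- if (k == 1) 0 else cum[k - 1]
  f <- if (lens[k] > 0) (t - t0) / lens[k] else 0
  f <- min(max(f, 0), 1)
  a <- as.numeric(chain[k, c("x0", "y0")])
  b <- as.numeric(chain[k, c("x1", "y1")])
  a + f * (b - a)
}

#' Transport the margin with its veins
#'
#' Each margin point is projected orthogonally onto the vein it is associated
#' with, in the before-step geometry; projections falling beyond the vein's
#' extent clamp to the nearest endpoint (the attachment point proximally, the
#' tip distally). The material point of the projection is located in the
#' after-step geometry (each segment stretches affinely), and the margin
#' point is displaced by the projection's displacement vector. Points with no
#' associated vein are displaced by the base displacement (zero).
#'
#' @param margin A `leaf_margin`.
#' @param veins_before,veins_after The vein tree before and after growth
#'   within the current step (same topology; segments matched by id).
#' @return The transported margin.
#' @export
transport_margin <- function(margin, veins_before, veins_after) {
  if (!identical(veins_before$segs$id, veins_after$segs$id)) {
    stop("vein trees must share topology (matching segment ids)")
  }
  veins <- unique(veins_before$segs$vein)
  pos <- margin$pos
  for (w in veins) {
    idx <- which(!is.na(margin$vein_id) & margin$vein_id == w)
    if (!length(idx)) next
    ch0 <- vein_chain(veins_before, w)
    ch1 <- veins_after$segs[match(ch0$id, veins_after$segs$id), , drop = FALSE]
    lens0 <- ch0$s1 - ch0$s0
    cum0 <- cumsum(lens0)
    for (i in idx) {
      t <- vein_project_t(ch0, pos[i, ])
      # material map: same segment, same fraction
      k <- which(t <= cum0 + 1e-12)[1]
      if (is.na(k)) k <- nrow(ch0)
      t0 <- if (k == 1) 0 else cum0[k - 1]
      f <- if (lens0[k] > 0) (t - t0) / lens0[k] else 0
      before <- as.numeric(ch0[k, c("x0", "y0")]) +
        f * (as.numeric(ch0[k, c("x1", "y1")]) - as.numeric(ch0[k, c("x0", "y0")]))
      after <- as.numeric(ch1[k, c("x0", "y0")]) +
        f * (as.numeric(ch1[k, c("x1", "y1")]) - as.numeric(ch1[k, c("x0", "y0")]))
      pos[i, ] <- pos[i, ] + (after - before)
    }
  }
  margin$pos <- pos
  margin
}

#' Propagate the margin outward along its normals
#'
#' Every interior point moves along its outward unit normal (adjacent-edge
#' bisector, oriented away from the blade interior) by `rate * dt`; the two
#' base endpoints stay fixed.
#'
#' @param margin A `leaf_margin`.
#' @param rates Per-point outward speeds (>= 0), recycled if scalar.
#' @param dt Time step.
#' @return The propagated margin.
#' @export
normal_propagation <- function(margin, rates, dt) {
  n <- margin_n(margin)
  rates <- rep_len(rates, n)
  stopifnot(all(rates >= 0))
  nor <- margin_normals(margin)
  mv <- nor * rates * dt
  mv[c(1, n), ] <- 0
  margin$pos <- margin$pos + mv
  margin
}

#' Isotropic expansion of the whole leaf
#'
#' Scales every position (margin, veins, mesh) by `1 + iso_rate * dt` about
#' the leaf base.
#'
#' @param state A `leaf_state`.
#' @param iso_rate Relative expansion rate (>= 0).
#' @param dt Time step.
#' @return The expanded state.
#' @export
isotropic_expand <- function(state, iso_rate, dt) {
  stopifnot(iso_rate >= 0)
  f <- 1 + iso_rate * dt
  if (f == 1) return(state)
  base <- state$veins$base
  scale_about <- function(xy) sweep(sweep(xy, 2, base, "-") * f, 2, base, "+")
  state$margin$pos <- scale_about(state$margin$pos)
  segs <- state$veins$segs
  p0 <- scale_about(cbind(segs$x0, segs$y0))
  p1 <- scale_about(cbind(segs$x1, segs$y1))
  segs$x0 <- p0[, 1]; segs$y0 <- p0[, 2]
  segs$x1 <- p1[, 1]; segs$y1 <- p1[, 2]
  segs$s0 <- segs$s0 * f
  segs$s1 <- segs$s1 * f
  state$veins <- new_vein_tree(segs, base)
  if (!is.null(state$mesh)) state$mesh$vertices <- scale_about(state$mesh$vertices)
  state
}
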