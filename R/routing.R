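# Vein routing: connect a new convergence point to the existing vasculature
# by minimizing the transport resistance tau = b |CP - P| + v |P - B| over the
# vein segments and branching points bordering the lamina face that contains
# the convergence point, with the margin-normal angle clamp.

# tips (terminal coordinates) of all veins; these coincide with margin
# convergence points and are not valid attachment sites
vein_tip_matrix <- function(veins) {
  ws <- unique(veins$segs$vein)
  t(vapply(ws, function(w) vein_tip(veins, w), numeric(2)))
}

#' Vein segments and branch points bordering a convergence point's face
#'
#' The lamina face containing a new convergence point is bounded by the
#' margin interval between its two neighbouring convergence points (or base
#' endpoints) and by the vein-tree path joining their terminals; a new vein
#' may attach anywhere on that path without crossing existing veins.
#'
#' @param state A `leaf_state`.
#' @param cp Margin index of a newly flagged convergence point (vein not yet
#'   attached).
#' @return A list with `segs` (data.frame of candidate segments) and
#'   `branch_points` (matrix of candidate junction coordinates with a
#'   `path` attribute of base distances).
#' @export
candidate_region <- function(state, cp) {
  margin <- state$margin
  veins <- state$veins
  n <- margin_n(margin)
  if (cp < 1 || cp > n || !margin$is_cp[cp]) stop("cp must be a margin convergence point")
  attached <- which(margin$is_cp & seq_len(n) != cp &
                      !is.na(margin$vein_id) &
                      margin$vein_id %in% veins$segs$vein)
  below <- attached[attached < cp]
  above <- attached[attached > cp]
  term_ids <- function(idx) {
    if (!length(idx)) return(integer(0)) # base endpoint: empty root path
    w <- margin$vein_id[idx]
    ch <- vein_chain(veins, w)
    root_path_ids(veins, ch$id[nrow(ch)])
  }
  ra <- term_ids(if (length(below)) max(below) else integer(0))
  rb <- term_ids(if (length(above)) min(above) else integer(0))
  path_ids <- union(setdiff(ra, rb), setdiff(rb, ra))
  if (!length(path_ids)) path_ids <- union(ra, rb) # single-midvein degenerate case
  segs <- veins$segs[match(path_ids, veins$segs$id), , drop = FALSE]
  if (!nrow(segs)) stop("convergence point has no bordering vein segments")
  # candidate branch points: endpoints of path segments that are not vein
  # tips (tips are margin convergence points)
  tips <- vein_tip_matrix(veins)
  eps <- eps_geom(margin$pos)
  pts <- rbind(as.matrix(segs[, c("x0", "y0")]), as.matrix(segs[, c("x1", "y1")]))
  spath <- c(segs$s0, segs$s1)
  keep <- !apply(pts, 1, function(q) any(sqrt(rowSums(sweep(tips, 2, q, "-")^2)) <= eps))
  pts <- pts[keep, , drop = FALSE]
  spath <- spath[keep]
  if (nrow(pts)) {
    dup <- duplicated(round(pts / max(eps, 1e-12)))
    pts <- pts[!dup, , drop = FALSE]
    spath <- spath[!dup]
  }
  attr(pts, "path") <- spath
  list(segs = segs, branch_points = pts)
}

rot2 <- function(theta) matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)

#' Resistance-minimizing attachment of a new vein
#'
#' Minimizes the total transport resistance `tau = b * |CP - P| + v * |P - B|`
#' over the candidate region. On each segment the interior minimizer is
#' computed in closed form (the attachment at which the new vein meets the
#' segment at the branching angle `theta = acos(v/b)`); it competes with the
#' candidate branch points. If the optimal vein's angle to the outward margin
#' normal at the convergence point exceeds `sigma_max`, the vein direction is
#' clamped to `+/- sigma_max` about the normal and attached where the clamped
#' ray first meets the candidate region (the tighter of the two signs wins);
#' if neither clamped ray hits, the unclamped optimum is returned with
#' attribute `clamp_fallback = TRUE`.
#'
#' @param cp_pos Convergence point coordinate.
#' @param region Output of [candidate_region()].
#' @param b,v Blade and vein resistances, `b >= v > 0`.
#' @param sigma_max Clamp half-angle in degrees, or `NULL` to disable.
#' @param normal Outward unit margin normal at the convergence point
#'   (required when `sigma_max` is given).
#' @param margin Optional `leaf_margin` used for a visibility filter: in a
#'   deeply indented face the resistance optimum may lie behind a sinus, and
#'   a straight vein to it would leave the blade; candidates whose connecting
#'   segment crosses the margin are then discarded.
#' @return A list (class `vein_attachment`) with `kind`
#'   (`"interior"`/`"branch"`), `location`, `path_to_base`, `tau`, `seg_id`
#'   (`NA` for branch points) and `clamped`.
#' @export
optimal_attachment <- function(cp_pos, region, b, v, sigma_max = NULL, normal = NULL,
                               margin = NULL) {
  stopifnot(b >= v, v > 0)
  segs <- region$segs
  visible <- function(loc) {
    is.null(margin) || !vein_crosses(loc, cp_pos, segs[0, , drop = FALSE], margin,
                                     eps_geom(margin$pos))
  }
  cand <- list()
  add <- function(kind, loc, path, seg_id) {
    if (!visible(loc)) return(invisible())
    tau <- b * sqrt(sum((cp_pos - loc)^2)) + v * path
    cand[[length(cand) + 1L]] <<- list(kind = kind, location = loc,
                                       path_to_base = path, tau = tau,
                                       seg_id = seg_id)
  }
  for (k in seq_len(nrow(segs))) {
    A <- c(segs$x0[k], segs$y0[k]); B2 <- c(segs$x1[k], segs$y1[k])
    L <- sqrt(sum((B2 - A)^2))
    if (L == 0) next
    u_hat <- (B2 - A) / L
    uF <- sum((cp_pos - A) * u_hat)
    perp <- cp_pos - (A + uF * u_hat)
    h <- sqrt(sum(perp^2))
    if (b > v) {
      w <- h * v / sqrt(b^2 - v^2)
      ustar <- uF - w
      if (ustar > 0 && ustar < L) {
        add("interior", A + ustar * u_hat, segs$s0[k] + ustar, segs$id[k])
      }
    }
  }
  bp <- region$branch_points
  if (!is.null(bp) && nrow(bp)) {
    sp <- attr(bp, "path")
    for (k in seq_len(nrow(bp))) add("branch", as.numeric(bp[k, ]), sp[k], NA_integer_)
  }
  if (!length(cand) && !is.null(normal) && !is.null(margin)) {
    # every candidate is occluded by a sinus: attach along the inward normal,
    # which leaves the convergence point into the blade interior
    hit <- ray_region_hit(cp_pos, -normal, segs)
    if (!is.null(hit) && visible(hit$loc)) {
      tau <- b * hit$dist + v * hit$path
      cand <- list(list(kind = "interior", location = hit$loc,
                        path_to_base = hit$path, tau = tau, seg_id = hit$seg_id))
    }
  }
  if (!length(cand)) stop("no attachment candidates")
  pick_best <- function(cl) {
    taus <- vapply(cl, `[[`, 0, "tau")
    lens <- vapply(cl, function(x) sqrt(sum((cp_pos - x$location)^2)), 0)
    paths <- vapply(cl, `[[`, 0, "path_to_base")
    cl[[order(taus, lens, paths)[1]]]
  }
  best <- pick_best(cand)
  best$clamped <- FALSE
  # angle clamp against the outward margin normal
  if (!is.null(sigma_max) && !is.null(normal)) {
    dirv <- cp_pos - best$location
    nd <- sqrt(sum(dirv^2))
    if (nd > 0) {
      cosang <- sum(dirv / nd * normal)
      sig <- acos(min(max(cosang, -1), 1)) * 180 / pi
      if (sig > sigma_max) {
        hits <- list()
        for (sgn in c(1, -1)) {
          rd <- -as.numeric(rot2(sgn * sigma_max * pi / 180) %*% normal)
          hit <- ray_region_hit(cp_pos, rd, segs)
          if (!is.null(hit) && !visible(hit$loc)) hit <- NULL
          if (!is.null(hit)) {
            tau <- b * hit$dist + v * hit$path
            hits[[length(hits) + 1L]] <- list(kind = "interior", location = hit$loc,
                                              path_to_base = hit$path, tau = tau,
                                              seg_id = hit$seg_id)
          }
        }
        if (length(hits)) {
          best <- pick_best(hits)
          best$clamped <- TRUE
        } else {
          attr(best, "clamp_fallback") <- TRUE
        }
      }
    }
  }
  class(best) <- "vein_attachment"
  best
}

# first intersection of the ray origin + t*dir (t > 0) with the candidate
# segments; returns location, base path and distance, or NULL
ray_region_hit <- function(origin, dir, segs) {
  best <- NULL
  for (k in seq_len(nrow(segs))) {
    A <- c(segs$x0[k], segs$y0[k]); B2 <- c(segs$x1[k], segs$y1[k])
    d2 <- B2 - A
    den <- dir[1] * d2[2] - dir[2] * d2[1]
    if (abs(den) < 1e-14) next
    w <- A - origin
    t <- (w[1] * d2[2] - w[2] * d2[1]) / den
    u <- (w[1] * dir[2] - w[2] * dir[1]) / den
    if (t > 1e-12 && u >= -1e-12 && u <= 1 + 1e-12) {
      u <- min(max(u, 0), 1)
      loc <- A + u * d2
      L <- sqrt(sum(d2^2))
      if (is.null(best) || t < best$t) {
        best <- list(t = t, loc = loc, dist = t * sqrt(sum(dir^2)),
                     path = segs$s0[k] + u * L, seg_id = segs$id[k])
      }
    }
  }
  best
}

#' Attach a new vein from an attachment point to a convergence point
#'
#' Adds a straight vein segment from the attachment to the convergence
#' point. An attachment interior to an existing segment splits it in two
#' (arc-length coordinates preserved); the new vein takes the convergence
#' point's reserved vein id. The new segment is rejected if it would cross an
#' existing vein or the margin.
#'
#' @param state A `leaf_state`.
#' @param cp Margin index of the convergence point.
#' @param attachment A `vein_attachment` from [optimal_attachment()].
#' @return The updated `leaf_state`.
#' @export
attach_vein <- function(state, cp, attachment) {
  margin <- state$margin
  veins <- state$veins
  segs <- veins$segs
  w <- margin$vein_id[cp]
  if (is.na(w)) stop("convergence point has no reserved vein id")
  cp_pos <- margin$pos[cp, ]
  loc <- attachment$location
  newlen <- sqrt(sum((cp_pos - loc)^2))
  eps <- eps_geom(margin$pos)
  # forbid crossings (touching at the attachment endpoint is fine)
  if (vein_crosses(loc, cp_pos, segs, margin, eps)) {
    stop("new vein would cross an existing vein or the margin")
  }
  next_id <- max(segs$id) + 1L
  if (identical(attachment$kind, "interior")) {
    k <- match(attachment$seg_id, segs$id)
    A <- c(segs$x0[k], segs$y0[k]); B2 <- c(segs$x1[k], segs$y1[k])
    u <- sqrt(sum((loc - A)^2))
    L <- segs$s1[k] - segs$s0[k]
    if (u <= eps || u >= L - eps) {
      # effectively an endpoint: treat as branch attachment there
      parent_id <- if (u <= eps) segs$parent[k] else segs$id[k]
      if (u <= eps) loc <- A else loc <- B2
    } else {
      old <- segs[k, ]
      # proximal half keeps the id; distal half gets a fresh id
      distal_id <- next_id
      next_id <- next_id + 1L
      segs$x1[k] <- loc[1]; segs$y1[k] <- loc[2]
      segs$s1[k] <- old$s0 + u
      distal <- old
      distal$id <- distal_id
      distal$parent <- old$id
      distal$x0 <- loc[1]; distal$y0 <- loc[2]
      distal$s0 <- old$s0 + u
      # children that attached at the old end now hang off the distal half
      kids <- segs$id != old$id & segs$parent == old$id
      segs$parent[kids] <- distal_id
      segs <- rbind(segs, distal)
      parent_id <- old$id
    }
  } else {
    # branch point: parent is the segment ending at the location (0 at base)
    atb <- sqrt(sum((loc - veins$base)^2)) <= eps
    if (atb) {
      parent_id <- 0L
    } else {
      ends <- sqrt((segs$x1 - loc[1])^2 + (segs$y1 - loc[2])^2)
      j <- which(ends <= eps)
      if (!length(j)) stop("branch attachment does not coincide with a junction")
      parent_id <- segs$id[j[1]]
    }
  }
  newseg <- data.frame(id = next_id, parent = parent_id, vein = as.integer(w),
                       x0 = loc[1], y0 = loc[2], x1 = cp_pos[1], y1 = cp_pos[2],
                       s0 = attachment$path_to_base,
                       s1 = attachment$path_to_base + newlen)
  segs <- rbind(segs, newseg)
  state$veins <- new_vein_tree(segs, veins$base)
  state
}

# does the candidate segment (a -> b) cross existing veins or margin edges
# anywhere away from its own endpoints?
vein_crosses <- function(a, b, segs, margin, eps) {
  n1 <- nrow(segs)
  p <- margin$pos
  m <- nrow(p) - 1L
  q1 <- rbind(as.matrix(segs[, c("x0", "y0")]), p[1:m, , drop = FALSE])
  q2 <- rbind(as.matrix(segs[, c("x1", "y1")]), p[2:(m + 1L), , drop = FALSE])
  a1 <- matrix(a, nrow(q1), 2, byrow = TRUE)
  b1 <- matrix(b, nrow(q1), 2, byrow = TRUE)
  segments_intersect_any(a1, b1, q1, q2, max(eps, 1e-9))
}
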