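# Hofmeister-rule patterning: insertion of convergence points in margin
# intervals whose morphogen-weighted arc length exceeds the spacing threshold
# lambda, plus the morphogen bookkeeping triggered by each insertion.

# logical: may a convergence point form at each point?
cp_permitted <- function(margin, rules) {
  ok <- rep(TRUE, margin_n(margin))
  has_permit <- any(vapply(rules, `[[`, TRUE, "permits_cp"))
  if (has_permit) {
    permit <- rep(FALSE, margin_n(margin))
    for (r in rules) if (r$permits_cp) permit <- permit | morph_active(margin, r$name)
    ok <- ok & permit
  }
  for (r in rules) if (r$blocks_cp) ok <- ok & !morph_active(margin, r$name)
  ok & !margin$barrier
}

# indices bounding the maximal patterning intervals: base endpoints,
# convergence points and barrier points
margin_anchors <- function(margin) {
  sort(unique(c(1L, margin_n(margin), which(margin$is_cp | margin$barrier))))
}

# weighted arc distance from point i to every point, measured independently
# within barrier intervals (Inf beyond a barrier)
weighted_dist_from <- function(margin, i, rules) {
  wel <- weighted_edge_lengths(margin, rules)
  n <- margin_n(margin)
  d <- numeric(n)
  if (i > 1) d[(i - 1):1] <- cumsum(wel[(i - 1):1])
  if (i < n) d[(i + 1):n] <- cumsum(wel[i:(n - 1)])
  bar <- which(margin$barrier)
  for (bidx in bar[bar < i]) d[seq_len(bidx - 1L)] <- Inf
  for (bidx in bar[bar > i]) if (bidx < n) d[(bidx + 1L):n] <- Inf
  d
}

#' Find margin intervals ready for a new convergence point
#'
#' Scans each maximal margin interval bounded by consecutive convergence
#' points, barrier points or base endpoints. An interval qualifies when the
#' morphogen-weighted arc length of its largest permitted sub-interval
#' exceeds the spacing threshold `lambda` and the candidate position (the
#' weighted midpoint of that sub-interval) passes the competence filters
#' (distance from the leaf base and leaf age).
#'
#' @param margin A `leaf_margin`.
#' @param veins The vein tree (supplies the leaf base for the competence
#'   distance; the candidate has no vein yet, so the Euclidean distance from
#'   the base is used).
#' @param params A [leaf_params()].
#' @param age Current leaf age.
#' @return A list of candidate sites ordered by descending weighted length
#'   (ties: proximal first). Each site has elements `bounds` (anchor index
#'   pair), `wlen`, `edge` (index of the edge carrying the midpoint), `tfrac`
#'   (weighted fraction along that edge) and `pos`.
#' @export
find_insertion_sites <- function(margin, veins, params, age = 0) {
  rules <- params$rules
  if (age > params$competence$max_age) return(list())
  anch <- margin_anchors(margin)
  perm <- cp_permitted(margin, rules)
  wel <- weighted_edge_lengths(margin, rules)
  sites <- list()
  for (k in seq_len(length(anch) - 1L)) {
    a <- anch[k]; b <- anch[k + 1L]
    if (b - a < 2L) next
    inner <- (a + 1L):(b - 1L)
    # permitted runs of points within (a, b); interval bounds count as run
    # ends so edges adjacent to an anchor are usable when the inner endpoint
    # is permitted
    pmask <- perm[inner]
    if (!any(pmask)) next
    r <- rle(pmask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    best <- NULL
    for (q in seq_along(r$values)) {
      if (!r$values[q]) next
      rs <- inner[starts[q]]; re <- inner[ends[q]]
      # edges fully inside the permitted run, extended to the anchors when
      # the run touches them
      e_lo <- if (rs == a + 1L) a else rs
      e_hi <- if (re == b - 1L) b else re
      if (e_hi <= e_lo) next
      ed <- e_lo:(e_hi - 1L)
      wl <- sum(wel[ed])
      if (is.null(best) || wl > best$wlen) {
        best <- list(wlen = wl, edges = ed, rs = rs, re = re)
      }
    }
    if (is.null(best) || best$wlen <= params$lambda) next
    # weighted midpoint of the permitted sub-interval
    cw <- cumsum(wel[best$edges])
    half <- best$wlen / 2
    ei <- which(cw >= half - 1e-15)[1]
    edge <- best$edges[ei]
    prev <- if (ei == 1) 0 else cw[ei - 1]
    tf <- if (wel[edge] > 0) (half - prev) / wel[edge] else 0.5
    tf <- min(max(tf, 0), 1)
    pos <- margin$pos[edge, ] + tf * (margin$pos[edge + 1L, ] - margin$pos[edge, ])
    # competence: the candidate has no vein yet; use Euclidean distance from
    # the leaf base as the base-path proxy
    if (sqrt(sum((pos - veins$base)^2)) > params$competence$max_base_distance) next
    # the midpoint itself must be permitted (guards against landing on a
    # blocked sample when tf snaps to an end)
    snap <- if (tf < 0.5) edge else edge + 1L
    if (!perm[snap]) next
    sites[[length(sites) + 1L]] <- list(bounds = c(a, b), wlen = best$wlen,
                                        edge = edge, tfrac = tf, pos = pos)
  }
  if (!length(sites)) return(sites)
  # descending weighted length; ties proximal-first (nearer a base endpoint
  # along the margin), left before right
  n <- margin_n(margin)
  prox <- vapply(sites, function(s) min(s$edge, n - s$edge), 0)
  idx <- vapply(sites, function(s) s$edge, 0)
  ord <- order(-vapply(sites, `[[`, 0, "wlen"), prox, idx)
  sites[ord]
}

#' Insert a convergence point at a candidate site
#'
#' A new sample point is created at the site's exact weighted midpoint
#' (attributes interpolated from the edge endpoints), flagged as a
#' convergence point, and margin points within weighted arc distance `delta`
#' become associated with the new (yet-to-be-attached) vein; the association
#' never crosses an existing convergence point or barrier.
#'
#' @param margin A `leaf_margin`.
#' @param site A site from [find_insertion_sites()] computed on this margin.
#' @param params A [leaf_params()].
#' @param vein_id Identifier reserved for the vein that will terminate at the
#'   new convergence point.
#' @param step Birth step recorded on the new point.
#' @return A list with the updated `margin` and `cp` (index of the new
#'   convergence point).
#' @export
insert_convergence_point <- function(margin, site, params, vein_id, step = 0L) {
  k <- site$edge; tf <- site$tfrac
  eps <- 1e-9
  if (tf <= eps || tf >= 1 - eps) {
    i <- if (tf <= eps) k else k + 1L
    if (margin$is_cp[i]) stop("site coincides with an existing convergence point")
  } else {
    # splice in the new sample point
    i <- k + 1L
    pos <- margin$pos[k, ] + tf * (margin$pos[k + 1L, ] - margin$pos[k, ])
    ins <- function(x, val) append(x, val, after = k)
    margin$pos <- rbind(margin$pos[1:k, , drop = FALSE], pos,
                        margin$pos[(k + 1L):margin_n(margin), , drop = FALSE])
    m1 <- margin$morph[k, ]; m2 <- margin$morph[k + 1L, ]
    crisp <- (m1 == 0 | m1 == 1) & (m2 == 0 | m2 == 1)
    mr <- ifelse(crisp, m1 * m2, m1 * (1 - tf) + m2 * tf)
    margin$morph <- rbind(margin$morph[1:k, , drop = FALSE], mr,
                          margin$morph[(k + 1L):nrow(margin$morph), , drop = FALSE])
    margin$is_cp <- ins(margin$is_cp, FALSE)
    margin$vein_id <- ins(margin$vein_id, NA_integer_)
    margin$birth_step <- ins(margin$birth_step, as.integer(step))
    margin$barrier <- ins(margin$barrier, FALSE)
  }
  margin$is_cp[i] <- TRUE
  margin$vein_id[i] <- as.integer(vein_id)
  # delta-ball association, clipped at convergence points and barriers
  d <- weighted_dist_from(margin, i, params$rules)
  ball <- which(d <= params$delta)
  blockers <- which((margin$is_cp | margin$barrier) & seq_len(margin_n(margin)) != i)
  lo <- blockers[blockers < i]
  hi <- blockers[blockers > i]
  if (length(lo)) ball <- ball[ball > max(lo)]
  if (length(hi)) ball <- ball[ball < min(hi)]
  margin$vein_id[ball] <- as.integer(vein_id)
  list(margin = margin, cp = i)
}

#' Apply per-morphogen insertion rules around a new convergence point
#'
#' For each rule, the morphogen is removed from points at weighted arc
#' distance < `rho_r` from the convergence point and introduced (strength 1)
#' at points with distance strictly inside `(rho_bmin, rho_bmax)`, subject to
#' the rule's own competence age. Barrier morphogens promote the points they
#' mark to interval barriers.
#'
#' @param margin A `leaf_margin`.
#' @param cp Indices of the convergence points inserted this step (all
#'   processed together: the union of exclusion zones is applied after the
#'   union of introduction bands, so the result does not depend on the order
#'   of the convergence points).
#' @param rules List of [morphogen_rule()]s.
#' @param age Current leaf age (checked against each rule's `max_age`).
#' @return The updated margin.
#' @export
apply_insertion_rules <- function(margin, cp, rules, age = 0) {
  if (!length(rules) || !length(cp)) return(margin)
  dmat <- vapply(cp, function(i) weighted_dist_from(margin, i, rules),
                 numeric(margin_n(margin)))
  for (r in rules) {
    excl <- if (r$rho_r > 0) rowSums(dmat < r$rho_r) > 0 else FALSE
    intro <- if (r$rho_bmax > r$rho_bmin && age <= r$max_age) {
      # a convergence point keeps its protrusion identity: introduction
      # bands never paint onto existing convergence points
      rowSums(dmat > r$rho_bmin & dmat < r$rho_bmax) > 0 & !margin$is_cp
    } else FALSE
    touched <- FALSE
    if (any(intro)) {
      if (!(r$name %in% colnames(margin$morph))) {
        margin$morph <- cbind(margin$morph, 0)
        colnames(margin$morph)[ncol(margin$morph)] <- r$name
      }
      margin$morph[intro, r$name] <- 1
      touched <- TRUE
    }
    if (any(excl) && r$name %in% colnames(margin$morph)) {
      margin$morph[excl, r$name] <- 0
      touched <- TRUE
    }
    if (touched && r$is_barrier) {
      margin$barrier <- margin$barrier | morph_active(margin, r$name)
    }
  }
  margin
}
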