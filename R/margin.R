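# Margin container: an ordered open polyline of attributed sample points (the
# marginal blastozone). First and last points are the two petiole-base
# endpoints; closing the polyline with the base edge must give a simple
# polygon. Morphogen strengths live in an n x m matrix with one column per
# morphogen name.

new_leaf_margin <- function(pos, is_cp = NULL, vein_id = NULL, birth_step = NULL,
                            morph = NULL, barrier = NULL) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  n <- nrow(pos)
  stopifnot(ncol(pos) == 2, n >= 3)
  if (is.null(is_cp)) is_cp <- rep(FALSE, n)
  if (is.null(vein_id)) vein_id <- rep(NA_integer_, n)
  if (is.null(birth_step)) birth_step <- rep(0L, n)
  if (is.null(morph)) morph <- matrix(numeric(0), n, 0)
  if (is.null(barrier)) barrier <- rep(FALSE, n)
  structure(list(pos = pos, is_cp = is_cp, vein_id = as.integer(vein_id),
                 birth_step = as.integer(birth_step), morph = morph,
                 barrier = barrier),
            class = "leaf_margin")
}

margin_n <- function(m) nrow(m$pos)

# subset a margin's per-point attributes by index vector
margin_subset <- function(m, idx) {
  new_leaf_margin(m$pos[idx, , drop = FALSE], m$is_cp[idx], m$vein_id[idx],
                  m$birth_step[idx], m$morph[idx, , drop = FALSE], m$barrier[idx])
}

# geometric tolerance scaled to the current extent
eps_geom <- function(pos) {
  rng <- apply(pos, 2, range)
  1e-9 * max(sqrt(sum((rng[2, ] - rng[1, ])^2)), 1)
}

morph_strength <- function(margin, name) {
  if (name %in% colnames(margin$morph)) margin$morph[, name] else rep(0, margin_n(margin))
}

morph_active <- function(margin, name) morph_strength(margin, name) > 0.5

# per-point multiplicative factor for one of the morphogen-modulated
# processes; graded: 1 + s * (f - 1)
point_factor <- function(margin, rules, what) {
  f <- rep(1, margin_n(margin))
  for (r in rules) {
    s <- morph_strength(margin, r$name)
    f <- f * (1 + s * (r[[what]] - 1))
  }
  f
}

# Euclidean edge lengths, edges i -> i+1
edge_lengths <- function(margin) {
  d <- diff(margin$pos)
  sqrt(rowSums(d^2))
}

# morphogen-weighted edge lengths. A metric morphogen rescales an edge only
# to the extent it is present on both endpoints: the edge factor is
# 1 + min(s_i, s_j) (f - 1) per rule, so a factor-f morphogen covering both
# ends of an edge scales it by exactly f and an edge with one bare endpoint
# keeps some full-length contribution.
weighted_edge_lengths <- function(margin, rules) {
  el <- edge_lengths(margin)
  n <- length(el) + 1L
  f <- rep(1, n - 1L)
  for (r in rules) {
    s <- morph_strength(margin, r$name)
    f <- f * (1 + pmin(s[-n], s[-1]) * (r$metric_factor - 1))
  }
  el * f
}

#' Morphogen-weighted arc length along the margin
#'
#' Sums Euclidean edge lengths between sample indices `i` and `j`, each edge
#' scaled by the product of the metric factors of morphogens active on it
#' (edge factor = mean of its endpoints' factors). Distances are measured
#' independently within barrier-delimited intervals: if a barrier point lies
#' strictly between `i` and `j` the points are unreachable and `Inf` is
#' returned.
#'
#' @param margin A `leaf_margin`.
#' @param i,j Sample indices with `i <= j`.
#' @param rules List of [morphogen_rule()]s supplying metric factors.
#' @return The weighted arc length, or `Inf` if a barrier intervenes.
#' @export
margin_arc_length <- function(margin, i, j, rules = list()) {
  n <- margin_n(margin)
  if (i < 1 || j > n || i > j) stop("invalid indices")
  if (i == j) return(0)
  if (j - i >= 2L && any(margin$barrier[(i + 1L):(j - 1L)])) return(Inf)
  sum(weighted_edge_lengths(margin, rules)[i:(j - 1L)])
}

# outward unit normals at every point; outward = away from the blade
# interior, defined via the signed area of the polygon closed by the base
# edge. Endpoints get their single edge's normal; degenerate interior
# normals fall back to the average of neighbours'.
margin_normals <- function(margin) {
  p <- margin$pos
  n <- nrow(p)
  d <- diff(p)
  len <- sqrt(rowSums(d^2))
  len[len == 0] <- 1
  t_edge <- d / len
  # point tangents: average of adjacent edge tangents
  tp <- rbind(t_edge[1, ], (t_edge[-nrow(t_edge), ] + t_edge[-1, ]) / 2,
              t_edge[nrow(t_edge), ])
  tl <- sqrt(rowSums(tp^2))
  bad <- tl < 1e-12
  if (any(bad)) {
    for (k in which(bad)) {
      nb <- tp[max(1, k - 1), ] + tp[min(n, k + 1), ]
      tp[k, ] <- if (sqrt(sum(nb^2)) > 1e-12) nb else c(1, 0)
    }
    tl <- sqrt(rowSums(tp^2))
  }
  tp <- tp / tl
  # rotate tangent by -90 or +90 depending on polygon orientation so the
  # normal points outward
  a <- polygon_signed_area(p)
  if (a > 0) {
    cbind(tp[, 2], -tp[, 1]) # CCW: interior left, outward is right of travel
  } else {
    cbind(-tp[, 2], tp[, 1])
  }
}

polygon_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# TRUE if the margin, closed by its base edge, is a simple polygon.
margin_is_simple <- function(margin, eps = NULL) {
  p <- rbind(margin$pos, margin$pos[1, ])
  if (is.null(eps)) eps <- eps_geom(margin$pos)
  !polyline_self_intersects(p, eps)
}

# vectorized segment-pair intersection test for a closed polyline given as an
# (n+1) x 2 matrix with last row == first row; adjacent segments share an
# endpoint and are excluded.
polyline_self_intersects <- function(p, eps) {
  nrow(polyline_crossing_pairs(p, eps, first_only = TRUE)) > 0L
}

# all (i, j) pairs of crossing segments of a closed polyline
polyline_crossing_pairs <- function(p, eps, first_only = FALSE) {
  m <- nrow(p) - 1L
  none <- matrix(integer(0), 0, 2)
  if (m < 3) return(none)
  a <- p[1:m, , drop = FALSE]
  b <- p[2:(m + 1), , drop = FALSE]
  ij <- which(outer(seq_len(m), seq_len(m), function(i, j) j > i + 1L), arr.ind = TRUE)
  # exclude the wrap-around adjacency (segment 1 vs segment m)
  ij <- ij[!(ij[, 1] == 1L & ij[, 2] == m), , drop = FALSE]
  if (!nrow(ij)) return(none)
  i <- ij[, 1]; j <- ij[, 2]
  hit <- segments_intersect_which(a[i, , drop = FALSE], b[i, , drop = FALSE],
                                  a[j, , drop = FALSE], b[j, , drop = FALSE], eps)
  ij[hit, , drop = FALSE]
}

# which of the segment pairs (p1->p2, q1->q2) properly intersect?
segments_intersect_which <- function(p1, p2, q1, q2, eps) {
  d1 <- p2 - p1
  d2 <- q2 - q1
  denom <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1]
  w <- q1 - p1
  t <- (w[, 1] * d2[, 2] - w[, 2] * d2[, 1])
  u <- (w[, 1] * d1[, 2] - w[, 2] * d1[, 1])
  ok <- abs(denom) > eps^2
  t <- t / denom
  u <- u / denom
  hit <- ok & t > eps & t < 1 - eps & u > eps & u < 1 - eps
  hit & !is.na(hit)
}

segments_intersect_any <- function(p1, p2, q1, q2, eps) {
  any(segments_intersect_which(p1, p2, q1, q2, eps))
}

# margin edge indices that properly cross some vein segment
margin_vein_crossings <- function(pos, veins, eps) {
  segs <- veins$segs
  m <- nrow(pos) - 1L
  if (!nrow(segs) || m < 1) return(integer(0))
  ns <- nrow(segs)
  ei <- rep(seq_len(m), each = ns)
  si <- rep(seq_len(ns), times = m)
  hit <- segments_intersect_which(
    pos[ei, , drop = FALSE], pos[ei + 1L, , drop = FALSE],
    cbind(segs$x0, segs$y0)[si, , drop = FALSE],
    cbind(segs$x1, segs$y1)[si, , drop = FALSE], eps)
  unique(ei[hit])
}

# One pass of fold-over repair: for every pair of crossing margin edges the
# interior points they span are relaxed toward their neighbour midpoints,
# and wiggles across a vein are straightened onto the chord between their
# unaffected neighbours. All crossings are treated simultaneously so
# mirror-symmetric states stay symmetric. Returns the margin plus whether
# anything was still crossing.
fold_repair_pass <- function(margin, veins, pass, eps) {
  n <- margin_n(margin)
  movable <- !margin$is_cp
  movable[c(1L, n)] <- FALSE
  cr <- polyline_crossing_pairs(rbind(margin$pos, margin$pos[1, ]), eps)
  ve <- if (is.null(veins)) integer(0) else margin_vein_crossings(margin$pos, veins, eps)
  if (!nrow(cr) && !length(ve)) return(list(margin = margin, clean = TRUE))
  # late passes may also move convergence points (overhanging tooth tips);
  # the caller re-synchronizes vein tips
  allow_cp <- pass > 15L
  if (length(ve)) {
    pad <- 1L + (pass - 1L) %/% 3L
    bad <- sort(unique(c(ve, ve + 1L)))
    for (rg in split(bad, cumsum(c(1, diff(bad) > 2 * pad)))) {
      lo <- max(2L, min(rg) - pad)
      hi <- min(n - 1L, max(rg) + pad)
      if (hi - lo < 2L) next
      span <- (lo + 1L):(hi - 1L)
      span <- span[movable[span] | allow_cp]
      if (!length(span)) next
      tfrac <- (span - lo) / (hi - lo)
      chord <- outer(1 - tfrac, margin$pos[lo, ]) + outer(tfrac, margin$pos[hi, ])
      margin$pos[span, ] <- (margin$pos[span, , drop = FALSE] + chord) / 2
    }
  }
  if (nrow(cr)) {
    mv <- movable
    if (allow_cp) {
      mv <- rep(TRUE, n)
      mv[c(1L, n)] <- FALSE
    }
    touch <- logical(n)
    for (k in seq_len(nrow(cr))) {
      i <- cr[k, 1]; j <- cr[k, 2]
      span <- intersect(seq.int(i, min(j + 1L, n)), 2:(n - 1L))
      touch[span] <- TRUE
    }
    idx <- which(touch & mv)
    if (length(idx)) {
      mid <- (margin$pos[pmax(idx - 1L, 1L), , drop = FALSE] +
                margin$pos[pmin(idx + 1L, n), , drop = FALSE]) / 2
      margin$pos[idx, ] <- (margin$pos[idx, , drop = FALSE] + mid) / 2
    }
  }
  list(margin = margin, clean = FALSE)
}

# margin-only driver (used where no veins are at stake)
resolve_margin_folds <- function(margin, veins = NULL, max_pass = 30L) {
  eps <- eps_geom(margin$pos)
  for (pass in seq_len(max_pass)) {
    out <- fold_repair_pass(margin, veins, pass, eps)
    margin <- out$margin
    if (out$clean) return(margin)
  }
  out <- fold_repair_pass(margin, veins, max_pass + 1L, eps)
  if (!out$clean) stop("margin fold-over could not be resolved")
  out$margin
}

#' Resample the margin to a bounded edge-length range
#'
#' Splits every edge longer than `h_max` at its midpoint and removes interior
#' sample points hemmed in by edges shorter than `h_min`. New points inherit
#' linearly interpolated attributes; convergence points, barrier points and
#' the two base endpoints are never removed, and resampling never creates a
#' convergence point. Both rules are mirror-symmetric so that symmetric
#' states stay symmetric.
#'
#' @param margin A `leaf_margin`.
#' @param h_max,h_min Edge-length bounds (`h_min < h_max`).
#' @param step Birth step recorded on newly created points.
#' @return The resampled `leaf_margin`.
#' @export
resample_margin <- function(margin, h_max, h_min = h_max / 4, step = 0L) {
  # split pass (repeat until no long edges; one midpoint per edge per pass)
  repeat {
    el <- edge_lengths(margin)
    long <- which(el > h_max)
    if (!length(long)) break
    margin <- split_edges(margin, long, step)
  }
  # merge pass: mark interior removable points whose both adjacent edges are
  # short; within each run of adjacent marked points keep/remove a pattern
  # symmetric under reversal (remove those at even distance from the nearer
  # run end)
  el <- edge_lengths(margin)
  n <- margin_n(margin)
  if (n > 3) {
    short_before <- c(Inf, el)   # edge ending at point i
    short_after <- c(el, Inf)    # edge starting at point i
    cand <- short_before < h_min & short_after < h_min
    cand[c(1L, n)] <- FALSE
    cand[margin$is_cp | margin$barrier] <- FALSE
    # never remove a point at a morphogen boundary: merging there would slide
    # the material extent of the morphogen along the margin
    if (ncol(margin$morph)) {
      act <- margin$morph > 0.5
      same_prev <- c(FALSE, rowSums(act[-1, , drop = FALSE] != act[-n, , drop = FALSE]) == 0)
      same_next <- c(same_prev[-1], FALSE)
      cand <- cand & same_prev & same_next
    }
    if (any(cand)) {
      rem <- logical(n)
      r <- rle(cand)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in seq_along(r$values)) {
        if (!r$values[k]) next
        idx <- starts[k]:ends[k]
        off <- pmin(idx - starts[k], ends[k] - idx)
        rem[idx[off %% 2L == 0L]] <- TRUE
      }
      margin <- margin_subset(margin, which(!rem))
    }
  }
  margin
}

split_edges <- function(margin, edges, step) {
  n <- margin_n(margin)
  keep_order <- order(c(seq_len(n), edges + 0.5))
  midpos <- (margin$pos[edges, , drop = FALSE] + margin$pos[edges + 1L, , drop = FALSE]) / 2
  m1 <- margin$morph[edges, , drop = FALSE]
  m2 <- margin$morph[edges + 1L, , drop = FALSE]
  # crisp presence/absence flags must not diffuse under repeated resampling:
  # a midpoint of a 0/1 edge carries the morphogen only if both ends do;
  # graded strengths interpolate linearly
  crisp <- (m1 == 0 | m1 == 1) & (m2 == 0 | m2 == 1)
  midmorph <- ifelse(crisp, m1 * m2, (m1 + m2) / 2)
  dim(midmorph) <- dim(m1)
  dimnames(midmorph) <- dimnames(m1)
  # vein association: inherit from the endpoint in the same vein if both ends
  # agree, else from the nearer endpoint deterministically (proximal-end)
  v1 <- margin$vein_id[edges]; v2 <- margin$vein_id[edges + 1L]
  vid <- ifelse(!is.na(v1) & !is.na(v2) & v1 == v2, v1, NA_integer_)
  pos <- rbind(margin$pos, midpos)[keep_order, , drop = FALSE]
  morph <- rbind(margin$morph, midmorph)[keep_order, , drop = FALSE]
  is_cp <- c(margin$is_cp, rep(FALSE, length(edges)))[keep_order]
  vein_id <- c(margin$vein_id, as.integer(vid))[keep_order]
  birth <- c(margin$birth_step, rep(as.integer(step), length(edges)))[keep_order]
  barrier <- c(margin$barrier, margin$barrier[edges] & margin$barrier[edges + 1L])[keep_order]
  new_leaf_margin(pos, is_cp, vein_id, birth, morph, barrier)
}
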