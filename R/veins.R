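# Vein tree: a rooted tree of straight segments. `segs` is a data.frame with
# one row per segment: id, parent (0 = rooted at the leaf base), vein (the
# straight vein a segment belongs to; splitting a vein at an attachment point
# leaves collinear segments with the same vein id), endpoints (x0,y0)->(x1,y1)
# oriented away from the base, and arc-length coordinates s0 < s1 measured
# along the vasculature from the base.

new_vein_tree <- function(segs, base) {
  stopifnot(is.data.frame(segs),
            all(c("id", "parent", "vein", "x0", "y0", "x1", "y1", "s0", "s1") %in% names(segs)))
  structure(list(segs = segs, base = as.numeric(base)), class = "vein_tree")
}

# single midvein from base to apex
midvein_tree <- function(base, apex) {
  len <- sqrt(sum((apex - base)^2))
  new_vein_tree(data.frame(
    id = 1L, parent = 0L, vein = 1L,
    x0 = base[1], y0 = base[2], x1 = apex[1], y1 = apex[2],
    s0 = 0, s1 = len
  ), base)
}

seg_len <- function(segs) sqrt((segs$x1 - segs$x0)^2 + (segs$y1 - segs$y0)^2)

vein_total_length <- function(veins) sum(seg_len(veins$segs))

# ids of a vein's segments ordered from attachment to tip
vein_chain <- function(veins, vein) {
  s <- veins$segs[veins$segs$vein == vein, , drop = FALSE]
  s[order(s$s0), , drop = FALSE]
}

# terminal (tip) coordinate of a vein
vein_tip <- function(veins, vein) {
  ch <- vein_chain(veins, vein)
  as.numeric(ch[nrow(ch), c("x1", "y1")])
}

# sequence of segment ids from a segment up to the root (inclusive)
root_path_ids <- function(veins, seg_id) {
  segs <- veins$segs
  out <- integer(0)
  cur <- seg_id
  repeat {
    out <- c(out, cur)
    p <- segs$parent[match(cur, segs$id)]
    if (is.na(p)) stop("unknown segment id")
    if (p == 0L) break
    cur <- p
  }
  out
}

# consistency check: connected, acyclic, s-coordinates additive, children
# start where the parent ends
vein_tree_valid <- function(veins, eps = NULL) {
  segs <- veins$segs
  if (is.null(eps)) {
    eps <- eps_geom(rbind(as.matrix(segs[, c("x0", "y0")]), as.matrix(segs[, c("x1", "y1")])))
  }
  ok <- TRUE
  for (k in seq_len(nrow(segs))) {
    if (segs$parent[k] == 0L) {
      ok <- ok && sqrt(sum((c(segs$x0[k], segs$y0[k]) - veins$base)^2)) <= eps
      ok <- ok && abs(segs$s0[k]) <= eps
    } else {
      pk <- match(segs$parent[k], segs$id)
      if (is.na(pk)) return(FALSE)
      ok <- ok && sqrt((segs$x0[k] - segs$x1[pk])^2 + (segs$y0[k] - segs$y1[pk])^2) <= eps
      ok <- ok && abs(segs$s0[k] - segs$s1[pk]) <= eps
    }
    ok <- ok && abs(segs$s1[k] - segs$s0[k] - seg_len(segs[k, ])) <= max(eps, 1e-9 * segs$s1[k])
    if (!ok) return(FALSE)
  }
  # acyclicity: every root path terminates (root_path_ids errors or loops
  # would hang; bound by n)
  n <- nrow(segs)
  for (k in segs$id) {
    cnt <- 0L
    cur <- k
    while (cur != 0L) {
      cur <- segs$parent[match(cur, segs$id)]
      cnt <- cnt + 1L
      if (cnt > n) return(FALSE)
    }
  }
  TRUE
}

#' Arc-length distance from a point on the vasculature to the leaf base
#'
#' The point must lie on some vein segment (within the geometric tolerance);
#' the returned value is the arc length of the unique tree path from the
#' point to the base, measured along the veins.
#'
#' @param veins A vein tree.
#' @param point Numeric length-2 coordinate on the tree.
#' @return Path length to the base.
#' @export
vein_path_length <- function(veins, point) {
  segs <- veins$segs
  eps <- 1e-7 * max(1, max(segs$s1))
  best <- NULL
  for (k in seq_len(nrow(segs))) {
    a <- c(segs$x0[k], segs$y0[k]); b <- c(segs$x1[k], segs$y1[k])
    L <- sqrt(sum((b - a)^2))
    if (L == 0) next
    u <- sum((point - a) * (b - a)) / L
    u <- min(max(u, 0), L)
    foot <- a + u * (b - a) / L
    d <- sqrt(sum((point - foot)^2))
    if (d <= eps && (is.null(best) || d < best$d)) best <- list(d = d, s = segs$s0[k] + u)
  }
  if (is.null(best)) stop("point does not lie on the vein tree")
  best$s
}

#' @export
print.vein_tree <- function(x, ...) {
  cat(sprintf("<vein_tree> %d segments, %d veins, total length %.4g\n",
              nrow(x$segs), length(unique(x$segs$vein)), vein_total_length(x)))
  invisible(x)
}
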