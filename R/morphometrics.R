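# Shape descriptors: the test surface for morphospace trends.

#' Width-to-length aspect ratio of a leaf margin
#'
#' Length is the extent from the leaf base to the farthest tip along the
#' initial midvein axis (+y); width is the maximal extent perpendicular to
#' it. Invariant under uniform scaling.
#'
#' @param margin A `leaf_margin`.
#' @return Positive ratio width : length.
#' @export
aspect_ratio <- function(margin) {
  p <- margin$pos
  len <- max(p[, 2]) - min(0, min(p[, 2]))
  wid <- max(p[, 1]) - min(p[, 1])
  if (len <= 0 || wid <= 0) stop("degenerate margin")
  wid / len
}

#' Sinus depths between consecutive convergence points
#'
#' For each margin interval between consecutive convergence points, the
#' depth is the maximal inward deviation of the interval's points from the
#' chord joining the two convergence points (inward = toward the blade
#' interior; outward bulges score 0).
#'
#' @param margin A `leaf_margin`.
#' @param veins Unused placeholder for interface symmetry; may be `NULL`.
#' @return Numeric vector of depths (empty when fewer than 2 convergence
#'   points).
#' @export
sinus_depths <- function(margin, veins = NULL) {
  cps <- which(margin$is_cp)
  if (length(cps) < 2) return(numeric(0))
  inward_sign <- if (polygon_signed_area(margin$pos) > 0) 1 else -1
  out <- numeric(length(cps) - 1L)
  for (k in seq_len(length(cps) - 1L)) {
    a <- cps[k]; b <- cps[k + 1L]
    if (b - a < 2L) { out[k] <- 0; next }
    c1 <- margin$pos[a, ]; c2 <- margin$pos[b, ]
    d <- c2 - c1
    L <- sqrt(sum(d^2))
    if (L == 0) { out[k] <- 0; next }
    q <- margin$pos[(a + 1L):(b - 1L), , drop = FALSE]
    cr <- (d[1] * (q[, 2] - c1[2]) - d[2] * (q[, 1] - c1[1])) / L
    # interior lies left of travel for CCW; inward deviation is toward it
    out[k] <- max(0, inward_sign * cr)
  }
  out
}

#' Count lobes by sinus depth
#'
#' A lobe is a protrusion (a convergence point) whose two bounding sinus
#' depths both exceed `depth_threshold` times the blade length.
#'
#' @param margin A `leaf_margin`.
#' @param veins Unused; may be `NULL`.
#' @param depth_threshold Fraction of blade length (default 0.1).
#' @return Integer lobe count (monotone nonincreasing in the threshold).
#' @export
count_lobes <- function(margin, veins = NULL, depth_threshold = 0.1) {
  dep <- sinus_depths(margin, veins)
  if (length(dep) < 2) return(0L)
  blade <- max(margin$pos[, 2]) - min(0, min(margin$pos[, 2]))
  thr <- depth_threshold * blade
  sum(dep[-length(dep)] > thr & dep[-1] > thr)
}

#' Mirror-asymmetry score of the margin
#'
#' Mean distance between the margin and its mirror image about the midvein
#' axis (x = base x) after arc-length correspondence, normalized by the
#' bounding-box diagonal. Exactly 0 for mirror-symmetric polylines.
#'
#' @param margin A `leaf_margin`.
#' @param n_samples Number of arc-length samples used for correspondence.
#' @return Nonnegative score.
#' @export
symmetry_score <- function(margin, n_samples = 256) {
  p <- margin$pos
  s <- c(0, cumsum(sqrt(rowSums(diff(p)^2))))
  if (s[length(s)] == 0) return(0)
  ts <- seq(0, s[length(s)], length.out = n_samples)
  px <- stats::approx(s, p[, 1], xout = ts)$y
  py <- stats::approx(s, p[, 2], xout = ts)$y
  # mirror about the vertical axis through the base midpoint and reverse the
  # traversal direction
  axis_x <- (p[1, 1] + p[nrow(p), 1]) / 2
  qx <- rev(2 * axis_x - px)
  qy <- rev(py)
  diag_len <- sqrt(sum((apply(p, 2, max) - apply(p, 2, min))^2))
  mean(sqrt((px - qx)^2 + (py - qy)^2)) / max(diag_len, 1e-300)
}

#' Branching angles of the vein tree
#'
#' The angle, in degrees, between each vein's first segment and the parent
#' segment it attaches to (segments of the same vein are collinear and are
#' skipped; the midvein, rooted at the base, has no parent).
#'
#' @param veins A vein tree.
#' @return Numeric vector of angles in `[0, 180]`.
#' @export
branching_angles <- function(veins) {
  segs <- veins$segs
  out <- numeric(0)
  for (k in seq_len(nrow(segs))) {
    pk <- segs$parent[k]
    if (pk == 0L) next
    j <- match(pk, segs$id)
    if (segs$vein[k] == segs$vein[j]) next
    d1 <- c(segs$x1[k] - segs$x0[k], segs$y1[k] - segs$y0[k])
    d2 <- c(segs$x1[j] - segs$x0[j], segs$y1[j] - segs$y0[j])
    n1 <- sqrt(sum(d1^2)); n2 <- sqrt(sum(d2^2))
    if (n1 == 0 || n2 == 0) next
    cosang <- sum(d1 * d2) / (n1 * n2)
    out <- c(out, acos(min(max(cosang, -1), 1)) * 180 / pi)
  }
  out
}

#' Normalized position of the widest point along the leaf axis
#'
#' The y-coordinate (fraction of blade length from the base) at which the
#' margin attains its maximal width; moves toward 0 as growth is restricted
#' to the leaf base (elliptic to ovate to oblong shapes).
#'
#' @param margin A `leaf_margin`.
#' @param nbin Number of bins along the axis.
#' @return Fraction in \[0, 1\].
#' @export
widest_position <- function(margin, nbin = 40) {
  p <- margin$pos
  ylo <- min(0, min(p[, 2])); yhi <- max(p[, 2])
  # width profile from linear interpolation of the two margin sides
  ys <- seq(ylo + 1e-9, yhi - 1e-9, length.out = nbin)
  width_at <- function(y) {
    # all crossings of the closed polygon with the horizontal line at y
    q <- rbind(p, p[1, ])
    x <- numeric(0)
    for (k in seq_len(nrow(q) - 1L)) {
      y1 <- q[k, 2]; y2 <- q[k + 1L, 2]
      if ((y1 - y) * (y2 - y) <= 0 && y1 != y2) {
        t <- (y - y1) / (y2 - y1)
        x <- c(x, q[k, 1] + t * (q[k + 1L, 1] - q[k, 1]))
      }
    }
    if (length(x) < 2) 0 else max(x) - min(x)
  }
  w <- vapply(ys, width_at, 0)
  (ys[which.max(w)] - ylo) / (yhi - ylo)
}
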