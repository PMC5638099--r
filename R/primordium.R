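# Initial state: a small primordium with a single convergence point at its
# apex and a midvein connecting it to the leaf base at the origin.

#' Build the initial leaf state from a primordium description
#'
#' The primordium is an open simple polyline whose first and last points are
#' the two petiole-base endpoints; the leaf base sits at the origin and the
#' midvein initially points along +y. The apex sample becomes the single
#' initial convergence point, connected to the base by the midvein. Morphogen
#' intervals, given as fractional arc-length ranges of the outline, are
#' painted onto the sample points.
#'
#' @param params A [leaf_params()].
#' @param preset A list with elements:
#'   \describe{
#'     \item{outline}{n x 2 matrix of margin positions (open polyline).}
#'     \item{apex}{optional index of the apical sample; default: the point
#'       farthest from the base.}
#'     \item{morphogens}{optional named list; each element a list of
#'       `c(lo, hi)` fractional arc ranges (in \[0,1\]) where the morphogen
#'       has strength 1.}
#'   }
#'   Alternatively the name of a packaged preset (see [leaf_preset()]).
#' @return A `leaf_state` with margin, midvein tree and (if
#'   `params$mesh_every > 0`) a blade mesh.
#' @export
make_primordium <- function(params, preset = primordium_outline()) {
  if (is.character(preset)) preset <- leaf_preset(preset)$primordium
  pos <- as.matrix(preset$outline)
  if (nrow(pos) < 3) stop("primordium outline needs at least 3 points")
  margin <- new_leaf_margin(pos)
  if (!margin_is_simple(margin)) {
    stop("primordium outline is self-intersecting")
  }
  # paint morphogen intervals by fractional (unweighted) arc length
  el <- edge_lengths(margin)
  frac <- c(0, cumsum(el)) / sum(el)
  rule_names <- names(params$rules)
  mor <- preset$morphogens
  if (length(mor)) {
    unknown <- setdiff(names(mor), rule_names)
    if (length(unknown)) {
      stop("preset paints morphogens with no declared rule: ",
           paste(unknown, collapse = ", "))
    }
    m <- matrix(0, nrow(pos), length(mor), dimnames = list(NULL, names(mor)))
    for (nm in names(mor)) {
      for (rg in mor[[nm]]) {
        m[frac >= rg[1] - 1e-12 & frac <= rg[2] + 1e-12, nm] <- 1
      }
    }
    margin$morph <- m
    for (nm in names(mor)) {
      r <- params$rules[[nm]]
      if (!is.null(r) && r$is_barrier) {
        margin$barrier <- margin$barrier | morph_active(margin, nm)
      }
    }
  }
  apex <- preset$apex
  base <- c(0, 0)
  if (is.null(apex)) {
    apex <- which.max(rowSums(sweep(pos, 2, base, "-")^2))
  }
  margin$is_cp[apex] <- TRUE
  veins <- midvein_tree(base, pos[apex, ])
  # associate margin with the midvein; petiole-flagged points stay unattached
  margin$vein_id <- rep(1L, nrow(pos))
  pet <- if ("petiole" %in% colnames(margin$morph)) morph_active(margin, "petiole") else FALSE
  margin$vein_id[pet] <- NA_integer_
  state <- structure(list(margin = margin, veins = veins, mesh = NULL,
                          step = 0L, age = 0, next_vein = 2L),
                     class = "leaf_state")
  if (params$mesh_every > 0) state$mesh <- triangulate_blade(state$margin, state$veins)
  state
}

#' Default primordium outline
#'
#' A mirror-symmetric half-ellipse of the given length and basal half-width,
#' sampled at an odd number of points so the apex is an exact sample point.
#'
#' @param length Primordium length (base to apex).
#' @param half_width Basal half-width.
#' @param n Number of samples (forced odd).
#' @param morphogens Optional morphogen paint list (see [make_primordium()]).
#' @return A primordium description list.
#' @export
primordium_outline <- function(length = 1, half_width = 0.25, n = 21,
                               morphogens = list()) {
  if (n %% 2 == 0) n <- n + 1L
  phi <- seq(pi, 0, length.out = n)
  outline <- cbind(half_width * cos(phi), length * sin(phi))
  list(outline = outline, apex = (n + 1L) %/% 2L, morphogens = morphogens)
}

#' @export
print.leaf_state <- function(x, ...) {
  cat(sprintf("<leaf_state> step %d (age %.3g): %d margin points, %d convergence points, %d vein segments\n",
              x$step, x$age, margin_n(x$margin), sum(x$margin$is_cp), nrow(x$veins$segs)))
  invisible(x)
}

#' Plot a leaf state
#'
#' Draws the margin (closed by the base edge), the vein tree and, if present,
#' the blade mesh; convergence points are marked.
#'
#' @param x A `leaf_state`.
#' @param mesh Draw the mesh if available.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.leaf_state <- function(x, mesh = TRUE, ...) {
  p <- x$margin$pos
  graphics::plot(rbind(p, p[1, ]), type = "n", asp = 1, xlab = "", ylab = "", ...)
  if (mesh && !is.null(x$mesh)) {
    tri <- x$mesh$triangles
    v <- x$mesh$vertices
    for (k in seq_len(nrow(tri))) {
      graphics::polygon(v[tri[k, ], 1], v[tri[k, ], 2], border = "palegreen3", lwd = 0.4)
    }
  }
  graphics::lines(rbind(p, p[1, ]), lwd = 1.4)
  segs <- x$veins$segs
  graphics::segments(segs$x0, segs$y0, segs$x1, segs$y1, col = "steelblue", lwd = 1.6)
  cp <- x$margin$is_cp
  graphics::points(p[cp, 1], p[cp, 2], pch = 21, bg = "gold", cex = 0.9)
  invisible(x)
}
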