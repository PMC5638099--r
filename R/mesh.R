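# Conforming triangle mesh of the lamina. The vein tree, whose terminals lie
# on the margin (convergence points) and whose root is the leaf base on the
# closing edge, partitions the closed margin polygon into simple faces; each
# face is triangulated by ear clipping, so every margin and vein edge is a
# mesh edge by construction. Refinement bisects long interior edges; passive
# deformation moves interior vertices by a cotangent-Laplacian harmonic
# solve (which reproduces affine maps exactly).

# node bookkeeping shared by meshing and face extraction ------------------

# vertex ids: 1..n margin points, n+1 the leaf base, then one junction vertex
# per non-terminal segment end
mesh_nodes <- function(margin, veins) {
  n <- margin_n(margin)
  segs <- veins$segs
  term_seg <- vapply(unique(segs$vein), function(w) {
    ch <- vein_chain(veins, w)
    ch$id[nrow(ch)]
  }, integer(1))
  cp_of_vein <- function(w) {
    i <- which(margin$is_cp & !is.na(margin$vein_id) & margin$vein_id == w)
    if (length(i) != 1L) stop("vein without a unique terminal convergence point")
    i
  }
  end_vertex <- integer(nrow(segs))
  names(end_vertex) <- as.character(segs$id)
  extra <- list()
  nextv <- n + 2L
  for (k in seq_len(nrow(segs))) {
    if (segs$id[k] %in% term_seg) {
      end_vertex[k] <- cp_of_vein(segs$vein[k])
    } else {
      end_vertex[k] <- nextv
      extra[[length(extra) + 1L]] <- c(segs$x1[k], segs$y1[k])
      nextv <- nextv + 1L
    }
  }
  start_vertex <- ifelse(segs$parent == 0L, n + 1L,
                         end_vertex[as.character(segs$parent)])
  vertices <- rbind(margin$pos, matrix(veins$base, 1), do.call(rbind, c(extra, list(matrix(0, 0, 2)))))
  role <- c(rep("margin", n), "vein", rep("vein", length(extra)))
  list(vertices = vertices, role = role,
       start_vertex = as.integer(start_vertex), end_vertex = as.integer(end_vertex),
       seg_id = segs$id, n_margin = n)
}

# faces of the margin+vein planar subdivision, as cycles of global vertex ids
blade_faces <- function(margin, veins, nodes) {
  n <- margin_n(margin)
  segs <- veins$segs
  base_v <- n + 1L
  cps <- which(margin$is_cp & !is.na(margin$vein_id) & margin$vein_id %in% segs$vein)
  if (!length(cps)) stop("leaf has no attached convergence point")
  root_ids <- function(anchor) {
    if (anchor == base_v) return(integer(0))
    w <- margin$vein_id[anchor]
    ch <- vein_chain(veins, w)
    root_path_ids(veins, ch$id[nrow(ch)])
  }
  start_of <- function(ids) nodes$start_vertex[match(ids, nodes$seg_id)]
  anchors <- c(base_v, cps, base_v)
  faces <- list()
  for (k in seq_len(length(anchors) - 1L)) {
    P <- anchors[k]; Q <- anchors[k + 1L]
    cyc <- if (P == base_v) c(base_v, 1:Q) else if (Q == base_v) c(P:n, base_v) else P:Q
    Rq <- root_ids(Q); Rp <- root_ids(P)
    nq <- setdiff(Rq, Rp) # tip -> root order
    np <- setdiff(Rp, Rq)
    q_side <- start_of(nq)
    if (P == base_v && length(q_side)) q_side <- q_side[-length(q_side)]
    p_side <- if (length(np) > 1L) rev(start_of(np[seq_len(length(np) - 1L)])) else integer(0)
    faces[[k]] <- c(cyc, q_side, p_side)
  }
  faces
}

# ear-clip a simple polygon given as global vertex ids; returns an m x 3
# matrix of ids (counter-clockwise)
ear_clip <- function(ids, vertices) {
  # drop consecutive duplicates (coincident vertices)
  pts <- vertices[ids, , drop = FALSE]
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2) > 0)
  if (sum(keep) >= 2 && all(pts[1, ] == pts[nrow(pts), ])) keep[nrow(pts)] <- FALSE
  ids <- ids[keep]
  m <- length(ids)
  if (m < 3) return(matrix(integer(0), 0, 3))
  p <- vertices[ids, , drop = FALSE]
  if (polygon_signed_area(p) < 0) {
    ids <- rev(ids)
    p <- p[rev(seq_len(m)), , drop = FALSE]
  }
  scale <- max(apply(p, 2, function(z) diff(range(z))), 1e-12)
  eps_a <- 1e-12 * scale^2
  tris <- matrix(integer(0), 0, 3)
  act <- seq_len(m)
  guard <- 0L
  while (length(act) > 3) {
    guard <- guard + 1L
    if (guard > 4L * m^2) stop("ear clipping failed to terminate")
    na <- length(act)
    clipped <- FALSE
    best_fallback <- NULL
    for (j in seq_len(na)) {
      i0 <- act[(j - 2L) %% na + 1L]
      i1 <- act[(j - 1L) %% na + 1L]
      i2 <- act[j %% na + 1L]
      a <- p[i0, ]; bq <- p[i1, ]; cq <- p[i2, ]
      cr <- (bq[1] - a[1]) * (cq[2] - a[2]) - (bq[2] - a[2]) * (cq[1] - a[1])
      if (cr <= eps_a) next
      # no other active vertex strictly inside the candidate ear
      others <- setdiff(act, c(i0, i1, i2))
      inside <- FALSE
      if (length(others)) {
        q <- p[others, , drop = FALSE]
        d1 <- (bq[1] - a[1]) * (q[, 2] - a[2]) - (bq[2] - a[2]) * (q[, 1] - a[1])
        d2 <- (cq[1] - bq[1]) * (q[, 2] - bq[2]) - (cq[2] - bq[2]) * (q[, 1] - bq[1])
        d3 <- (a[1] - cq[1]) * (q[, 2] - cq[2]) - (a[2] - cq[2]) * (q[, 1] - cq[1])
        inside <- any(d1 > -eps_a & d2 > -eps_a & d3 > -eps_a)
      }
      if (!inside) {
        tris <- rbind(tris, c(ids[i0], ids[i1], ids[i2]))
        act <- setdiff(act, i1)
        clipped <- TRUE
        break
      } else if (is.null(best_fallback) || cr > best_fallback$cr) {
        best_fallback <- list(tri = c(i0, i1, i2), cr = cr)
      }
    }
    if (!clipped) {
      if (is.null(best_fallback)) stop("polygon cannot be triangulated")
      t <- best_fallback$tri
      tris <- rbind(tris, c(ids[t[1]], ids[t[2]], ids[t[3]]))
      act <- setdiff(act, t[2])
    }
  }
  a <- p[act[1], ]; bq <- p[act[2], ]; cq <- p[act[3], ]
  cr <- (bq[1] - a[1]) * (cq[2] - a[2]) - (bq[2] - a[2]) * (cq[1] - a[1])
  if (cr > 0) tris <- rbind(tris, ids[act])
  tris
}

#' Constrained triangulation of the leaf blade
#'
#' Triangulates the closed margin polygon with the vein tree as internal
#' constraints: every margin point, the leaf base, and every vein junction is
#' a mesh vertex, and every margin and vein edge is a mesh edge. No interior
#' (Steiner) vertices are introduced; [refine_mesh()] adds them.
#'
#' @param margin A simple `leaf_margin`.
#' @param veins A vein tree inside the margin.
#' @return A `blade_mesh`: list with `vertices`, `role`
#'   (margin/vein/interior), `triangles` (CCW vertex triples),
#'   `constraints` (edge matrix) and the node bookkeeping used to rebuild.
#' @export
triangulate_blade <- function(margin, veins) {
  if (!margin_is_simple(margin)) stop("margin is not simple")
  nodes <- mesh_nodes(margin, veins)
  faces <- blade_faces(margin, veins, nodes)
  tris <- do.call(rbind, lapply(faces, ear_clip, vertices = nodes$vertices))
  n <- nodes$n_margin
  constraints <- rbind(
    cbind(1:(n - 1), 2:n),          # margin edges
    c(n, n + 1L), c(n + 1L, 1L),    # closing base edges through the base
    cbind(nodes$start_vertex, nodes$end_vertex) # vein edges
  )
  mesh <- structure(list(vertices = nodes$vertices, role = nodes$role,
                         triangles = tris, constraints = constraints,
                         nodes = nodes),
                    class = "blade_mesh")
  mesh
}

mesh_edges <- function(tris) {
  e <- rbind(tris[, 1:2], tris[, 2:3], tris[, c(3, 1)])
  cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
}

triangle_areas <- function(mesh) {
  v <- mesh$vertices; t3 <- mesh$triangles
  a <- v[t3[, 1], , drop = FALSE]; b <- v[t3[, 2], , drop = FALSE]; cc <- v[t3[, 3], , drop = FALSE]
  ((b[, 1] - a[, 1]) * (cc[, 2] - a[, 2]) - (b[, 2] - a[, 2]) * (cc[, 1] - a[, 1])) / 2
}

# does the mesh contain every margin and vein edge, with no inverted
# triangle?
mesh_conforms <- function(mesh) {
  if (any(triangle_areas(mesh) <= 0)) return(FALSE)
  ed <- mesh_edges(mesh$triangles)
  key <- paste(ed[, 1], ed[, 2])
  con <- mesh$constraints
  all(paste(pmin(con[, 1], con[, 2]), pmax(con[, 1], con[, 2])) %in% key)
}

#' Refine a blade mesh by longest-edge bisection
#'
#' Splits edges longer than `max_edge` at their midpoints until none remain.
#' Over-long constraint edges (in practice: long vein segments) are
#' subdivided collinearly first — a triangle standing on a constraint edge of
#' length L forces interior edges of at least L/2, so the interior bound is
#' otherwise unattainable; the margin and vein geometry is unchanged.
#' Subdivision preserves total area.
#'
#' @param mesh A `blade_mesh`.
#' @param max_edge Maximum allowed edge length.
#' @return The refined mesh (new vertices have role `"interior"`).
#' @export
refine_mesh <- function(mesh, max_edge) {
  # A triangle standing on a constraint edge of length L forces interior
  # edges of length >= L/2, so the interior bound is attainable only if long
  # constraint edges are subdivided too; the subdivision is collinear and
  # leaves the margin/vein geometry unchanged.
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 20000L) stop("refinement failed to terminate")
    v <- mesh$vertices
    tris <- mesh$triangles
    ed <- unique(mesh_edges(tris))
    lens <- sqrt(rowSums((v[ed[, 1], , drop = FALSE] - v[ed[, 2], , drop = FALSE])^2))
    if (max(lens) <= max_edge) break
    con <- mesh$constraints
    conkey <- paste(pmin(con[, 1], con[, 2]), pmax(con[, 1], con[, 2]))
    is_con <- paste(ed[, 1], ed[, 2]) %in% conkey
    # split constraint edges first (longest first), then free edges
    pick <- if (any(is_con & lens > max_edge)) {
      which(is_con & lens > max_edge)[which.max(lens[is_con & lens > max_edge])]
    } else {
      which.max(lens)
    }
    e <- ed[pick, ]
    mid <- (v[e[1], ] + v[e[2], ]) / 2
    newv <- nrow(v) + 1L
    mesh$vertices <- rbind(v, mid)
    if (is_con[pick]) {
      # a constraint midpoint rides its parent edge, not the harmonic solve
      mesh$role <- c(mesh$role, "constraint-sub")
      mesh$subdivided <- rbind(mesh$subdivided, c(newv, e[1], e[2]))
      ckey <- paste(pmin(con[, 1], con[, 2]), pmax(con[, 1], con[, 2]))
      hit <- which(ckey == paste(min(e), max(e)))
      mesh$constraints <- rbind(con[-hit, , drop = FALSE],
                                c(e[1], newv), c(newv, e[2]))
    } else {
      mesh$role <- c(mesh$role, "interior")
    }
    holds <- apply(tris, 1, function(tr) all(e %in% tr))
    newt <- list()
    for (k in which(holds)) {
      tr <- tris[k, ]
      # preserve orientation: replace each endpoint of e in turn
      t1 <- tr; t1[t1 == e[2]] <- newv
      t2 <- tr; t2[t2 == e[1]] <- newv
      newt[[length(newt) + 1L]] <- rbind(t1, t2)
    }
    tris <- rbind(tris[!holds, , drop = FALSE], do.call(rbind, newt))
    mesh$triangles <- tris
  }
  mesh
}

# cotangent-weight harmonic interpolation of interior vertices given new
# boundary/constraint positions
harmonic_interior <- function(mesh, newpos) {
  interior <- which(mesh$role == "interior")
  if (!length(interior)) return(newpos)
  v <- mesh$vertices
  nv <- nrow(v)
  W <- matrix(0, nv, nv)
  t3 <- mesh$triangles
  for (k in seq_len(nrow(t3))) {
    tr <- t3[k, ]
    for (j in 1:3) {
      i1 <- tr[j]; i2 <- tr[j %% 3 + 1]; i3 <- tr[(j + 1) %% 3 + 1]
      # cotangent of the angle at i3, opposite edge (i1, i2)
      u <- v[i1, ] - v[i3, ]; w2 <- v[i2, ] - v[i3, ]
      cr <- u[1] * w2[2] - u[2] * w2[1]
      ct <- sum(u * w2) / max(abs(cr), 1e-300) * sign(cr)
      W[i1, i2] <- W[i1, i2] + ct / 2
      W[i2, i1] <- W[i2, i1] + ct / 2
    }
  }
  L <- W - diag(rowSums(W))
  bnd <- setdiff(seq_len(nv), interior)
  A <- L[interior, interior, drop = FALSE]
  rhs <- -L[interior, bnd, drop = FALSE] %*% newpos[bnd, , drop = FALSE]
  newpos[interior, ] <- solve(A, rhs)
  newpos
}

#' Deform the blade mesh to follow margin and veins
#'
#' Margin and vein vertices snap to their new positions; interior vertices
#' are placed by harmonic (cotangent-Laplacian) interpolation of the boundary
#' displacement, which reproduces affine maps exactly. If any triangle
#' inverts, the domain is retriangulated from scratch (refinement is then
#' lost).
#'
#' @param mesh A `blade_mesh`.
#' @param margin_new,veins_new New margin and vein tree with the same
#'   topology as the mesh constraints.
#' @return The deformed (or rebuilt) `blade_mesh`.
#' @export
deform_blade <- function(mesh, margin_new, veins_new) {
  nodes <- mesh$nodes
  n <- nodes$n_margin
  if (margin_n(margin_new) != n ||
      !identical(veins_new$segs$id, nodes$seg_id)) {
    return(refresh_mesh(mesh, margin_new, veins_new))
  }
  newpos <- mesh$vertices
  newpos[1:n, ] <- margin_new$pos
  newpos[n + 1L, ] <- veins_new$base
  segs <- veins_new$segs
  for (k in seq_along(nodes$seg_id)) {
    ev <- nodes$end_vertex[k]
    if (ev > n) newpos[ev, ] <- c(segs$x1[k], segs$y1[k])
  }
  if (!is.null(mesh$subdivided)) {
    for (k in seq_len(nrow(mesh$subdivided))) {
      s <- mesh$subdivided[k, ]
      newpos[s[1], ] <- (newpos[s[2], ] + newpos[s[3], ]) / 2
    }
  }
  newpos <- harmonic_interior(mesh, newpos)
  out <- mesh
  out$vertices <- newpos
  if (any(triangle_areas(out) <= 0)) {
    return(refresh_mesh(mesh, margin_new, veins_new))
  }
  out
}

refresh_mesh <- function(mesh, margin_new, veins_new) {
  triangulate_blade(margin_new, veins_new)
}

#' @export
print.blade_mesh <- function(x, ...) {
  cat(sprintf("<blade_mesh> %d vertices (%d interior), %d triangles, area %.5g\n",
              nrow(x$vertices), sum(x$role == "interior"), nrow(x$triangles),
              sum(triangle_areas(x))))
  invisible(x)
}
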