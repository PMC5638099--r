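# Webbing: geometric fairing of the margin. The margin resists stretching and
# bending; each fairing iteration minimizes a quadratic majorizer of the
# discrete energy (spring form of the stretch term, exact bending term) plus
# a unit inertia anchoring the current positions, so the true energy is
# nonincreasing (majorize-minimize) and the displacement per iteration scales
# with the webbing weights. Morphogens modulate the local weights (a sinus
# morphogen with webbing_factor < 1 deepens sinuses).

# discrete fairing energy: stretch on edge lengths against a rest length,
# bend on second differences of positions
fair_energy <- function(pos, rest, ke, kb) {
  d <- diff(pos)
  el <- sqrt(rowSums(d^2))
  n <- nrow(pos)
  second <- pos[1:(n - 2), , drop = FALSE] - 2 * pos[2:(n - 1), , drop = FALSE] +
    pos[3:n, , drop = FALSE]
  sum(ke * (el - rest)^2) + sum(kb[2:(n - 1)] * rowSums(second^2))
}

# one majorize-minimize iteration: solve
#   (D' W1 D + L2' W2 L2 + mu I) p = D' W1 g + mu p0
# over the free points, with g the rest-length spring vectors along the
# current edge directions and pinned points held fixed; the system is a
# sparse SPD pentadiagonal solved via Matrix
fair_mm_iteration <- function(pos, rest, ke, kb, pinned, mu) {
  n <- nrow(pos)
  d <- diff(pos)
  el <- pmax(sqrt(rowSums(d^2)), 1e-300)
  g <- d / el * rest
  e1 <- seq_len(n - 1); e2 <- e1 + 1L
  ti <- c(e1, e2, e1, e2)
  tj <- c(e1, e2, e2, e1)
  tv <- c(ke, ke, -ke, -ke)
  bx <- matrix(0, n, 2)
  bx[1:(n - 1), ] <- bx[1:(n - 1), , drop = FALSE] - ke * g
  bx[2:n, ] <- bx[2:n, , drop = FALSE] + ke * g
  if (n >= 3) {
    m <- 2:(n - 1)
    w <- kb[m]
    cf <- c(1, -2, 1)
    for (a in 1:3) for (bq in 1:3) {
      ti <- c(ti, m - 2L + a)
      tj <- c(tj, m - 2L + bq)
      tv <- c(tv, w * cf[a] * cf[bq])
    }
  }
  ti <- c(ti, seq_len(n)); tj <- c(tj, seq_len(n)); tv <- c(tv, rep(mu, n))
  A <- Matrix::sparseMatrix(i = ti, j = tj, x = tv, dims = c(n, n))
  bx <- bx + mu * pos
  free <- which(!pinned)
  if (!length(free)) return(pos)
  fix <- which(pinned)
  rhs <- bx[free, , drop = FALSE] -
    as.matrix(A[free, fix, drop = FALSE] %*% pos[fix, , drop = FALSE])
  pos[free, ] <- as.matrix(Matrix::solve(A[free, free, drop = FALSE], rhs))
  pos
}

#' Fair (smooth) the margin by stretching and bending resistance
#'
#' Minimizes the discrete energy \eqn{E = \sum_e k_e (|e| - r_e)^2 + \sum_i
#' k_b |p_{i-1} - 2 p_i + p_{i+1}|^2} with per-edge rest lengths \eqn{r_e}
#' equal to the current length times `1 - relax` (positive `relax` pulls the
#' margin taut between pinned points). Each of the `iterations` passes takes
#' one majorize-minimize step with unit inertia, so `stretch`, `bend` and
#' `iterations` jointly set the webbing strength and the energy is
#' nonincreasing. Convergence points and the two base endpoints are pinned.
#' Per-point weights are multiplied by the product of `webbing_factor`s of
#' active morphogens; for `asym != 1` the stretch weight of edges on the
#' proximal (base-ward) side of their nearest convergence point is multiplied
#' by `asym`. If the result self-intersects, the whole sweep restarts with
#' increased inertia (smaller motion) until the margin stays simple.
#'
#' @param margin A `leaf_margin`.
#' @param stretch,bend Energy weights (>= 0).
#' @param iterations Number of fairing iterations (>= 0).
#' @param asym Proximal/distal stretch asymmetry ratio (> 0, 1 = symmetric).
#' @param relax Fractional rest-length deficit in \[0, 1).
#' @param rules Morphogen rules supplying `webbing_factor`s.
#' @param veins Optional vein tree; when given, a fairing sweep that would
#'   drag the margin across a vein is also rejected and restarted with more
#'   inertia.
#' @return The faired margin.
#' @export
fair_margin <- function(margin, stretch, bend, iterations, asym = 1,
                        relax = 0.15, rules = list(), veins = NULL) {
  n <- margin_n(margin)
  if (iterations == 0 || (stretch == 0 && bend == 0) || n < 4) return(margin)
  f <- point_factor(margin, rules, "webbing_factor")
  ke <- stretch * (f[-n] + f[-1]) / 2
  kb <- bend * f
  if (asym != 1) {
    cps <- which(margin$is_cp)
    if (length(cps)) {
      emid <- seq_len(n - 1) + 0.5
      nearest <- cps[apply(abs(outer(emid, cps, "-")), 1, which.min)]
      # proximal side of a CP = side toward the nearer base endpoint
      left_half <- nearest <= (n + 1) / 2
      proximal <- ifelse(left_half, emid < nearest, emid > nearest)
      ke <- ke * ifelse(proximal, asym, 1)
    }
  }
  # convergence points, barrier points (leaflet boundaries) and the base
  # endpoints move only by growth and transport, never by fairing
  pinned <- margin$is_cp | margin$barrier
  pinned[c(1L, n)] <- TRUE
  rest <- edge_lengths(margin) * (1 - relax)
  eps <- eps_geom(margin$pos)
  mu <- 1
  for (restart in 1:12) {
    pos <- margin$pos
    for (it in seq_len(iterations)) {
      # rest lengths track the current geometry so every edge stays under
      # tension; buckled (compressed) equilibria away from the taut curve
      # cannot arise
      d <- diff(pos)
      rest <- sqrt(rowSums(d^2)) * (1 - relax)
      pos <- fair_mm_iteration(pos, rest, ke, kb, pinned, mu)
    }
    ok <- !polyline_self_intersects(rbind(pos, pos[1, ]), eps) &&
      (is.null(veins) || !length(margin_vein_crossings(pos, veins, eps)))
    if (ok) break
    mu <- mu * 4
    pos <- margin$pos
  }
  margin$pos <- pos
  margin
}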