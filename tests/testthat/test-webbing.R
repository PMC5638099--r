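test_that("fairing with no iterations or zero weights is the identity", {
  m <- toy_triangle_margin()
  expect_equal(fair_margin(m, 1, 1, iterations = 0)$pos, m$pos)
  expect_equal(fair_margin(m, 0, 0, iterations = 5)$pos, m$pos)
})

test_that("collinear equally spaced points at rest are a fixed point", {
  m <- toy_flat_margin(n = 11)
  m$pos[, 2] <- 0 # exactly straight
  out <- fair_margin(m, stretch = 1, bend = 1, iterations = 5, relax = 0)
  expect_equal(out$pos, m$pos, tolerance = 1e-12)
})

test_that("one fairing iteration solves the inertial quadratic exactly", {
  # single free point between two pinned neighbours; oracle: numeric
  # minimization of the majorizer energy with unit inertia
  m <- leafdev:::new_leaf_margin(rbind(c(0, 0), c(0.5, 0.4), c(1, 0), c(1, -0.1)))
  m$is_cp[3] <- TRUE # pin so only point 2 is free
  stretch <- 0.7
  relax <- 0.2
  p0 <- m$pos
  rest <- leafdev:::edge_lengths(m) * (1 - relax)
  d <- diff(p0)
  el <- sqrt(rowSums(d^2))
  g <- d / el * rest
  obj <- function(q) {
    p <- p0
    p[2, ] <- q
    dd <- diff(p)
    ke <- stretch
    sum(ke * rowSums((dd - g)^2)) + sum((p - p0)^2)
  }
  oracle <- stats::optim(p0[2, ], obj, method = "BFGS",
                         control = list(reltol = 1e-14))$par
  out <- fair_margin(m, stretch = stretch, bend = 0, iterations = 1,
                     relax = relax)
  expect_equal(unname(out$pos[2, ]), unname(oracle), tolerance = 1e-6)
})

test_that("the fairing energy is nonincreasing over iterations", {
  set.seed(5)
  pos <- cbind(seq(0, 4, length.out = 21), c(0, runif(19, 0, 0.8), 0))
  m <- leafdev:::new_leaf_margin(pos)
  f <- rep(1, 21)
  ke <- 1 * (f[-21] + f[-1]) / 2
  kb <- 0.5 * f
  # energy functional with rest lengths tracking the current geometry
  efun <- function(p) {
    rest <- sqrt(rowSums(diff(p)^2)) * (1 - 0.1)
    leafdev:::fair_energy(p, rest, ke, kb)
  }
  energies <- sapply(0:6, function(it) {
    efun(fair_margin(m, 1, 0.5, iterations = it, relax = 0.1)$pos)
  })
  expect_true(all(diff(energies) <= 1e-10))
})

test_that("stretch-only fairing converges to straight chords between pins", {
  set.seed(6)
  pos <- cbind(seq(0, 4, length.out = 31), c(0, runif(29, 0, 0.6), 0))
  m <- leafdev:::new_leaf_margin(pos)
  m$is_cp[16] <- TRUE
  out <- fair_margin(m, stretch = 5, bend = 0, iterations = 500, relax = 0.4)
  # interior points should lie on the chords between consecutive pins
  for (i in 2:15) {
    chord_y <- m$pos[1, 2] + (m$pos[16, 2] - m$pos[1, 2]) *
      (out$pos[i, 1] - m$pos[1, 1]) / (m$pos[16, 1] - m$pos[1, 1])
    expect_lt(abs(out$pos[i, 2] - chord_y), 1e-6)
  }
})

test_that("morphogen webbing factors weaken fairing locally", {
  set.seed(8)
  pos <- cbind(seq(0, 4, length.out = 21), c(0, runif(19, 0.2, 0.5), 0))
  rules <- list(morphogen_rule("sinus", webbing_factor = 0))
  m <- leafdev:::new_leaf_margin(pos)
  m$morph <- cbind(sinus = c(rep(0, 7), rep(1, 7), rep(0, 7)))
  out <- fair_margin(m, 1, 1, iterations = 3, relax = 0.1, rules = rules)
  moved <- sqrt(rowSums((out$pos - m$pos)^2))
  # the heart of the weakened region barely moves; untouched regions do
  expect_lt(mean(moved[10:12]), 0.2 * mean(moved[c(3:6, 16:19)]))
})

test_that("asymmetric stretch skews teeth toward the apex side", {
  # one pinned tooth tip; asym > 1 strengthens the proximal (base-ward) side
  mk_tooth <- function() {
    x <- seq(0, 2, length.out = 21)
    y <- pmax(0, 0.5 - abs(x - 1)) + c(0, rep(1e-6, 19), 0)
    m <- leafdev:::new_leaf_margin(cbind(x, y))
    m$is_cp[11] <- TRUE
    m
  }
  sym <- fair_margin(mk_tooth(), 1, 0, iterations = 4, asym = 1, relax = 0.1)
  skew <- fair_margin(mk_tooth(), 1, 0, iterations = 4, asym = 4, relax = 0.1)
  # asym = 1 keeps the tooth mirror-symmetric; asym != 1 skews the flanks
  # with a deterministic sign (the stiffer proximal flank holds its shape,
  # the distal flank sags more), so teeth lean consistently
  sym_skew <- sum(sym$pos[2:10, 2]) - sum(rev(sym$pos[12:20, 2]))
  expect_lt(abs(sym_skew), 1e-9)
  prox_drop <- sum(sym$pos[2:10, 2] - skew$pos[2:10, 2])
  dist_drop <- sum(sym$pos[12:20, 2] - skew$pos[12:20, 2])
  expect_gt(abs(dist_drop - prox_drop), 1e-4)
  expect_gt(dist_drop, prox_drop)
})
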