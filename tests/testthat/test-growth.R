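test_that("rerg_at interpolates piecewise-linearly with constant tails", {
  uni <- rerg_profile(0, 0.1)
  expect_equal(rerg_at(uni, c(0, 1, 100)), rep(0.1, 3))

  bas <- rerg_profile(c(0, 2), c(0.4, 0))
  expect_equal(rerg_at(bas, 1), 0.2)   # r0 / 2 at L / 2
  expect_equal(rerg_at(bas, 5), 0)     # beyond the growth zone
  expect_equal(rerg_at(bas, 0), 0.4)
})

test_that("segment_elongation integrates the profile analytically", {
  uni <- rerg_profile(0, 0.1)
  expect_equal(segment_elongation(uni, 0, 2, dt = 1), 0.2) # l * r * dt

  lin <- rerg_profile(c(0, 2), c(0, 0.2)) # RERG(s) = 0.1 s on [0, 2]
  expect_equal(segment_elongation(lin, 0, 2, dt = 1), 0.2, tolerance = 1e-12)

  bas <- rerg_profile(c(0, 2), c(0.4, 0))
  expect_equal(segment_elongation(bas, 3, 5, dt = 1), 0) # outside the zone
})

test_that("segment_elongation agrees with adaptive quadrature on random profiles", {
  set.seed(7)
  for (rep in 1:50) {
    pr <- random_rerg()
    s <- sort(runif(2, 0, 12))
    dt <- runif(1, 0.01, 1)
    num <- dt * quad_rerg(pr, s[1], s[2])
    ana <- segment_elongation(pr, s[1], s[2], dt)
    expect_equal(ana, num, tolerance = 1e-10)
  }
})

test_that("elongate_veins stretches segments in place and translates subtrees", {
  mv <- leafdev:::midvein_tree(c(0, 0), c(0, 2))
  out <- elongate_veins(mv, rerg_profile(0, 0.1), dt = 1)
  expect_equal(out$segs$s1, 2.2)
  expect_equal(c(out$segs$x1, out$segs$y1), c(0, 2.2))

  # lateral entirely outside a basal growth zone: own length constant, both
  # endpoints translated by its attachment's displacement
  tr <- toy_tree_with_lateral(att = 3, lat = 1)
  zone <- rerg_profile(c(0, 2), c(0.5, 0))
  out2 <- elongate_veins(tr, zone, dt = 1)
  grown <- segment_elongation(zone, 0, 3, 1)
  expect_equal(out2$segs$s1[1] - out2$segs$s0[1], 3 + grown)
  lat_before <- tr$segs[3, ]
  lat_after <- out2$segs[3, ]
  expect_equal(lat_after$s1 - lat_after$s0, lat_before$s1 - lat_before$s0)
  expect_equal(c(lat_after$x1 - lat_before$x1, lat_after$y1 - lat_before$y1),
               c(0, grown))

  # zero profile is the identity
  expect_equal(elongate_veins(tr, rerg_profile(0, 0), 1)$segs, tr$segs)
})

test_that("uniform elongation scales total tree length by exactly 1 + r dt", {
  tr <- toy_tree_with_lateral(att = 2.5, lat = 1.5, angle = 60)
  r <- 0.07; dt <- 0.5
  out <- elongate_veins(tr, rerg_profile(0, r), dt)
  expect_equal(leafdev:::vein_total_length(out),
               (1 + r * dt) * leafdev:::vein_total_length(tr), tolerance = 1e-12)
})

test_that("vein directions are preserved by elongation", {
  set.seed(11)
  for (rep in 1:10) {
    tr <- toy_tree_with_lateral(att = runif(1, 1, 3.5), lat = runif(1, 0.5, 2),
                                angle = runif(1, 10, 80))
    out <- elongate_veins(tr, random_rerg(), runif(1, 0.01, 0.5))
    for (k in 1:nrow(tr$segs)) {
      d0 <- c(tr$segs$x1[k] - tr$segs$x0[k], tr$segs$y1[k] - tr$segs$y0[k])
      d1 <- c(out$segs$x1[k] - out$segs$x0[k], out$segs$y1[k] - out$segs$y0[k])
      expect_equal(d0 / sqrt(sum(d0^2)), d1 / sqrt(sum(d1^2)), tolerance = 1e-12)
    }
  }
})

test_that("extend_tips advances terminals and carries the convergence point", {
  st <- toy_state()
  same <- extend_tips(st$veins, st$margin, 0)
  expect_equal(same$veins$segs, st$veins$segs)

  out <- extend_tips(st$veins, st$margin, 0.05)
  expect_equal(out$veins$segs$s1, 2.05)
  apex <- which(st$margin$is_cp)
  expect_equal(unname(out$margin$pos[apex, ]), c(0, 2.05))
})

test_that("transport_margin displaces points by their projection displacement", {
  st <- toy_state(L = 2, w = 1, n = 9)
  # rigid translation of all veins translates every associated point equally
  moved <- st$veins
  moved$segs$y0 <- moved$segs$y0 + 1
  moved$segs$y1 <- moved$segs$y1 + 1
  out <- transport_margin(st$margin, st$veins, moved)
  expect_equal(out$pos, st$margin$pos + cbind(0, rep(1, 9)))

  # static veins: identity
  out2 <- transport_margin(st$margin, st$veins, st$veins)
  expect_equal(out2$pos, st$margin$pos)

  # uniform stretch by 1.1 about the vein start moves a point by 0.1 x the
  # offset of its projection
  stretched <- st$veins
  stretched$segs$y1 <- stretched$segs$y1 * 1.1
  stretched$segs$s1 <- stretched$segs$s1 * 1.1
  out3 <- transport_margin(st$margin, st$veins, stretched)
  i <- 3 # somewhere mid-margin
  proj_y <- min(max(st$margin$pos[i, 2], 0), 2)
  expect_equal(out3$pos[i, 2] - st$margin$pos[i, 2], 0.1 * proj_y,
               tolerance = 1e-12)
  expect_equal(out3$pos[i, 1], st$margin$pos[i, 1])
})

test_that("normal propagation moves interior points outward and pins the base", {
  m <- toy_flat_margin(n = 9)
  out <- normal_propagation(m, rates = 0, dt = 1)
  expect_equal(out$pos, m$pos)

  out2 <- normal_propagation(m, rates = 0.5, dt = 0.2)
  mv <- out2$pos - m$pos
  expect_equal(mv[1, ], c(0, 0))
  expect_equal(mv[9, ], c(0, 0))
  # interior points move perpendicular to the (horizontal) margin, away from
  # the interior below it
  expect_equal(mv[3, ], c(0, 0.1), tolerance = 1e-4)
})

test_that("petiole-style growth factor freezes its points", {
  params <- leaf_params(rules = list(morphogen_rule("petiole", growth_factor = 0)))
  m <- toy_flat_margin(n = 9)
  m$morph <- cbind(petiole = c(0, 0, 1, 1, 0, 0, 0, 0, 0))
  rates <- 0.5 * leafdev:::point_factor(m, params$rules, "growth_factor")
  out <- normal_propagation(m, rates, dt = 0.2)
  expect_equal(out$pos[3, ], m$pos[3, ])
  expect_equal(out$pos[4, ], m$pos[4, ])
  expect_false(isTRUE(all.equal(out$pos[6, ], m$pos[6, ])))
})

test_that("isotropic expansion is an exact similarity about the base", {
  st <- toy_state()
  same <- isotropic_expand(st, 0, 1)
  expect_equal(same$margin$pos, st$margin$pos)

  out <- isotropic_expand(st, iso_rate = 0.5, dt = 0.2) # factor 1.1
  d0 <- dist(st$margin$pos)
  d1 <- dist(out$margin$pos)
  expect_equal(as.vector(d1), as.vector(d0) * 1.1, tolerance = 1e-12)
  expect_equal(out$veins$segs$s1, st$veins$segs$s1 * 1.1)
})
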