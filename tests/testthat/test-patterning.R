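# A long nearly-straight margin with the apex convergence point replaced by
# ordinary samples makes spacing arithmetic easy: intervals are bounded by
# the two base endpoints unless CPs/barriers are added.
patterning_margin <- function(n = 41, h = 0.1) {
  toy_flat_margin(n = n, h = h)
}

test_that("intervals below the spacing threshold yield no insertion site", {
  m <- patterning_margin(n = 21, h = 0.1) # total arc 2
  veins <- leafdev:::midvein_tree(c(0, 0), c(1, 0.5))
  params <- leaf_params(lambda = 2.1)
  expect_length(find_insertion_sites(m, veins, params), 0)
})

test_that("a qualifying interval proposes its weighted midpoint", {
  m <- patterning_margin(n = 21, h = 0.1) # arc 2
  veins <- leafdev:::midvein_tree(c(0, 0), c(1, 0.5))
  params <- leaf_params(lambda = 1.6)
  sites <- find_insertion_sites(m, veins, params)
  expect_length(sites, 1)
  expect_equal(sites[[1]]$wlen, 2, tolerance = 1e-8)
  expect_equal(sites[[1]]$pos[1], 1.0, tolerance = 1e-9) # arc midpoint x
})

test_that("a blocking morphogen covering the interval suppresses insertion", {
  params <- leaf_params(lambda = 1.6,
                        rules = list(morphogen_rule("sinus", blocks_cp = TRUE)))
  m <- patterning_margin(n = 21, h = 0.1)
  m$morph <- cbind(sinus = rep(1, 21))
  veins <- leafdev:::midvein_tree(c(0, 0), c(1, 0.5))
  expect_length(find_insertion_sites(m, veins, params), 0)
})

test_that("competence filters veto otherwise qualifying sites", {
  m <- patterning_margin(n = 21, h = 0.1)
  veins <- leafdev:::midvein_tree(c(0, 0), c(1, 0.5))
  p_age <- leaf_params(lambda = 1.6, competence = list(max_age = 0.5))
  expect_length(find_insertion_sites(m, veins, p_age, age = 1), 0)
  expect_length(find_insertion_sites(m, veins, p_age, age = 0.4), 1)
  p_dist <- leaf_params(lambda = 1.6, competence = list(max_base_distance = 0.5))
  expect_length(find_insertion_sites(m, veins, p_dist), 0)
})

test_that("insertion assigns exactly the delta-ball to the new vein", {
  m <- patterning_margin(n = 21, h = 0.1)
  veins <- leafdev:::midvein_tree(c(0, 0), c(1, 0.5))
  site <- find_insertion_sites(m, veins, leaf_params(lambda = 1.6))[[1]]

  # delta = 0: only the convergence point itself
  p0 <- leaf_params(lambda = 1.6, delta = 0)
  ins0 <- insert_convergence_point(m, site, p0, vein_id = 7L)
  expect_true(ins0$margin$is_cp[ins0$cp])
  expect_equal(which(!is.na(ins0$margin$vein_id) & ins0$margin$vein_id == 7L),
               ins0$cp)

  # delta spanning three points on each side: exactly 7 points
  p3 <- leaf_params(lambda = 1.6, delta = 0.31)
  ins3 <- insert_convergence_point(m, site, p3, vein_id = 7L)
  ball <- which(!is.na(ins3$margin$vein_id) & ins3$margin$vein_id == 7L)
  expect_length(ball, 7)
  expect_equal(ball, (ins3$cp - 3L):(ins3$cp + 3L))
})

test_that("delta-ball assignment is clipped at an existing convergence point", {
  m <- patterning_margin(n = 21, h = 0.1)
  site <- find_insertion_sites(m, leafdev:::midvein_tree(c(0, 0), c(1, 0.5)),
                               leaf_params(lambda = 1.6))[[1]]
  m2 <- m
  m2$is_cp[site$edge - 1L] <- TRUE # neighbour CP two samples proximal
  p <- leaf_params(lambda = 1.6, delta = 0.35)
  ins <- insert_convergence_point(m2, site, p, vein_id = 7L)
  ball <- which(!is.na(ins$margin$vein_id) & ins$margin$vein_id == 7L)
  expect_true(all(ball > site$edge - 1L)) # nothing at or beyond the blocker
})

test_that("insertion morphogen rules exclude near and introduce in the open band", {
  rules <- list(
    morphogen_rule("red", rho_r = 0.4),
    morphogen_rule("blue", rho_bmin = 0.5, rho_bmax = 0.9),
    morphogen_rule("empty", rho_bmin = 0.7, rho_bmax = 0.7)
  )
  m <- patterning_margin(n = 21, h = 0.1)
  m$morph <- cbind(red = rep(1, 21))
  cp <- 11L
  m$is_cp[cp] <- TRUE
  out <- apply_insertion_rules(m, cp, rules, age = 0)
  d <- leafdev:::weighted_dist_from(out, cp, rules)
  expect_true(all(out$morph[d < 0.4, "red"] == 0))
  expect_true(all(out$morph[d > 0.4 + 1e-9, "red"] == 1))
  expect_true(all(out$morph[d > 0.5 & d < 0.9, "blue"] == 1))
  expect_true(all(out$morph[d <= 0.5 | d >= 0.9, "blue"] == 0))
  expect_false("empty" %in% colnames(out$morph)) # empty open band
})

test_that("a rule's competence age gates only its introduction band", {
  rules <- list(morphogen_rule("late", rho_bmin = 0.2, rho_bmax = 0.6,
                               max_age = 1))
  m <- patterning_margin(n = 21, h = 0.1)
  cp <- 11L
  m$is_cp[cp] <- TRUE
  young <- apply_insertion_rules(m, cp, rules, age = 0.5)
  old <- apply_insertion_rules(m, cp, rules, age = 2)
  expect_true("late" %in% colnames(young$morph) && any(young$morph[, "late"] > 0))
  expect_false("late" %in% colnames(old$morph))
})

test_that("barrier morphogens promote their points to interval barriers", {
  rules <- list(morphogen_rule("leaflet-base", rho_bmin = 0.3, rho_bmax = 0.6,
                               is_barrier = TRUE))
  m <- patterning_margin(n = 21, h = 0.1)
  cp <- 11L
  m$is_cp[cp] <- TRUE
  out <- apply_insertion_rules(m, cp, rules, age = 0)
  expect_true(any(out$barrier))
  expect_equal(out$barrier, leafdev:::morph_active(out, "leaflet-base"))
})

test_that("after the patterning stage no permitted interval exceeds lambda", {
  pr <- leaf_preset("simple-cordate")
  st <- make_primordium(pr$params, pr$primordium)
  for (k in 1:40) {
    st <- leaf_step(st, pr$params)
    expect_length(find_insertion_sites(st$margin, st$veins, pr$params, st$age), 0)
  }
  expect_gt(sum(st$margin$is_cp), 1)
})
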