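midvein_region <- function(L = 4) {
  segs <- data.frame(id = 1L, parent = 0L, vein = 1L,
                     x0 = 0, y0 = 0, x1 = 0, y1 = L, s0 = 0, s1 = L)
  bp <- rbind(c(0, 0))
  attr(bp, "path") <- 0
  list(segs = segs, branch_points = bp)
}

test_that("large b/v attaches at the perpendicular foot (right angle)", {
  reg <- midvein_region()
  att <- optimal_attachment(c(1, 2), reg, b = 1e6, v = 1)
  expect_equal(att$kind, "interior")
  expect_equal(att$location, c(0, 2), tolerance = 1e-5)
})

test_that("b = v attaches at the branch point toward the base", {
  reg <- midvein_region()
  att <- optimal_attachment(c(1, 2), reg, b = 1, v = 1)
  expect_equal(att$kind, "branch")
  expect_equal(att$location, c(0, 0))
})

test_that("the interior optimum meets the vein at theta = acos(v/b)", {
  reg <- midvein_region()
  att <- optimal_attachment(c(1, 2), reg, b = 2, v = 1) # theta = 60 degrees
  expect_equal(att$kind, "interior")
  dirv <- c(1, 2) - att$location
  distal <- c(0, 1) # midvein direction away from the base
  ang <- acos(sum(dirv / sqrt(sum(dirv^2)) * distal)) * 180 / pi
  expect_lt(abs(ang - 60), 0.5)

  # tau also matches a dense brute-force scan
  inst <- list(region = reg, cp = c(1, 2), b = 2, v = 1)
  expect_lte(att$tau, brute_force_tau(inst, 1e5) + 1e-6 * att$tau)
})

test_that("optimal_attachment matches the brute-force tau scan on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    inst <- random_routing_instance()
    att <- optimal_attachment(inst$cp, inst$region, inst$b, inst$v)
    bf <- brute_force_tau(inst, 2e4)
    expect_lte(att$tau, bf + 1e-6 * att$tau)
  }
})

test_that("optimal tau is monotone in the resistances", {
  reg <- midvein_region()
  cp <- c(1.5, 2.5)
  taus_v <- sapply(c(0.2, 0.5, 0.8, 1), function(v) {
    optimal_attachment(cp, reg, b = 1, v = v)$tau
  })
  expect_true(all(diff(taus_v) >= -1e-12))
  taus_b <- sapply(c(1, 2, 4, 8), function(b) {
    optimal_attachment(cp, reg, b = b, v = 1)$tau
  })
  expect_true(all(diff(taus_b) >= -1e-12))
})

test_that("the sigma_max clamp overrides grazing attachments", {
  reg <- midvein_region()
  cp <- c(0.5, 3.9)
  nrm <- c(1, 0) # outward normal pointing straight away from the vein
  free <- optimal_attachment(cp, reg, b = 1.05, v = 1, sigma_max = NULL)
  clamped <- optimal_attachment(cp, reg, b = 1.05, v = 1, sigma_max = 20,
                                normal = nrm)
  # with b close to v the free optimum runs nearly parallel to the margin
  dir_free <- (cp - free$location)
  ang_free <- acos(sum(dir_free / sqrt(sum(dir_free^2)) * nrm)) * 180 / pi
  expect_gt(ang_free, 20)
  dir_cl <- (cp - clamped$location)
  ang_cl <- acos(sum(dir_cl / sqrt(sum(dir_cl^2)) * nrm)) * 180 / pi
  expect_true(clamped$clamped)
  expect_lt(ang_cl, 20 + 1e-6)
})

test_that("candidate_region of a midvein-only leaf is the midvein", {
  st <- toy_state(n = 9)
  # flag a site on the left flank as a new convergence point with a reserved
  # vein id
  st$margin$is_cp[3] <- TRUE
  st$margin$vein_id[3] <- 2L
  reg <- candidate_region(st, 3L)
  expect_equal(reg$segs$id, 1L)
  expect_equal(attr(reg$branch_points, "path"), 0) # the base only
})

test_that("attach_vein splits interior attachments and keeps path lengths additive", {
  st <- toy_state(n = 9)
  st$margin$is_cp[3] <- TRUE
  st$margin$vein_id[3] <- 2L
  reg <- candidate_region(st, 3L)
  cp_pos <- st$margin$pos[3, ]
  att <- optimal_attachment(cp_pos, reg, b = 2, v = 1)

  if (att$kind == "interior") {
    out <- attach_vein(st, 3L, att)
    expect_equal(nrow(out$veins$segs), 3L) # split: net +2 segments
    expect_equal(vein_path_length(out$veins, cp_pos),
                 att$path_to_base + sqrt(sum((cp_pos - att$location)^2)),
                 tolerance = 1e-9)
  }

  # branch-point attachment adds exactly one segment
  attb <- optimal_attachment(cp_pos, reg, b = 1, v = 1)
  expect_equal(attb$kind, "branch")
  outb <- attach_vein(st, 3L, attb)
  expect_equal(nrow(outb$veins$segs), 2L)
  expect_true(leafdev:::vein_tree_valid(outb$veins))
})

test_that("branching angles over random instances follow arccos(v/b)", {
  set.seed(202)
  checked <- 0
  for (rep in 1:60) {
    inst <- random_routing_instance()
    att <- optimal_attachment(inst$cp, inst$region, inst$b, inst$v)
    if (att$kind != "interior") next
    segs <- inst$region$segs
    k <- match(att$seg_id, segs$id)
    distal <- c(segs$x1[k] - segs$x0[k], segs$y1[k] - segs$y0[k])
    distal <- distal / sqrt(sum(distal^2))
    dirv <- inst$cp - att$location
    dirv <- dirv / sqrt(sum(dirv^2))
    ang <- acos(min(max(sum(dirv * distal), -1), 1)) * 180 / pi
    theta <- acos(inst$v / inst$b) * 180 / pi
    expect_lt(abs(ang - theta), 1)
    checked <- checked + 1
  }
  expect_gte(checked, 20)
})
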