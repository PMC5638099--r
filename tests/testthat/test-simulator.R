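test_that("a step with all rates zero changes only bookkeeping", {
  params <- leaf_params(tip_growth = 0, iso_rate = 0, margin_rate = 0,
                        rerg = rerg_profile(0, 0), lambda = 100,
                        h_max = 10, h_min = 1e-9,
                        webbing = list(iterations = 0))
  st <- make_primordium(params, primordium_outline())
  out <- leaf_step(st, params)
  expect_equal(out$margin$pos, st$margin$pos)
  expect_equal(out$veins$segs, st$veins$segs)
  expect_equal(out$step, 1L)
  expect_equal(out$age, params$dt)
})

test_that("lateral convergence points emerge as the margin outgrows lambda", {
  pr <- leaf_preset("simple-cordate")
  st <- make_primordium(pr$params, pr$primordium)
  steps_to_first <- NA
  for (k in 1:60) {
    st <- leaf_step(st, pr$params)
    if (sum(st$margin$is_cp) >= 3) { steps_to_first <- k; break }
  }
  expect_false(is.na(steps_to_first))
  # the second and third convergence points appear lateral to the apex,
  # mirror-symmetrically
  cps <- which(st$margin$is_cp)
  expect_equal(sum(st$margin$is_cp), 3)
  xs <- sort(st$margin$pos[cps, 1])
  expect_lt(xs[1], 0)
  expect_gt(xs[3], 0)
  expect_equal(xs[1], -xs[3], tolerance = 1e-9)
})

test_that("runs are deterministic and convergence point counts never decrease", {
  pr <- leaf_preset("simple-cordate")
  r1 <- simulate_leaf(pr$params, pr$primordium, n_steps = 25, snapshot_every = 5)
  r2 <- simulate_leaf(pr$params, pr$primordium, n_steps = 25, snapshot_every = 5)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_snapshot(final_of(r1), f1)
  write_snapshot(final_of(r2), f2)
  expect_identical(readLines(f1), readLines(f2))

  cps <- vapply(r1$states, function(s) sum(s$margin$is_cp), 0L)
  expect_true(all(diff(cps) >= 0))
})

test_that("a zero-step run returns the initial state only", {
  pr <- leaf_preset("simple-cordate")
  r <- simulate_leaf(pr$params, pr$primordium, n_steps = 0)
  expect_equal(final_of(r)$step, 0L)
})

test_that("mirror-symmetric states stay mirror-symmetric", {
  pr <- leaf_preset("simple-cordate")
  st <- make_primordium(pr$params, pr$primordium)
  for (k in 1:60) st <- leaf_step(st, pr$params)
  expect_lt(symmetry_score(st$margin), 1e-8)
})

test_that("configurations round-trip through YAML exactly", {
  pr <- leaf_preset("palmate-lobed")
  f <- tempfile(fileext = ".yaml")
  write_leaf_config(pr$params, pr$primordium, f)
  back <- load_leaf_config(f)
  expect_equal(back$params, pr$params)
  expect_equal(back$primordium$outline, pr$primordium$outline, tolerance = 1e-12)
})

test_that("configs with unknown fields or unpainted morphogens are rejected", {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(params = list(lambda = 1, bogus = 2)), f)
  expect_error(load_leaf_config(f), "bogus")
  yaml::write_yaml(list(primordium = list(
    morphogens = list(mystery = list(c(0, 0.1)))
  )), f)
  expect_error(load_leaf_config(f), "mystery")
})

test_that("SVG snapshots carry a margin path and one line per vein segment", {
  pr <- leaf_preset("simple-cordate")
  r <- simulate_leaf(pr$params, pr$primordium, n_steps = 30)
  st <- final_of(r)
  f <- tempfile(fileext = ".svg")
  write_snapshot(st, f, format = "svg", mesh = TRUE)
  svg <- readLines(f)
  expect_equal(sum(grepl('class="margin"', svg)), 1)
  expect_equal(sum(grepl('class="vein"', svg)), nrow(st$veins$segs))
  expect_equal(sum(grepl('class="mesh"', svg)), 1)
})

test_that("OFF snapshots describe the blade mesh", {
  st <- toy_state(n = 9)
  st$mesh <- triangulate_blade(st$margin, st$veins)
  f <- tempfile(fileext = ".off")
  write_snapshot(st, f, format = "off")
  lines <- readLines(f)
  expect_equal(lines[1], "OFF")
  counts <- as.integer(strsplit(lines[2], " ")[[1]])
  expect_equal(counts[1], nrow(st$mesh$vertices))
  expect_equal(counts[2], nrow(st$mesh$triangles))
  expect_equal(length(lines), 2 + counts[1] + counts[2])
})

test_that("JSON snapshots carry the complete margin and vein state", {
  pr <- leaf_preset("simple-cordate")
  r <- simulate_leaf(pr$params, pr$primordium, n_steps = 10)
  st <- final_of(r)
  f <- tempfile(fileext = ".json")
  write_snapshot(st, f)
  doc <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(doc$step, st$step)
  expect_equal(nrow(doc$margin$pos), margin_n(st$margin))
  expect_equal(doc$veins$segments$id, st$veins$segs$id)
})
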