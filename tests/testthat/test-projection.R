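test_that("identity scenarios reproduce the current map and zero change", {
  world <- demo_world(seed = 23, n = 30)
  pres <- demo_presences(world, seed = 24,
                         species = virtual_species(n_presences = 40))
  ens <- suppressMessages(run_ensemble(
    pres, world$bias, world$stack,
    brt_config(tree_complexity = 2, learning_rate = 0.02, max_trees = 600),
    n_replicates = 3, seed = 2))

  sc <- scenario_stack("identity", world$stack, world$stack)
  fut <- project_scenario(ens$models, sc)
  expect_identical(fut$values, ens$mean_suitability$values)
  expect_true(all(fut$values[world$stack$shared_mask] >= 0 &
                    fut$values[world$stack$shared_mask] <= 1))

  ref <- suitability_max(ens$mean_suitability)
  cur_mask <- very_suitable_mask(ens$mean_suitability, ref)
  fut_mask <- very_suitable_mask(fut, ref)
  ch <- suitability_change(cur_mask, fut_mask)
  expect_identical(ch$delta_km2, 0)
  expect_identical(ch$delta_pct, 0)
})

test_that("scenario stacks borrow the current biome and check variables", {
  world <- demo_world(seed = 25, n = 20)
  no_biome <- assemble_stack(world$stack$layers[
    setdiff(names(world$stack$layers), "biome")])
  sc <- scenario_stack("SSP245", no_biome, world$stack)
  expect_identical(names(sc$stack$layers), names(world$stack$layers))
  expect_identical(sc$stack$layers$biome$values,
                   world$stack$layers$biome$values)
  expect_error(
    scenario_stack("bad", assemble_stack(world$stack$layers[1:3]),
                   world$stack),
    "match")
})

test_that("the very-suitable cut is a multiplicative threshold", {
  g <- toy_grid(1, 3)
  suit <- new_raster(g, matrix(c(0.9, 0.8, 0.7), 1, 3))
  m <- very_suitable_mask(suit, reference_max = 0.9)
  expect_equal(as.vector(m$values), c(1, 1, 0))  # threshold 0.765

  # fraction 0 keeps only cells attaining the maximum
  m0 <- very_suitable_mask(suit, reference_max = 0.9, fraction = 0)
  expect_equal(as.vector(m0$values), c(1, 0, 0))

  expect_error(very_suitable_mask(suit, 0.9, analysis_mask =
                                    matrix(FALSE, 1, 3)), "empty")
})

test_that("raising the cut fraction never shrinks the mask", {
  world <- demo_world(seed = 26, n = 25)
  sp <- virtual_species(n_presences = 30)
  suit <- true_suitability(world$stack, sp)
  ref <- suitability_max(suit)
  prev <- 0
  for (f in c(0, 0.05, 0.15, 0.3, 0.6)) {
    m <- very_suitable_mask(suit, ref, fraction = f)
    n_now <- sum(m$values)
    expect_gte(n_now, prev)
    prev <- n_now
  }
})

test_that("exclusions subtract from the mask and warn when total", {
  g <- toy_grid(4, 4)
  m <- new_raster(g, matrix(1, 4, 4))
  expect_identical(apply_exclusions(m, NULL)$values, m$values)

  # half-plane exclusion: survivors are hand-countable
  excl <- matrix(FALSE, 4, 4)
  excl[, 1:2] <- TRUE
  suppressMessages(out <- apply_exclusions(m, excl))
  expect_equal(sum(out$values), 8)
  expect_true(all(out$values[, 1:2] == 0))

  suppressMessages(
    expect_warning(apply_exclusions(m, matrix(TRUE, 4, 4)), "entire"))
})

test_that("area change matches a brute-force per-cell oracle", {
  # 3-row toy grid touching the equator, masks set by hand
  g <- build_grid(0, 0, 1.5, 0.125, 2.5)
  stopifnot(g$n_rows == 3)
  cur <- matrix(0, 3, g$n_cols)
  cur[1, 1:5] <- 1
  cur[2, 3:9] <- 1
  fut <- cur
  fut[3, 7] <- 1  # one extra near-equatorial cell

  cur_r <- new_raster(g, cur)
  fut_r <- new_raster(g, fut)
  ch <- suitability_change(cur_r, fut_r, species = "toy", scenario_id = "t")

  brute <- function(m) {
    tot <- 0
    for (i in 1:nrow(m)) for (j in 1:ncol(m))
      if (m[i, j] > 0) tot <- tot + cell_area_km2(g, i)
    tot
  }
  expect_equal(ch$current_area_km2, brute(cur), tolerance = 1e-12)
  expect_equal(ch$future_area_km2, brute(fut), tolerance = 1e-12)
  expect_equal(ch$delta_km2, 21.47, tolerance = 0.001)
  expect_equal(ch$delta_pct, 100 * ch$delta_km2 / ch$current_area_km2)

  # area additivity: |A or B| + |A and B| = |A| + |B|
  a <- new_raster(g, (cur + fut > 0) * 1)       # union
  b <- new_raster(g, (cur * fut) * 1)           # intersection
  lhs <- suitability_change(a, b)
  expect_equal(lhs$current_area_km2 + lhs$future_area_km2,
               brute(cur) + brute(fut), tolerance = 1e-9)

  # zero current area flags an undefined percentage
  z <- new_raster(g, matrix(0, 3, g$n_cols))
  ch0 <- suitability_change(z, fut_r)
  expect_true(ch0$undefined_pct)
  expect_true(is.na(ch0$delta_pct))
})

test_that("presence bounding-box masks buffer the data extent", {
  g <- toy_grid(10, 10)  # 0..5 degrees, 0.5-degree cells
  pres <- structure(list(grid = g,
                         cells = cbind(row = c(5L, 6L), col = c(5L, 6L)),
                         n_raw = 2L, species = "A"),
                    class = "sdm_presences")
  m <- presence_bbox_mask(pres, buffer_deg = 0.5)
  expect_true(m[5, 5] && m[6, 6])
  expect_false(m[1, 1])
  # a big buffer covers the whole grid
  expect_true(all(presence_bbox_mask(pres, buffer_deg = 10)))
})
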