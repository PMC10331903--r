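# a tiny world where every cell index is known
sampling_setup <- function(n = 6) {
  grid <- toy_grid(n, n)
  pres <- structure(list(
    grid = grid, cells = cbind(row = 1L, col = 1L), n_raw = 1L,
    species = "A"), class = "sdm_presences")
  list(grid = grid, pres = pres)
}

test_that("zero-weight cells are never drawn; seeds reproduce draws", {
  s <- sampling_setup(4)
  w <- matrix(1, 4, 4)
  w[2, 2] <- 0
  bias <- bias_layer(new_raster(s$grid, w))
  region <- matrix(TRUE, 4, 4)
  for (i in 1:50) {
    set.seed(i)
    drawn <- sample_pseudo_absences(s$pres, bias, region, n = 10)
    expect_false(any(drawn[, 1] == 2 & drawn[, 2] == 2))
    expect_false(any(drawn[, 1] == 1 & drawn[, 2] == 1))  # presence cell
    expect_equal(nrow(unique(drawn)), 10)                 # no replacement
  }
  set.seed(99)
  d1 <- sample_pseudo_absences(s$pres, bias, region, n = 5)
  set.seed(99)
  d2 <- sample_pseudo_absences(s$pres, bias, region, n = 5)
  expect_identical(d1, d2)
})

test_that("draw frequencies follow the bias weights", {
  s <- sampling_setup(2)
  # two candidate cells with weights 3 and 1 (others masked out)
  w <- matrix(0, 2, 2)
  w[1, 2] <- 3
  w[2, 1] <- 1
  bias <- bias_layer(new_raster(s$grid, w))
  region <- matrix(TRUE, 2, 2)
  set.seed(42)
  hits <- 0L
  n_draws <- 2000L
  for (i in seq_len(n_draws)) {
    d <- sample_pseudo_absences(s$pres, bias, region, n = 1)
    if (d[1, 1] == 1 && d[1, 2] == 2) hits <- hits + 1L
  }
  p <- stats::chisq.test(c(hits, n_draws - hits),
                         p = c(3, 1) / 4)$p.value
  expect_gt(p, 0.001)
})

test_that("absence count defaults to the presence count", {
  world <- demo_world(seed = 3, n = 30)
  sp <- virtual_species(n_presences = 40)
  pres <- demo_presences(world, seed = 4, species = sp)
  set.seed(1)
  absences <- sample_pseudo_absences(pres, world$bias, world$stack$shared_mask)
  expect_equal(nrow(absences), nrow(pres$cells))
})

test_that("errors on infeasible draws", {
  s <- sampling_setup(2)
  bias <- bias_layer(new_raster(s$grid, matrix(1, 2, 2)))
  region <- matrix(TRUE, 2, 2)
  expect_error(sample_pseudo_absences(s$pres, bias, region, n = 10),
               "fewer than n")
  w0 <- matrix(c(1, 0, 0, 0), 2, 2)  # only the presence cell has weight
  expect_error(
    sample_pseudo_absences(s$pres, bias_layer(new_raster(s$grid, w0)),
                           region, n = 1),
    "zero|fewer")
})

test_that("model tables carry labels, covariates and complete cases", {
  world <- demo_world(seed = 5, n = 20)
  sp <- virtual_species(n_presences = 10)
  pres <- demo_presences(world, seed = 6, species = sp)
  set.seed(2)
  absences <- sample_pseudo_absences(pres, world$bias,
                                     world$stack$shared_mask)
  tab <- build_table(pres, absences, world$stack)
  expect_s3_class(tab, "sdm_patable")
  expect_equal(nrow(tab$x), nrow(pres$cells) + nrow(absences))
  expect_equal(ncol(tab$x), 8)
  expect_equal(sum(tab$label), nrow(pres$cells))
  expect_identical(tab$column_names, names(world$stack$layers))

  # overlap between classes is rejected
  expect_error(build_table(pres, pres$cells, world$stack), "disjoint")

  # cells with any invalid covariate are excluded
  holed <- world$stack$layers
  vm <- holed$min_temp$valid_mask
  vm[pres$cells[1, 1], pres$cells[1, 2]] <- FALSE
  holed$min_temp <- new_raster(world$grid, holed$min_temp$values,
                               valid_mask = vm)
  st2 <- assemble_stack(holed)
  expect_message(tab2 <- build_table(pres, absences, st2), "excluded")
  expect_equal(nrow(tab2$x), nrow(tab$x) - 1)
})

test_that("collinearity screen reports r, flags pairs, tolerates constants", {
  g <- toy_grid(40, 40)
  set.seed(8)
  a <- matrix(rnorm(1600), 40, 40)
  b <- matrix(rnorm(1600), 40, 40)
  st <- assemble_stack(list(
    a = new_raster(g, a),
    a_copy = new_raster(g, a),          # r = 1 with a
    b = new_raster(g, b),               # independent noise
    flat = new_raster(g, matrix(2, 40, 40))))
  scr <- collinearity_screen(st)
  expect_equal(scr$threshold, 0.7)
  expect_equal(scr$correlations["a", "a_copy"], 1)
  expect_true(any(scr$flags$var1 == "a" & scr$flags$var2 == "a_copy"))
  # independent noise at 1600 cells stays far from the flag bound
  expect_lt(abs(scr$correlations["a", "b"]), 0.1)
  # constant layers are reported as NA, not an error
  expect_true(is.na(scr$correlations["flat", "a"]))
  expect_identical(scr$constant, "flat")

  expect_error(collinearity_screen(assemble_stack(list(
    a = new_raster(g, a)))), "two continuous")
})
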