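test_that("bernoulli deviance matches its closed form", {
  expect_equal(bernoulli_deviance(c(1, 0), c(1, 0)), 0)
  expect_equal(bernoulli_deviance(c(1, 0), c(0.5, 0.5)), -2 * log(0.5),
               tolerance = 1e-12)
  expect_equal(bernoulli_deviance(c(1, 1, 0), c(0.9, 0.8, 0.3)),
               -2 * mean(log(c(0.9, 0.8, 0.7))), tolerance = 1e-12)
  expect_error(bernoulli_deviance(numeric(0), numeric(0)), "empty")
  expect_error(bernoulli_deviance(c(1, 0), 0.5), "length")
  # clipping keeps impossible predictions finite
  expect_true(is.finite(bernoulli_deviance(1, 0)))
})

test_that("AUC equals brute-force pair counting on small inputs", {
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)
  expect_equal(auc(c(1, 0, 1, 0), c(0.8, 0.7, 0.4, 0.6)), 0.5)
  expect_error(auc(c(1, 1), c(0.2, 0.3)), "both classes")

  # exhaustive small cases, scores with deliberate ties
  set.seed(10)
  for (n in 2:8) {
    for (rep in 1:20) {
      labels <- integer(n)
      labels[sample(n, sample(n - 1, 1))] <- 1L
      scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)
      expect_equal(auc(labels, scores), auc_bruteforce(labels, scores))
    }
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(11)
  labels <- rbinom(50, 1, 0.5)
  labels[1:2] <- c(0, 1)
  scores <- rnorm(50)
  a0 <- auc(labels, scores)
  expect_equal(auc(labels, exp(scores)), a0)
  expect_equal(auc(labels, 2 * scores - 7), a0)
  skip_if_not_installed("pROC")
  a_proc <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(a0, a_proc, tolerance = 1e-12)
})

test_that("fits are deterministic and beat the null on real signal", {
  tab <- signal_table(n = 200, seed = 2)
  cfg <- brt_config(tree_complexity = 2, learning_rate = 0.02,
                    max_trees = 1500)
  set.seed(7)
  m1 <- fit_brt(tab, cfg)
  set.seed(7)
  m2 <- fit_brt(tab, cfg)
  expect_identical(m1$n_trees, m2$n_trees)
  expect_identical(predict(m1, tab$x), predict(m2, tab$x))

  # resubstitution deviance beats the intercept-only model
  expect_lt(bernoulli_deviance(tab$label, m1$fitted), m1$null_deviance)
  # the CV curve's selected point is optimal on the recorded curve
  expect_equal(m1$cv_deviance, min(m1$cv_curve))
  expect_lte(m1$cv_deviance, m1$cv_curve[1])
  expect_true(all(predict(m1, tab$x) >= 0 & predict(m1, tab$x) <= 1))
})

test_that("coin-flip labels give chance-level cross-validated AUC", {
  tab <- null_table(n = 200, seed = 3)
  set.seed(5)
  m <- fit_brt(tab, brt_config(tree_complexity = 2, learning_rate = 0.01,
                               max_trees = 800))
  expect_gt(m$cv_auc, 0.4)
  expect_lt(m$cv_auc, 0.6)
})

test_that("intercept-only predictions equal the training prevalence", {
  tab <- signal_table(n = 100, seed = 4)
  set.seed(1)
  m <- fit_brt(tab, brt_config(tree_complexity = 1, learning_rate = 0.05,
                               max_trees = 200))
  p0 <- predict(m, tab$x, n_trees = 0)
  expect_equal(unique(round(p0, 10)), mean(tab$label))
})

test_that("a one-split model partitions the data at one threshold", {
  # noiseless step signal: y = 1 iff x > 0
  n <- 100
  x <- matrix(c(seq(-1, 1, length.out = n), rnorm(n)), n, 2,
              dimnames = list(NULL, c("x", "junk")))
  y <- as.numeric(x[, 1] > 0)
  tab <- structure(list(label = y, x = x,
                        cells = cbind(row = rep(1L, n), col = 1:n),
                        column_names = colnames(x),
                        is_categorical = c(x = FALSE, junk = FALSE),
                        replicate_id = 1L), class = "sdm_patable")
  set.seed(2)
  m <- fit_brt(tab, brt_config(tree_complexity = 1, learning_rate = 0.1,
                               max_trees = 300, cv_folds = 5))
  p <- predict(m, tab$x)
  # predictions split cleanly away from the class boundary (bagging lets
  # individual trees place their cut a hair to either side of it)
  expect_lt(max(p[x[, 1] < -0.1]), min(p[x[, 1] > 0.1]))
  expect_gt(auc(y, p), 0.99)
  # every split uses the informative variable
  expect_equal(unname(relative_influence(m)["x"]), 100)
  expect_equal(unname(relative_influence(m)["junk"]), 0)
})

test_that("relative influence recovers a dominant driver and sums to 100", {
  tab <- signal_table(n = 300, p_noise = 4, beta = 3, seed = 6)
  set.seed(3)
  m <- fit_brt(tab, brt_config(tree_complexity = 3, learning_rate = 0.02,
                               max_trees = 1500))
  infl <- relative_influence(m)
  expect_equal(sum(infl), 100, tolerance = 1e-6)
  expect_true(all(infl >= 0))
  expect_identical(names(which.max(infl)), "driver")
  expect_gt(infl["driver"], 50)
})

test_that("lower learning rates select at least as many trees", {
  n_hi <- n_lo <- 0
  for (s in 1:3) {
    tab <- signal_table(n = 200, seed = 20 + s)
    set.seed(s)
    m_hi <- fit_brt(tab, brt_config(tree_complexity = 2,
                                    learning_rate = 0.05,
                                    max_trees = 3000))
    set.seed(s)
    m_lo <- fit_brt(tab, brt_config(tree_complexity = 2,
                                    learning_rate = 0.01,
                                    max_trees = 3000))
    n_hi <- n_hi + m_hi$n_trees
    n_lo <- n_lo + m_lo$n_trees
  }
  expect_gte(n_lo, n_hi)
})

test_that("hyperparameter selection follows the deviance/tree-count rule", {
  tab <- signal_table(n = 250, seed = 8)
  set.seed(4)
  sel <- select_hyperparameters(tab, tc_grid = c(1, 3),
                                lr_grid = c(0.01, 0.05),
                                config = brt_config(max_trees = 1500),
                                min_trees = 100)
  expect_true(sel$tree_complexity %in% c(1, 3))
  expect_true(sel$learning_rate %in% c(0.01, 0.05))
  expect_equal(nrow(sel$trace), 4)
  # the chosen complexity attains the lowest minimum CV deviance
  agg <- tapply(sel$trace$cv_deviance, sel$trace$tree_complexity, min)
  expect_equal(unname(agg[as.character(sel$tree_complexity)]), min(agg))
  # among rates clearing the tree floor, the largest is chosen
  sub <- sel$trace[sel$trace$tree_complexity == sel$tree_complexity &
                     sel$trace$n_trees > 100, ]
  if (nrow(sub) > 0) expect_equal(sel$learning_rate, max(sub$learning_rate))

  # unreachable tree floor falls back to the smallest rate, with a message
  set.seed(4)
  expect_message(
    sel2 <- select_hyperparameters(tab, tc_grid = 2, lr_grid = c(0.03, 0.05),
                                   config = brt_config(max_trees = 300),
                                   min_trees = 10000),
    "smallest rate")
  expect_equal(sel2$learning_rate, 0.03)
})

test_that("categorical predictors split on level subsets", {
  set.seed(9)
  n <- 200
  code <- sample(0:3, n, replace = TRUE)
  y <- as.numeric(code %in% c(1, 3))  # level subset fully determines y
  x <- cbind(biome = code, noise = rnorm(n))
  tab <- structure(list(label = y, x = x,
                        cells = cbind(row = rep(1L, n), col = 1:n),
                        column_names = colnames(x),
                        is_categorical = c(biome = TRUE, noise = FALSE),
                        replicate_id = 1L), class = "sdm_patable")
  set.seed(10)
  m <- fit_brt(tab, brt_config(tree_complexity = 2, learning_rate = 0.1,
                               max_trees = 500, cv_folds = 5))
  expect_gt(relative_influence(m)["biome"], 90)
  expect_gt(auc(y, predict(m, x)), 0.999)
  # an unseen level routes to the majority branch, with a message
  xu <- cbind(biome = c(7, 1), noise = c(0, 0))
  expect_message(pu <- predict(m, xu), "unseen")
  expect_true(all(pu >= 0 & pu <= 1))
})

test_that("a hand-built one-split tree is evaluated exactly", {
  # single tree: split x at 0.5, leaf values -1 (left) and +1 (right)
  doc <- list(
    format = "macrosdm-brt", version = 1L,
    var_names = list("x"), is_categorical = list(FALSE),
    cat_levels = list(x = NULL),
    intercept = 0, n_trees = 1L, cv_curve = list(1),
    cv_deviance = 1, null_deviance = -2 * log(0.5), cv_auc = 0.5,
    relative_influence = list(x = 100),
    config = unclass(brt_config()),
    trees = list(list(
      list(var = 0, thr = 0.5, mask = 0, seen = 0, defdir = 0,
           left = 1, right = 2, value = 0, improve = 1),
      list(var = -1, thr = 0, mask = 0, seen = 0, defdir = 0,
           left = -1, right = -1, value = -1, improve = 0),
      list(var = -1, thr = 0, mask = 0, seen = 0, defdir = 0,
           left = -1, right = -1, value = 1, improve = 0))))
  m <- brt_from_json(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                      null = "null"))
  x <- matrix(c(0.1, 0.5, 0.50001, 0.9), ncol = 1,
              dimnames = list(NULL, "x"))
  p <- predict(m, x)
  expect_equal(p, plogis(c(-1, -1, 1, 1)), tolerance = 1e-12)
})

test_that("JSON serialization round-trips models and predictions", {
  tab <- signal_table(n = 120, seed = 12)
  set.seed(6)
  m <- fit_brt(tab, brt_config(tree_complexity = 2, learning_rate = 0.05,
                               max_trees = 400))
  path <- withr::local_tempfile(fileext = ".json")
  brt_to_json(m, path)
  m2 <- brt_from_json(path)
  expect_equal(m2$n_trees, m$n_trees)
  expect_equal(m2$relative_influence, m$relative_influence)
  expect_equal(predict(m2, tab$x), predict(m, tab$x), tolerance = 1e-12)
})
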