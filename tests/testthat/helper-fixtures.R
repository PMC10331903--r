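# Shared fixtures, all generated in code.

# small anchored grid at the origin
toy_grid <- function(n_rows = 4, n_cols = 4, resolution_arcmin = 30) {
  delta <- resolution_arcmin / 60
  build_grid(0, 0, n_cols * delta, n_rows * delta, resolution_arcmin)
}

# deterministic continuous layer: values 1..n laid out row-major
seq_layer <- function(grid) {
  m <- matrix(seq_len(grid$n_rows * grid$n_cols),
              grid$n_rows, grid$n_cols, byrow = TRUE)
  new_raster(grid, m, kind = "continuous")
}

# presence/absence table with one informative covariate and pure noise
signal_table <- function(n = 200, p_noise = 2, beta = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * (1 + p_noise)), n, 1 + p_noise)
  colnames(x) <- c("driver", paste0("noise", seq_len(p_noise)))
  prob <- plogis(beta * x[, 1])
  y <- rbinom(n, 1, prob)
  # guarantee both classes
  if (sum(y) < 10) y[order(prob, decreasing = TRUE)[1:10]] <- 1
  if (sum(1 - y) < 10) y[order(prob)[1:10]] <- 0
  is_cat <- setNames(rep(FALSE, ncol(x)), colnames(x))
  structure(list(label = y, x = x,
                 cells = cbind(row = rep(1L, n), col = seq_len(n)),
                 column_names = colnames(x), is_categorical = is_cat,
                 replicate_id = 1L),
            class = "sdm_patable")
}

# label vector independent of covariates (null model check)
null_table <- function(n = 200, p = 3, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p)))
  y <- rep(c(0, 1), length.out = n)[sample(n)]
  is_cat <- setNames(rep(FALSE, p), colnames(x))
  structure(list(label = y, x = x,
                 cells = cbind(row = rep(1L, n), col = seq_len(n)),
                 column_names = colnames(x), is_categorical = is_cat,
                 replicate_id = 1L),
            class = "sdm_patable")
}

# brute-force AUC by pair enumeration: the independent oracle
auc_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# a small shared synthetic world for pipeline-level tests
demo_world <- function(seed = 7, n = 60) {
  delta <- 2.5 / 60
  grid <- build_grid(20, -20, 20 + n * delta, -20 + n * delta, 2.5)
  stack <- generate_covariates(
    grid, seed = seed,
    correlations = list(list(pair = c("mean_annual_temp", "min_temp"),
                             rho = 0.72)))
  bias <- generate_bias_layer(grid, hotspots = 25, seed = seed + 1,
                              floor = 0.2)
  list(grid = grid, stack = stack, bias = bias)
}

# presences for a driver-dominated virtual species on a demo world
demo_presences <- function(world, seed = 11, species = virtual_species()) {
  suit <- true_suitability(world$stack, species)
  set.seed(seed)
  occ <- sample_virtual_occurrences(suit, species)
  thin_to_grid(occ, world$grid)
}
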