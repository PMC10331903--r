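# Virtual-species simulator: covariate stacks, bias surfaces and
# occurrence records with known ground truth. Emulates the statistical
# structure of gridded bioclimate data (large-scale gradients plus smooth
# local variation, a categorical biome mosaic, survey-effort hotspots),
# not any real geography.

#' Default synthetic covariate field definitions
#'
#' The seven canonical climate covariates with plausible value ranges
#' (temperatures in degrees C, precipitation in mm, seasonality as a
#' coefficient of variation), used by [generate_covariates()].
#'
#' @return Named list of `list(range = c(lo, hi))` definitions.
#' @export
default_covariate_fields <- function() {
  list(
    mean_annual_temp = list(range = c(10, 32)),
    min_temp = list(range = c(-5, 24)),
    max_temp = list(range = c(22, 45)),
    temp_range = list(range = c(5, 40)),
    diurnal_range = list(range = c(6, 20)),
    annual_precip = list(range = c(20, 2200)),
    precip_seasonality = list(range = c(10, 140)))
}

# smooth standardized random field: separable Gaussian kernel smoothing of
# white noise, z-scored over all cells
smooth_field <- function(n_rows, n_cols, sigma) {
  pad <- ceiling(3 * sigma)
  k <- stats::dnorm(seq(-pad, pad), sd = sigma)
  k <- k / sum(k)
  z <- matrix(stats::rnorm((n_rows + 2 * pad) * (n_cols + 2 * pad)),
              n_rows + 2 * pad, n_cols + 2 * pad)
  z <- apply(z, 2, function(col) stats::filter(col, k, sides = 2))
  z <- t(apply(z, 1, function(row) stats::filter(row, k, sides = 2)))
  z <- z[(pad + 1):(pad + n_rows), (pad + 1):(pad + n_cols)]
  (z - mean(z)) / stats::sd(z)
}

# random-orientation linear gradient, standardized
gradient_field <- function(n_rows, n_cols) {
  theta <- stats::runif(1, 0, 2 * pi)
  r <- matrix(seq_len(n_rows), n_rows, n_cols)
  c_ <- matrix(seq_len(n_cols), n_rows, n_cols, byrow = TRUE)
  g <- cos(theta) * c_ + sin(theta) * r
  (g - mean(g)) / stats::sd(g)
}

std_field <- function(m) (m - mean(m)) / stats::sd(m)

#' Generate a synthetic covariate stack
#'
#' Each continuous layer is an equal mix of a random-orientation linear
#' gradient (the large-scale climatic trend) and a Gaussian-kernel
#' smoothed noise field (local structure), rescaled to its stated range.
#' Pairs named in `correlations` are rebuilt by mixing with the first
#' layer's standardized field after exact orthogonalization, so the
#' achieved cell-wise Pearson correlation equals the request exactly. A
#' categorical biome layer is cut from its own smooth field at value
#' quantiles, so every code is present.
#'
#' @param grid An `sdm_grid`; intended for desk-scale grids
#'   (<= ~1e5 cells).
#' @param fields Named list of field definitions
#'   (see [default_covariate_fields()]).
#' @param seed Integer seed; the stack is a deterministic function of it.
#' @param correlations Optional list of `list(pair = c(a, b), rho = r)`
#'   entries with `|r| < 1`.
#' @param biome_codes Number of biome classes (0 to omit the biome layer).
#' @param smooth_sigma Kernel standard deviation in cells.
#' @return An `sdm_stack`.
#' @export
generate_covariates <- function(grid, fields = default_covariate_fields(),
                                seed = 1, correlations = NULL,
                                biome_codes = 4, smooth_sigma = 3) {
  if (grid$n_rows * grid$n_cols > 1e6)
    stop("grid too large for the synthetic generator")
  set.seed(seed)
  z <- list()
  for (nm in names(fields)) {
    f <- sqrt(0.5) * gradient_field(grid$n_rows, grid$n_cols) +
      sqrt(0.5) * smooth_field(grid$n_rows, grid$n_cols, smooth_sigma)
    z[[nm]] <- std_field(f)
  }
  for (cr in correlations) {
    a <- cr$pair[1]; b <- cr$pair[2]; rho <- cr$rho
    if (!all(c(a, b) %in% names(fields)))
      stop("correlation pair names not in fields")
    if (abs(rho) >= 1) stop("target correlation must satisfy |rho| < 1")
    za <- z[[a]]
    # orthogonalize b's field against a's, then remix to the exact rho
    zb <- z[[b]]
    proj <- sum(za * zb) / sum(za * za)
    perp <- std_field(zb - proj * za)
    z[[b]] <- std_field(rho * za + sqrt(1 - rho^2) * perp)
  }
  layers <- list()
  for (nm in names(fields)) {
    rng <- fields[[nm]]$range
    zz <- z[[nm]]
    v <- rng[1] + (zz - min(zz)) / (max(zz) - min(zz)) * (rng[2] - rng[1])
    layers[[nm]] <- new_raster(grid, v, kind = "continuous")
  }
  if (biome_codes > 0) {
    bf <- smooth_field(grid$n_rows, grid$n_cols, 2 * smooth_sigma)
    cuts <- stats::quantile(bf, probs = seq_len(biome_codes - 1) / biome_codes)
    codes <- matrix(findInterval(bf, cuts) + 1, grid$n_rows, grid$n_cols)
    layers$biome <- new_raster(grid, codes, kind = "categorical")
  }
  assemble_stack(layers)
}

#' Define a virtual species
#'
#' A ground-truth suitability function on the logit scale: a linear
#' combination of z-scored covariates plus optional per-biome offsets.
#'
#' @param coefficients Named numeric vector of effects on the logit scale
#'   per standard deviation of each covariate.
#' @param intercept Logit intercept (controls overall prevalence).
#' @param biome_preferences Optional named numeric vector of logit offsets
#'   keyed by biome code (as character).
#' @param n_presences Target number of presence records (>= 5).
#' @param name Species label used in occurrence records.
#' @return An object of class `virtual_species`.
#' @export
virtual_species <- function(coefficients = c(min_temp = 6),
                            intercept = -9,
                            biome_preferences = NULL,
                            n_presences = 150,
                            name = "Virtualis exempli") {
  if (length(coefficients) == 0 && length(biome_preferences) == 0)
    stop("need at least one active variable or biome preference")
  stopifnot(n_presences >= 5)
  structure(list(coefficients = coefficients, intercept = intercept,
                 biome_preferences = biome_preferences,
                 n_presences = as.integer(n_presences), name = name),
            class = "virtual_species")
}

#' Ground-truth suitability of a virtual species
#'
#' `p(cell) = plogis(intercept + sum_v coef_v * z_v + biome offset)`, with
#' each active covariate z-scored over the stack's valid cells so
#' coefficients are comparable effect sizes.
#'
#' @param stack An `sdm_stack`.
#' @param species A [virtual_species()].
#' @return Continuous `sdm_raster` of probabilities.
#' @export
true_suitability <- function(stack, species) {
  active <- names(species$coefficients)[species$coefficients != 0]
  missing_vars <- setdiff(active, names(stack$layers))
  if (length(missing_vars) > 0)
    stop("stack is missing active variable(s): ",
         paste(missing_vars, collapse = ", "))
  keep <- stack$shared_mask
  eta <- matrix(species$intercept, stack$grid$n_rows, stack$grid$n_cols)
  for (v in active) {
    vals <- stack$layers[[v]]$values
    mu <- mean(vals[keep])
    sdv <- stats::sd(vals[keep])
    eta <- eta + species$coefficients[[v]] * (vals - mu) / sdv
  }
  if (length(species$biome_preferences) > 0) {
    if (!("biome" %in% names(stack$layers)))
      stop("species has biome preferences but the stack has no biome layer")
    codes <- stack$layers$biome$values
    off <- matrix(0, nrow(codes), ncol(codes))
    for (code in names(species$biome_preferences))
      off[codes == as.numeric(code)] <- species$biome_preferences[[code]]
    eta <- eta + off
  }
  p <- stats::plogis(eta)
  p[!keep] <- NA_real_
  new_raster(stack$grid, p, kind = "continuous", valid_mask = keep)
}

#' Sample occurrence records from a true-suitability surface
#'
#' Draws `n_presences` distinct cells with probability proportional to
#' suitability, then emits each as a point jittered uniformly inside the
#' open cell box (so thinning the points recovers exactly the sampled
#' cells). Uses the R RNG stream; `set.seed()` first for reproducibility.
#'
#' @param suitability Continuous `sdm_raster` of probabilities.
#' @param species A [virtual_species()].
#' @return An `sdm_occurrences` object.
#' @export
sample_virtual_occurrences <- function(suitability, species) {
  grid <- suitability$grid
  p <- suitability$values
  p[!suitability$valid_mask | !is.finite(p)] <- 0
  pos <- which(p > 0)
  if (length(pos) < species$n_presences)
    stop("fewer positive-suitability cells than requested presences")
  drawn <- pos[sample.int(length(pos), species$n_presences,
                          replace = FALSE, prob = p[pos])]
  row <- (drawn - 1) %% grid$n_rows + 1
  col <- (drawn - 1) %/% grid$n_rows + 1
  delta <- grid_delta(grid)
  u <- stats::runif(length(drawn), 1e-6, 1 - 1e-6)
  v <- stats::runif(length(drawn), 1e-6, 1 - 1e-6)
  occurrence_set(
    species = species$name,
    points = data.frame(
      longitude = grid$west + (col - 1 + u) * delta,
      latitude = grid_north(grid) - (row - 1 + v) * delta),
    source = "synthetic")
}

#' Generate a synthetic survey-effort bias surface
#'
#' Sum of Gaussian effort bumps at seeded random centres plus an optional
#' uniform floor — the shape of a collection-record density map with a few
#' well-surveyed hotspots.
#'
#' @param grid An `sdm_grid`.
#' @param hotspots Number of bumps (>= 0; with 0 and `floor = 0` the
#'   surface is all zero and pseudo-absence sampling will refuse it).
#' @param seed Integer seed.
#' @param sigma_cells Bump width in cells.
#' @param floor Uniform background effort added everywhere.
#' @return An `sdm_bias` with smoothing 0.
#' @export
generate_bias_layer <- function(grid, hotspots = 5, seed = 1,
                                sigma_cells = 8, floor = 0) {
  stopifnot(hotspots >= 0, floor >= 0)
  set.seed(seed)
  vals <- matrix(floor, grid$n_rows, grid$n_cols)
  if (hotspots > 0) {
    r <- matrix(seq_len(grid$n_rows), grid$n_rows, grid$n_cols)
    c_ <- matrix(seq_len(grid$n_cols), grid$n_rows, grid$n_cols,
                 byrow = TRUE)
    for (h in seq_len(hotspots)) {
      cr <- stats::runif(1, 1, grid$n_rows)
      cc <- stats::runif(1, 1, grid$n_cols)
      vals <- vals + exp(-((r - cr)^2 + (c_ - cc)^2) / (2 * sigma_cells^2))
    }
  }
  layer <- new_raster(grid, vals, kind = "continuous")
  if (all(vals == 0))
    return(structure(list(layer = layer, smoothing = 0),
                     class = "sdm_bias"))
  bias_layer(layer, smoothing = 0)
}
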