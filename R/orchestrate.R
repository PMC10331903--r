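# Configuration-driven orchestration of the full workflow:
# simulate -> fit (thin, screen, select, ensemble) -> project.
# A config is a plain named list, usually read from YAML.

#' Read and validate a run configuration
#'
#' @param config Path to a YAML file or a named list.
#' @return The validated config list.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$seed))
    stop("config must set an explicit seed (no implicit entropy)")
  config
}

default_demo_config <- function(out_dir, seed) {
  list(
    seed = seed,
    out_dir = out_dir,
    grid = list(west = 20, south = -20, east = 24.1666, north = -15.8334,
                resolution_arcmin = 2.5),
    species = list(list(
      name = "Virtualis exempli",
      coefficients = list(min_temp = 6),
      intercept = -9,
      n_presences = 150)),
    correlations = list(list(pair = c("mean_annual_temp", "min_temp"),
                             rho = 0.72)),
    biome_codes = 4,
    bias = list(hotspots = 25, sigma_cells = 8, floor = 0.2),
    brt = list(tree_complexity = 3, learning_rate = 0.005,
               max_trees = 2000),
    n_replicates = 100,
    min_presences = 10,
    fraction = 0.15,
    buffer_deg = 5)
}

config_grid <- function(config) {
  g <- config$grid
  build_grid(g$west, g$south, g$east, g$north,
             resolution_arcmin = if (is.null(g$resolution_arcmin)) 2.5
                                 else g$resolution_arcmin)
}

config_brt <- function(config) {
  args <- config$brt
  if (is.null(args)) args <- list()
  do.call(brt_config, args[names(args) %in% names(formals(brt_config))])
}

config_species <- function(sp) {
  virtual_species(
    coefficients = unlist(sp$coefficients),
    intercept = if (is.null(sp$intercept)) 0 else sp$intercept,
    biome_preferences = unlist(sp$biome_preferences),
    n_presences = if (is.null(sp$n_presences)) 150 else sp$n_presences,
    name = sp$name)
}

#' Simulate a complete synthetic dataset on disk
#'
#' Writes covariate layers (`layers/<name>.asc`), a bias surface
#' (`bias.asc`), occurrence records for every configured virtual species
#' (`occurrences.csv`) and the ground truth (`truth.json`) under the
#' configured output directory. Deterministic per seed.
#'
#' @param config Config list or YAML path (see [read_run_config()]);
#'   `NULL` uses a self-contained demo configuration.
#' @param out_dir Output directory (overrides the config's).
#' @param seed Master seed (overrides the config's).
#' @param force Overwrite an existing output directory.
#' @return Invisibly, a list with the stack, bias, occurrences and config.
#' @export
sdm_simulate <- function(config = NULL, out_dir = NULL, seed = NULL,
                         force = FALSE) {
  if (is.null(config)) {
    if (is.null(out_dir) || is.null(seed))
      stop("without a config, out_dir and seed are required")
    config <- default_demo_config(out_dir, seed)
  } else {
    config <- read_run_config(config)
    if (!is.null(out_dir)) config$out_dir <- out_dir
    if (!is.null(seed)) config$seed <- seed
  }
  out <- config$out_dir
  if (dir.exists(out) && length(dir(out)) > 0 && !force)
    stop("output directory exists and is not empty; use force = TRUE")
  dir.create(file.path(out, "layers"), recursive = TRUE,
             showWarnings = FALSE)

  grid <- config_grid(config)
  corr <- lapply(config$correlations, function(cr)
    list(pair = unlist(cr$pair), rho = cr$rho))
  stack <- generate_covariates(
    grid, seed = config$seed, correlations = corr,
    biome_codes = if (is.null(config$biome_codes)) 4 else config$biome_codes)
  for (nm in names(stack$layers))
    write_layer(stack$layers[[nm]], file.path(out, "layers",
                                              paste0(nm, ".asc")))
  b <- config$bias
  bias <- generate_bias_layer(
    grid, hotspots = if (is.null(b$hotspots)) 5 else b$hotspots,
    seed = config$seed + 1000L,
    sigma_cells = if (is.null(b$sigma_cells)) 8 else b$sigma_cells,
    floor = if (is.null(b$floor)) 0 else b$floor)
  write_layer(bias$layer, file.path(out, "bias.asc"))

  occ_rows <- list()
  truth <- list(seed = config$seed, species = list())
  for (i in seq_along(config$species)) {
    sp <- config_species(config$species[[i]])
    suit <- true_suitability(stack, sp)
    set.seed(config$seed + 2000L + i)
    occ <- sample_virtual_occurrences(suit, sp)
    occ_rows[[i]] <- data.frame(species = sp$name,
                                longitude = occ$points$longitude,
                                latitude = occ$points$latitude)
    truth$species[[i] ] <- list(
      name = sp$name, coefficients = as.list(sp$coefficients),
      intercept = sp$intercept,
      biome_preferences = as.list(sp$biome_preferences),
      n_presences = sp$n_presences)
  }
  occs <- do.call(rbind, occ_rows)
  utils::write.csv(occs, file.path(out, "occurrences.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
             file.path(out, "truth.json"))
  invisible(list(stack = stack, bias = bias, occurrences = occs,
                 config = config))
}

load_stack_from_dir <- function(layer_dir) {
  files <- sort(dir(layer_dir, pattern = "\\.asc$", full.names = TRUE))
  if (length(files) == 0) stop("no .asc layers in ", layer_dir)
  nms <- sub("\\.asc$", "", basename(files))
  layers <- list()
  for (i in seq_along(files)) {
    kind <- if (nms[i] == "biome") "categorical" else "continuous"
    layers[[nms[i]]] <- read_layer(files[i], kind = kind)
  }
  # canonical order: continuous covariates first, biome last
  ord <- c(setdiff(sort(nms), "biome"), intersect("biome", nms))
  assemble_stack(layers[ord])
}

#' Fit pseudo-absence ensembles for every configured species
#'
#' Reads the dataset written by [sdm_simulate()] (or any dataset in the
#' same layout), thins occurrences to the grid, runs the collinearity
#' screen, optionally selects hyperparameters on the first replicate's
#' table, runs the replicate ensemble per species, and writes: mean
#' suitability (`suitability_<species>.asc`), the influence table
#' (`influence_table.csv`), per-replicate diagnostics
#' (`diagnostics_<species>.csv`), the screening report
#' (`collinearity.csv`, `screening.json`) and a run manifest
#' (`manifest.json`, with input hashes, seed and config). Species with
#' fewer thinned presences than `min_presences` are skipped with a
#' warning. If the bias surface is missing, sampling falls back to
#' uniform weighting with a message.
#'
#' @param config Config list or YAML path; needs `out_dir` (the dataset
#'   directory) and `seed`.
#' @param run_dir Directory for fit outputs; defaults to
#'   `<out_dir>/fit`.
#' @param select_hyper Run [select_hyperparameters()] per species instead
#'   of using the configured `brt` parameters.
#' @return Invisibly, a list with `results` (named list of
#'   `sdm_ensemble`), `stack`, `presences`, `screen`, `table`
#'   (influence table).
#' @export
sdm_fit <- function(config, run_dir = NULL, select_hyper = FALSE) {
  config <- read_run_config(config)
  data_dir <- config$out_dir
  if (is.null(run_dir)) run_dir <- file.path(data_dir, "fit")
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)

  stack <- load_stack_from_dir(file.path(data_dir, "layers"))
  bias_path <- file.path(data_dir, "bias.asc")
  if (file.exists(bias_path)) {
    bias <- bias_layer(read_layer(bias_path, kind = "continuous"))
  } else {
    message("no bias layer found; falling back to uniform weighting")
    bias <- bias_layer(new_raster(stack$grid, 1, kind = "continuous"))
  }
  occ_path <- file.path(data_dir, "occurrences.csv")

  screen <- collinearity_screen(stack, threshold = 0.7)
  utils::write.csv(as.data.frame(screen$correlations),
                   file.path(run_dir, "collinearity.csv"))
  writeLines(jsonlite::toJSON(list(
    threshold = screen$threshold, flagged = screen$flags,
    constant = screen$constant), auto_unbox = TRUE, digits = NA,
    dataframe = "rows"),
    file.path(run_dir, "screening.json"))

  min_presences <- if (is.null(config$min_presences)) 10
                   else config$min_presences
  n_replicates <- if (is.null(config$n_replicates)) 100
                  else config$n_replicates
  base_config <- config_brt(config)

  results <- list()
  for (i in seq_along(config$species)) {
    sp_name <- config$species[[i]]$name
    occ <- read_occurrences(occ_path, sp_name)
    presences <- thin_to_grid(occ, stack$grid)
    if (nrow(presences$cells) < min_presences) {
      warning("species '", sp_name, "' has fewer than ", min_presences,
              " thinned presences; skipped")
      next
    }
    write_presences(presences,
                    file.path(run_dir, paste0("presences_",
                                              gsub("\\W+", "_", sp_name),
                                              ".csv")))
    cfg <- base_config
    if (select_hyper) {
      set.seed(config$seed)
      absences <- sample_pseudo_absences(presences, bias,
                                         stack$shared_mask)
      tab0 <- build_table(presences, absences, stack, replicate_id = 0L)
      set.seed(config$seed)
      sel <- select_hyperparameters(tab0, config = cfg)
      cfg$tree_complexity <- sel$tree_complexity
      cfg$learning_rate <- sel$learning_rate
    }
    ens <- run_ensemble(presences, bias, stack, cfg,
                        n_replicates = n_replicates, seed = config$seed)
    results[[sp_name]] <- ens
    slug <- gsub("\\W+", "_", sp_name)
    write_layer(ens$mean_suitability,
                file.path(run_dir, paste0("suitability_", slug, ".asc")))
    utils::write.csv(ens$diagnostics,
                     file.path(run_dir, paste0("diagnostics_", slug,
                                               ".csv")),
                     row.names = FALSE)
  }
  if (length(results) == 0) stop("no species could be fitted")
  tab <- influence_table(results)
  utils::write.csv(tab, file.path(run_dir, "influence_table.csv"),
                   row.names = FALSE)

  inputs <- c(dir(file.path(data_dir, "layers"), full.names = TRUE),
              occ_path, if (file.exists(bias_path)) bias_path)
  manifest <- list(
    seed = config$seed,
    n_replicates = n_replicates,
    brt = unclass(config_brt(config)),
    package_version = as.character(utils::packageVersion("macrosdm")),
    input_hashes = as.list(tools::md5sum(inputs)))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             file.path(run_dir, "manifest.json"))
  invisible(list(results = results, stack = stack, screen = screen,
                 table = tab, run_dir = run_dir, config = config))
}

#' Project fitted ensembles onto future scenarios
#'
#' Applies every replicate model to each scenario's covariates, thresholds
#' current and future maps at the same cut below the current maximum
#' (within the presence bounding-box analysis mask, minus exclusions) and
#' writes, per species and scenario: the future suitability and
#' very-suitable masks as `.asc`, plus a combined change report
#' (`change_report.csv` and `.json`).
#'
#' @param fit Result of [sdm_fit()] (the returned list).
#' @param scenarios Named list: scenario id -> `sdm_stack` (or directory
#'   of `.asc` layers). Missing biome layers are borrowed from the current
#'   stack.
#' @param run_dir Output directory; defaults to the fit's `run_dir`.
#' @param fraction Very-suitable cut below the current maximum
#'   (default 0.15).
#' @param buffer_deg Analysis-mask buffer around the presence bounding box
#'   (default 5 degrees).
#' @param exclusion Optional boolean `sdm_raster` (or logical matrix) of
#'   areas to exclude; `NULL` proceeds with none.
#' @return Invisibly, the change report data frame.
#' @export
sdm_project <- function(fit, scenarios, run_dir = NULL, fraction = 0.15,
                        buffer_deg = 5, exclusion = NULL) {
  if (is.null(run_dir)) run_dir <- fit$run_dir
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (sp_name in names(fit$results)) {
    ens <- fit$results[[sp_name]]
    slug <- gsub("\\W+", "_", sp_name)
    pres_path <- file.path(run_dir, paste0("presences_", slug, ".csv"))
    analysis <- if (file.exists(pres_path)) {
      df <- utils::read.csv(pres_path)
      pres <- structure(list(grid = fit$stack$grid,
                             cells = cbind(row = df$row, col = df$col),
                             species = sp_name, n_raw = nrow(df)),
                        class = "sdm_presences")
      presence_bbox_mask(pres, buffer_deg)
    } else NULL
    ref_max <- suitability_max(ens$mean_suitability, analysis)
    cur_mask <- apply_exclusions(
      very_suitable_mask(ens$mean_suitability, ref_max, fraction, analysis),
      exclusion)
    for (sc_name in names(scenarios)) {
      sc <- scenarios[[sc_name]]
      if (is.character(sc)) sc <- load_stack_from_dir(sc)
      sc <- scenario_stack(sc_name, sc, fit$stack)
      fut <- project_scenario(ens$models, sc)
      fut_mask <- apply_exclusions(
        very_suitable_mask(fut, ref_max, fraction, analysis), exclusion)
      write_layer(fut, file.path(run_dir, paste0(
        "suitability_", slug, "_", sc_name, ".asc")))
      write_layer(fut_mask, file.path(run_dir, paste0(
        "very_suitable_", slug, "_", sc_name, ".asc")))
      ch <- suitability_change(cur_mask, fut_mask, species = sp_name,
                               scenario_id = sc_name,
                               threshold = (1 - fraction) * ref_max)
      rows[[length(rows) + 1]] <- data.frame(
        species = sp_name, scenario = sc_name, threshold = ch$threshold,
        current_area_km2 = ch$current_area_km2,
        future_area_km2 = ch$future_area_km2,
        delta_km2 = ch$delta_km2, delta_pct = ch$delta_pct)
    }
  }
  report <- do.call(rbind, rows)
  utils::write.csv(report, file.path(run_dir, "change_report.csv"),
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"),
             file.path(run_dir, "change_report.json"))
  invisible(report)
}
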