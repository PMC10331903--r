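#' Bundle future covariates as a scenario stack
#'
#' Checks that the future stack matches the current one in grid and
#' variable names. If the future layers lack a biome layer while the
#' current stack has one, the current biome is carried over (no future
#' biome raster is usually available).
#'
#' @param scenario_id Label, e.g. `"SSP245"`.
#' @param stack Future `sdm_stack`.
#' @param current Current `sdm_stack` to validate against (and to borrow
#'   the biome layer from if absent).
#' @return An object of class `sdm_scenario` (`scenario_id`, `stack`).
#' @export
scenario_stack <- function(scenario_id, stack, current) {
  if (!grids_identical(stack$grid, current$grid))
    stop("scenario grid does not match the current grid")
  layers <- stack$layers
  if ("biome" %in% names(current$layers) && !("biome" %in% names(layers)))
    layers$biome <- current$layers$biome
  if (!setequal(names(layers), names(current$layers)))
    stop("scenario variables do not match the current stack")
  stack <- assemble_stack(layers[names(current$layers)])
  structure(list(scenario_id = scenario_id, stack = stack),
            class = "sdm_scenario")
}

#' Project an ensemble onto future covariates
#'
#' Cell-wise mean of every replicate model's prediction on the future
#' stack. With the future stack identical to the training stack this
#' reproduces the ensemble's current mean suitability exactly.
#'
#' @param models List of `brt_model` objects (e.g. `ensemble$models`).
#' @param future An `sdm_scenario` or `sdm_stack`.
#' @return Continuous `sdm_raster` of mean suitability.
#' @export
project_scenario <- function(models, future) {
  stack <- if (inherits(future, "sdm_scenario")) future$stack else future
  stopifnot(length(models) >= 1)
  acc <- NULL
  for (m in models) {
    p <- predict_suitability(m, stack)$values
    acc <- if (is.null(acc)) p else acc + p
  }
  new_raster(stack$grid, acc / length(models),
             valid_mask = stack$shared_mask)
}

#' Threshold a suitability map at a share below its current maximum
#'
#' "Very suitable" cells are those with suitability at least
#' `(1 - fraction) * reference_max`, where `reference_max` is the maximum
#' of the CURRENT suitability map inside the analysis mask. The same
#' reference is reused unchanged when thresholding future maps, so current
#' and future areas are cut at the same absolute level. The cut is
#' multiplicative (e.g. 15% below a maximum of 0.9 means 0.765), keeping
#' the threshold inside `[0, 1]` for species whose maximum is low.
#'
#' @param suitability Continuous `sdm_raster` in `[0, 1]`.
#' @param reference_max Current maximum suitability in `(0, 1]`.
#' @param fraction Share below the maximum that still counts as very
#'   suitable (default 0.15).
#' @param analysis_mask Optional logical matrix or logical-valued
#'   `sdm_raster` restricting the analysis region.
#' @return Boolean `sdm_raster` (values 0/1).
#' @export
very_suitable_mask <- function(suitability, reference_max, fraction = 0.15,
                               analysis_mask = NULL) {
  stopifnot(reference_max > 0, reference_max <= 1,
            fraction >= 0, fraction < 1)
  keep <- suitability$valid_mask
  if (!is.null(analysis_mask)) {
    region <- if (inherits(analysis_mask, "sdm_raster")) {
      analysis_mask$valid_mask & analysis_mask$values > 0
    } else analysis_mask
    keep <- keep & region
  }
  if (!any(keep)) stop("analysis mask is empty")
  thr <- (1 - fraction) * reference_max
  m <- (suitability$values >= thr) & keep
  m[is.na(m)] <- FALSE
  new_raster(suitability$grid, m * 1, valid_mask = suitability$valid_mask)
}

#' Maximum suitability within an analysis region
#'
#' @param suitability Continuous `sdm_raster`.
#' @param analysis_mask Optional region restriction as in
#'   [very_suitable_mask()].
#' @return Scalar maximum.
#' @export
suitability_max <- function(suitability, analysis_mask = NULL) {
  keep <- suitability$valid_mask
  if (!is.null(analysis_mask)) {
    region <- if (inherits(analysis_mask, "sdm_raster")) {
      analysis_mask$valid_mask & analysis_mask$values > 0
    } else analysis_mask
    keep <- keep & region
  }
  if (!any(keep)) stop("analysis mask is empty")
  max(suitability$values[keep])
}

#' Analysis mask from the presence bounding box
#'
#' The projection analysis is limited to the neighbourhood of the data
#' that informed the model: the bounding box of the presence cells,
#' buffered outward by `buffer_deg` degrees.
#'
#' @param presences An `sdm_presences` object.
#' @param buffer_deg Buffer in degrees (default 5).
#' @return Logical matrix on the presence grid.
#' @export
presence_bbox_mask <- function(presences, buffer_deg = 5) {
  grid <- presences$grid
  ctr <- cell_centers(grid, presences$cells)
  lon_rng <- range(ctr[, 1]) + c(-1, 1) * buffer_deg
  lat_rng <- range(ctr[, 2]) + c(-1, 1) * buffer_deg
  all_cells <- mask_cells(matrix(TRUE, grid$n_rows, grid$n_cols))
  cc <- cell_centers(grid, all_cells)
  inside <- cc[, 1] >= lon_rng[1] & cc[, 1] <= lon_rng[2] &
    cc[, 2] >= lat_rng[1] & cc[, 2] <= lat_rng[2]
  m <- matrix(FALSE, grid$n_rows, grid$n_cols)
  m[all_cells[inside, , drop = FALSE]] <- TRUE
  m
}

#' Remove excluded areas from a boolean mask
#'
#' Clears mask cells covered by an exclusion raster (biologically
#' irrelevant areas a user rules out). An exclusion that removes every
#' masked cell triggers a warning but proceeds.
#'
#' @param mask Boolean `sdm_raster`.
#' @param exclusion Boolean `sdm_raster` (or logical matrix) of areas to
#'   remove; `NULL` is the identity.
#' @return Boolean `sdm_raster`.
#' @export
apply_exclusions <- function(mask, exclusion = NULL) {
  if (is.null(exclusion)) return(mask)
  excl <- if (inherits(exclusion, "sdm_raster")) {
    exclusion$valid_mask & exclusion$values > 0
  } else exclusion
  stopifnot(all(dim(excl) == dim(mask$values)))
  before <- mask$values > 0 & mask$valid_mask
  after <- before & !excl
  removed <- sum(before) - sum(after)
  if (removed > 0)
    message(removed, " very-suitable cell(s) removed by exclusions")
  if (sum(before) > 0 && sum(after) == 0)
    warning("exclusion removed the entire mask")
  new_raster(mask$grid, after * 1, valid_mask = mask$valid_mask)
}

#' Area change between current and future very-suitable masks
#'
#' Sums spherical cell areas over the TRUE cells of each mask and reports
#' the signed difference in square kilometres and as a percentage of the
#' current area.
#'
#' @param current_mask,future_mask Boolean `sdm_raster`s on the same grid.
#' @param species,scenario_id,threshold Labels carried into the report.
#' @return An object of class `sdm_change`: `current_area_km2`,
#'   `future_area_km2`, `delta_km2`, `delta_pct` (NA with a flag when the
#'   current area is 0).
#' @export
suitability_change <- function(current_mask, future_mask,
                               species = "", scenario_id = "",
                               threshold = NA_real_) {
  if (!grids_identical(current_mask$grid, future_mask$grid))
    stop("masks must share a grid")
  cur <- mask_area_km2(current_mask)
  fut <- mask_area_km2(future_mask)
  delta <- fut - cur
  pct <- if (cur > 0) 100 * delta / cur else NA_real_
  structure(list(species = species, scenario_id = scenario_id,
                 threshold = threshold,
                 current_area_km2 = cur, future_area_km2 = fut,
                 delta_km2 = delta, delta_pct = pct,
                 undefined_pct = cur == 0),
            class = "sdm_change")
}

#' @export
print.sdm_change <- function(x, ...) {
  cat(sprintf(
    "sdm_change %s [%s]: %.0f -> %.0f km2 (delta %+.0f km2, %+.2f%%)\n",
    x$species, x$scenario_id, x$current_area_km2, x$future_area_km2,
    x$delta_km2, ifelse(is.na(x$delta_pct), NaN, x$delta_pct)))
  invisible(x)
}
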