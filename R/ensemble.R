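#' Run a pseudo-absence replicate ensemble
#'
#' For each replicate `r` (seeded with `seed + r`, giving an independent,
#' reproducible stream per replicate) a fresh pseudo-absence set is drawn
#' with the bias weights, a presence/absence table is built and a boosted
#' regression tree model is fitted. Replicate outputs are aggregated with
#' plain arithmetic means: suitability per cell, relative influence per
#' variable, and mean/sd summaries for AUC, deviance explained and tree
#' count. Degenerate replicates are skipped with a warning; more than 10%
#' failures aborts the run.
#'
#' @param presences An `sdm_presences` object.
#' @param bias An `sdm_bias` (or nonnegative `sdm_raster`).
#' @param stack An `sdm_stack`.
#' @param config A [brt_config()] (applied to every replicate).
#' @param region_mask Optional candidate-region mask for absence draws;
#'   defaults to the stack's shared validity mask.
#' @param n_replicates Number of pseudo-absence sets / models
#'   (default 100).
#' @param seed Master seed; replicate `r` uses `seed + r`.
#' @param aggregate_map If `FALSE`, skip the per-replicate suitability maps
#'   (summaries only), which is much faster when only influence and AUC
#'   are needed.
#' @return An object of class `sdm_ensemble`: `mean_suitability`
#'   (`sdm_raster` or `NULL`), `mean_influence`, `auc_mean`, `auc_sd`,
#'   `deviance_explained_mean`, `deviance_explained_sd`, `n_trees_mean`,
#'   `n_replicates` (completed), `records_used`, `records_raw`,
#'   `diagnostics` (per-replicate data frame), `models` (list of
#'   `brt_model`), `failed` (indices).
#' @export
run_ensemble <- function(presences, bias, stack, config = brt_config(),
                         region_mask = NULL, n_replicates = 100,
                         seed = 1, aggregate_map = TRUE) {
  stopifnot(n_replicates >= 1)
  if (inherits(bias, "sdm_raster")) bias <- bias_layer(bias)
  if (is.null(region_mask)) region_mask <- stack$shared_mask
  n_pres_in_mask <- sum(stack$shared_mask[presences$cells])
  if (n_pres_in_mask == 0) stop("no presence cells inside the covariate mask")

  models <- list()
  failed <- integer(0)
  sum_map <- NULL
  min_map <- NULL
  max_map <- NULL
  diag_rows <- list()

  for (r in seq_len(n_replicates)) {
    set.seed(seed + r)
    res <- tryCatch({
      absences <- sample_pseudo_absences(presences, bias, region_mask,
                                         n = n_pres_in_mask)
      tab <- build_table(presences, absences, stack, replicate_id = r)
      fit_brt(tab, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("replicate ", r, " failed: ", conditionMessage(res))
      failed <- c(failed, r)
      next
    }
    models[[length(models) + 1]] <- res
    diag_rows[[length(diag_rows) + 1]] <- data.frame(
      replicate = r, n_trees = res$n_trees, cv_deviance = res$cv_deviance,
      deviance_explained = res$deviance_explained, cv_auc = res$cv_auc)
    if (aggregate_map) {
      pmap <- predict_suitability(res, stack)$values
      if (is.null(sum_map)) {
        sum_map <- pmap
        min_map <- pmap
        max_map <- pmap
      } else {
        sum_map <- sum_map + pmap
        min_map <- pmin(min_map, pmap)
        max_map <- pmax(max_map, pmap)
      }
    }
  }

  if (length(failed) > 0.1 * n_replicates)
    stop("more than 10% of replicates failed (",
         length(failed), "/", n_replicates, ")")
  n_done <- length(models)
  diagnostics <- do.call(rbind, diag_rows)

  infl <- rowMeans(vapply(models, relative_influence,
                          numeric(length(models[[1]]$var_names))))
  mean_suit <- NULL
  min_suit <- NULL
  max_suit <- NULL
  if (aggregate_map) {
    mean_suit <- new_raster(stack$grid, sum_map / n_done,
                            valid_mask = stack$shared_mask)
    min_suit <- new_raster(stack$grid, min_map,
                           valid_mask = stack$shared_mask)
    max_suit <- new_raster(stack$grid, max_map,
                           valid_mask = stack$shared_mask)
  }
  one <- n_done == 1
  structure(list(
    species = presences$species,
    mean_suitability = mean_suit,
    min_suitability = min_suit,
    max_suitability = max_suit,
    mean_influence = infl,
    auc_mean = mean(diagnostics$cv_auc),
    auc_sd = if (one) NA_real_ else stats::sd(diagnostics$cv_auc),
    deviance_explained_mean = mean(diagnostics$deviance_explained),
    deviance_explained_sd = if (one) NA_real_ else
      stats::sd(diagnostics$deviance_explained),
    n_trees_mean = mean(diagnostics$n_trees),
    n_replicates = n_done,
    records_used = n_pres_in_mask,
    records_raw = presences$n_raw,
    config = config,
    seed = seed,
    diagnostics = diagnostics,
    models = models,
    failed = failed),
    class = "sdm_ensemble")
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf(
    "sdm_ensemble: %s, %d replicate(s), AUC %.3f +/- %.3f, %d presences\n",
    x$species, x$n_replicates, x$auc_mean,
    ifelse(is.na(x$auc_sd), 0, x$auc_sd), x$records_used))
  top <- names(which.max(x$mean_influence))
  cat(sprintf("  top influence: %s (%.1f%%)\n", top,
              max(x$mean_influence)))
  invisible(x)
}

#' Cross-species influence and performance table
#'
#' Lays out the ensemble summaries the way SDM studies tabulate them: one
#' column per species; rows are the covariates (mean relative influence,
#' %, summing to 100) followed by model descriptors (records used, mean
#' number of trees, deviance explained, AUC mean and sd). The most
#' influential variable per species is recorded in the
#' `"top_variable"` attribute.
#'
#' @param results Named list of `sdm_ensemble` objects (names = species).
#' @return Data frame with a `variable` column and one column per species.
#' @export
influence_table <- function(results) {
  stopifnot(length(results) >= 1)
  if (is.null(names(results)))
    names(results) <- vapply(results, function(r) r$species, "")
  vars <- names(results[[1]]$mean_influence)
  tab <- data.frame(variable = c(vars, "records used", "number of trees (mean)",
                                 "deviance explained", "mean AUC", "AUC s.d."),
                    stringsAsFactors = FALSE)
  for (nm in names(results)) {
    r <- results[[nm]]
    infl <- r$mean_influence[vars]
    tab[[nm]] <- c(unname(infl), r$records_used, r$n_trees_mean,
                   r$deviance_explained_mean, r$auc_mean, r$auc_sd)
  }
  attr(tab, "top_variable") <- vapply(
    results, function(r) names(which.max(r$mean_influence)), "")
  tab
}
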