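#' Construct a survey-effort bias layer
#'
#' Wraps a nonnegative continuous raster (for example a density surface of
#' insect collection records) used to weight pseudo-absence sampling toward
#' well-surveyed regions. `smoothing` is an additive constant applied to
#' every valid cell; with the default 0, zero-effort cells can never be
#' drawn as pseudo-absences.
#'
#' @param layer Continuous nonnegative `sdm_raster`.
#' @param smoothing Additive constant >= 0.
#' @return An object of class `sdm_bias`.
#' @export
bias_layer <- function(layer, smoothing = 0) {
  stopifnot(inherits(layer, "sdm_raster"), layer$kind == "continuous",
            smoothing >= 0)
  v <- layer$values[layer$valid_mask]
  if (any(v < 0)) stop("bias layer must be nonnegative")
  if (all(v + smoothing <= 0))
    stop("bias layer has no positive weight after smoothing")
  structure(list(layer = layer, smoothing = smoothing), class = "sdm_bias")
}

#' Draw bias-weighted pseudo-absence cells
#'
#' Samples `n` distinct cells, without replacement, from the candidate set
#' (cells of `region_mask` that are not presences) with probability
#' proportional to the bias weight (effort + smoothing). Draws consume the
#' R random number stream, so results are reproducible under `set.seed()`.
#'
#' @param presences An `sdm_presences` object.
#' @param bias An `sdm_bias` object (or a nonnegative `sdm_raster`, wrapped
#'   with smoothing 0).
#' @param region_mask Logical-valued `sdm_raster` (or logical matrix) whose
#'   TRUE cells delimit the candidate region, typically the covariate
#'   stack's shared validity mask.
#' @param n Number of cells to draw; defaults to the presence count, so the
#'   table has as many absences as presences.
#' @return Matrix of drawn cells with columns `row`, `col`.
#' @export
sample_pseudo_absences <- function(presences, bias, region_mask,
                                   n = nrow(presences$cells)) {
  if (n < 1) stop("n must be >= 1")
  if (inherits(bias, "sdm_raster")) bias <- bias_layer(bias)
  grid <- presences$grid
  region <- if (inherits(region_mask, "sdm_raster")) {
    region_mask$valid_mask & region_mask$values > 0
  } else region_mask
  stopifnot(all(dim(region) == c(grid$n_rows, grid$n_cols)))
  if (!grids_identical(grid, bias$layer$grid))
    stop("bias layer grid does not match the presence grid")

  cand <- region & bias$layer$valid_mask
  cand[presences$cells] <- FALSE
  w <- bias$layer$values + bias$smoothing
  w[!cand | !is.finite(w)] <- 0
  pos <- which(w > 0)
  if (length(pos) == 0) stop("all candidate weights are zero")
  if (length(pos) < n)
    stop("fewer than n candidate cells with positive weight")
  drawn <- pos[sample.int(length(pos), n, replace = FALSE, prob = w[pos])]
  cbind(row = (drawn - 1) %% grid$n_rows + 1,
        col = (drawn - 1) %/% grid$n_rows + 1)
}

#' Build a presence/absence model table
#'
#' One row per cell with a 0/1 label and the covariates in the stack's
#' recorded layer order. Cells falling outside the stack's shared validity
#' mask are excluded (complete-case rule) with a message. The biome layer
#' enters as a single integer-coded categorical column.
#'
#' @param presences An `sdm_presences` object.
#' @param absences Matrix of absence cells (`row`, `col`), disjoint from
#'   the presence cells.
#' @param stack An `sdm_stack`.
#' @param replicate_id Integer tag carried through to diagnostics.
#' @return An object of class `sdm_patable`: fields `label` (0/1 vector),
#'   `x` (covariate matrix), `cells`, `column_names`, `is_categorical`,
#'   `replicate_id`.
#' @export
build_table <- function(presences, absences, stack, replicate_id = 1L) {
  pres <- presences$cells
  abs_ <- as.matrix(absences)
  key_p <- paste(pres[, 1], pres[, 2])
  key_a <- paste(abs_[, 1], abs_[, 2])
  if (any(key_a %in% key_p))
    stop("absence cells must be disjoint from presence cells")
  keep_p <- stack$shared_mask[pres]
  keep_a <- stack$shared_mask[abs_]
  n_drop <- sum(!keep_p) + sum(!keep_a)
  if (n_drop > 0)
    message(n_drop, " cell(s) outside the covariate mask excluded")
  pres <- pres[keep_p, , drop = FALSE]
  abs_ <- abs_[keep_a, , drop = FALSE]
  if (nrow(pres) == 0 || nrow(abs_) == 0)
    stop("one class is empty after masking")
  cells <- rbind(pres, abs_)
  x <- stack_matrix(stack, cells)
  label <- c(rep(1, nrow(pres)), rep(0, nrow(abs_)))
  structure(list(label = label, x = x, cells = cells,
                 column_names = names(stack$layers),
                 is_categorical = vapply(stack$layers,
                                         function(l) l$kind == "categorical",
                                         logical(1)),
                 replicate_id = as.integer(replicate_id)),
            class = "sdm_patable")
}

#' @export
print.sdm_patable <- function(x, ...) {
  cat(sprintf("sdm_patable: %d presences + %d absences x %d covariates\n",
              sum(x$label == 1), sum(x$label == 0), ncol(x$x)))
  invisible(x)
}

#' Pairwise collinearity screen of continuous covariates
#'
#' Pearson correlations between all pairs of continuous layers over jointly
#' valid cells (optionally restricted to a region mask). Pairs with
#' `|r| > threshold` are flagged but nothing is dropped: screening is
#' report-only, since decision trees tolerate collinearity and the default
#' 0.7 bound is conventional.
#'
#' @param stack An `sdm_stack`.
#' @param region_mask Optional logical matrix or logical-valued
#'   `sdm_raster` restricting the cells used.
#' @param threshold Absolute-correlation flag bound (default 0.7).
#' @return An object of class `sdm_collinearity`: fields `correlations`
#'   (symmetric matrix, `NA` for constant layers), `flags` (data frame of
#'   flagged pairs), `threshold`.
#' @export
collinearity_screen <- function(stack, region_mask = NULL, threshold = 0.7) {
  cont <- names(stack$layers)[!vapply(stack$layers,
                                      function(l) l$kind == "categorical",
                                      logical(1))]
  if (length(cont) < 2) stop("need at least two continuous layers")
  keep <- stack$shared_mask
  if (!is.null(region_mask)) {
    region <- if (inherits(region_mask, "sdm_raster")) {
      region_mask$valid_mask & region_mask$values > 0
    } else region_mask
    keep <- keep & region
  }
  if (sum(keep) < 3) stop("need at least three jointly valid cells")
  m <- vapply(stack$layers[cont], function(l) l$values[keep],
              numeric(sum(keep)))
  const <- apply(m, 2, function(v) stats::sd(v) == 0)
  r <- suppressWarnings(stats::cor(m))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r) <- ifelse(const, NA_real_, 1)
  idx <- which(upper.tri(r) & !is.na(r) & abs(r) > threshold, arr.ind = TRUE)
  flags <- data.frame(var1 = cont[idx[, 1]], var2 = cont[idx[, 2]],
                      r = r[idx])
  structure(list(correlations = r, flags = flags, threshold = threshold,
                 constant = cont[const]),
            class = "sdm_collinearity")
}

#' @export
print.sdm_collinearity <- function(x, ...) {
  cat(sprintf("collinearity screen (|r| > %.2g): %d flagged pair(s)\n",
              x$threshold, nrow(x$flags)))
  if (nrow(x$flags) > 0) print(x$flags)
  invisible(x)
}
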