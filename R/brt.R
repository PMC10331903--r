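#' Boosted regression tree configuration
#'
#' Fitting parameters for the staged, cross-validated boosting procedure.
#' `tree_complexity` is the exact number of splits per tree (interaction
#' depth); `learning_rate` shrinks each tree's contribution; trees are
#' added `step_size` at a time and the number of trees is chosen by the
#' minimum of the mean cross-validated predictive deviance; fitting stops
#' once the deviance has not improved for `patience` consecutive stages or
#' `max_trees` is reached.
#'
#' @param tree_complexity Splits per tree (>= 1).
#' @param learning_rate Shrinkage in (0, 1).
#' @param bag_fraction Share of training rows subsampled per tree.
#' @param step_size Trees added per stage.
#' @param max_trees Hard cap on the number of trees.
#' @param cv_folds Number of cross-validation folds (>= 2), stratified by
#'   class.
#' @param patience Stages without improvement before stopping.
#' @param min_obs Minimum rows per tree node; 5 suits the desk-scale
#'   tables this package targets.
#' @return A list of class `brt_config`.
#' @export
brt_config <- function(tree_complexity = 3, learning_rate = 0.002,
                       bag_fraction = 0.75, step_size = 50,
                       max_trees = 10000, cv_folds = 10,
                       patience = 5, min_obs = 5) {
  stopifnot(tree_complexity >= 1, learning_rate > 0, learning_rate < 1,
            bag_fraction > 0, bag_fraction <= 1, step_size >= 1,
            max_trees >= step_size, cv_folds >= 2, patience >= 1,
            min_obs >= 1)
  structure(list(tree_complexity = as.integer(tree_complexity),
                 learning_rate = learning_rate,
                 bag_fraction = bag_fraction,
                 step_size = as.integer(step_size),
                 max_trees = as.integer(max_trees),
                 cv_folds = as.integer(cv_folds),
                 patience = as.integer(patience),
                 min_obs = as.integer(min_obs)),
            class = "brt_config")
}

# class-stratified fold assignment from the current RNG stream
stratified_folds <- function(label, k) {
  fold <- integer(length(label))
  for (cls in unique(label)) {
    idx <- sample(which(label == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# encode a model table for the C++ core: categorical columns become
# 0-based level indices; level tables are kept for prediction
encode_table <- function(x, is_categorical) {
  levels <- vector("list", ncol(x))
  names(levels) <- colnames(x)
  xm <- x
  for (j in which(is_categorical)) {
    lev <- sort(unique(x[, j]))
    if (length(lev) > 64)
      stop("categorical predictors are limited to 64 levels")
    levels[[j]] <- lev
    xm[, j] <- match(x[, j], lev) - 1
  }
  list(x = xm, levels = levels)
}

encode_newdata <- function(x, is_categorical, levels) {
  xm <- x
  unseen <- 0L
  for (j in which(is_categorical)) {
    code <- match(x[, j], levels[[j]]) - 1
    miss <- is.na(code) & is.finite(x[, j])
    if (any(miss)) {
      unseen <- unseen + sum(miss)
      code[miss] <- 9999  # out-of-range: trees route it to the majority branch
    }
    xm[, j] <- code
  }
  if (unseen > 0)
    message(unseen, " value(s) with categorical codes unseen in training ",
            "routed to the majority branch")
  xm
}

#' Fit a boosted regression tree model
#'
#' Forward-stagewise boosting of the Bernoulli log-likelihood. At each
#' stage every cross-validation fold adds `step_size` trees fitted to the
#' current gradient on a bagged subsample; the stage's mean held-out
#' deviance forms the CV curve, whose minimum fixes the number of trees.
#' A final model with that many trees is then refitted on all rows, and
#' the cross-validated AUC is computed from the out-of-fold predictions at
#' the selected stage. Fold assignment and bagging consume the R random
#' number stream: call `set.seed()` first for reproducible fits.
#'
#' @param table An `sdm_patable` from [build_table()].
#' @param config A [brt_config()].
#' @return An object of class `brt_model` with, among others, `n_trees`,
#'   `cv_curve`, `cv_deviance`, `null_deviance`, `deviance_explained`
#'   (1 - cv_deviance/null_deviance), `relative_influence` (percentages
#'   summing to 100) and `cv_auc`.
#' @export
fit_brt <- function(table, config = brt_config()) {
  stopifnot(inherits(table, "sdm_patable"), inherits(config, "brt_config"))
  label <- table$label
  n1 <- sum(label == 1); n0 <- sum(label == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  if (min(n1, n0) < config$cv_folds)
    stop("need at least cv_folds rows in each class")
  enc <- encode_table(table$x, table$is_categorical)
  ncat <- vapply(enc$levels, function(l) if (is.null(l)) 0L else length(l),
                 integer(1))
  fold <- stratified_folds(label, config$cv_folds)
  fit <- brt_fit_cpp(enc$x, as.integer(table$is_categorical), ncat,
                     as.numeric(label), as.integer(fold),
                     config$tree_complexity, config$learning_rate,
                     config$bag_fraction, config$step_size,
                     config$max_trees, config$patience, config$min_obs)
  if (isTRUE(fit$diverged))
    warning("cross-validated deviance diverged; learning rate may be too large")
  infl <- fit$split_improvement
  infl <- if (sum(infl) > 0) 100 * infl / sum(infl) else
    rep(0, length(infl))
  names(infl) <- table$column_names
  oof <- as.numeric(fit$oof_prob)
  structure(list(
    config = config,
    var_names = table$column_names,
    is_categorical = table$is_categorical,
    cat_levels = enc$levels,
    intercept = fit$intercept,
    trees = fit$trees,
    n_trees = fit$n_trees,
    cv_curve = as.numeric(fit$cv_curve),
    cv_deviance = fit$cv_deviance,
    null_deviance = fit$null_deviance,
    deviance_explained = 1 - fit$cv_deviance / fit$null_deviance,
    relative_influence = infl,
    cv_auc = auc(label, oof),
    oof_prob = oof,
    fitted = as.numeric(fit$fitted),
    label = label,
    replicate_id = table$replicate_id),
    class = "brt_model")
}

#' @export
print.brt_model <- function(x, ...) {
  cat(sprintf(
    "brt_model: %d trees (tc %d, lr %.4g), cv deviance %.4f, cv AUC %.3f\n",
    x$n_trees, x$config$tree_complexity, x$config$learning_rate,
    x$cv_deviance, x$cv_auc))
  invisible(x)
}

#' Predict suitability probabilities from a fitted model
#'
#' @param object A `brt_model`.
#' @param newdata Matrix or data frame with the model's covariate columns.
#' @param n_trees Number of leading trees to use; `NULL` (default) uses
#'   all. `0` gives the intercept-only prediction (the training
#'   prevalence, 0.5 with balanced classes).
#' @param ... Unused.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict.brt_model <- function(object, newdata, n_trees = NULL, ...) {
  x <- as.matrix(newdata[, object$var_names, drop = FALSE])
  storage.mode(x) <- "double"
  x <- encode_newdata(x, object$is_categorical, object$cat_levels)
  nt <- if (is.null(n_trees)) -1L else as.integer(n_trees)
  as.numeric(brt_predict_cpp(object$trees, object$intercept, x,
                             as.integer(object$is_categorical), nt))
}

#' Map suitability over a covariate stack
#'
#' Applies a fitted model to every valid cell of the stack; invalid cells
#' stay invalid.
#'
#' @param model A `brt_model`.
#' @param stack An `sdm_stack` containing every variable the model was
#'   trained on (same names and categorical coding).
#' @param n_trees Optional tree-count override, as in
#'   [predict.brt_model()].
#' @return Continuous `sdm_raster` of probabilities.
#' @export
predict_suitability <- function(model, stack, n_trees = NULL) {
  missing_vars <- setdiff(model$var_names, names(stack$layers))
  if (length(missing_vars) > 0)
    stop("stack is missing variable(s): ",
         paste(missing_vars, collapse = ", "))
  cells <- mask_cells(stack$shared_mask)
  x <- stack_matrix(stack, cells)
  p <- predict(model, x, n_trees = n_trees)
  vals <- matrix(NA_real_, stack$grid$n_rows, stack$grid$n_cols)
  vals[cells] <- p
  new_raster(stack$grid, vals, kind = "continuous",
             valid_mask = stack$shared_mask)
}

#' Relative influence of each predictor
#'
#' Per-variable sums of the squared-error improvements of every split that
#' uses the variable, across all trees of the final model, normalized to
#' percentages summing to 100. Variables never split on get 0.
#'
#' @param model A `brt_model`.
#' @return Named numeric vector of percentages.
#' @export
relative_influence <- function(model) model$relative_influence

#' Select tree complexity and learning rate on a deviance grid
#'
#' Fits a model for every combination of the candidate grids, then picks
#' the tree complexity with the lowest minimum cross-validated deviance
#' (ties resolved toward lower complexity) and, among the learning rates
#' for that complexity whose selected model used more than
#' `min_trees` trees, the largest such rate. If no rate clears
#' `min_trees`, the smallest rate is chosen and a message records the
#' deviation.
#'
#' @param table An `sdm_patable`.
#' @param tc_grid Candidate tree complexities (default 1..7).
#' @param lr_grid Candidate learning rates (default 0.001, 0.002, 0.003).
#' @param config Base [brt_config()] supplying the remaining parameters.
#' @param min_trees Tree-count floor a chosen rate must exceed
#'   (default 1000).
#' @return List with `tree_complexity`, `learning_rate`, and `trace`
#'   (a data frame of all fits).
#' @export
select_hyperparameters <- function(table, tc_grid = 1:7,
                                   lr_grid = c(0.001, 0.002, 0.003),
                                   config = brt_config(),
                                   min_trees = 1000) {
  stopifnot(length(tc_grid) > 0, length(lr_grid) > 0)
  tc_grid <- sort(unique(as.integer(tc_grid)))
  lr_grid <- sort(unique(lr_grid))
  trace <- expand.grid(tree_complexity = tc_grid, learning_rate = lr_grid,
                       KEEP.OUT.ATTRS = FALSE)
  trace$cv_deviance <- NA_real_
  trace$n_trees <- NA_integer_
  for (i in seq_len(nrow(trace))) {
    cfg <- config
    cfg$tree_complexity <- trace$tree_complexity[i]
    cfg$learning_rate <- trace$learning_rate[i]
    fit <- tryCatch(fit_brt(table, cfg), error = function(e) NULL)
    if (!is.null(fit)) {
      trace$cv_deviance[i] <- fit$cv_deviance
      trace$n_trees[i] <- fit$n_trees
    }
  }
  if (all(is.na(trace$cv_deviance))) stop("all candidate fits failed")
  best_by_tc <- vapply(tc_grid, function(tc) {
    suppressWarnings(min(trace$cv_deviance[trace$tree_complexity == tc],
                         na.rm = TRUE))
  }, numeric(1))
  tc <- tc_grid[which.min(best_by_tc)]  # first minimum: lower tc wins ties
  sub <- trace[trace$tree_complexity == tc & !is.na(trace$cv_deviance), ]
  deep <- sub[sub$n_trees > min_trees, ]
  if (nrow(deep) > 0) {
    lr <- max(deep$learning_rate)
  } else {
    lr <- min(sub$learning_rate)
    message("no learning rate produced more than ", min_trees,
            " trees; falling back to the smallest rate ", lr)
  }
  list(tree_complexity = tc, learning_rate = lr, trace = trace)
}

#' Mean Bernoulli deviance
#'
#' `-2 * mean(y*log(p) + (1-y)*log(1-p))`, with probabilities clipped to
#' `[1e-12, 1 - 1e-12]` for numerical safety.
#'
#' @param labels 0/1 vector.
#' @param probs Predicted probabilities, same length.
#' @return Mean deviance (scalar).
#' @export
bernoulli_deviance <- function(labels, probs) {
  if (length(labels) == 0) stop("empty input")
  if (length(labels) != length(probs)) stop("length mismatch")
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  -2 * mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Area under the ROC curve
#'
#' Mann-Whitney estimator: the fraction of (presence, absence) pairs in
#' which the presence outscores the absence, ties counting one half.
#'
#' @param labels 0/1 vector.
#' @param scores Numeric scores, same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  if (length(labels) != length(scores)) stop("length mismatch")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Serialize a fitted model to JSON
#'
#' Trees are stored as nested split records (variable, threshold or
#' category set, children, leaf value) in a version-stamped,
#' self-describing document readable by [brt_from_json()].
#'
#' @param model A `brt_model`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
brt_to_json <- function(model, path = NULL) {
  doc <- list(
    format = "macrosdm-brt",
    version = 1L,
    var_names = model$var_names,
    is_categorical = model$is_categorical,
    cat_levels = model$cat_levels,
    intercept = model$intercept,
    n_trees = model$n_trees,
    cv_curve = model$cv_curve,
    cv_deviance = model$cv_deviance,
    null_deviance = model$null_deviance,
    cv_auc = model$cv_auc,
    relative_influence = as.list(model$relative_influence),
    config = unclass(model$config),
    trees = lapply(model$trees, function(m) {
      lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
    }))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}

#' Restore a fitted model from JSON
#'
#' @param path File path or JSON string produced by [brt_to_json()].
#' @return A `brt_model` (prediction-complete; per-row training artefacts
#'   such as out-of-fold probabilities are not stored).
#' @export
brt_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$format, "macrosdm-brt"))
    stop("not a macrosdm BRT model document")
  node_names <- c("var", "thr", "mask", "seen", "defdir", "left", "right",
                  "value", "improve")
  trees <- lapply(doc$trees, function(tr) {
    m <- do.call(rbind, lapply(tr, function(nd) unlist(nd)[node_names]))
    m <- matrix(as.numeric(m), ncol = 9,
                dimnames = list(NULL, node_names))
    m
  })
  cfg <- doc$config
  structure(list(
    config = do.call(brt_config, cfg[names(formals(brt_config))]),
    var_names = unlist(doc$var_names),
    is_categorical = unlist(doc$is_categorical),
    cat_levels = lapply(doc$cat_levels, function(l)
      if (is.null(l)) NULL else unlist(l)),
    intercept = doc$intercept,
    trees = trees,
    n_trees = doc$n_trees,
    cv_curve = unlist(doc$cv_curve),
    cv_deviance = doc$cv_deviance,
    null_deviance = doc$null_deviance,
    deviance_explained = 1 - doc$cv_deviance / doc$null_deviance,
    relative_influence = unlist(doc$relative_influence),
    cv_auc = doc$cv_auc),
    class = "brt_model")
}
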