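# Stochastic gradient-boosted trees with logistic loss: R interface over
# the compiled core, plus up-sampling and cross-validated grid search.

#' Logistic loss and its negative gradient
#'
#' `logistic_loss(y, margin)` is `y ln(1 + e^-margin) +
#' (1 - y) ln(1 + e^margin)`, computed overflow-safe;
#' `loss_gradient(y, margin)` is the negative gradient `y - p` with
#' `p = plogis(margin)` -- the pseudo-residual each boosting iteration fits.
#'
#' @param y Binary outcomes in {0, 1}.
#' @param margin Real-valued margin (log-odds) predictions.
#' @return Numeric vector.
#' @export
logistic_loss <- function(y, margin) {
  z <- (2 * y - 1) * margin
  ifelse(z > 0, log1p(exp(-z)), -z + log1p(exp(z)))
}

#' @rdname logistic_loss
#' @export
loss_gradient <- function(y, margin) {
  y - stats::plogis(margin)
}

as_feature_matrix <- function(x) {
  if (is.matrix(x)) {
    X <- x
  } else {
    x <- as_tibble(x)
    X <- as.matrix(x[setdiff(names(x), ".id")])
  }
  storage.mode(X) <- "double"
  if (anyNA(X)) abort("Features must not contain missing values.")
  X
}

as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  if (!all(y %in% c(0, 1))) abort("`y` must be binary (0/1).")
  as.numeric(y)
}

#' Fit a single regression tree to pseudo-residuals
#'
#' Greedy least-squares splits over all features, candidate thresholds at
#' midpoints of consecutive distinct sorted values, ties broken toward the
#' lowest feature index then the lowest threshold. Leaf values are the
#' Newton step `sum(targets) / sum(weights)`; with unit weights that is the
#' leaf mean. Exposed mainly for inspection and testing; boosting calls the
#' same compiled routine internally.
#'
#' @param x Feature data frame or matrix.
#' @param targets Pseudo-residuals (numeric).
#' @param weights Per-row curvature terms `p (1 - p)`; defaults to 1.
#' @param depth Maximum splits along any root-to-leaf path.
#' @param min_leaf Minimum training rows per leaf.
#' @return Tibble of tree nodes (class `cb_tree`): `feature`, `threshold`,
#'   `left`, `right`, `value` (leaves have `feature = NA`).
#' @export
fit_tree <- function(x, targets, weights = NULL, depth = 2, min_leaf = 1) {
  X <- as_feature_matrix(x)
  if (is.null(weights)) weights <- rep(1, nrow(X))
  M <- fit_tree_cpp(X, as.numeric(targets), as.numeric(weights),
                    as.integer(depth), as.integer(min_leaf))
  nodes <- as_tibble(M)
  nodes$feature[nodes$feature < 0] <- NA
  nodes$left[nodes$left < 0] <- NA
  nodes$right[nodes$right < 0] <- NA
  class(nodes) <- c("cb_tree", class(nodes))
  nodes
}

#' Fit a stochastic gradient-boosted tree ensemble
#'
#' Boosting with logistic loss: the initial margin is the log-odds of the
#' training base rate; each iteration computes pseudo-residuals `y - p` on
#' all rows, fits a depth-limited regression tree on a without-replacement
#' subsample, sets leaf values by a single Newton step, and updates margins
#' by `shrinkage` times the tree prediction. With `n_trees = 0` the
#' ensemble predicts the base rate for every row.
#'
#' @param x Feature data frame (numeric columns; an `.id` column is
#'   ignored) or matrix.
#' @param y Binary labels (0/1, logical, or 2-level factor); both classes
#'   must be present.
#' @param n_trees Number of boosting iterations M.
#' @param depth Maximum splits along any root-to-leaf path.
#' @param min_leaf Minimum rows per leaf.
#' @param shrinkage Learning rate.
#' @param bag_fraction Without-replacement subsample fraction per iteration.
#' @param seed RNG seed (identical seed and data give a bit-identical
#'   ensemble).
#' @param validation Optional list `(x, y)` whose per-iteration mean loss is
#'   recorded in `val_loss`.
#' @param keep_trees Store the fitted trees and the training-loss trace
#'   (set `FALSE` when only the validation-loss trace is needed, as during
#'   cross-validation).
#' @return Object of class `careless_gbm`.
#' @export
gbm_fit <- function(x, y, n_trees = 250, depth = 2, min_leaf = 10,
                    shrinkage = 0.01, bag_fraction = 0.5, seed = 1,
                    validation = NULL, keep_trees = TRUE) {
  X <- as_feature_matrix(x)
  yb <- as_binary(y)
  if (length(unique(yb)) < 2) abort("`y` must contain both classes.")
  if (nrow(X) != length(yb)) abort("`x` and `y` sizes differ.")
  if (is.null(validation)) {
    Xv <- matrix(0, 0, ncol(X)); yv <- numeric(0)
  } else {
    Xv <- as_feature_matrix(validation$x)
    yv <- as_binary(validation$y)
  }
  fit <- if (n_trees == 0) {
    pbar <- min(1 - 1e-6, max(1e-6, mean(yb)))
    list(f0 = log(pbar / (1 - pbar)), trees = list(),
         train_loss = numeric(0), val_loss = numeric(0))
  } else {
    fit_gbm_cpp(X, yb, as.integer(n_trees), as.integer(depth),
                as.integer(min_leaf), shrinkage, bag_fraction,
                as.integer(seed), Xv, yv, keep_trees)
  }
  structure(
    list(f0 = fit$f0, trees = fit$trees, shrinkage = shrinkage,
         n_trees = if (keep_trees) length(fit$trees) else n_trees,
         depth = depth, min_leaf = min_leaf,
         bag_fraction = bag_fraction, seed = seed,
         n_features = ncol(X), feature_names = colnames(X),
         train_loss = as.numeric(fit$train_loss),
         val_loss = as.numeric(fit$val_loss)),
    class = "careless_gbm"
  )
}

#' @export
print.careless_gbm <- function(x, ...) {
  cat("<careless_gbm> ", x$n_trees, " trees, depth ", x$depth,
      ", min leaf ", x$min_leaf, ", shrinkage ", x$shrinkage,
      ", bag ", x$bag_fraction, "\n", sep = "")
  if (x$n_trees > 0) {
    cat("  final training loss: ",
        format(x$train_loss[x$n_trees], digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' Predict from a boosted ensemble
#'
#' The margin is `F0 + shrinkage * sum of tree outputs`; probabilities go
#' through the logistic link; classes are thresholded at `p >= 0.5`.
#'
#' @param object A `careless_gbm`.
#' @param newdata Feature data frame or matrix with the same columns as the
#'   training features.
#' @param type `"prob"`, `"margin"`, or `"class"`.
#' @param n_trees Use only the first `n_trees` trees (default all).
#' @param ... Unused.
#' @return Numeric (prob/margin) or integer 0/1 (class) vector.
#' @export
predict.careless_gbm <- function(object, newdata, type = c("prob", "margin",
                                                           "class"),
                                 n_trees = NULL, ...) {
  type <- match.arg(type)
  X <- as_feature_matrix(newdata)
  if (ncol(X) != object$n_features) {
    abort(sprintf("Expected %d features, got %d.",
                  object$n_features, ncol(X)))
  }
  if (is.null(n_trees)) n_trees <- object$n_trees
  margin <- predict_gbm_cpp(object$f0, object$trees, object$shrinkage, X,
                            as.integer(n_trees))
  switch(type,
         margin = margin,
         prob = stats::plogis(margin),
         class = as.integer(stats::plogis(margin) >= 0.5))
}

#' @export
tidy.careless_gbm <- function(x, ...) {
  tibble(
    tree = seq_len(x$n_trees),
    n_nodes = vapply(x$trees, nrow, integer(1)),
    n_leaves = vapply(x$trees, function(m) sum(m[, "feature"] < 0),
                      numeric(1)),
    train_loss = x$train_loss
  )
}

#' @export
glance.careless_gbm <- function(x, ...) {
  tibble(n_trees = x$n_trees, depth = x$depth, min_leaf = x$min_leaf,
         shrinkage = x$shrinkage, bag_fraction = x$bag_fraction,
         f0 = x$f0,
         final_train_loss = if (x$n_trees > 0) x$train_loss[x$n_trees]
         else NA_real_)
}

#' @export
autoplot.careless_gbm <- function(object, ...) {
  df <- tibble(iteration = seq_len(object$n_trees),
               training = object$train_loss)
  if (length(object$val_loss) > 0) df$validation <- object$val_loss
  df <- tidyr::pivot_longer(df, -"iteration", names_to = "set",
                            values_to = "loss")
  ggplot(df, aes(x = .data$iteration, y = .data$loss,
                 colour = .data$set)) +
    geom_line() +
    labs(x = "Boosting iteration", y = "Mean logistic loss",
         colour = NULL) +
    theme_minimal()
}

#' Up-sample the minority class
#'
#' Replicates minority-class rows (sampling with replacement) until both
#' classes match the majority count. Majority rows are untouched; provenance
#' indices into the original data are returned so leakage checks can assert
#' that no replicated row escapes its training fold. Balanced input is
#' returned unchanged.
#'
#' @param x Feature data frame or matrix.
#' @param y Binary labels.
#' @param seed RNG seed.
#' @return List with `x`, `y`, and `provenance` (original row index of every
#'   output row).
#' @export
upsample <- function(x, y, seed = 1) {
  X <- as_feature_matrix(x)
  yb <- as_binary(y)
  if (length(unique(yb)) < 2) abort("`y` must contain both classes.")
  n1 <- sum(yb == 1); n0 <- sum(yb == 0)
  if (n1 == n0) {
    return(list(x = X, y = yb, provenance = seq_along(yb)))
  }
  minority <- if (n1 < n0) 1 else 0
  idx_min <- which(yb == minority)
  extra <- with_seed(seed, sample(idx_min, abs(n0 - n1), replace = TRUE))
  keep <- c(seq_along(yb), extra)
  list(x = X[keep, , drop = FALSE], y = yb[keep], provenance = keep)
}

#' Hyperparameter grids
#'
#' `full_grid()` is the complete benchmark grid: interaction depth 2-4,
#' minimum leaf size 4-10, shrinkage .001 to .03 in steps of .002, and 250
#' to 800 trees in steps of 50. `reduced_grid()` is the desk-scale default
#' used by the replication harness: depth {2, 3}, leaf {5, 10}, shrinkage
#' {.005, .015, .03}, trees {250, 500}.
#'
#' @return Tibble with columns `depth`, `min_leaf`, `shrinkage`, `n_trees`.
#' @export
full_grid <- function() {
  tidyr::expand_grid(depth = 2:4, min_leaf = 4:10,
                     shrinkage = seq(0.001, 0.03, by = 0.002),
                     n_trees = seq(250L, 800L, by = 50L))
}

#' @rdname full_grid
#' @export
reduced_grid <- function() {
  tidyr::expand_grid(depth = c(2L, 3L), min_leaf = c(5L, 10L),
                     shrinkage = c(0.005, 0.015, 0.03),
                     n_trees = c(250L, 500L))
}

stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Cross-validated grid search
#'
#' Stratified k-fold cross-validation over a hyperparameter grid. The
#' minority class is up-sampled inside each training fold only (validation
#' folds stay untouched), the selection metric is the mean validation
#' logistic loss, and ties are broken toward fewer trees, then shallower
#' depth, then larger leaves. Grid cells differing only in `n_trees` share
#' one fit: the validation loss is read off the boosting trace.
#'
#' @param x Feature data frame or matrix.
#' @param y Binary labels.
#' @param grid Hyperparameter tibble (see [reduced_grid()]).
#' @param folds Number of CV folds.
#' @param bag_fraction Subsample fraction passed to [gbm_fit()].
#' @param seed RNG seed.
#' @return List of class `cb_grid_search`: `best` (one-row tibble),
#'   `cv_table` (mean validation loss per cell), `fold_id` assignment, and
#'   `provenance` (per fold, the original row index of every row -- replicas
#'   included -- the fold's models trained on; never intersects the fold's
#'   validation rows).
#' @export
grid_search_cv <- function(x, y, grid = reduced_grid(), folds = 10,
                           bag_fraction = 0.5, seed = 1) {
  if (nrow(grid) == 0) abort("Empty hyperparameter grid.")
  X <- as_feature_matrix(x)
  yb <- as_binary(y)
  if (length(yb) < folds) abort("Fewer rows than folds.")
  seeds <- derive_seeds(seed, folds * 2 + 1)
  fold_id <- stratified_folds(yb, folds, seeds[1])
  combos <- dplyr::distinct(grid[c("depth", "min_leaf", "shrinkage")])
  m_values <- sort(unique(grid$n_trees))
  m_max <- max(m_values)

  loss_acc <- matrix(0, nrow(combos), length(m_values))
  provenance <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- which(fold_id != f)
    va <- which(fold_id == f)
    up <- upsample(X[tr, , drop = FALSE], yb[tr], seed = seeds[1 + f])
    provenance[[f]] <- tr[up$provenance]  # rows (incl. replicas) trained on
    for (ci in seq_len(nrow(combos))) {
      fit <- gbm_fit(up$x, up$y, n_trees = m_max,
                     depth = combos$depth[ci],
                     min_leaf = combos$min_leaf[ci],
                     shrinkage = combos$shrinkage[ci],
                     bag_fraction = bag_fraction,
                     seed = seeds[1 + folds + f],
                     validation = list(x = X[va, , drop = FALSE],
                                       y = yb[va]),
                     keep_trees = FALSE)
      loss_acc[ci, ] <- loss_acc[ci, ] + fit$val_loss[m_values]
    }
  }
  cv_table <- tidyr::expand_grid(combo = seq_len(nrow(combos)),
                                 n_trees = m_values)
  cv_table <- bind_cols(combos[cv_table$combo, ],
                        tibble(n_trees = cv_table$n_trees,
                               mean_loss = as.vector(t(loss_acc)) / folds))
  # keep only cells present in the requested grid
  cv_table <- dplyr::semi_join(cv_table, grid,
                               by = c("depth", "min_leaf", "shrinkage",
                                      "n_trees"))
  best <- cv_table %>%
    arrange(.data$mean_loss, .data$n_trees, .data$depth,
            dplyr::desc(.data$min_leaf)) %>%
    slice(1)
  structure(list(best = best, cv_table = cv_table, fold_id = fold_id,
                 provenance = provenance, seed = seed),
            class = "cb_grid_search")
}

#' @export
print.cb_grid_search <- function(x, ...) {
  cat("<cb_grid_search> ", nrow(x$cv_table), " grid cells, ",
      max(x$fold_id), "-fold CV\n", sep = "")
  cat("  best: depth ", x$best$depth, ", min leaf ", x$best$min_leaf,
      ", shrinkage ", x$best$shrinkage, ", ", x$best$n_trees,
      " trees (loss ", format(x$best$mean_loss, digits = 4), ")\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.cb_grid_search <- function(x, ...) x$cv_table

#' Train the classifier as in the benchmark pipeline
#'
#' Up-samples the full training set, runs [grid_search_cv()] (up-sampling
#' again inside each fold on the raw training rows), and fits the final
#' ensemble at the selected hyperparameters on the up-sampled training set.
#'
#' @param x Training features.
#' @param y Training labels.
#' @param grid Hyperparameter grid.
#' @param folds CV folds.
#' @param bag_fraction Subsample fraction.
#' @param seed RNG seed.
#' @return A `careless_gbm` with the grid-search result attached as
#'   attribute `"search"`.
#' @export
gbm_train <- function(x, y, grid = reduced_grid(), folds = 10,
                      bag_fraction = 0.5, seed = 1) {
  seeds <- derive_seeds(seed, 3)
  search <- grid_search_cv(x, y, grid = grid, folds = folds,
                           bag_fraction = bag_fraction, seed = seeds[1])
  up <- upsample(x, y, seed = seeds[2])
  fit <- gbm_fit(up$x, up$y, n_trees = search$best$n_trees,
                 depth = search$best$depth,
                 min_leaf = search$best$min_leaf,
                 shrinkage = search$best$shrinkage,
                 bag_fraction = bag_fraction, seed = seeds[3])
  attr(fit, "search") <- search
  fit
}
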