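# From-scratch stochastic gradient boosting: losses, trees, ensembles,
# up-sampling, and cross-validated grid search.

test_that("logistic loss matches closed forms and its gradient matches finite differences", {
  expect_equal(logistic_loss(1, 0), log(2))
  expect_equal(logistic_loss(0, 0), log(2))
  expect_lt(logistic_loss(1, 20), 1e-8)
  expect_lt(logistic_loss(0, -20), 1e-8)
  # no overflow at extreme margins
  expect_equal(logistic_loss(1, -800), 800)

  eps <- 1e-6
  for (y in c(0, 1)) {
    for (m in seq(-4, 4, by = 0.5)) {
      fd <- -(logistic_loss(y, m + eps) - logistic_loss(y, m - eps)) /
        (2 * eps)
      expect_equal(loss_gradient(y, m), fd, tolerance = 1e-6)
    }
  }
})

test_that("tree root splits equal an exhaustive-search oracle on 12-row toys", {
  set.seed(51)
  for (rep in 1:25) {
    X <- matrix(sample.int(5, 12 * 2, TRUE), 12, 2)
    g <- round(rnorm(12), 3)
    tree <- fit_tree(X, g, depth = 1, min_leaf = 2)
    oracle <- oracle_best_split(X, g, 2)
    if (is.na(oracle$feature)) {
      expect_true(is.na(tree$feature[1]))
    } else {
      expect_equal(tree$feature[1], oracle$feature)
      expect_equal(tree$threshold[1], oracle$threshold)
    }
  }
})

test_that("constant targets give a single leaf holding the Newton value", {
  X <- matrix(sample.int(5, 20, TRUE), 10, 2)
  tree <- fit_tree(X, rep(0.3, 10), weights = rep(0.5, 10))
  expect_equal(nrow(tree), 1)
  expect_true(is.na(tree$feature[1]))
  expect_equal(tree$value[1], sum(rep(0.3, 10)) / sum(rep(0.5, 10)))
})

test_that("every split strictly reduces training SSE relative to its parent", {
  set.seed(52)
  X <- matrix(sample.int(5, 200 * 6, TRUE), 200, 6)
  g <- rnorm(200) + X[, 1] * 0.5
  tree <- fit_tree(X, g, depth = 3, min_leaf = 5)
  # walk the tree, checking the least-squares criterion at every split
  sse <- function(v) sum((v - mean(v))^2)
  check_node <- function(node, rows) {
    if (is.na(tree$feature[node])) return(invisible())
    L <- rows[X[rows, tree$feature[node]] <= tree$threshold[node]]
    R <- setdiff(rows, L)
    expect_lt(sse(g[L]) + sse(g[R]), sse(g[rows]))
    check_node(tree$left[node], L)
    check_node(tree$right[node], R)
  }
  check_node(1, seq_len(200))
})

test_that("an empty ensemble predicts the base rate and a separable toy is learned", {
  set.seed(53)
  y <- rep(c(0, 1), c(30, 10))
  X <- matrix(rnorm(40 * 3), 40, 3)
  f0 <- gbm_fit(X, y, n_trees = 0)
  expect_equal(unique(predict(f0, X, type = "prob")), 0.25)

  Xs <- cbind(y, matrix(rnorm(40 * 2), 40, 2))
  fs <- gbm_fit(Xs, y, n_trees = 50, depth = 2, shrinkage = 0.1,
                bag_fraction = 1, min_leaf = 1, seed = 2)
  expect_equal(predict(fs, Xs, type = "class"), y)
})

test_that("training loss is non-increasing without subsampling at small shrinkage", {
  spec <- hexaco_spec()
  ds <- assemble_condition(study_config(style = "midpoint"), spec, seed = 54)
  fit <- gbm_fit(ds$responses, ds$labels$careless, n_trees = 200,
                 depth = 2, shrinkage = 0.01, bag_fraction = 1, seed = 3)
  expect_true(all(diff(fit$train_loss) <= 1e-12))
})

test_that("prediction unrolls to F0 plus shrunken tree sums and ignores row order", {
  set.seed(55)
  X <- matrix(sample.int(5, 30 * 4, TRUE), 30, 4)
  y <- rbinom(30, 1, 0.4)
  fit <- gbm_fit(X, y, n_trees = 2, depth = 2, shrinkage = 0.1,
                 bag_fraction = 1, min_leaf = 2, seed = 4)
  route <- function(tree, x) {
    node <- 1
    while (tree[node, "feature"] > 0) {
      node <- if (x[tree[node, "feature"]] <= tree[node, "threshold"]) {
        tree[node, "left"]
      } else {
        tree[node, "right"]
      }
    }
    tree[node, "value"]
  }
  manual <- fit$f0 + 0.1 * (apply(X, 1, route, tree = fit$trees[[1]]) +
                              apply(X, 1, route, tree = fit$trees[[2]]))
  expect_equal(predict(fit, X, type = "margin"), manual)

  p <- predict(fit, X, type = "prob")
  expect_true(all(p > 0 & p < 1))
  perm <- sample(30)
  expect_equal(predict(fit, X[perm, ], type = "prob"), p[perm])
  expect_error(predict(fit, X[, 1:3]), "features")
})

test_that("identical seeds give bit-identical ensembles", {
  set.seed(56)
  X <- matrix(sample.int(5, 100 * 5, TRUE), 100, 5)
  y <- rbinom(100, 1, 0.3)
  f1 <- gbm_fit(X, y, n_trees = 30, seed = 11)
  f2 <- gbm_fit(X, y, n_trees = 30, seed = 11)
  expect_identical(f1$trees, f2$trees)
  f3 <- gbm_fit(X, y, n_trees = 30, seed = 12)
  expect_false(identical(f1$trees, f3$trees))
})

test_that("up-sampling balances classes, keeps the majority intact, and is reproducible", {
  set.seed(57)
  X <- matrix(rnorm(180 * 3), 180, 3)
  y <- rep(c(0, 1), c(162, 18))
  up <- upsample(X, y, seed = 5)
  expect_equal(length(up$y), 324)
  expect_equal(sum(up$y == 0), 162)
  expect_equal(sum(up$y == 1), 162)
  expect_identical(up$x[1:180, ], X)  # originals untouched, replicas appended
  expect_true(all(up$provenance[181:324] %in% which(y == 1)))
  up2 <- upsample(X, y, seed = 5)
  expect_identical(up$provenance, up2$provenance)
  # balanced input passes through unchanged
  yb <- rep(c(0, 1), each = 90)
  expect_equal(upsample(X, yb, seed = 6)$x, X)
})

test_that("grid search partitions rows, respects the stated grids, and avoids leakage", {
  expect_equal(sort(unique(full_grid()$depth)), 2:4)
  expect_equal(sort(unique(full_grid()$min_leaf)), 4:10)
  expect_equal(sort(unique(full_grid()$shrinkage)), seq(0.001, 0.03, 0.002))
  expect_equal(sort(unique(full_grid()$n_trees)), seq(250L, 800L, 50L))
  expect_equal(nrow(full_grid()), 3 * 7 * 15 * 12)
  expect_equal(nrow(reduced_grid()), 2 * 2 * 3 * 2)

  set.seed(58)
  X <- matrix(sample.int(5, 120 * 4, TRUE), 120, 4)
  y <- rep(c(0, 1), c(100, 20))
  grid <- tidyr::expand_grid(depth = 2L, min_leaf = c(2L, 5L),
                             shrinkage = 0.05, n_trees = c(20L, 40L))
  gs <- grid_search_cv(X, y, grid = grid, folds = 5, seed = 7)
  # every row lands in exactly one validation fold
  expect_equal(sort(unique(gs$fold_id)), 1:5)
  expect_equal(length(gs$fold_id), 120)
  # stratification keeps both classes in each fold
  for (f in 1:5) expect_true(all(c(0, 1) %in% y[gs$fold_id == f]))
  expect_equal(nrow(gs$cv_table), nrow(grid))
  # no trained row (original or up-sampled replica) sits in its own
  # validation fold
  for (f in 1:5) {
    expect_length(intersect(gs$provenance[[f]], which(gs$fold_id == f)), 0)
    # up-sampling happened: both classes balanced inside the fold training
    expect_equal(sum(y[gs$provenance[[f]]] == 0),
                 sum(y[gs$provenance[[f]]] == 1))
  }
  expect_error(grid_search_cv(X, y, grid = grid[0, ]), "Empty")
})

test_that("grid search prefers the shrinkage that actually fits the signal", {
  # strong clean signal: tiny shrinkage at few trees underfits badly
  set.seed(59)
  n <- 150
  y <- rbinom(n, 1, 0.5)
  X <- cbind(y * 2 + rnorm(n, sd = 0.3),
             matrix(sample.int(5, n * 2, TRUE), n, 2))
  grid <- tidyr::expand_grid(depth = 2L, min_leaf = 5L,
                             shrinkage = c(0.001, 0.1), n_trees = 100L)
  gs <- grid_search_cv(X, y, grid = grid, folds = 5, seed = 8)
  expect_equal(gs$best$shrinkage, 0.1)
})

test_that("held-out accuracy tracks an established boosting implementation", {
  skip_if_not_installed("xgboost")
  set.seed(60)
  gaps <- vapply(1:5, function(case) {
    n <- 200
    X <- matrix(rnorm(n * 5), n, 5)
    eta <- 1.2 * X[, 1] - 0.8 * X[, 2] + 0.6 * X[, 3] * (case %% 2)
    y <- rbinom(n, 1, plogis(eta))
    tr <- 1:140; te <- 141:200
    fit <- gbm_fit(X[tr, ], y[tr], n_trees = 150, depth = 2, min_leaf = 5,
                   shrinkage = 0.1, bag_fraction = 0.8, seed = case)
    mine <- confusion_metrics(predict(fit, X[te, ], type = "class"),
                              y[te])$balanced_accuracy
    dm <- xgboost::xgb.DMatrix(X[tr, ], label = y[tr])
    ref <- xgboost::xgb.train(
      params = list(max_depth = 2, eta = 0.1, subsample = 0.8,
                    min_child_weight = 0, lambda = 0,
                    objective = "binary:logistic", nthread = 1),
      data = dm, nrounds = 150)
    pref <- as.integer(predict(ref, xgboost::xgb.DMatrix(X[te, ])) >= 0.5)
    theirs <- confusion_metrics(pref, y[te])$balanced_accuracy
    abs(mine - theirs)
  }, numeric(1))
  # split criteria differ in detail (least-squares on gradients here,
  # second-order gain there), so agreement is asserted on average across
  # the problems with a looser per-problem cap
  expect_lt(mean(gaps), 0.05)
  expect_lt(max(gaps), 0.10)
})
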