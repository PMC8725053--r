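# End-to-end replication harness: constrained train/test splits,
# response-time preprocessing, confusion metrics, and the simulation /
# empirical-emulation experiment loops.

#' Class-constrained train/test split
#'
#' Draws a test sample of (at most) `round(test_fraction * n)` respondents
#' whose regular:careless ratio is exactly `test_ratio`:1, shrinking the
#' test size to the nearest size admitting the exact ratio; everything else
#' becomes the training set. With n = 605 (361 regular, 244 careless),
#' 30% test and a 9:1 ratio this gives the canonical (162, 18) test and
#' (199, 226) training split.
#'
#' @param labels 0/1 careless labels (vector, or tibble with `careless`
#'   column).
#' @param test_fraction Target fraction of respondents in the test sample.
#' @param test_ratio Regular-to-careless ratio in the test sample.
#' @param seed RNG seed.
#' @return List with integer index vectors `test` and `train`.
#' @export
constrained_split <- function(labels, test_fraction = 0.30, test_ratio = 9,
                              seed = 1) {
  y <- if (is.data.frame(labels)) labels$careless else as_binary(labels)
  n <- length(y)
  n_reg <- sum(y == 0); n_car <- sum(y == 1)
  unit <- test_ratio + 1
  size <- (round(test_fraction * n) %/% unit) * unit
  feasible <- function(s) {
    s / unit <= n_car && test_ratio * s / unit <= n_reg
  }
  while (size > 0 && !feasible(size)) size <- size - unit
  if (size <= 0) {
    abort(sprintf(
      "Cannot form a %d:1 test sample: %d regular and %d careless respondents available.",
      test_ratio, n_reg, n_car))
  }
  k_car <- size %/% unit
  k_reg <- test_ratio * k_car
  test <- with_seed(seed, {
    c(sample(which(y == 0), k_reg), sample(which(y == 1), k_car))
  })
  list(test = sort(test), train = setdiff(seq_len(n), test))
}

#' Winsorize response times at a per-item percentile
#'
#' Replaces values above each item's `pct`-th percentile with that
#' percentile; the lower tail is untouched.
#'
#' @param data Wide response-time tibble (`.id` + item columns) or matrix.
#' @param pct Upper percentile (default 95).
#' @return Same shape as `data`.
#' @export
winsorize_rt <- function(data, pct = 95) {
  is_df <- is.data.frame(data)
  X <- if (is_df) {
    as.matrix(as_tibble(data)[setdiff(names(data), ".id")])
  } else {
    data
  }
  caps <- apply(X, 2, quantile, probs = pct / 100, names = FALSE)
  X <- pmin(X, matrix(caps, nrow(X), ncol(X), byrow = TRUE))
  if (is_df) {
    out <- as_tibble(X, .name_repair = "minimal")
    bind_cols(tibble(.id = data$.id), out)
  } else {
    X
  }
}

#' Aggregate response times into page parcels
#'
#' Sums consecutive blocks of `parcel_size` items (the survey page layout)
#' per respondent. Means are sums divided by a constant, so either choice is
#' equivalent for tree-based learners; sums are returned.
#'
#' @param data Wide response-time tibble or matrix.
#' @param parcel_size Items per parcel; must divide the item count.
#' @return Tibble `.id` + `parcel_1..parcel_P` (or matrix for matrix input).
#' @export
parcel_rt <- function(data, parcel_size = 10) {
  is_df <- is.data.frame(data)
  X <- if (is_df) {
    as.matrix(as_tibble(data)[setdiff(names(data), ".id")])
  } else {
    data
  }
  J <- ncol(X)
  if (parcel_size < 1 || J %% parcel_size != 0) {
    abort("`parcel_size` must be positive and divide the item count.")
  }
  P <- J %/% parcel_size
  parc <- vapply(seq_len(P), function(p) {
    rowSums(X[, ((p - 1) * parcel_size + 1):(p * parcel_size),
              drop = FALSE])
  }, numeric(nrow(X)))
  parc <- matrix(parc, nrow = nrow(X),
                 dimnames = list(NULL, paste0("parcel_", seq_len(P))))
  if (is_df) {
    bind_cols(tibble(.id = data$.id),
              as_tibble(parc, .name_repair = "minimal"))
  } else {
    parc
  }
}

#' Confusion metrics for one flagging rule
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(FP+TN)`, precision
#' `TP/(TP+FP)` (`NA` when nothing is flagged), accuracy, and balanced
#' accuracy (the mean of sensitivity and specificity). Careless is the
#' positive class.
#'
#' @param flags Logical/0-1 predicted-careless flags.
#' @param labels 0/1 true careless labels.
#' @return One-row tibble of counts and the five metrics.
#' @export
confusion_metrics <- function(flags, labels) {
  f <- as.integer(flags)
  y <- as_binary(labels)
  if (length(f) != length(y)) abort("`flags` and `labels` lengths differ.")
  if (length(unique(y)) < 2) abort("`labels` must contain both classes.")
  tp <- sum(f == 1 & y == 1); fp <- sum(f == 1 & y == 0)
  tn <- sum(f == 0 & y == 0); fn <- sum(f == 0 & y == 1)
  sens <- tp / (tp + fn)
  spec <- tn / (fp + tn)
  tibble(tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sens, specificity = spec,
         precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
         accuracy = (tp + tn) / length(y),
         balanced_accuracy = (sens + spec) / 2)
}

default_rules <- function(design, config) {
  list(
    mahalanobis = flag_rule("chisq", alpha = config$mahalanobis_alpha,
                            df = design$n_items),
    antonyms = flag_rule("absolute", cutoff = config$antonym_cutoff,
                         direction = ">"),
    evenodd = flag_rule("absolute", cutoff = config$evenodd_cutoff,
                        direction = "<"),
    longstring = flag_rule("absolute", cutoff = config$longstring_cutoff,
                           direction = ">="),
    irv = flag_rule("two_sided_percentile",
                    percentiles = config$irv_percentiles),
    zh = flag_rule("absolute", cutoff = config$zh_cutoff, direction = "<")
  )
}

score_one_method <- function(method, test_resp, design, config) {
  switch(method,
    mahalanobis = mahalanobis_scores(test_resp, design),
    antonyms = antonym_scores(test_resp, design),
    evenodd = evenodd_scores(test_resp, design),
    longstring = longstring_scores(test_resp, design),
    irv = irv_scores(test_resp, design),
    # EAP/Zh flags stabilize long before full parameter convergence, so
    # the benchmark loop runs the EM on a coarser grid with a cycle cap;
    # convergence warnings are expected on contaminated samples
    zh = suppressWarnings(
      zh_scores(test_resp, design, n_quad = 21, max_cycles = 150)),
    abort(sprintf("Unknown method '%s'.", method)))
}

evaluate_indices <- function(test_resp, test_labels, design, config,
                             methods) {
  rules <- default_rules(design, config)
  bind_rows(lapply(methods, function(m) {
    sc <- score_one_method(m, test_resp, design, config)
    fl <- apply_flag_rule(sc, rules[[m]], labels = test_labels)
    cm <- confusion_metrics(fl$flag, test_labels)
    bind_cols(tibble(method = m), cm)
  }))
}

aggregate_replicates <- function(reps, config) {
  long <- bind_rows(reps, .id = "replicate")
  agg <- long %>%
    tidyr::pivot_longer(c("sensitivity", "specificity", "precision",
                          "accuracy", "balanced_accuracy"),
                        names_to = "metric", values_to = "value") %>%
    group_by(.data$method, .data$metric) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE), .groups = "drop")
  structure(agg, class = c("replication_table", class(agg)),
            replicates = long, config = config,
            n_replications = length(reps))
}

#' @export
print.replication_table <- function(x, ...) {
  cat("<replication_table> ", attr(x, "n_replications"),
      " replications\n", sep = "")
  wide <- x %>%
    mutate(cell = sprintf("%.2f (%.2f)", .data$mean, .data$sd)) %>%
    select("method", "metric", "cell") %>%
    tidyr::pivot_wider(names_from = "method", values_from = "cell")
  print(as.data.frame(wide), row.names = FALSE)
  invisible(x)
}

#' @export
autoplot.replication_table <- function(object, ...) {
  ggplot(object, aes(x = .data$method, y = .data$mean)) +
    geom_col(fill = "grey35") +
    geom_errorbar(aes(ymin = pmax(.data$mean - .data$sd, 0),
                      ymax = pmin(.data$mean + .data$sd, 1)),
                  width = 0.2) +
    facet_wrap(~ .data$metric) +
    labs(x = NULL, y = "Mean across replications") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Run the simulation benchmark
#'
#' Per replication: generate a training sample (`config$n_train`) and a test
#' sample (`config$n_total`) at the configured prevalence and careless
#' style; score the traditional indices (and Zh) on the test sample; train
#' the boosted-tree classifier on the training sample (up-sampled, grid
#' search with stratified 10-fold CV) and classify the test sample; compute
#' confusion metrics per method. Results are aggregated as means and SDs
#' across replications.
#'
#' @param config A [study_config()].
#' @param spec An [ordinal_spec()]; built from defaults (seeded by
#'   `config$seed`) when `NULL`.
#' @param methods Index methods to evaluate.
#' @param include_gbm Train and evaluate the boosted-tree classifier.
#' @param grid Hyperparameter grid for the classifier.
#' @param max_failures Abort when more than this fraction of replications
#'   errors.
#' @return A `replication_table` tibble (method x metric, mean and SD) with
#'   per-replicate values in attribute `"replicates"` and a run log in
#'   attribute `"log"`.
#' @export
run_simulation_study <- function(config = study_config(), spec = NULL,
                                 methods = c("mahalanobis", "antonyms",
                                             "evenodd", "longstring",
                                             "irv", "zh"),
                                 include_gbm = TRUE, grid = reduced_grid(),
                                 max_failures = 0.05) {
  if (is.null(spec)) {
    spec <- ordinal_spec(scale_design(), seed = config$seed)
  }
  design <- spec$design
  R <- config$replications
  seeds <- derive_seeds(config$seed, 2 * R)
  reps <- vector("list", R)
  log <- vector("list", R)
  for (r in seq_len(R)) {
    res <- tryCatch({
      test <- assemble_condition(config, spec, seed = seeds[r])
      out <- evaluate_indices(test$responses, test$labels$careless, design,
                              config, methods)
      gbm_pars <- NULL
      if (include_gbm) {
        train <- assemble_condition(config, spec, seed = seeds[R + r],
                                    n = config$n_train)
        fit <- gbm_train(train$responses, train$labels$careless,
                         grid = grid, folds = config$folds,
                         seed = seeds[R + r])
        gbm_pars <- attr(fit, "search")$best
        pred <- predict(fit, test$responses, type = "class")
        out <- bind_rows(out, bind_cols(
          tibble(method = "gbm"),
          confusion_metrics(pred, test$labels$careless)))
      }
      list(metrics = out,
           log = list(replicate = r, seed = seeds[r], ok = TRUE,
                      gbm = gbm_pars))
    }, error = function(e) {
      list(metrics = NULL,
           log = list(replicate = r, seed = seeds[r], ok = FALSE,
                      error = conditionMessage(e)))
    })
    reps[[r]] <- res$metrics
    log[[r]] <- res$log
  }
  failed <- sum(vapply(log, function(l) !l$ok, logical(1)))
  if (failed > max_failures * R) {
    abort(sprintf("%d of %d replications failed; first error: %s",
                  failed, R,
                  log[[which(!vapply(log, `[[`, logical(1), "ok"))[1]]]$error))
  }
  out <- aggregate_replicates(reps[!vapply(reps, is.null, logical(1))],
                              config)
  attr(out, "log") <- log
  out
}

#' Build a synthetic empirical-style dataset
#'
#' A stand-in for an instructed-careless web study: `n_regular` copula
#' regulars and `n_careless` careless respondents whose styles mix the three
#' generators in equal shares, plus log-normal item response times. Entirely
#' synthetic; used by [run_empirical_emulation()] when no real dataset is
#' supplied.
#'
#' @param spec An [ordinal_spec()].
#' @param n_regular,n_careless Group sizes (defaults mirror a 605-respondent
#'   two-arm design).
#' @param rt An [rt_params()]; identical condition parameters give the
#'   no-signal response-time control.
#' @param seed RNG seed.
#' @return A `labeled_dataset` with an `rt` element.
#' @export
synthesize_empirical <- function(spec, n_regular = 361, n_careless = 244,
                                 rt = rt_params(), seed = 1) {
  design <- spec$design
  seeds <- derive_seeds(seed, 6)
  reg <- sample_regular(n_regular, spec, seed = seeds[1])
  n_each <- diff(round(seq(0, n_careless, length.out = 4)))
  car <- rbind(
    response_matrix(sample_random_careless(n_each[1], design,
                                           seed = seeds[2]), design),
    response_matrix(sample_midpoint_careless(n_each[2], design,
                                             seed = seeds[3]), design),
    response_matrix(sample_pattern_careless(n_each[3], design,
                                            seed = seeds[4]), design))
  style <- c(rep(NA_character_, n_regular),
             rep(c("random", "midpoint", "pattern"), n_each))
  X <- rbind(response_matrix(reg, design), car)
  careless <- c(rep(0L, n_regular), rep(1L, n_careless))
  n <- nrow(X)
  ord <- with_seed(seeds[5], sample.int(n))
  X <- X[ord, , drop = FALSE]
  careless <- careless[ord]
  style <- style[ord]
  ids <- paste0("r", formatC(seq_len(n), width = nchar(n), flag = "0"))
  labels <- tibble(.id = ids, careless = careless, style = style)
  structure(
    list(responses = responses_as_tibble(X, design, ids = ids),
         labels = labels,
         rt = sample_response_times(labels, design, rt, seed = seeds[6])),
    class = "labeled_dataset"
  )
}

#' Run the empirical-emulation benchmark
#'
#' Mirrors the design of an instructed-careless web study on synthetic (or
#' user-supplied) data: repeated class-constrained 9:1 splits; traditional
#' indices evaluated on each test sample; boosted-tree classifiers trained
#' on responses only (`gbm_res`), winsorized page-parcel response times only
#' (`gbm_rt`), and both (`gbm_res_rt`).
#'
#' @param config A [study_config()]; `replications` controls the number of
#'   splits.
#' @param dataset A `labeled_dataset` with response times; synthesized via
#'   [synthesize_empirical()] when `NULL`.
#' @param spec Ordinal spec used when synthesizing.
#' @param methods Traditional index methods to evaluate.
#' @param grid Classifier hyperparameter grid.
#' @param gbm_feature_sets Subset of `c("gbm_res", "gbm_rt", "gbm_res_rt")`.
#' @return A `replication_table`.
#' @export
run_empirical_emulation <- function(config = study_config(), dataset = NULL,
                                    spec = NULL,
                                    methods = c("mahalanobis", "antonyms",
                                                "evenodd", "longstring",
                                                "irv", "zh"),
                                    grid = reduced_grid(),
                                    gbm_feature_sets = c("gbm_res",
                                                         "gbm_rt",
                                                         "gbm_res_rt")) {
  if (is.null(dataset)) {
    if (is.null(spec)) {
      spec <- ordinal_spec(scale_design(), seed = config$seed)
    }
    dataset <- synthesize_empirical(spec, seed = config$seed)
    design <- spec$design
  } else {
    design <- if (!is.null(spec)) spec$design else scale_design(
      n_items = ncol(dataset$responses) - 1)
  }
  if (is.null(dataset$rt)) {
    abort("The empirical emulation needs response times in `dataset$rt`.")
  }
  X_resp <- response_matrix(dataset$responses, design)
  y_all <- dataset$labels$careless
  rt_w <- winsorize_rt(dataset$rt)
  rt_parc <- parcel_rt(rt_w, parcel_size = design$page_size)
  X_rt <- as.matrix(as_tibble(rt_parc)[setdiff(names(rt_parc), ".id")])
  feature_sets <- list(gbm_res = X_resp, gbm_rt = X_rt,
                       gbm_res_rt = cbind(X_resp, X_rt))

  R <- config$replications
  seeds <- derive_seeds(config$seed, 2 * R)
  reps <- vector("list", R)
  for (r in seq_len(R)) {
    sp <- constrained_split(y_all, config$test_fraction, config$test_ratio,
                            seed = seeds[r])
    test_resp <- X_resp[sp$test, , drop = FALSE]
    y_test <- y_all[sp$test]
    out <- evaluate_indices(test_resp, y_test, design, config, methods)
    for (fs in gbm_feature_sets) {
      Xf <- feature_sets[[fs]]
      fit <- gbm_train(Xf[sp$train, , drop = FALSE], y_all[sp$train],
                       grid = grid, folds = config$folds,
                       seed = seeds[R + r])
      pred <- predict(fit, Xf[sp$test, , drop = FALSE], type = "class")
      out <- bind_rows(out, bind_cols(tibble(method = fs),
                                      confusion_metrics(pred, y_test)))
    }
    reps[[r]] <- out
  }
  aggregate_replicates(reps, config)
}
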