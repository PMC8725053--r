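# Shared fixtures. The calibrated 60-item generator is expensive to build,
# so it is constructed once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

hexaco_design <- function() scale_design()

hexaco_spec <- function() {
  if (is.null(fixture_env$spec)) {
    fixture_env$spec <- ordinal_spec(hexaco_design(), seed = 1)
  }
  fixture_env$spec
}

tiny_design <- function() {
  scale_design(n_items = 12, n_categories = 5,
               constructs = rep(1:2, each = 6),
               reversed = rep(c(FALSE, TRUE), 6), page_size = 6)
}

# draw one ordinal response matrix from given GRM item parameters
draw_grm_sample <- function(a, b, theta) {
  n <- length(theta)
  J <- length(a)
  X <- matrix(0L, n, J)
  for (j in seq_len(J)) {
    P <- grm_category_probs(a[j], b[j, ], theta)
    u <- runif(n)
    X[, j] <- 1L + rowSums(u > t(apply(P, 1, cumsum)))
  }
  X
}

# known GRM item parameter set for one 10-item construct
known_grm_params <- function(seed = 3, J = 10) {
  set.seed(seed)
  list(a = runif(J, 0.8, 2),
       b = t(vapply(seq_len(J), function(j) sort(runif(4, -2, 2)),
                    numeric(4))))
}

# cb_grm object from known parameters (no fitting)
grm_from_params <- function(p, item_ids = NULL, n_quad = 41) {
  structure(
    list(a = p$a, b = p$b, loglik = NA_real_, converged = TRUE,
         n_cycles = 0L, quad = carelessboost:::gauss_hermite_normal(n_quad),
         n_categories = ncol(p$b) + 1L, item_ids = item_ids),
    class = "cb_grm"
  )
}

# exact distribution of the maximum identical-response run for iid uniform
# categorical draws: probability that the longest run is < run_len
prob_max_run_below <- function(n_items, n_cat, run_len) {
  s <- numeric(run_len - 1)
  s[1] <- 1
  for (t in seq_len(n_items - 1)) {
    s_new <- numeric(run_len - 1)
    s_new[1] <- sum(s) * (n_cat - 1) / n_cat
    if (run_len > 2) s_new[2:(run_len - 1)] <- s[1:(run_len - 2)] / n_cat
    s <- s_new
  }
  sum(s)
}

# exhaustive-search oracle over every feature and midpoint threshold for a
# single least-squares split
oracle_best_split <- function(X, g, min_leaf) {
  best <- list(sse = sum((g - mean(g))^2) - 1e-10, feature = NA,
               threshold = NA)
  for (f in seq_len(ncol(X))) {
    vals <- sort(unique(X[, f]))
    if (length(vals) < 2) next
    for (thr in head(vals, -1) + diff(vals) / 2) {
      L <- X[, f] <= thr
      if (sum(L) < min_leaf || sum(!L) < min_leaf) next
      sse <- sum((g[L] - mean(g[L]))^2) + sum((g[!L] - mean(g[!L]))^2)
      if (sse < best$sse - 1e-12) {
        best <- list(sse = sse, feature = f, threshold = thr)
      }
    }
  }
  best
}
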