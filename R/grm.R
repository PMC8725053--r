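# Graded response model (GRM) estimation and the polytomous Zh person-fit
# statistic.
#
# The multidimensional structure is between-item: one unidimensional GRM per
# construct with independent standard-normal traits, EAP trait estimates per
# construct, and Zh aggregated over all items at each item's own construct
# estimate. Estimation is marginal maximum likelihood via EM on a fixed
# Gauss-Hermite grid; the M-step takes a few quasi-Newton steps per item
# (a generalized EM), which keeps every cycle cheap while the observed-data
# log-likelihood still ascends.

#' GRM category probabilities
#'
#' Cumulative-logit graded model: `P*(k) = plogis(a * (theta - b[k-1]))` for
#' boundaries `k = 2..K` with `P*(1) = 1`, `P*(K+1) = 0`; the probability of
#' category k is `P*(k) - P*(k+1)`.
#'
#' @param a Discrimination (> 0 for an informative item; 0 gives a flat
#'   item).
#' @param b Strictly increasing thresholds, length K-1.
#' @param theta Vector of latent trait values.
#' @return `length(theta) x K` matrix of category probabilities (rows sum to
#'   1).
#' @export
grm_category_probs <- function(a, b, theta) {
  if (length(b) > 1 && any(diff(b) <= 0)) {
    abort("Thresholds `b` must be strictly increasing.")
  }
  K <- length(b) + 1
  Pstar <- cbind(1, stats::plogis(outer(theta, b, function(t, bb) a * (t - bb))), 0)
  P <- Pstar[, 1:K, drop = FALSE] - Pstar[, 2:(K + 1), drop = FALSE]
  pmax(P, 0)
}

# --- M-step objective (expected complete-data log-lik) per item ------------
# parametrization: par = (log a, b1, log diff_2, ..., log diff_{K-1})
par_to_ab <- function(par) {
  a <- exp(par[1])
  K1 <- length(par) - 1
  b <- cumsum(c(par[2], if (K1 > 1) exp(par[3:(K1 + 1)])))
  list(a = a, b = b)
}

ab_to_par <- function(a, b) {
  c(log(a), b[1], if (length(b) > 1) log(diff(b)))
}

# Shared objective/gradient factory for one item's M-step.  optim() calls
# fn and gr separately with the same parameters; the factory caches the
# category-probability computation between the two calls.
make_mstep <- function(theta) {
  last_par <- NULL
  thb <- NULL; Pb <- NULL; P <- NULL; ab <- NULL
  refresh <- function(par) {
    if (!identical(par, last_par)) {
      ab <<- par_to_ab(par)
      thb <<- outer(theta, ab$b, "-")
      Pb <<- 1 / (1 + exp(-ab$a * thb))
      K <- length(ab$b) + 1
      Pfull <- cbind(1, Pb) - cbind(Pb, 0)
      Pfull[Pfull < 1e-10] <- 1e-10
      P <<- Pfull
      last_par <<- par
    }
  }
  fn <- function(par, r) {
    refresh(par)
    -sum(r * log(P))
  }
  gr <- function(par, r) {
    refresh(par)
    K <- length(ab$b) + 1
    W <- Pb * (1 - Pb)
    Tm <- r[, 2:K, drop = FALSE] / P[, 2:K, drop = FALSE] -
      r[, 1:(K - 1), drop = FALSE] / P[, 1:(K - 1), drop = FALSE]
    TW <- Tm * W
    d_b <- colSums(TW) * (-ab$a)
    g <- c(sum(TW * thb) * ab$a, sum(d_b))
    K1 <- K - 1
    if (K1 > 1) {
      rev_cum <- rev(cumsum(rev(d_b)))
      g <- c(g, rev_cum[2:K1] * exp(par[3:(K1 + 1)]))
    }
    -g
  }
  list(fn = fn, gr = gr)
}

collapse_map <- function(x, K) {
  # merge unobserved categories with their neighbor toward the modal category
  obs <- tabulate(x, nbins = K)
  map <- seq_len(K)
  if (all(obs > 0)) return(list(map = map, K2 = K, merged = FALSE))
  mode_k <- which.max(obs)
  for (k in seq_len(K)) {
    if (obs[k] == 0) {
      map[k] <- if (k < mode_k) k + 1 else k - 1
    }
  }
  # resolve chains (e.g. two empty neighbors)
  for (it in seq_len(K)) map <- map[map]
  lev <- sort(unique(map))
  list(map = match(map, lev), K2 = length(lev), merged = TRUE, levels = lev)
}

#' Fit a graded response model to one construct
#'
#' Marginal maximum likelihood with a standard-normal latent prior on a
#' fixed Gauss-Hermite grid. Each EM cycle recomputes posterior weights and
#' takes a handful of BFGS steps per item on the expected complete-data
#' log-likelihood (generalized EM). Convergence is declared when the largest
#' absolute parameter change falls below `tol`. Categories unobserved for an
#' item are merged with their neighbor toward the mode during estimation and
#' the threshold grid is expanded back on output.
#'
#' @param data Wide responses for the items of one construct (`.id` + item
#'   columns), or a matrix.
#' @param n_categories Number of response categories K.
#' @param n_quad Number of quadrature nodes (default 41).
#' @param max_cycles Maximum EM cycles.
#' @param tol Convergence tolerance on the parameter change.
#' @param mstep_it Quasi-Newton iterations per item per cycle.
#' @param stall_tol Secondary stop: the EM also halts when the observed-data
#'   log-likelihood improves by less than this for three consecutive cycles
#'   (guards against slow parameter drift on a flat likelihood).
#' @return List of class `cb_grm`: `a` (discriminations), `b` (J x (K-1)
#'   threshold matrix), `loglik` (observed-data log-likelihood trace),
#'   `converged`, `n_cycles`, `quad`.
#' @export
fit_grm <- function(data, n_categories = 5, n_quad = 41, max_cycles = 500,
                    tol = 1e-4, mstep_it = 3, stall_tol = 1e-6) {
  X <- if (is.matrix(data)) data else {
    as.matrix(as_tibble(data)[setdiff(names(data), ".id")])
  }
  storage.mode(X) <- "integer"
  n <- nrow(X); J <- ncol(X); K <- as.integer(n_categories)
  if (J < 2) abort("A construct needs at least two items.")
  quad <- gauss_hermite_normal(n_quad)
  th <- quad$nodes
  logw <- log(quad$weights)

  maps <- lapply(seq_len(J), function(j) collapse_map(X[, j], K))
  Xc <- X
  for (j in seq_len(J)) Xc[, j] <- maps[[j]]$map[X[, j]]
  Kj <- vapply(maps, function(m) m$K2, integer(1))
  if (any(Kj < 2)) {
    abort("An item has fewer than two observed categories after collapsing.")
  }

  # starts: a = 1, b from observed cumulative proportions
  pars <- lapply(seq_len(J), function(j) {
    p_gt <- 1 - cumsum(tabulate(Xc[, j], Kj[j]) / n)[-Kj[j]]
    p_gt <- pmin(pmax(p_gt, 1e-3), 1 - 1e-3)
    b <- -stats::qlogis(p_gt)
    b <- sort(b)
    if (any(diff(b) < 1e-3)) b <- b + seq_along(b) * 1e-3
    ab_to_par(1, b)
  })

  loglik <- numeric(0)
  converged <- FALSE
  stalled <- 0L
  ind <- lapply(seq_len(J), function(j) {
    outer(Xc[, j], seq_len(Kj[j]), "==") * 1
  })
  mstep <- make_mstep(th)

  delta <- Inf
  for (cycle in seq_len(max_cycles)) {
    # E-step
    Lnq <- matrix(0, n, n_quad)
    for (j in seq_len(J)) {
      ab <- par_to_ab(pars[[j]])
      P <- pmax(grm_category_probs(ab$a, ab$b, th), 1e-10)  # Q x Kj
      Lnq <- Lnq + log(t(P)[Xc[, j], , drop = FALSE])
    }
    Lnq_w <- sweep(Lnq, 2, logw, "+")
    lse <- logsumexp_rows(Lnq_w)
    ll <- sum(lse)
    loglik <- c(loglik, ll)
    post <- exp(Lnq_w - lse)

    # M-step (few quasi-Newton steps per item; generalized EM)
    old <- pars
    for (j in seq_len(J)) {
      r <- crossprod(post, ind[[j]])  # Q x Kj expected counts
      opt <- optim(pars[[j]], mstep$fn, mstep$gr, r = r,
                   method = "BFGS",
                   control = list(maxit = mstep_it, reltol = 1e-12))
      pars[[j]] <- opt$par
    }
    delta <- max(abs(unlist(pars) - unlist(old)))
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (cycle > 1 &&
        loglik[cycle] - loglik[cycle - 1] < stall_tol) {
      stalled <- stalled + 1L
      if (stalled >= 3L) {
        converged <- TRUE
        break
      }
    } else {
      stalled <- 0L
    }
  }
  if (!converged) {
    warn(sprintf("GRM EM did not reach tol %.0e in %d cycles (last change %.2e); returning best iterate.",
                 tol, max_cycles, delta))
  }

  a <- numeric(J)
  b <- matrix(NA_real_, J, K - 1)
  for (j in seq_len(J)) {
    ab <- par_to_ab(pars[[j]])
    a[j] <- ab$a
    if (Kj[j] == K) {
      b[j, ] <- ab$b
    } else {
      # expand collapsed thresholds: boundaries interior to a merged block
      # reuse the neighbor's threshold, nudged to keep strict ordering
      map <- maps[[j]]$map
      bfull <- numeric(K - 1)
      for (m in seq_len(K - 1)) {
        if (map[m + 1] > map[m]) {
          bfull[m] <- ab$b[map[m]]
        } else {
          bfull[m] <- if (map[m] > 1) ab$b[map[m] - 1] else ab$b[1] - 1
        }
      }
      bfull <- bfull + cumsum(c(0, diff(bfull) <= 0)) * 1e-3
      b[j, ] <- sort(bfull) + seq_len(K - 1) * 1e-6
    }
  }
  structure(
    list(a = a, b = b, loglik = loglik, converged = converged,
         n_cycles = length(loglik), quad = quad, n_categories = K,
         item_ids = colnames(X)),
    class = "cb_grm"
  )
}

#' @export
print.cb_grm <- function(x, ...) {
  cat("<cb_grm> ", length(x$a), " items, K = ", x$n_categories,
      ", logLik ", round(max(x$loglik), 2), " after ", x$n_cycles,
      " EM cycles", if (!x$converged) " (not converged)", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.cb_grm <- function(x, ...) {
  tb <- tibble(item = x$item_ids %||% paste0("item", seq_along(x$a)),
               a = x$a)
  bind_cols(tb, as_tibble(x$b, .name_repair = ~ paste0("b", seq_along(.x))))
}

#' @export
glance.cb_grm <- function(x, ...) {
  tibble(logLik = max(x$loglik), n_cycles = x$n_cycles,
         converged = x$converged, n_items = length(x$a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' EAP trait estimates
#'
#' Expected-a-posteriori trait estimates under the standard-normal prior on
#' the fitted quadrature grid. With no items the prior mean 0 is returned.
#'
#' @param fit A [fit_grm()] object.
#' @param data Responses for the same items (tibble or matrix).
#' @return Numeric vector of trait estimates, one per respondent.
#' @export
estimate_theta <- function(fit, data) {
  X <- if (is.matrix(data)) data else {
    as.matrix(as_tibble(data)[setdiff(names(data), ".id")])
  }
  storage.mode(X) <- "integer"
  n <- nrow(X)
  if (ncol(X) == 0) return(rep(0, n))
  th <- fit$quad$nodes
  logw <- log(fit$quad$weights)
  Lnq <- matrix(0, n, length(th))
  for (j in seq_len(ncol(X))) {
    P <- pmax(grm_category_probs(fit$a[j], fit$b[j, ], th), 1e-10)
    Lnq <- Lnq + log(t(P)[X[, j], , drop = FALSE])
  }
  Lnq_w <- sweep(Lnq, 2, logw, "+")
  post <- exp(Lnq_w - logsumexp_rows(Lnq_w))
  as.numeric(post %*% th)
}

#' Zh person-fit statistic
#'
#' Standardized log-likelihood of each respondent's pattern at the estimated
#' trait values: `l` is the observed pattern log-likelihood, `E[l]` and
#' `V[l]` its model-implied mean and variance at the same trait values, and
#' `Zh = (l - E[l]) / sqrt(V[l])`, summed over all items with each item
#' evaluated at its own construct's trait estimate. Strongly negative values
#' signal misfit (carelessness).
#'
#' @param fits Named list of [fit_grm()] objects, one per construct.
#' @param thetas Matrix (n x n_constructs) of trait estimates, columns in
#'   the same order as `fits`.
#' @param data Wide responses for all items (`.id` + item columns or
#'   matrix).
#' @param design The [scale_design()] mapping items to constructs.
#' @return A tibble with `.id`, `loglik`, `expected`, `variance`, `zh`.
#' @export
zh_statistic <- function(fits, thetas, data, design) {
  X <- response_matrix(data, design)
  validate_responses(X, design)
  n <- nrow(X)
  ctors <- unique(design$constructs)
  l <- E <- V <- numeric(n)
  for (c_i in seq_along(ctors)) {
    fit <- fits[[c_i]]
    items <- which(design$constructs == ctors[c_i])
    th_i <- thetas[, c_i]
    for (jj in seq_along(items)) {
      P <- pmax(grm_category_probs(fit$a[jj], fit$b[jj, ], th_i), 1e-12)
      logP <- log(P)
      xi <- X[, items[jj]]
      l <- l + logP[cbind(seq_len(n), xi)]
      Ej <- rowSums(P * logP)
      E <- E + Ej
      V <- V + rowSums(P * logP^2) - Ej^2
    }
  }
  if (all(V <= 1e-6)) abort("All items are flat; Zh is undefined.")
  tibble(.id = rownames(X) %||% paste0("r", seq_len(n)),
         loglik = l, expected = E, variance = V,
         zh = (l - E) / sqrt(V))
}

#' Zh index scores for a full sample
#'
#' Fits a GRM per construct (on `calibration` data, by default the analysis
#' sample itself), computes per-construct EAP trait estimates, and returns
#' Zh as an `index_scores` tibble (orientation "low").
#'
#' @param data Wide responses (`.id` + item columns).
#' @param design A [scale_design()].
#' @param calibration Optional separate calibration sample (same layout).
#' @param fits Optional pre-fitted list from [fit_grm_all()] to reuse.
#' @param ... Passed to [fit_grm()].
#' @return An `index_scores` tibble with attribute `"fits"`.
#' @export
zh_scores <- function(data, design, calibration = NULL, fits = NULL, ...) {
  X <- response_matrix(data, design)
  validate_responses(X, design)
  if (is.null(fits)) {
    calib <- if (is.null(calibration)) X else {
      response_matrix(calibration, design)
    }
    fits <- fit_grm_all(calib, design, ...)
  }
  ctors <- unique(design$constructs)
  thetas <- vapply(seq_along(ctors), function(c_i) {
    items <- which(design$constructs == ctors[c_i])
    estimate_theta(fits[[c_i]], X[, items, drop = FALSE])
  }, numeric(nrow(X)))
  zh <- zh_statistic(fits, thetas, X, design)
  out <- index_scores(zh$.id, "zh", zh$zh, "low")
  attr(out, "fits") <- fits
  attr(out, "thetas") <- thetas
  out
}

#' Fit one GRM per construct
#'
#' @param data Wide responses for all items.
#' @param design A [scale_design()].
#' @param ... Passed to [fit_grm()].
#' @return Named list of `cb_grm` fits, one per construct.
#' @export
fit_grm_all <- function(data, design, ...) {
  X <- response_matrix(data, design)
  ctors <- unique(design$constructs)
  fits <- lapply(ctors, function(cc) {
    items <- which(design$constructs == cc)
    fit_grm(X[, items, drop = FALSE], n_categories = design$n_categories,
            ...)
  })
  names(fits) <- as.character(ctors)
  fits
}

#' Export / import fitted GRM parameters as JSON
#'
#' Allows a calibration fitted on one sample to score another.
#'
#' @param fits Named list of `cb_grm` fits (from [fit_grm_all()]).
#' @param path JSON path.
#' @return `grm_to_json`: the path, invisibly. `grm_from_json`: the list of
#'   fits (quadrature restored at `n_quad` nodes).
#' @export
grm_to_json <- function(fits, path) {
  payload <- lapply(fits, function(f) {
    list(a = f$a, b = f$b, n_categories = f$n_categories,
         item_ids = f$item_ids, n_quad = length(f$quad$nodes))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname grm_to_json
#' @export
grm_from_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(payload, function(p) {
    structure(
      list(a = p$a, b = matrix(p$b, nrow = length(p$a)),
           loglik = NA_real_, converged = NA, n_cycles = NA_integer_,
           quad = gauss_hermite_normal(p$n_quad %||% 41),
           n_categories = p$n_categories, item_ids = p$item_ids),
      class = "cb_grm"
    )
  })
}
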