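# Target correlation surrogate and Gaussian-copula calibration.
#
# Regular responders are simulated by discretizing a latent multivariate
# normal at per-item threshold grids. The latent correlation for each item
# pair is calibrated by monotone root finding so that the implied ordinal
# (Pearson) correlation of the discretized pair matches a target. The
# bivariate normal CDF uses the Drezner-Wesolowsky single-integral identity
# evaluated with fixed Gauss-Legendre nodes.

# vectorized standard bivariate normal CDF P(X <= h, Y <= k; rho)
bvn_cdf <- function(h, k, rho, n_nodes = 24) {
  n <- max(length(h), length(k), length(rho))
  h <- rep_len(h, n); k <- rep_len(k, n); rho <- rep_len(rho, n)
  rho <- pmin(pmax(rho, -0.9999), 0.9999)
  base <- pnorm(h) * pnorm(k)
  gl <- gauss_legendre(n_nodes, 0, 1)
  asr <- asin(rho)
  acc <- numeric(n)
  hk <- h * k
  hh <- h^2 + k^2
  for (g in seq_len(n_nodes)) {
    t <- asr * gl$nodes[g]
    st <- sin(t)
    ct2 <- cos(t)^2
    acc <- acc + gl$weights[g] * exp(-(hh - 2 * hk * st) / (2 * ct2))
  }
  base + asr * acc / (2 * pi)
}

# population Pearson correlation of two discretized items given latent rho.
# Uses Cov(X, Y) = sum_{k,l < K} [P(X<=k, Y<=l) - F1(k) F2(l)] for
# integer-valued categories. th1/th2: threshold vectors (length K-1);
# cum1/cum2: cumulative marginal probabilities at those thresholds;
# sd1/sd2: marginal category SDs. Vectorized over rho (one pair).
ordinal_corr_one <- function(rho, th1, th2, cum1, cum2, sd1, sd2) {
  grid <- expand.grid(a = seq_along(th1), b = seq_along(th2))
  nr <- length(rho)
  H <- rep(th1[grid$a], each = nr)
  K <- rep(th2[grid$b], each = nr)
  C <- bvn_cdf(H, K, rep.int(rho, nrow(grid)))
  FF <- rep(cum1[grid$a] * cum2[grid$b], each = nr)
  cov <- rowSums(matrix(C - FF, nrow = nr))
  cov / (sd1 * sd2)
}

marginal_moments <- function(p) {
  k <- seq_along(p)
  mu <- sum(k * p)
  list(mean = mu, sd = sqrt(sum((k - mu)^2 * p)))
}

#' Calibrate latent-normal correlations for an ordinal target
#'
#' For every item pair, finds the latent bivariate-normal correlation whose
#' implied ordinal Pearson correlation (computed from bivariate-normal
#' rectangle probabilities over the items' threshold grids) matches the
#' requested target within `tol`. The calibrated matrix is repaired to
#' positive definiteness by eigenvalue clipping; the repair-induced maximum
#' absolute drift is attached as attribute `"repair_drift"`.
#'
#' @param target_corr J x J target ordinal correlation matrix.
#' @param marginals J x K matrix of per-item category probabilities (rows sum
#'   to 1).
#' @param tol Per-pair calibration tolerance on the implied ordinal
#'   correlation.
#' @return J x J latent correlation matrix.
#' @export
calibrate_latent_corr <- function(target_corr, marginals, tol = 1e-3) {
  J <- nrow(target_corr)
  stopifnot(nrow(marginals) == J)
  if (any(abs(rowSums(marginals) - 1) > 1e-9) || any(marginals < 0)) {
    abort("Each row of `marginals` must be a probability vector summing to 1.")
  }
  K <- ncol(marginals)
  th <- t(apply(marginals, 1, function(p) qnorm(cumsum(p)[-K])))
  cum <- t(apply(marginals, 1, function(p) cumsum(p)[-K]))
  sds <- apply(marginals, 1, function(p) marginal_moments(p)$sd)

  latent <- diag(J)
  for (i in seq_len(J - 1)) {
    for (j in (i + 1):J) {
      tgt <- target_corr[i, j]
      if (abs(tgt) < 1e-12) next
      f <- function(r) {
        ordinal_corr_one(r, th[i, ], th[j, ], cum[i, ], cum[j, ],
                         sds[i], sds[j]) - tgt
      }
      lo <- f(-0.9999); hi <- f(0.9999)
      if (lo > 0 || hi < 0) {
        abort(sprintf(
          "Target correlation %.3f for items %d and %d is outside the attainable range [%.3f, %.3f].",
          tgt, i, j, lo + tgt, hi + tgt))
      }
      latent[i, j] <- latent[j, i] <-
        uniroot(f, c(-0.9999, 0.9999), tol = tol / 4)$root
    }
  }
  repaired <- nearest_pd(latent)
  attr(repaired, "repair_drift") <- max(abs(repaired - latent))
  repaired
}

# eigenvalue clipping to the nearest (in a practical sense) PD correlation
nearest_pd <- function(M, eps = 1e-6) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  if (min(e$values) > eps) return((M + t(M)) / 2)
  vals <- pmax(e$values, eps)
  R <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(R))
  R <- R / outer(d, d)
  diag(R) <- 1
  (R + t(R)) / 2
}

#' Build a HEXACO-like target correlation matrix
#'
#' Generates a J x J ordinal target correlation matrix from a
#' one-factor-per-construct model. On the conventionally recoded scale
#' (reverse-keyed items reflected) item loadings are drawn uniformly from
#' `loading_range`, construct factor intercorrelations uniformly from
#' `factor_corr_range`, and the implied correlations are rescaled so that
#' the mean off-diagonal entry on that recoded scale equals `target_mean` --
#' the value a sparse multi-construct personality inventory typically
#' reports -- with every entry constrained to `entry_bounds`. The returned
#' matrix is for the raw (un-recoded) responses, i.e. rows/columns of
#' reverse-keyed items have their correlation signs flipped; its recoded-
#' scale mean is attached as attribute `"recoded_mean"`.
#'
#' @param design A [scale_design()] supplying the construct map and
#'   reverse-key flags.
#' @param loading_range Interval for the absolute item loadings.
#' @param factor_corr_range Interval for construct intercorrelations.
#' @param target_mean Desired mean off-diagonal correlation on the recoded
#'   scale.
#' @param entry_bounds Admissible range for every off-diagonal entry.
#' @param seed RNG seed.
#' @return J x J symmetric positive-definite correlation matrix (raw scale).
#' @export
build_hexaco_like_corr <- function(design, loading_range = c(0.45, 0.75),
                                   factor_corr_range = c(-0.10, 0.20),
                                   target_mean = 0.05,
                                   entry_bounds = c(-0.45, 0.63),
                                   seed = 1) {
  if (length(unique(design$constructs)) < 2) {
    abort("The design must contain at least two constructs.")
  }
  if (loading_range[1] > loading_range[2] ||
      any(abs(loading_range) > 1)) {
    abort("`loading_range` must be an interval within [-1, 1].")
  }
  J <- design$n_items
  ctor <- match(design$constructs, unique(design$constructs))
  C <- max(ctor)
  with_seed(seed, {
    load <- runif(J, loading_range[1], loading_range[2])
    Phi <- diag(C)
    Phi[upper.tri(Phi)] <- runif(C * (C - 1) / 2,
                                 factor_corr_range[1], factor_corr_range[2])
    Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
    Phi <- nearest_pd(Phi)
    Lambda <- matrix(0, J, C)
    Lambda[cbind(seq_len(J), ctor)] <- load
    R <- Lambda %*% Phi %*% t(Lambda)
    diag(R) <- 1
    m <- mean(R[upper.tri(R)])
    if (abs(m) > 1e-12 && abs(loading_range[2]) > 0) {
      R <- (target_mean / m) * R
      diag(R) <- 1
    }
    off <- R[upper.tri(R)]
    if (any(off < entry_bounds[1]) || any(off > entry_bounds[2])) {
      abort("`loading_range` forces correlations outside `entry_bounds`.")
    }
    R <- nearest_pd(R)
    recoded_mean <- mean(R[upper.tri(R)])
    # flip to the raw-response scale
    s <- ifelse(design$reversed, -1, 1)
    R <- R * outer(s, s)
    diag(R) <- 1
    attr(R, "recoded_mean") <- recoded_mean
    R
  })
}

#' Specify (and calibrate) the ordinal response generator
#'
#' Bundles per-item marginal category probabilities with a target ordinal
#' correlation matrix and the calibrated latent-normal correlation matrix.
#' Default marginals emulate the item-to-item heterogeneity of real
#' personality inventories: each item's category distribution is a
#' discretized normal with an item-specific location drawn from
#' `item_mean_range` and spread from `item_sd_range` (mirrored on
#' reverse-keyed items), so some items are strongly skewed and others nearly
#' symmetric -- the single feature of empirical response distributions that
#' matters most for distinguishing content-driven from careless answering.
#'
#' @param design A [scale_design()].
#' @param marginals Optional J x K matrix of category probabilities
#'   (overrides the generated defaults).
#' @param target_corr Optional J x J target ordinal correlation matrix;
#'   defaults to [build_hexaco_like_corr()].
#' @param item_mean_range,item_sd_range Ranges for the item-specific
#'   location and spread of the default marginals (on the 1..K response
#'   scale).
#' @param floor_prob Minimum category probability before renormalization.
#' @param seed RNG seed for defaults.
#' @return A list of class `ordinal_spec` with elements `marginals`,
#'   `target_corr`, `latent_corr`, `thresholds`.
#' @export
ordinal_spec <- function(design, marginals = NULL, target_corr = NULL,
                         item_mean_range = c(2.2, 4.1),
                         item_sd_range = c(0.85, 1.35),
                         floor_prob = 0.01, seed = 1) {
  J <- design$n_items
  K <- design$n_categories
  seeds <- derive_seeds(seed, 3)
  if (is.null(marginals)) {
    cuts <- c(-Inf, seq(1.5, K - 0.5), Inf)
    marginals <- with_seed(seeds[1], {
      mu <- runif(J, item_mean_range[1], item_mean_range[2])
      sg <- runif(J, item_sd_range[1], item_sd_range[2])
      t(vapply(seq_len(J), function(j) {
        p <- pmax(diff(pnorm(cuts, mu[j], sg[j])), floor_prob)
        p / sum(p)
      }, numeric(K)))
    })
    marginals[design$reversed, ] <-
      marginals[design$reversed, K:1, drop = FALSE]
  }
  if (any(abs(rowSums(marginals) - 1) > 1e-9)) {
    abort("Rows of `marginals` must sum to 1.")
  }
  if (is.null(target_corr)) {
    target_corr <- build_hexaco_like_corr(design, seed = seeds[2])
  }
  latent <- calibrate_latent_corr(target_corr, marginals)
  structure(
    list(marginals = marginals, target_corr = target_corr,
         latent_corr = latent,
         thresholds = t(apply(marginals, 1,
                              function(p) qnorm(cumsum(p)[-K]))),
         design = design),
    class = "ordinal_spec"
  )
}

#' @export
print.ordinal_spec <- function(x, ...) {
  off <- x$target_corr[upper.tri(x$target_corr)]
  cat("<ordinal_spec> ", nrow(x$marginals), " items, K = ",
      ncol(x$marginals), "; mean |target r| = ",
      round(mean(abs(off)), 3), ", range [", round(min(off), 2), ", ",
      round(max(off), 2), "]\n", sep = "")
  invisible(x)
}
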