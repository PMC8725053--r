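# Copula calibration and careless-style samplers.

# independent 2-D Gauss-Legendre integration oracle for the ordinal
# correlation implied by a latent bivariate-normal correlation
ordinal_corr_oracle <- function(rho, marg1, marg2, n_nodes = 24) {
  K1 <- length(marg1); K2 <- length(marg2)
  cut1 <- c(-8, qnorm(cumsum(marg1)[-K1]), 8)
  cut2 <- c(-8, qnorm(cumsum(marg2)[-K2]), 8)
  gl <- carelessboost:::gauss_legendre(n_nodes)
  dens <- function(x, y) {
    exp(-(x^2 - 2 * rho * x * y + y^2) / (2 * (1 - rho^2))) /
      (2 * pi * sqrt(1 - rho^2))
  }
  P <- matrix(0, K1, K2)
  for (k in seq_len(K1)) {
    xs <- (cut1[k + 1] - cut1[k]) / 2 * gl$nodes + (cut1[k + 1] + cut1[k]) / 2
    wx <- (cut1[k + 1] - cut1[k]) / 2 * gl$weights
    for (l in seq_len(K2)) {
      ys <- (cut2[l + 1] - cut2[l]) / 2 * gl$nodes +
        (cut2[l + 1] + cut2[l]) / 2
      wy <- (cut2[l + 1] - cut2[l]) / 2 * gl$weights
      P[k, l] <- sum(outer(wx, wy) * outer(xs, ys, dens))
    }
  }
  k1 <- seq_len(K1); k2 <- seq_len(K2)
  m1 <- sum(k1 * rowSums(P)); m2 <- sum(k2 * colSums(P))
  s1 <- sqrt(sum((k1 - m1)^2 * rowSums(P)))
  s2 <- sqrt(sum((k2 - m2)^2 * colSums(P)))
  (sum(outer(k1, k2) * P) - m1 * m2) / (s1 * s2)
}

test_that("the target correlation surrogate matches the printed summaries", {
  design <- hexaco_design()
  R <- build_hexaco_like_corr(design, seed = 1)
  expect_equal(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 60))
  expect_gt(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), 0)
  off <- R[upper.tri(R)]
  expect_true(all(off >= -0.45 & off <= 0.63))
  # mean inter-item correlation on the conventionally recoded scale
  expect_equal(attr(R, "recoded_mean"), 0.05, tolerance = 0.02 / 0.05)
  s <- ifelse(design$reversed, -1, 1)
  Rrec <- R * outer(s, s)
  expect_equal(mean(Rrec[upper.tri(Rrec)]), 0.05, tolerance = 0.4)

  # zero loadings degenerate to the identity
  R0 <- build_hexaco_like_corr(design, loading_range = c(0, 0), seed = 2)
  expect_equal(unname(R0[1:60, ]), diag(60), ignore_attr = TRUE)
})

test_that("latent calibration matches the numerical-integration oracle", {
  unif <- rep(0.2, 5)
  marg <- rbind(unif, unif)
  target <- matrix(c(1, 0.5, 0.5, 1), 2)
  latent <- calibrate_latent_corr(target, marg)
  # oracle confirms the calibrated latent value reproduces ordinal r = .5
  expect_equal(ordinal_corr_oracle(latent[1, 2], unif, unif), 0.5,
               tolerance = 0.001 / 0.5)
  # independence maps to independence
  target0 <- diag(2)
  expect_equal(calibrate_latent_corr(target0, marg)[1, 2], 0)
  # implied ordinal correlation is monotone in the latent correlation
  grid <- seq(-0.95, 0.95, length.out = 21)
  implied <- vapply(grid, ordinal_corr_oracle, numeric(1),
                    marg1 = unif, marg2 = c(0.1, 0.2, 0.4, 0.2, 0.1))
  expect_true(all(diff(implied) > 0))
  # unattainable target names the pair
  skew <- c(0.94, 0.02, 0.02, 0.01, 0.01)
  expect_error(
    calibrate_latent_corr(matrix(c(1, 0.95, 0.95, 1), 2),
                          rbind(skew, rev(skew))),
    "items 1 and 2")
})

test_that("regular-responder sampling recovers marginals and correlations", {
  spec <- hexaco_spec()
  smp <- sample_regular(5000, spec, seed = 2)
  X <- as.matrix(smp[-1])
  freq <- vapply(seq_len(60), function(j) {
    tabulate(X[, j], 5) / 5000
  }, numeric(5))
  expect_lt(max(abs(t(freq) - spec$marginals)), 0.02)
  dev <- abs(cor(X) - spec$target_corr)
  expect_lt(mean(dev[upper.tri(dev)]), 0.03)
  expect_lt(max(dev[upper.tri(dev)]), 0.06)
  # determinism
  expect_identical(sample_regular(20, spec, seed = 9),
                   sample_regular(20, spec, seed = 9))
})

test_that("careless-style samplers have the stated category distributions", {
  design <- hexaco_design()
  rnd <- as.matrix(sample_random_careless(1000, design, seed = 3)[-1])
  expect_true(all(rnd %in% 1:5))
  expect_lt(max(abs(tabulate(rnd, 5) / length(rnd) - 0.2)), 0.01)

  mid <- as.matrix(sample_midpoint_careless(1000, design, seed = 4)[-1])
  fr <- tabulate(mid, 5) / length(mid)
  expect_equal(fr[3], 0.50, tolerance = 0.01 / 0.5)
  expect_equal(fr[1], 0.05, tolerance = 0.01 / 0.05)
  expect_equal(fr[5], 0.05, tolerance = 0.01 / 0.05)

  # degenerate distribution collapses to a constant matrix
  const <- sample_midpoint_careless(5, design, probs = c(0, 0, 1, 0, 0),
                                    seed = 5)
  expect_true(all(as.matrix(const[-1]) == 3))

  expect_identical(sample_random_careless(10, design, seed = 6),
                   sample_random_careless(10, design, seed = 6))

  # a seed expression drawn inline from the caller's RNG stream must not be
  # undone by the sampler's state restore: successive draws stay distinct
  set.seed(123)
  s1 <- sample_random_careless(2, design, seed = sample.int(1e6, 1))
  s2 <- sample_random_careless(2, design, seed = sample.int(1e6, 1))
  expect_false(identical(s1, s2))
})

test_that("pattern respondents tile ascending runs between two distinct categories", {
  design <- hexaco_design()
  pat <- as.matrix(sample_pattern_careless(50, design, seed = 7)[-1])
  for (i in seq_len(nrow(pat))) {
    a <- min(pat[i, ]); b <- max(pat[i, ])
    expect_lt(a, b)  # two distinct draws, so values vary within a cycle
    expect_equal(unname(pat[i, ]), rep_len(seq(a, b), 60))
  }
  # within a cycle consecutive responses always change
  runs <- apply(pat, 1, function(r) max(rle(r)$lengths))
  expect_true(all(runs == 1))
  degenerate <- scale_design(n_items = 4, constructs = rep(1, 4),
                             page_size = 2)
  degenerate$n_categories <- 1L
  expect_error(sample_pattern_careless(3, degenerate), "two categories")
})

test_that("condition assembly rounds prevalence, shuffles, and labels styles", {
  spec <- hexaco_spec()
  ds <- assemble_condition(study_config(prevalence = 0.10, style = "random"),
                           spec, seed = 8)
  expect_equal(nrow(ds$labels), 180)
  expect_equal(sum(ds$labels$careless), 18)
  expect_equal(sum(ds$labels$careless == 0), 162)
  expect_true(all(ds$labels$style[ds$labels$careless == 1] == "random"))
  expect_true(all(is.na(ds$labels$style[ds$labels$careless == 0])))

  ds5 <- assemble_condition(study_config(prevalence = 0.05), spec, seed = 9)
  expect_equal(sum(ds5$labels$careless), 9)

  expect_error(
    assemble_condition(study_config(prevalence = 0.001), spec, seed = 1),
    "zero careless")
})

test_that("response times are positive, overlap, and separate at the median", {
  design <- hexaco_design()
  labels <- tibble::tibble(.id = paste0("r", 1:4000),
                           careless = rep(c(0L, 1L), each = 2000))
  rt <- sample_response_times(labels, design, rt_params(), seed = 10)
  M <- as.matrix(rt[-1])
  expect_true(all(M > 0))
  med_reg <- median(M[labels$careless == 0, ])
  med_car <- median(M[labels$careless == 1, ])
  expect_lt(med_car, med_reg)
  expect_equal(med_reg, 7, tolerance = 0.05)
  expect_equal(med_car, 3, tolerance = 0.05)
  expect_identical(sample_response_times(labels[1:5, ], design, seed = 2),
                   sample_response_times(labels[1:5, ], design, seed = 2))
  expect_error(rt_params(regular_sdlog = 0), "positive")
})

test_that("style separation shows in intraindividual variability", {
  design <- hexaco_design()
  rnd <- irv_scores(sample_random_careless(300, design, seed = 11), design)
  mid <- irv_scores(sample_midpoint_careless(300, design, seed = 12), design)
  expect_equal(mean(rnd$score), sqrt(2), tolerance = 0.02)
  expect_lt(mean(mid$score), mean(rnd$score))
})
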