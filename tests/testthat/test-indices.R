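# Traditional detection indices against hand calculations and brute-force
# oracles.

test_that("Mahalanobis distances match an explicit-inverse hand calculation", {
  design <- scale_design(n_items = 2, constructs = c(1, 2), page_size = 1)
  X <- rbind(c(1, 2), c(3, 1), c(2, 5))
  sc <- mahalanobis_scores(X, design, recode = FALSE)
  # explicit 2x2 inverse oracle
  ctr <- sweep(X, 2, colMeans(X))
  S <- crossprod(ctr) / 2
  Sinv <- solve(S)
  d2 <- vapply(1:3, function(i) drop(ctr[i, ] %*% Sinv %*% ctr[i, ]),
               numeric(1))
  expect_equal(sc$score, d2)
  expect_equal(sc$orientation[1], "high")

  # a respondent sitting exactly at the centroid scores zero
  design3 <- scale_design(n_items = 3, constructs = 1:3, page_size = 1)
  Xc <- rbind(c(1, 2, 1), c(5, 1, 2), c(3, 5, 2), c(4, 4, 4), c(2, 3, 1),
              c(3, 3, 2))
  expect_equal(colMeans(Xc), Xc[6, ], ignore_attr = TRUE)
  scc <- mahalanobis_scores(Xc, design3, recode = FALSE)
  expect_equal(scc$score[6], 0)
})

test_that("sample Mahalanobis distances satisfy the mean identity", {
  spec <- hexaco_spec()
  X <- as.matrix(sample_regular(120, spec, seed = 21)[-1])
  sc <- mahalanobis_scores(X, hexaco_design())
  expect_equal(mean(sc$score), 60 * (120 - 1) / 120, tolerance = 1e-9)
})

test_that("injected random rows take the top Mahalanobis ranks", {
  spec <- hexaco_spec()
  design <- hexaco_design()
  reg <- as.matrix(sample_regular(162, spec, seed = 22)[-1])
  rnd <- as.matrix(sample_random_careless(18, design, seed = 23)[-1])
  sc <- mahalanobis_scores(rbind(reg, rnd), design)
  rank_rnd <- rank(sc$score)[163:180]
  expect_gt(mean(rank_rnd), 170)
})

test_that("antonym scores hit -1 for perfectly mirrored responding", {
  design <- hexaco_design()
  spec <- hexaco_spec()
  X <- as.matrix(sample_regular(200, spec, seed = 24)[-1])
  sc <- antonym_scores(X, design)
  expect_gt(attr(sc, "n_pairs"), 2)

  # append a respondent mirroring every qualifying pair: x2 = 6 - x1.
  # Mirroring every item against a fixed template guarantees it pairwise.
  mirror <- ifelse(design$reversed, 2, 4)
  X2 <- rbind(X, mirror)
  sc2 <- antonym_scores(X2, design)
  r_last <- sc2$score[nrow(X2)]
  expect_true(is.na(r_last) || r_last <= 0)

  # uniform-random respondents average near zero
  reg <- as.matrix(sample_regular(400, hexaco_spec(), seed = 24)[-1])
  rnd <- as.matrix(sample_random_careless(40, design, seed = 25)[-1])
  sc3 <- antonym_scores(rbind(reg, rnd), design)
  expect_lt(abs(mean(sc3$score[401:440], na.rm = TRUE)), 0.1)

  # an impossible criterion leaves no qualifying pairs
  expect_error(antonym_scores(X, design, r_crit = -0.99), "relax")
})

test_that("antonym score is exactly -1 for an explicit mirrored pair set", {
  # two independent constructs whose second item mirrors the first, so the
  # only qualifying pairs are the two exact mirrors
  design <- scale_design(n_items = 4, constructs = c(1, 1, 2, 2),
                         reversed = c(FALSE, TRUE, FALSE, TRUE),
                         page_size = 2)
  set.seed(26)
  x1 <- sample.int(5, 500, TRUE)
  x3 <- sample.int(5, 500, TRUE)
  X <- cbind(x1, 6 - x1, x3, 6 - x3)
  sc <- antonym_scores(X, design, min_pairs = 1)
  expect_equal(attr(sc, "n_pairs"), 2L)
  # respondents with x1 != x3 mirror both qualifying pairs exactly
  defined <- !is.na(sc$score)
  expect_true(any(defined))
  expect_equal(sc$score[defined], rep(-1, sum(defined)))
  expect_true(all(is.na(sc$score[x1 == x3])))
})

test_that("even-odd consistency is 1 for perfectly consistent halves and NA for constants", {
  design <- hexaco_design()
  # constant within construct, varying across constructs -> r = 1 -> adj 1
  lv <- rep(c(1, 2, 3, 4, 5, 3), times = 10)  # by construct rotation
  X <- matrix(0, 2, 60)
  for (j in 1:60) {
    v <- lv[j]
    X[1, j] <- if (design$reversed[j]) 6 - v else v
    X[2, j] <- 3
  }
  sc <- evenodd_scores(X, design)
  expect_equal(sc$score[1], 1)
  expect_true(is.na(sc$score[2]))  # straightliner: zero-variance halves
  expect_equal(sc$orientation[1], "low")

  # regular respondents outscore uniform-random careless on average
  spec <- hexaco_spec()
  reg <- evenodd_scores(sample_regular(300, spec, seed = 27), design)
  rnd <- evenodd_scores(sample_random_careless(300, design, seed = 28),
                        design)
  expect_gt(mean(reg$score, na.rm = TRUE), mean(rnd$score, na.rm = TRUE))
})

test_that("longstring and IRV agree with brute-force single-pass oracles", {
  design <- hexaco_design()
  X <- as.matrix(sample_random_careless(1000, design, seed = 29)[-1])
  ls <- longstring_scores(X, design)
  irv <- irv_scores(X, design)
  brute_max <- apply(X, 1, function(r) {
    best <- run <- 1
    for (j in 2:length(r)) {
      run <- if (r[j] == r[j - 1]) run + 1 else 1
      best <- max(best, run)
    }
    best
  })
  brute_sd <- apply(X, 1, function(r) sqrt(sum((r - mean(r))^2) / (length(r) - 1)))
  expect_equal(ls$score, brute_max)
  expect_equal(irv$score, brute_sd)
})

test_that("longstring and IRV closed-form examples", {
  design <- hexaco_design()
  row_run6 <- c(rep(3, 6), rep_len(c(1, 2), 54))
  row_alt <- rep_len(c(1, 5), 60)
  X <- rbind(row_run6, row_alt, rep(3, 60))
  ls <- longstring_scores(X, design)
  expect_equal(ls$score, c(6, 1, 60))
  fl <- apply_flag_rule(ls, flag_rule("absolute", cutoff = 6,
                                      direction = ">="))
  expect_equal(fl$flag, c(TRUE, FALSE, TRUE))

  irv <- irv_scores(X, design)
  expect_equal(irv$score[2], 2 * sqrt(60 / 59))
  expect_equal(irv$score[3], 0)
  expect_named(irv$score, NULL)
})

test_that("flag rules apply the stated cutoffs and never flag NA scores", {
  sc <- carelessboost:::index_scores(c("a", "b", "c"), "mahalanobis",
                                     c(80, 79, NA), "high")
  fl <- apply_flag_rule(sc, flag_rule("chisq", alpha = 0.05, df = 60))
  expect_equal(qchisq(0.95, 60), 79.0819, tolerance = 1e-5)
  expect_equal(fl$flag, c(TRUE, FALSE, FALSE))
  expect_equal(attr(fl, "n_na"), 1L)

  # two-sided percentile rule flags ~10% of a homogeneous sample
  set.seed(30)
  sc2 <- carelessboost:::index_scores(paste0("r", 1:1000), "irv",
                                      rnorm(1000), "two_sided")
  fl2 <- apply_flag_rule(sc2, flag_rule("two_sided_percentile",
                                        percentiles = c(5, 95)))
  expect_equal(mean(fl2$flag), 0.10, tolerance = 0.11)
  expect_true(all(fl2$flag == (fl2$flag_low | fl2$flag_high)))

  expect_error(apply_flag_rule(sc[0, ], flag_rule("chisq", df = 60)),
               "Empty")
})

test_that("flagging is invariant to respondent order", {
  spec <- hexaco_spec()
  design <- hexaco_design()
  ds <- assemble_condition(study_config(style = "random"), spec, seed = 31)
  X <- as.matrix(ds$responses[-1])
  sc <- mahalanobis_scores(X, design)
  fl <- apply_flag_rule(sc, flag_rule("chisq", df = 60))
  perm <- sample(nrow(X))
  fl_p <- apply_flag_rule(mahalanobis_scores(X[perm, ], design),
                          flag_rule("chisq", df = 60))
  expect_equal(fl_p$flag, fl$flag[perm])
})
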