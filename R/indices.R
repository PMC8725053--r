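# Traditional data-driven careless-responding indices.
#
# Each *_scores() function returns a long tibble (.id, method, score,
# orientation) of class "index_scores". Orientation records which tail of
# the score distribution signals carelessness ("high", "low", or
# "two_sided") and drives apply_flag_rule(). Conventions follow standard
# practice: longstring, IRV and antonyms are computed on the raw (un-recoded)
# responses; Mahalanobis and even-odd after reverse-key recoding.

index_scores <- function(ids, method, score, orientation) {
  if (is.null(ids)) ids <- paste0("r", seq_along(score))
  structure(
    tibble(.id = as.character(ids), method = method, score = score,
           orientation = orientation),
    class = c("index_scores", "tbl_df", "tbl", "data.frame")
  )
}

#' Squared Mahalanobis distances
#'
#' Computes each respondent's squared Mahalanobis distance
#' `D2 = (x - xbar)' S^-1 (x - xbar)` from the sample centroid, using the
#' sample mean and unbiased (n-1) covariance of the analysis sample itself
#' (careless respondents included, as in post-hoc screening). Reverse-keyed
#' items should be recoded first; `recode = TRUE` (default) does so. High
#' scores indicate multivariate outlyingness, i.e. potential carelessness.
#'
#' @param data Wide responses (`.id` + item columns) or matrix.
#' @param design A [scale_design()].
#' @param recode Recode reverse-keyed items before computing distances.
#' @param ridge Optional ridge `ridge * tr(S)/J` added to the covariance
#'   diagonal for n <= J situations; 0 (default) disables it.
#' @return An `index_scores` tibble (orientation "high").
#' @export
mahalanobis_scores <- function(data, design, recode = TRUE, ridge = 0) {
  X <- response_matrix(data, design)
  validate_responses(X, design)
  if (recode) {
    K <- design$n_categories
    X[, design$reversed] <- K + 1 - X[, design$reversed]
  }
  S <- cov(X)
  if (ridge > 0) S <- S + diag(ridge * sum(diag(S)) / ncol(X), ncol(X))
  d2 <- tryCatch(
    stats::mahalanobis(X, colMeans(X), S),
    error = function(e) abort(
      "Sample covariance is singular; supply `ridge > 0` or more respondents.")
  )
  index_scores(rownames(X), "mahalanobis", unname(d2), "high")
}

#' Psychometric-antonym scores
#'
#' Identifies all item pairs whose sample correlation (on the raw,
#' un-recoded data, across all scales) is at or below `r_crit`, then scores
#' each respondent as the within-person Pearson correlation between the
#' first- and second-element responses across those pairs. Consistent
#' respondents mirror the negative pairing and score near -1; careless
#' respondents drift toward 0 or positive values, so high scores flag
#' carelessness. Respondents with zero variance on either pair vector get
#' `NA` (reported, never flagged).
#'
#' @param data Wide responses or matrix.
#' @param design A [scale_design()].
#' @param r_crit Critical pair correlation (default -.20).
#' @param min_pairs Minimum number of qualifying pairs required.
#' @return An `index_scores` tibble (orientation "high").
#' @export
antonym_scores <- function(data, design, r_crit = -0.20, min_pairs = 3) {
  X <- response_matrix(data, design)
  validate_responses(X, design)
  R <- suppressWarnings(cor(X))
  idx <- which(upper.tri(R) & R <= r_crit, arr.ind = TRUE)
  if (nrow(idx) < min_pairs) {
    abort(sprintf(
      "Only %d item pair(s) correlate at or below %.2f; relax `r_crit`.",
      nrow(idx), r_crit))
  }
  A <- X[, idx[, 1], drop = FALSE]
  B <- X[, idx[, 2], drop = FALSE]
  score <- vapply(seq_len(nrow(X)), function(i) {
    a <- A[i, ]; b <- B[i, ]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  out <- index_scores(rownames(X), "antonyms", score, "high")
  attr(out, "n_pairs") <- nrow(idx)
  out
}

#' Even-odd consistency scores
#'
#' After recoding reverse-keyed items, splits each construct into its odd-
#' and even-positioned items (positions counted within the construct, in
#' administration order), averages each half, and scores each respondent as
#' the Pearson correlation between the two half-mean vectors across
#' constructs, Spearman-Brown adjusted (`2r / (1 + r)`). Low scores indicate
#' inconsistent (careless) responding; zero-variance half vectors give `NA`.
#'
#' @param data Wide responses or matrix.
#' @param design A [scale_design()]; every construct needs >= 2 items.
#' @return An `index_scores` tibble (orientation "low").
#' @export
evenodd_scores <- function(data, design) {
  X <- response_matrix(data, design)
  validate_responses(X, design)
  K <- design$n_categories
  X[, design$reversed] <- K + 1 - X[, design$reversed]
  ctors <- unique(design$constructs)
  if (any(table(design$constructs) < 2)) {
    abort("Every construct needs at least two items for an even-odd split.")
  }
  odd <- even <- matrix(0, nrow(X), length(ctors))
  for (c_i in seq_along(ctors)) {
    items <- which(design$constructs == ctors[c_i])
    pos <- seq_along(items)
    odd[, c_i] <- rowMeans(X[, items[pos %% 2 == 1], drop = FALSE])
    even[, c_i] <- rowMeans(X[, items[pos %% 2 == 0], drop = FALSE])
  }
  score <- vapply(seq_len(nrow(X)), function(i) {
    o <- odd[i, ]; e <- even[i, ]
    if (sd(o) == 0 || sd(e) == 0) return(NA_real_)
    r <- cor(o, e)
    2 * r / (1 + r)
  }, numeric(1))
  index_scores(rownames(X), "evenodd", score, "low")
}

#' Longstring scores
#'
#' Maximum run length of identical consecutive responses per respondent,
#' computed on the raw (un-recoded) responses in administration order. The
#' mean run length is attached as column `mean_run`. High scores indicate
#' straightlining.
#'
#' @param data Wide responses or matrix.
#' @param design A [scale_design()].
#' @return An `index_scores` tibble (orientation "high") with extra column
#'   `mean_run`.
#' @export
longstring_scores <- function(data, design) {
  X <- response_matrix(data, design)
  validate_responses(X, design)
  runs <- lapply(seq_len(nrow(X)), function(i) rle(X[i, ])$lengths)
  out <- index_scores(rownames(X), "longstring",
                      vapply(runs, max, numeric(1)), "high")
  out$mean_run <- vapply(runs, mean, numeric(1))
  out
}

#' Intraindividual response variability (IRV)
#'
#' Per-respondent sample standard deviation (n-1 denominator) across all raw
#' item responses. Low values indicate straightlining, high values random
#' responding, so the index is two-sided.
#'
#' @param data Wide responses or matrix.
#' @param design A [scale_design()].
#' @return An `index_scores` tibble (orientation "two_sided").
#' @export
irv_scores <- function(data, design) {
  X <- response_matrix(data, design)
  validate_responses(X, design)
  if (ncol(X) < 2) abort("IRV needs at least two items.")
  index_scores(rownames(X), "irv", unname(apply(X, 1, sd)), "two_sided")
}

#' Construct a flagging rule
#'
#' @param kind One of `"chisq"` (flag `score > qchisq(1 - alpha, df)`),
#'   `"absolute"` (fixed cutoff with a direction), `"percentile"` (sample
#'   percentile cutoff in the careless direction), or
#'   `"two_sided_percentile"` (low- and high-tail variants evaluated
#'   separately).
#' @param alpha,df Chi-square rule parameters.
#' @param cutoff,direction Absolute rule: flag when score is `">="`, `">"`,
#'   `"<="` or `"<"` the cutoff.
#' @param percentile Single percentile (0-100) for the one-sided percentile
#'   rule.
#' @param percentiles Length-2 percentiles for the two-sided rule.
#' @return A list of class `flag_rule`.
#' @export
flag_rule <- function(kind = c("chisq", "absolute", "percentile",
                               "two_sided_percentile"),
                      alpha = 0.05, df = NULL, cutoff = NULL,
                      direction = ">=", percentile = NULL,
                      percentiles = c(5, 95)) {
  kind <- match.arg(kind)
  if (kind == "chisq" && is.null(df)) abort("The chi-square rule needs `df`.")
  if (kind == "absolute" && is.null(cutoff)) {
    abort("The absolute rule needs `cutoff`.")
  }
  if (kind == "percentile" && is.null(percentile)) {
    abort("The percentile rule needs `percentile`.")
  }
  structure(list(kind = kind, alpha = alpha, df = df, cutoff = cutoff,
                 direction = direction, percentile = percentile,
                 percentiles = percentiles),
            class = "flag_rule")
}

#' Apply a flagging rule to index scores
#'
#' Undefined (`NA`) scores are never flagged; their count is attached as
#' attribute `"n_na"`. For the two-sided percentile rule both tail variants
#' are returned (`flag_low`, `flag_high`); when `labels` is supplied, `flag`
#' is the variant with the higher accuracy on those labels (an acknowledged
#' overestimate of field performance), otherwise the union of both tails.
#'
#' @param scores An `index_scores` tibble.
#' @param rule A [flag_rule()].
#' @param labels Optional 0/1 careless labels (for the two-sided rule's
#'   better-accuracy variant selection).
#' @return The `scores` tibble with an added logical `flag` column.
#' @export
apply_flag_rule <- function(scores, rule, labels = NULL) {
  if (nrow(scores) == 0) abort("Empty score vector.")
  s <- scores$score
  flag <- switch(rule$kind,
    chisq = s > qchisq(1 - rule$alpha, df = rule$df),
    absolute = switch(rule$direction,
      ">=" = s >= rule$cutoff, ">" = s > rule$cutoff,
      "<=" = s <= rule$cutoff, "<" = s < rule$cutoff,
      abort("Unknown direction.")),
    percentile = {
      orient <- scores$orientation[1]
      q <- quantile(s, rule$percentile / 100, na.rm = TRUE, names = FALSE)
      if (orient == "low") s <= q else s >= q
    },
    two_sided_percentile = {
      q_lo <- quantile(s, rule$percentiles[1] / 100, na.rm = TRUE,
                       names = FALSE)
      q_hi <- quantile(s, rule$percentiles[2] / 100, na.rm = TRUE,
                       names = FALSE)
      flag_low <- s <= q_lo
      flag_high <- s >= q_hi
      flag_low[is.na(flag_low)] <- FALSE
      flag_high[is.na(flag_high)] <- FALSE
      scores$flag_low <- flag_low
      scores$flag_high <- flag_high
      if (!is.null(labels)) {
        acc_low <- mean((flag_low * 1L) == labels)
        acc_high <- mean((flag_high * 1L) == labels)
        if (acc_low >= acc_high) flag_low else flag_high
      } else {
        flag_low | flag_high
      }
    }
  )
  n_na <- sum(is.na(flag))
  flag[is.na(flag)] <- FALSE
  scores$flag <- flag
  attr(scores, "n_na") <- n_na
  scores
}

#' Score a response sample with several indices at once
#'
#' Convenience wrapper: computes the requested traditional indices and
#' stacks them in one long tibble.
#'
#' @param data Wide responses (`.id` + item columns).
#' @param design A [scale_design()].
#' @param methods Subset of `c("mahalanobis", "antonyms", "evenodd",
#'   "longstring", "irv")`.
#' @return A long `index_scores` tibble.
#' @export
score_indices <- function(data, design,
                          methods = c("mahalanobis", "antonyms", "evenodd",
                                      "longstring", "irv")) {
  parts <- lapply(methods, function(m) {
    switch(m,
      mahalanobis = mahalanobis_scores(data, design),
      antonyms = antonym_scores(data, design),
      evenodd = evenodd_scores(data, design),
      longstring = longstring_scores(data, design)[
        c(".id", "method", "score", "orientation")],
      irv = irv_scores(data, design),
      abort(sprintf("Unknown method '%s'.", m)))
  })
  bind_rows(parts)
}
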