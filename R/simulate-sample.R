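# Samplers for regular responders, the three careless styles, and
# response-time paradata.

#' Sample regular (content-driven) responders
#'
#' Draws latent multivariate-normal vectors with the calibrated latent
#' correlation matrix and discretizes each item at its threshold grid, so
#' that the generated ordinal responses reproduce the spec's marginals and
#' target inter-item correlations.
#'
#' @param n Number of respondents.
#' @param spec An [ordinal_spec()].
#' @param seed RNG seed; identical seeds give identical samples.
#' @return Tibble with `.id` and one integer column per item.
#' @export
sample_regular <- function(n, spec, seed = 1) {
  stopifnot(inherits(spec, "ordinal_spec"), n >= 1)
  J <- nrow(spec$marginals)
  L <- tryCatch(chol(spec$latent_corr),
                error = function(e) abort(
                  "Latent correlation matrix is not positive definite; recalibrate the spec."))
  Z <- with_seed(seed, matrix(rnorm(n * J), n, J) %*% L)
  X <- matrix(0L, n, J)
  for (j in seq_len(J)) {
    X[, j] <- findInterval(Z[, j], spec$thresholds[j, ]) + 1L
  }
  responses_as_tibble(X, spec$design)
}

#' Sample uniform-random careless responders
#'
#' Every cell is an independent uniform draw over the K categories
#' (probability 1/K each).
#'
#' @param n Number of respondents.
#' @param design A [scale_design()], or `K`/`J` given directly.
#' @param seed RNG seed.
#' @return Tibble with `.id` and item columns.
#' @export
sample_random_careless <- function(n, design = scale_design(), seed = 1) {
  K <- design$n_categories
  J <- design$n_items
  X <- with_seed(seed, matrix(sample.int(K, n * J, replace = TRUE), n, J))
  responses_as_tibble(X, design)
}

#' Sample midpoint-style careless responders
#'
#' Cells are independent draws from a midpoint-heavy category distribution
#' (default .05, .20, .50, .20, .05), emulating respondents who hover around
#' the scale midpoint to evade outlier screens.
#'
#' @param n Number of respondents.
#' @param design A [scale_design()].
#' @param probs Category probability vector of length K summing to 1.
#' @param seed RNG seed.
#' @return Tibble with `.id` and item columns.
#' @export
sample_midpoint_careless <- function(n, design = scale_design(),
                                     probs = c(0.05, 0.20, 0.50, 0.20, 0.05),
                                     seed = 1) {
  K <- design$n_categories
  if (length(probs) != K || any(probs < 0) || abs(sum(probs) - 1) > 1e-9) {
    abort("`probs` must be a length-K probability vector summing to 1.")
  }
  J <- design$n_items
  X <- with_seed(seed, matrix(
    sample.int(K, n * J, replace = TRUE, prob = probs), n, J))
  responses_as_tibble(X, design)
}

#' Sample fixed-pattern careless responders
#'
#' Per respondent, two distinct categories a < b are drawn; the response row
#' is the ascending run a, a+1, ..., b tiled across the J items (the final
#' cycle truncated). For example, draws 1 and 3 give 1-2-3-1-2-3-... The two
#' draws are forced distinct so the pattern varies within each cycle rather
#' than repeating one response.
#'
#' @param n Number of respondents.
#' @param design A [scale_design()].
#' @param seed RNG seed.
#' @return Tibble with `.id` and item columns.
#' @export
sample_pattern_careless <- function(n, design = scale_design(), seed = 1) {
  K <- design$n_categories
  if (K < 2) abort("Pattern responding needs at least two categories.")
  J <- design$n_items
  X <- with_seed(seed, {
    t(vapply(seq_len(n), function(i) {
      ab <- sort(sample.int(K, 2))
      rep_len(seq(ab[1], ab[2]), J)
    }, integer(J)))
  })
  responses_as_tibble(X, design)
}

#' Assemble a labeled mixture of regular and careless respondents
#'
#' Rounds `prevalence * n` to the careless count, concatenates regular and
#' careless blocks, shuffles the rows, and attaches labels and style tags.
#'
#' @param config A [study_config()]; `n_total`, `prevalence`, and `style` are
#'   used.
#' @param spec An [ordinal_spec()] for the regular block.
#' @param seed RNG seed.
#' @param n Optional sample-size override of `config$n_total`.
#' @return A list of class `labeled_dataset` with elements `responses`
#'   (tibble `.id` + items) and `labels` (tibble `.id`, `careless`, `style`).
#' @export
assemble_condition <- function(config, spec, seed = 1, n = NULL) {
  if (is.null(n)) n <- config$n_total
  n_careless <- round(config$prevalence * n)
  if (n_careless < 1) {
    abort("The requested prevalence yields zero careless respondents.")
  }
  n_regular <- n - n_careless
  design <- spec$design
  seeds <- derive_seeds(seed, 3)
  reg <- sample_regular(n_regular, spec, seed = seeds[1])
  car <- switch(config$style,
    random = sample_random_careless(n_careless, design, seed = seeds[2]),
    midpoint = sample_midpoint_careless(n_careless, design, seed = seeds[2]),
    pattern = sample_pattern_careless(n_careless, design, seed = seeds[2]),
    abort(sprintf("No sampler for style '%s'.", config$style))
  )
  X <- rbind(response_matrix(reg, design), response_matrix(car, design))
  careless <- c(rep(0L, n_regular), rep(1L, n_careless))
  style <- c(rep(NA_character_, n_regular), rep(config$style, n_careless))
  ord <- with_seed(seeds[3], sample.int(n))
  X <- X[ord, , drop = FALSE]
  careless <- careless[ord]
  style <- style[ord]
  ids <- paste0("r", formatC(seq_len(n), width = nchar(n), flag = "0"))
  structure(
    list(
      responses = responses_as_tibble(X, design, ids = ids),
      labels = tibble(.id = ids, careless = careless, style = style)
    ),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$labels), " respondents (",
      sum(x$labels$careless), " careless); ",
      if (is.null(x$rt)) "no" else "with", " response times\n", sep = "")
  invisible(x)
}

#' Response-time generator parameters
#'
#' Item-level response durations are log-normal per condition. The defaults
#' (regular median 7 s, log-SD 0.45; careless median 3 s, log-SD 0.55) give
#' heavily overlapping distributions whose clearest separation sits in the
#' lower tail -- the qualitative shape observed for instructed careless
#' responding. They are deliberately configurable.
#'
#' @param regular_median,careless_median Median item duration in seconds.
#' @param regular_sdlog,careless_sdlog Log-scale SDs.
#' @return A list of class `rt_params`.
#' @export
rt_params <- function(regular_median = 7.0, regular_sdlog = 0.45,
                      careless_median = 3.0, careless_sdlog = 0.55) {
  if (regular_sdlog <= 0 || careless_sdlog <= 0) {
    abort("Log-scale SDs must be strictly positive.")
  }
  if (regular_median <= 0 || careless_median <= 0) {
    abort("Median durations must be strictly positive.")
  }
  structure(list(regular_median = regular_median,
                 regular_sdlog = regular_sdlog,
                 careless_median = careless_median,
                 careless_sdlog = careless_sdlog),
            class = "rt_params")
}

#' Sample item-level response times
#'
#' @param labels Tibble with `.id` and binary `careless` column (as produced
#'   by [assemble_condition()]), or a plain 0/1 vector.
#' @param design A [scale_design()].
#' @param params An [rt_params()].
#' @param seed RNG seed.
#' @return Tibble with `.id` and one positive duration column per item.
#' @export
sample_response_times <- function(labels, design = scale_design(),
                                  params = rt_params(), seed = 1) {
  if (is.data.frame(labels)) {
    ids <- labels$.id
    y <- labels$careless
  } else {
    y <- labels
    ids <- paste0("r", seq_along(y))
  }
  n <- length(y)
  J <- design$n_items
  meanlog <- ifelse(y == 1, log(params$careless_median),
                    log(params$regular_median))
  sdlog <- ifelse(y == 1, params$careless_sdlog, params$regular_sdlog)
  RT <- with_seed(seed, {
    matrix(stats::rlnorm(n * J, meanlog = rep(meanlog, J),
                         sdlog = rep(sdlog, J)), n, J)
  })
  colnames(RT) <- paste0("rt_", design$item_ids)
  bind_cols(tibble(.id = as.character(ids)),
            as_tibble(RT, .name_repair = "minimal"))
}
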