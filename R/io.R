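#' Read a wide response matrix from CSV
#'
#' Expects a comma-separated UTF-8 file with a mandatory header row, the
#' respondent id in the first column and one integer column per item
#' (categories `1..K`). Missing cells and out-of-range categories are errors:
#' the survey design forces a response to every item, so an absent value
#' indicates a broken export, not data to impute.
#'
#' @param path Path to the CSV file.
#' @param design A [scale_design()] the file must conform to.
#'
#' @return A tibble with an `.id` column and one column per item.
#' @export
read_responses <- function(path, design) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) != design$n_items + 1) {
    abort(sprintf("Expected 1 id column + %d item columns, found %d columns.",
                  design$n_items, ncol(raw)))
  }
  ids <- as.character(raw[[1]])
  X <- as.matrix(raw[-1])
  storage.mode(X) <- "double"
  rownames(X) <- ids
  validate_responses(X, design)
  responses_as_tibble(X, design, ids = ids)
}

#' Write a wide response matrix to CSV
#'
#' @param data Wide response tibble (`.id` + item columns) or matrix.
#' @param path Output path.
#' @param design A [scale_design()].
#' @return `path`, invisibly.
#' @export
write_responses <- function(data, path, design) {
  X <- response_matrix(data, design)
  validate_responses(X, design)
  tb <- responses_as_tibble(X, design,
                            ids = if (is.data.frame(data)) data$.id else NULL)
  readr::write_csv(tb, path, progress = FALSE)
  invisible(path)
}

#' Read / write an item-level response-time matrix
#'
#' Same wide CSV layout as [read_responses()] but with strictly positive
#' durations in seconds.
#'
#' @param path CSV path.
#' @param design A [scale_design()].
#' @return A tibble with `.id` plus one duration column per item.
#' @export
read_rt <- function(path, design) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (ncol(raw) != design$n_items + 1) {
    abort(sprintf("Expected 1 id column + %d item columns, found %d columns.",
                  design$n_items, ncol(raw)))
  }
  X <- as.matrix(raw[-1])
  storage.mode(X) <- "double"
  if (anyNA(X) || any(X <= 0)) {
    abort("Response times must be complete and strictly positive.")
  }
  bind_cols(tibble(.id = as.character(raw[[1]])),
            as_tibble(X, .name_repair = "minimal"))
}

#' @rdname read_rt
#' @param data Wide response-time tibble or matrix.
#' @export
write_rt <- function(data, path, design) {
  readr::write_csv(as_tibble(data), path, progress = FALSE)
  invisible(path)
}

config_defaults <- function() {
  list(
    prevalence = 0.10,
    style = "random",
    n_total = 180L,
    n_train = 425L,
    test_fraction = 0.30,
    test_ratio = 9,
    replications = 100L,
    seed = 1L,
    folds = 10L,
    zh_cutoff = -1.96,
    evenodd_cutoff = 0.30,
    antonym_cutoff = 0,
    irv_percentiles = c(5, 95),
    longstring_cutoff = 6L,
    mahalanobis_alpha = 0.05
  )
}

#' Load a study configuration from JSON
#'
#' Unspecified keys fall back to documented defaults (10% prevalence,
#' random style, n_test = 180, n_train = 425, 9:1 test ratio, 10 CV folds,
#' seed 1). Unknown keys raise a warning; invalid values are errors.
#'
#' @param path JSON path, or `NULL` for all defaults.
#' @return A named list of class `study_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("File not found: %s", path))
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown) > 0) {
      warn(paste0("Ignoring unknown config keys: ",
                  paste(unknown, collapse = ", ")))
      user <- user[setdiff(names(user), unknown)]
    }
    cfg <- modifyList(cfg, user)
  }
  study_config(cfg)
}

#' Build a validated study configuration
#'
#' @param ... Either a single named list or individual `key = value` pairs
#'   overriding the defaults of [load_config()].
#' @return A named list of class `study_config`.
#' @export
study_config <- function(...) {
  dots <- list(...)
  if (length(dots) == 1 && is.null(names(dots)) && is.list(dots[[1]])) {
    dots <- dots[[1]]
  }
  cfg <- modifyList(config_defaults(), dots)
  if (!(cfg$prevalence > 0 && cfg$prevalence < 1)) {
    abort("`prevalence` must lie strictly between 0 and 1.")
  }
  if (!cfg$style %in% c("random", "midpoint", "pattern", "empirical")) {
    abort("`style` must be one of random, midpoint, pattern, empirical.")
  }
  if (cfg$replications < 1) abort("`replications` must be at least 1.")
  if (cfg$test_ratio < 1) abort("`test_ratio` must be at least 1.")
  structure(cfg, class = "study_config")
}

#' Write a metric table with run metadata
#'
#' Serializes a results table both as CSV (rows = metrics, columns = methods,
#' mirroring the usual benchmark layout) and as JSON carrying run metadata
#' (seed, package version, config hash).
#'
#' @param table A tibble of results (e.g. from [run_simulation_study()]).
#' @param path Output path without extension; `.csv` and `.json` are added.
#' @param config The `study_config` used for the run.
#' @return Invisibly, the two file paths written.
#' @export
write_results <- function(table, path, config = study_config()) {
  csv_path <- paste0(path, ".csv")
  json_path <- paste0(path, ".json")
  readr::write_csv(as_tibble(table), csv_path, progress = FALSE)
  meta <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("carelessboost")),
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    written = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(list(metadata = meta, results = table), json_path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv_path, json_path))
}
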