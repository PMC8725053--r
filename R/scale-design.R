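#' Describe a multi-construct Likert scale
#'
#' A scale design records how the administered items map onto constructs,
#' which items are reverse-keyed, how many response categories the scale
#' offers, and the page layout (items per survey page, used for response-time
#' parcels). The default mirrors a HEXACO-60-style questionnaire: 60
#' five-category items measuring six constructs of ten items each, with the
#' constructs rotated across consecutive items (item 1 construct 1, item 2
#' construct 2, ...) and every second item within a construct reverse-keyed.
#'
#' @param n_items Number of items J.
#' @param n_categories Number of ordered response categories K (>= 2).
#' @param constructs Integer or character vector of length `n_items` assigning
#'   each item to a construct. Default: constructs rotated item by item.
#' @param reversed Logical vector of length `n_items` flagging reverse-keyed
#'   items. Default: every second item within each construct.
#' @param page_size Items per survey page; used as the response-time parcel
#'   size. Must divide `n_items`.
#'
#' @return An object of class `scale_design`.
#' @export
#'
#' @examples
#' d <- scale_design()
#' d$n_items
#' table(d$constructs)
scale_design <- function(n_items = 60, n_categories = 5,
                         constructs = NULL, reversed = NULL,
                         page_size = 10) {
  stopifnot(n_items >= 2, n_categories > 1, page_size >= 1)
  if (is.null(constructs)) {
    n_constructs <- if (n_items %% 6 == 0) 6L else 1L
    constructs <- rep_len(seq_len(n_constructs), n_items)
  }
  if (length(constructs) != n_items) {
    abort("`constructs` must have one entry per item.")
  }
  if (is.null(reversed)) {
    reversed <- logical(n_items)
    for (cc in unique(constructs)) {
      idx <- which(constructs == cc)
      reversed[idx[seq_along(idx) %% 2 == 0]] <- TRUE
    }
  }
  if (length(reversed) != n_items || !is.logical(reversed)) {
    abort("`reversed` must be a logical vector with one flag per item.")
  }
  if (n_items %% page_size != 0) {
    abort("`page_size` must divide `n_items`.")
  }
  structure(
    list(
      n_items = as.integer(n_items),
      n_categories = as.integer(n_categories),
      constructs = constructs,
      reversed = reversed,
      page_size = as.integer(page_size),
      item_ids = paste0("i", formatC(seq_len(n_items), width = 2, flag = "0"))
    ),
    class = "scale_design"
  )
}

#' @export
print.scale_design <- function(x, ...) {
  cat("<scale_design> ", x$n_items, " items, K = ", x$n_categories,
      ", ", length(unique(x$constructs)), " constructs, ",
      sum(x$reversed), " reverse-keyed, page size ", x$page_size, "\n",
      sep = "")
  invisible(x)
}

# coerce a wide tibble (id column + item columns) to a plain integer matrix
response_matrix <- function(data, design = NULL, id_col = ".id") {
  if (is.matrix(data)) {
    X <- data
  } else {
    data <- as_tibble(data)
    cols <- setdiff(names(data), id_col)
    X <- as.matrix(data[cols])
    if (id_col %in% names(data)) rownames(X) <- as.character(data[[id_col]])
  }
  storage.mode(X) <- "double"
  X
}

validate_responses <- function(X, design) {
  K <- design$n_categories
  if (ncol(X) != design$n_items) {
    abort(sprintf("Expected %d item columns, found %d.",
                  design$n_items, ncol(X)))
  }
  bad <- which(is.na(X), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("Missing response at row %d, column %d: responses must be complete.",
                  bad[1, 1], bad[1, 2]))
  }
  out <- which(X < 1 | X > K | X != round(X), arr.ind = TRUE)
  if (nrow(out) > 0) {
    abort(sprintf("Response out of range 1..%d at row %d, column %d (value %s).",
                  K, out[1, 1], out[1, 2], format(X[out[1, , drop = FALSE]])))
  }
  invisible(X)
}

responses_as_tibble <- function(X, design, ids = NULL) {
  if (is.null(ids)) ids <- rownames(X)
  if (is.null(ids)) ids <- paste0("r", seq_len(nrow(X)))
  colnames(X) <- design$item_ids
  bind_cols(tibble(.id = as.character(ids)),
            as_tibble(X, .name_repair = "minimal"))
}

#' Recode reverse-keyed items
#'
#' Maps responses on reverse-keyed items to `K + 1 - x`, leaving the other
#' items untouched. The mapping is its own inverse, so apply it exactly once;
#' applying it twice returns the original data.
#'
#' @param data Wide response data: a data frame with an `.id` column plus one
#'   column per item, or a plain numeric matrix.
#' @param design A [scale_design()].
#'
#' @return Object of the same shape as `data` with reverse-keyed items
#'   reflected.
#' @export
#'
#' @examples
#' d <- scale_design(n_items = 4, constructs = rep(1, 4),
#'                   reversed = c(FALSE, TRUE, FALSE, TRUE), page_size = 2)
#' m <- matrix(c(1, 2, 3, 4), nrow = 1)
#' recode_reversed(m, d)  # 1 4 3 2
recode_reversed <- function(data, design) {
  is_df <- is.data.frame(data)
  X <- response_matrix(data, design)
  validate_responses(X, design)
  K <- design$n_categories
  X[, design$reversed] <- K + 1 - X[, design$reversed]
  if (is_df) responses_as_tibble(X, design, ids = data$.id) else X
}
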