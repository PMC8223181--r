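# Internal helpers shared across modules.

# Sentinel used for category-wide indicators (one cell spanning all report
# items) in both the in-memory representation and the CSV dialect.
CATEGORY_WIDE <- "ALL"

indicator_id <- function(category, metric, item) {
  paste(category, metric, item, sep = ":")
}

#' Normalize a state name for joining
#'
#' Case-folds, trims, and collapses internal whitespace so that cosmetic
#' differences between data sources ("Tamil Nadu " vs "tamil nadu") do not
#' break joins between score tables and external index tables.
#'
#' @param x character vector of state names.
#' @return character vector of normalized names.
#' @keywords internal
normalize_state_name <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# Evaluate `expr` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
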