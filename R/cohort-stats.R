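#' Five-number summary of a score distribution
#'
#' Minimum, first quartile, median, third quartile and maximum. The
#' quartile convention defaults to linear interpolation between order
#' statistics (`stats::quantile()` type 7, the R default); the type is
#' exposed because published summaries do not always state which
#' convention produced them.
#'
#' @param values non-empty numeric vector.
#' @param type quantile algorithm type, 1-9 (see [stats::quantile()]).
#' @return named numeric vector `min`, `q1`, `median`, `q3`, `max`.
#' @examples
#' five_number_summary(c(0, 1))  # 0, 0.25, 0.5, 0.75, 1
#' @export
five_number_summary <- function(values, type = 7) {
  if (!length(values) || anyNA(values)) {
    stop("`values` must be non-empty with no missing values", call. = FALSE)
  }
  q <- stats::quantile(values, probs = c(0, 0.25, 0.5, 0.75, 1),
                       type = type, names = FALSE)
  stats::setNames(q, c("min", "q1", "median", "q3", "max"))
}

#' Rank states by CDRS
#'
#' Orders states by decreasing CDRS; ties are broken alphabetically by
#' state id, so the ranking is deterministic regardless of input order.
#'
#' @param scores tibble with columns `state` and `cdrs` (as returned by
#'   [score_cohort()]).
#' @return character vector of state ids, best first.
#' @export
rank_states <- function(scores) {
  if (!nrow(scores)) stop("no scores to rank", call. = FALSE)
  scores$state[order(-scores$cdrs, scores$state)]
}

#' Summarize a scored cohort
#'
#' Bundles the state count, the five-number summary of CDRS, the ranking
#' and the per-category median normalized scores (NAs from inapplicable
#' categories excluded).
#'
#' @param scores tibble from [score_cohort()].
#' @param type quartile convention for [five_number_summary()].
#' @return list with `n`, `five_number`, `ranking`, `category_medians`.
#' @export
cohort_summary <- function(scores, type = 7) {
  if (!nrow(scores)) stop("empty score table", call. = FALSE)
  cat_cols <- setdiff(names(scores), c("state", "cdrs"))
  medians <- vapply(cat_cols, function(cc) {
    stats::median(scores[[cc]], na.rm = TRUE)
  }, double(1))
  list(
    n = nrow(scores),
    five_number = five_number_summary(scores$cdrs, type = type),
    ranking = rank_states(scores),
    category_medians = medians
  )
}

#' Per-indicator reporting counts
#'
#' For each indicator of the framework, the number of states whose cell
#' value is at least 1 (i.e. the item is reported); NA and 0 cells do
#' not count. This reproduces the "number of states reporting an item"
#' table layout (metric rows by report-item columns).
#'
#' @param framework a `cdrs_framework`.
#' @param cohort a `cdrs_cohort`.
#' @return tibble `category`, `metric`, `item`, `id`, `n_reporting`.
#' @export
reporting_counts <- function(framework, cohort) {
  ind <- enumerate_indicators(framework)
  v <- cohort$values
  v_id <- indicator_id(v$category, v$metric, v$item)
  reported <- !is.na(v$value) & v$value >= 1
  tally <- table(factor(v_id[reported], levels = ind$id))
  tibble::tibble(category = ind$category, metric = ind$metric,
                 item = ind$item, id = ind$id,
                 n_reporting = as.integer(tally[ind$id]))
}

#' Correlate CDRS with an external index
#'
#' Joins a score table to an external index table on normalized state
#' names (inner join; unmatched names are listed in a warning) and
#' computes the Pearson product-moment correlation and Spearman's rank
#' correlation with two-sided p-values. Both p-values use the t
#' transform t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of
#' freedom (for Spearman this is the usual large-sample approximation,
#' adequate at cohort sizes of a few dozen; an exact permutation p-value
#' can be requested for small cohorts).
#'
#' @param scores tibble with `state` and `cdrs` columns.
#' @param index tibble with `state` and `index_value` columns (see
#'   [read_index_table()]).
#' @param n_perm if > 0, also compute seeded permutation p-values from
#'   this many permutations.
#' @param seed RNG seed for the permutation test.
#' @return list: `pearson_r`, `pearson_p`, `spearman_r`, `spearman_p`,
#'   `n_pairs`, and when requested `pearson_p_perm`, `spearman_p_perm`.
#' @export
correlate_index <- function(scores, index, n_perm = 0, seed = 1) {
  key_s <- normalize_state_name(scores$state)
  key_i <- normalize_state_name(index$state)
  matched <- intersect(key_s, key_i)
  unmatched <- c(setdiff(key_s, key_i), setdiff(key_i, key_s))
  if (length(unmatched)) {
    warning("states present on one side of the join only: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
  }
  n <- length(matched)
  if (n < 3) {
    stop("need at least 3 matched state pairs, got ", n, call. = FALSE)
  }
  x <- scores$cdrs[match(matched, key_s)]
  y <- index$index_value[match(matched, key_i)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in CDRS or index values; correlation undefined",
         call. = FALSE)
  }
  pear <- stats::cor.test(x, y, method = "pearson")
  # exact = FALSE selects the asymptotic t approximation for the
  # Spearman p-value, matching the Pearson t transform applied to rho.
  spear <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE)
  )
  out <- list(
    pearson_r = unname(pear$estimate), pearson_p = pear$p.value,
    spearman_r = unname(spear$estimate), spearman_p = spear$p.value,
    n_pairs = n
  )
  if (n_perm > 0) {
    out <- c(out, with_seed(seed, {
      rp <- abs(out$pearson_r)
      rs <- abs(out$spearman_r)
      hits_p <- 0L
      hits_s <- 0L
      ry <- rank(y)
      rx <- rank(x)
      for (i in seq_len(n_perm)) {
        perm <- sample.int(n)
        if (abs(stats::cor(x, y[perm])) >= rp - 1e-12) hits_p <- hits_p + 1L
        if (abs(stats::cor(rx, ry[perm])) >= rs - 1e-12) hits_s <- hits_s + 1L
      }
      list(pearson_p_perm = (hits_p + 1) / (n_perm + 1),
           spearman_p_perm = (hits_s + 1) / (n_perm + 1))
    }))
  }
  out
}
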