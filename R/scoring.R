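#' Scoring engine: category scores and the overall CDRS
#'
#' For a state s and category c, the category total T(c, s) is the sum of
#' the state's non-NA cell values in that category, and M(c, s) and
#' m(c, s) are the sums of the domain maxima and minima over the same
#' (applicable) cells. The normalized category score is
#' N(c, s) = T / (M - m), and the overall score is
#' CDRS(s) = sum_c T(c, s) / sum_c M(c, s), both NA-adjusted: cells
#' marked NA contribute to neither the numerator nor the bounds. With
#' the default rubric a privacy cell (domain \{-1, 1\}) normalizes to
#' +0.5 when privacy is respected and -0.5 when it is violated, and the
#' privacy-NA rule (privacy is inapplicable to states that report no
#' data) keeps CDRS within [0, 1].
#'
#' @name scoring
#' @keywords internal
NULL

# Extract one state's sheet (long tibble) from a cohort.
cohort_sheet <- function(cohort, state) {
  cohort$values[cohort$values$state == state, ]
}

#' Is the privacy indicator applicable to a sheet?
#'
#' Privacy does not apply to a state that reports no data at all: if
#' every non-privacy cell is 0 or NA, the privacy cell is treated as NA
#' in all downstream sums.
#'
#' @param framework a `cdrs_framework`.
#' @param sheet one state's cells: tibble with `category`, `metric`,
#'   `item`, `value`.
#' @return `TRUE` if any non-privacy cell has a value >= 1.
#' @export
privacy_applicable <- function(framework, sheet) {
  priv_cat <- framework$roles$privacy_category
  if (is.null(priv_cat)) return(TRUE)
  other <- sheet$value[sheet$category != priv_cat]
  any(!is.na(other) & other >= 1)
}

# Apply the privacy-NA rule to a sheet, warning when the recorded value
# contradicts the derivation (the rule is derived from sheet content,
# never trusted from the input file).
enforce_privacy_na <- function(framework, sheet, state = "?") {
  priv_cat <- framework$roles$privacy_category
  if (is.null(priv_cat) || !any(sheet$category == priv_cat)) return(sheet)
  applicable <- privacy_applicable(framework, sheet)
  priv_rows <- sheet$category == priv_cat
  if (!applicable && any(!is.na(sheet$value[priv_rows]))) {
    warning("state ", state, ": privacy cell has a value but the state ",
            "reports no data; treating privacy as NA", call. = FALSE)
    sheet$value[priv_rows] <- NA_integer_
  }
  if (applicable && all(is.na(sheet$value[priv_rows]))) {
    warning("state ", state, ": privacy cell is NA but the state reports ",
            "data; privacy should be scored", call. = FALSE)
  }
  sheet
}

#' Score one category of one sheet
#'
#' Computes the NA-adjusted category total T, bounds M and m, and the
#' normalized score N = T / (M - m) for a single category. Cells absent
#' from the sheet are treated as NA (inapplicable). If no cell in the
#' category is applicable, T, M and m are 0 and N is NA.
#'
#' @param framework a `cdrs_framework`.
#' @param sheet one state's cells (see [privacy_applicable()]), with the
#'   privacy-NA rule already applied if desired.
#' @param category category name.
#' @return one-row tibble: `category`, `T`, `M`, `m`, `N`.
#' @examples
#' fw <- default_framework()
#' sheet <- perfect_sheet(fw)
#' category_score(fw, sheet, "privacy")  # N = 0.5
#' @export
category_score <- function(framework, sheet, category) {
  ind <- enumerate_indicators(framework, category)
  sheet_ids <- indicator_id(sheet$category, sheet$metric, sheet$item)
  val <- sheet$value[match(ind$id, sheet_ids)]  # absent cells -> NA
  ok <- !is.na(val)
  T_ <- sum(val[ok])
  M_ <- sum(ind$dmax[ok])
  m_ <- sum(ind$dmin[ok])
  N_ <- if (any(ok) && M_ > m_) T_ / (M_ - m_) else NA_real_
  tibble::tibble(category = category, T = as.integer(T_),
                 M = as.integer(M_), m = as.integer(m_), N = N_)
}

#' Score one state: per-category scores and CDRS
#'
#' Applies the privacy-NA rule, scores every category, and computes
#' CDRS = sum(T) / sum(M) over the applicable cells of all categories.
#' Integer totals and bounds are kept exact; the single division comes
#' last.
#'
#' @param framework a `cdrs_framework`.
#' @param sheet one state's cells.
#' @param state state label used in messages.
#' @return list with `state`, `per_category` (tibble of T/M/m/N rows) and
#'   `cdrs`.
#' @examples
#' fw <- default_framework()
#' cdrs_score(fw, perfect_sheet(fw))$cdrs  # 1
#' @export
cdrs_score <- function(framework, sheet, state = "state") {
  sheet <- enforce_privacy_na(framework, sheet, state)
  cats <- unique(framework$indicators$category)
  per_cat <- do.call(rbind, lapply(cats, function(cc) {
    category_score(framework, sheet, cc)
  }))
  sumM <- sum(per_cat$M)
  if (sumM == 0 && all(is.na(per_cat$N))) {
    stop("state ", state, ": no applicable cells, CDRS undefined",
         call. = FALSE)
  }
  score <- sum(per_cat$T) / sumM
  if (score < 0 || score > 1) {
    warning("state ", state, ": CDRS ", format(score),
            " outside [0, 1]; the rubric permits scores the privacy-NA ",
            "rule normally rules out", call. = FALSE)
  }
  list(state = state, per_category = per_cat, cdrs = score)
}

#' Score every state of a cohort
#'
#' Scores each sheet independently, preserving cohort order. Per-state
#' scoring failures are collected and reported at the end rather than
#' aborting the whole cohort.
#'
#' @param framework a `cdrs_framework`.
#' @param cohort a `cdrs_cohort`.
#' @return tibble with one row per state: `state`, one `N` column per
#'   category (named by category), and `cdrs`.
#' @export
score_cohort <- function(framework, cohort) {
  states <- unique(cohort$values$state)
  cats <- unique(framework$indicators$category)
  failures <- character()
  rows <- lapply(states, function(s) {
    res <- tryCatch(cdrs_score(framework, cohort_sheet(cohort, s), s),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures <<- c(failures, res)
      return(NULL)
    }
    ncol_vals <- stats::setNames(as.list(res$per_category$N),
                                 res$per_category$category)
    tibble::as_tibble(c(list(state = s), ncol_vals, list(cdrs = res$cdrs)))
  })
  if (length(failures)) {
    warning("scoring failed for ", length(failures), " state(s):\n  ",
            paste(failures, collapse = "\n  "), call. = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    cols <- c(list(state = character()),
              stats::setNames(rep(list(double()), length(cats)), cats),
              list(cdrs = double()))
    return(tibble::as_tibble(cols))
  }
  do.call(rbind, rows)
}

#' Validate a cohort against a framework
#'
#' Semantic checks beyond the parse-level validation done by
#' [read_cohort()]: missing cells, NA placement (NA is only legitimate
#' on district cells of a state without districts, and on the privacy
#' cell of a state that reports no data), and district cells that
#' contradict the metadata.
#'
#' @param framework a `cdrs_framework`.
#' @param cohort a `cdrs_cohort`.
#' @return tibble of diagnostics: `state`, `cell`, `severity`, `message`;
#'   zero rows if the cohort is clean.
#' @export
validate_cohort <- function(framework, cohort) {
  ind <- framework$indicators
  district_metric <- framework$roles$district_metric
  priv_cat <- framework$roles$privacy_category
  diags <- list()
  add <- function(state, cell, severity, message) {
    diags[[length(diags) + 1L]] <<- tibble::tibble(
      state = state, cell = cell, severity = severity, message = message
    )
  }
  for (s in unique(cohort$values$state)) {
    sheet <- cohort_sheet(cohort, s)
    sheet_ids <- indicator_id(sheet$category, sheet$metric, sheet$item)
    missing <- setdiff(ind$id, sheet_ids)
    for (id in missing) add(s, id, "info", "cell absent from sheet")
    meta <- cohort$meta[cohort$meta$state == s, ]
    has_districts <- if (nrow(meta)) meta$has_districts else TRUE
    if (!is.null(district_metric)) {
      d_rows <- sheet$metric == district_metric
      if (!has_districts && any(!is.na(sheet$value[d_rows]))) {
        add(s, sheet_ids[d_rows & !is.na(sheet$value)][1], "warning",
            "district cell scored for a state without districts")
      }
      if (has_districts && any(is.na(sheet$value[d_rows]))) {
        add(s, sheet_ids[d_rows & is.na(sheet$value)][1], "warning",
            "district cell NA for a state with districts")
      }
    }
    if (!is.null(priv_cat)) {
      applicable <- privacy_applicable(framework, sheet)
      priv_rows <- sheet$category == priv_cat
      if (any(priv_rows)) {
        priv_na <- all(is.na(sheet$value[priv_rows]))
        if (!applicable && !priv_na) {
          add(s, sheet_ids[priv_rows][1], "warning",
              "privacy scored for a state that reports no data")
        }
        if (applicable && priv_na) {
          add(s, sheet_ids[priv_rows][1], "warning",
              "privacy NA for a state that reports data")
        }
      }
    }
    non_special <- !(sheet$metric %in% district_metric) &
      !(sheet$category %in% priv_cat)
    stray_na <- non_special & is.na(sheet$value)
    if (any(stray_na)) {
      for (id in sheet_ids[stray_na]) {
        add(s, id, "warning",
            "NA on a cell with no inapplicability rule")
      }
    }
  }
  if (!length(diags)) {
    return(tibble::tibble(state = character(), cell = character(),
                          severity = character(), message = character()))
  }
  do.call(rbind, diags)
}

#' Construct reference sheets
#'
#' `perfect_sheet()` builds a sheet with every applicable cell at its
#' domain maximum (patient-level death comorbidities, no privacy
#' violation): the best attainable reporting, CDRS = 1. `empty_sheet()`
#' builds a sheet with every cell at its domain minimum-of-zero and the
#' privacy cell NA: a state that reports nothing, CDRS = 0.
#'
#' @param framework a `cdrs_framework`.
#' @param state state label for the generated rows.
#' @return tibble in sheet layout (`state`, `category`, `metric`, `item`,
#'   `value`).
#' @export
perfect_sheet <- function(framework, state = "perfect") {
  ind <- enumerate_indicators(framework)
  tibble::tibble(state = state, category = ind$category,
                 metric = ind$metric, item = ind$item,
                 value = ind$dmax)
}

#' @rdname perfect_sheet
#' @export
empty_sheet <- function(framework, state = "empty") {
  ind <- enumerate_indicators(framework)
  priv_cat <- framework$roles$privacy_category
  value <- rep(0L, nrow(ind))
  if (!is.null(priv_cat)) {
    value[ind$category == priv_cat] <- NA_integer_
  }
  tibble::tibble(state = state, category = ind$category,
                 metric = ind$metric, item = ind$item, value = value)
}
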