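#' Cohort tables: scoring sheets plus state metadata
#'
#' A cohort bundles the per-state scoring sheets (one integer or NA per
#' rubric cell) with per-state metadata (whether the state has districts,
#' and its cumulative confirmed-case count at the study cutoff, used by
#' the inclusion filter).
#'
#' @param values tibble with columns `state`, `category`, `metric`,
#'   `item`, `value` (integer or NA), one row per scored cell.
#' @param meta tibble with columns `state`, `has_districts` (logical),
#'   `confirmed_at_cutoff` (non-negative integer). Defaults to all states
#'   having districts and an unknown (NA) case count.
#' @return a `cdrs_cohort` object.
#' @export
new_cohort <- function(values, meta = NULL) {
  values <- tibble::as_tibble(values)
  needed <- c("state", "category", "metric", "item", "value")
  if (!all(needed %in% names(values))) {
    stop("cohort values need columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  values$value <- as.integer(values$value)
  states <- unique(values$state)
  if (is.null(meta)) {
    meta <- tibble::tibble(state = states, has_districts = TRUE,
                           confirmed_at_cutoff = NA_integer_)
  }
  meta <- tibble::as_tibble(meta)
  if (anyDuplicated(meta$state)) {
    stop("duplicate state in metadata: ",
         paste(unique(meta$state[duplicated(meta$state)]), collapse = ", "),
         call. = FALSE)
  }
  missing_meta <- setdiff(states, meta$state)
  if (length(missing_meta)) {
    stop("states without metadata: ", paste(missing_meta, collapse = ", "),
         call. = FALSE)
  }
  structure(list(values = values, meta = meta), class = "cdrs_cohort")
}

#' @export
print.cdrs_cohort <- function(x, ...) {
  cat(sprintf("<cdrs_cohort: %d states, %d cells>\n",
              length(unique(x$values$state)), nrow(x$values)))
  invisible(x)
}

#' Read a cohort of scoring sheets
#'
#' Reads per-state scoring sheets from a long-format CSV with header
#' `state,category,metric,report_item,value` (category-wide indicators
#' use `report_item=ALL`; the NA token is the literal string `NA`) and,
#' optionally, a state-metadata CSV with header
#' `state,has_districts,confirmed_at_cutoff`. Every row is validated
#' against the framework: unknown cells, structurally inapplicable cells
#' and out-of-domain values are errors naming the offending line.
#'
#' @param values_path path to the scoring-sheet CSV.
#' @param meta_path optional path to the state-metadata CSV.
#' @param framework a `cdrs_framework` (default: [default_framework()]).
#' @return a `cdrs_cohort`.
#' @export
read_cohort <- function(values_path, meta_path = NULL,
                        framework = default_framework()) {
  if (!file.exists(values_path)) {
    stop("scoring-sheet file not found: ", values_path, call. = FALSE)
  }
  raw <- utils::read.csv(values_path, colClasses = "character",
                         na.strings = character(), check.names = FALSE)
  expected <- c("state", "category", "metric", "report_item", "value")
  if (!identical(names(raw), expected)) {
    stop("scoring-sheet header must be `", paste(expected, collapse = ","),
         "`, got `", paste(names(raw), collapse = ","), "`", call. = FALSE)
  }
  ind <- framework$indicators
  if (nrow(raw)) {
    line <- seq_len(nrow(raw)) + 1L  # header is line 1
    id <- indicator_id(raw$category, raw$metric, raw$report_item)
    unknown <- !(id %in% ind$id)
    if (any(unknown)) {
      sna_key <- paste(framework$structural_na$metric,
                       framework$structural_na$item, sep = ":")
      is_sna <- unknown &
        paste(raw$metric, raw$report_item, sep = ":") %in% sna_key
      if (any(is_sna)) {
        stop("line ", line[is_sna][1], ": cell ", id[is_sna][1],
             " is structurally inapplicable (a dash in the rubric) and ",
             "must not appear in a scoring sheet", call. = FALSE)
      }
      stop("line ", line[unknown][1], ": unknown indicator ",
           id[unknown][1], call. = FALSE)
    }
    is_na <- raw$value == "NA"
    num <- suppressWarnings(as.integer(raw$value))
    malformed <- !is_na & is.na(num)
    if (any(malformed)) {
      stop("line ", line[malformed][1], ": malformed value `",
           raw$value[malformed][1], "` for ", id[malformed][1],
           call. = FALSE)
    }
    dom <- ind$domain[match(id, ind$id)]
    in_dom <- mapply(function(v, d) is.na(v) || v %in% d, num, dom)
    if (!all(in_dom)) {
      bad <- which(!in_dom)[1]
      stop("line ", line[bad], ": value ", num[bad],
           " outside domain {", paste(dom[[bad]], collapse = ","),
           "} for cell ", id[bad], " of state ", raw$state[bad],
           call. = FALSE)
    }
    dup <- duplicated(paste(raw$state, id))
    if (any(dup)) {
      stop("line ", line[dup][1], ": duplicate cell ", id[dup][1],
           " for state ", raw$state[dup][1], call. = FALSE)
    }
    values <- tibble::tibble(state = raw$state, category = raw$category,
                             metric = raw$metric, item = raw$report_item,
                             value = num)
  } else {
    values <- tibble::tibble(state = character(), category = character(),
                             metric = character(), item = character(),
                             value = integer())
  }
  meta <- if (!is.null(meta_path)) read_state_meta(meta_path) else NULL
  new_cohort(values, meta)
}

#' Read a state-metadata table
#'
#' @param path CSV with header `state,has_districts,confirmed_at_cutoff`.
#' @return tibble with typed columns.
#' @export
read_state_meta <- function(path) {
  if (!file.exists(path)) {
    stop("state-metadata file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(), check.names = FALSE)
  expected <- c("state", "has_districts", "confirmed_at_cutoff")
  if (!identical(names(raw), expected)) {
    stop("state-metadata header must be `", paste(expected, collapse = ","),
         "`", call. = FALSE)
  }
  hd <- tolower(raw$has_districts) %in% c("true", "1", "yes")
  bad_hd <- !(tolower(raw$has_districts) %in%
                c("true", "false", "1", "0", "yes", "no"))
  if (any(bad_hd)) {
    stop("line ", which(bad_hd)[1] + 1L, ": has_districts must be boolean, ",
         "got `", raw$has_districts[bad_hd][1], "`", call. = FALSE)
  }
  # the literal token NA means the count is unknown for that state
  count <- suppressWarnings(as.integer(raw$confirmed_at_cutoff))
  bad <- (is.na(count) & raw$confirmed_at_cutoff != "NA") |
    (!is.na(count) & count < 0)
  if (any(bad)) {
    i <- which(bad)[1]
    stop("line ", i + 1L, ": confirmed_at_cutoff must be a non-negative ",
         "integer or NA, got `", raw$confirmed_at_cutoff[i], "`",
         call. = FALSE)
  }
  tibble::tibble(state = raw$state, has_districts = hd,
                 confirmed_at_cutoff = count)
}

#' Write a cohort to CSV
#'
#' Emits the long-format scoring-sheet CSV (and optionally the
#' state-metadata CSV) in the dialect read by [read_cohort()]. NA cells
#' are written as the literal token `NA`; reading the files back yields
#' an identical cohort.
#'
#' @param cohort a `cdrs_cohort`.
#' @param values_path output path for the scoring sheet CSV.
#' @param meta_path optional output path for the metadata CSV.
#' @return `values_path`, invisibly.
#' @export
write_cohort <- function(cohort, values_path, meta_path = NULL) {
  v <- cohort$values
  out <- data.frame(state = v$state, category = v$category,
                    metric = v$metric, report_item = v$item,
                    value = ifelse(is.na(v$value), "NA",
                                   as.character(v$value)),
                    check.names = FALSE)
  utils::write.csv(out, values_path, row.names = FALSE, quote = FALSE)
  if (!is.null(meta_path)) {
    m <- cohort$meta
    out_m <- data.frame(state = m$state,
                        has_districts = ifelse(m$has_districts, "true",
                                               "false"),
                        confirmed_at_cutoff = m$confirmed_at_cutoff)
    utils::write.csv(out_m, meta_path, row.names = FALSE, quote = FALSE)
  }
  invisible(values_path)
}

#' Apply the cohort inclusion filter
#'
#' States reporting fewer than `threshold` cumulative confirmed cases at
#' the study cutoff are excluded from assessment; a state at exactly the
#' threshold is included ("less than" is strict). Order is preserved.
#'
#' @param meta tibble with at least `state` and `confirmed_at_cutoff`.
#' @param threshold non-negative integer; default 10.
#' @return character vector of included state ids.
#' @export
apply_inclusion_filter <- function(meta, threshold = 10L) {
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  if (anyNA(meta$confirmed_at_cutoff)) {
    stop("confirmed_at_cutoff is unknown (NA) for: ",
         paste(meta$state[is.na(meta$confirmed_at_cutoff)],
               collapse = ", "), call. = FALSE)
  }
  meta$state[meta$confirmed_at_cutoff >= threshold]
}

#' Read an external development-index table
#'
#' Reads a two-column CSV (`state,index_value`) such as a state-level
#' SDG health-index table on the 0-100 scale. Values outside [0, 100]
#' and duplicate states are errors.
#'
#' @param path path to the index CSV.
#' @return tibble with columns `state`, `index_value`.
#' @export
read_index_table <- function(path) {
  if (!file.exists(path)) {
    stop("index file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(), check.names = FALSE)
  expected <- c("state", "index_value")
  if (!identical(names(raw), expected)) {
    stop("index header must be `state,index_value`", call. = FALSE)
  }
  if (!nrow(raw)) {
    return(tibble::tibble(state = character(), index_value = double()))
  }
  val <- suppressWarnings(as.numeric(raw$index_value))
  if (anyNA(val)) {
    bad <- which(is.na(val))[1]
    stop("line ", bad + 1L, ": malformed index value `",
         raw$index_value[bad], "`", call. = FALSE)
  }
  out_of_range <- val < 0 | val > 100
  if (any(out_of_range)) {
    bad <- which(out_of_range)[1]
    stop("line ", bad + 1L, ": index value ", val[bad],
         " outside [0, 100] for state ", raw$state[bad], call. = FALSE)
  }
  dup <- duplicated(normalize_state_name(raw$state))
  if (any(dup)) {
    stop("duplicate state in index table: ", raw$state[dup][1],
         call. = FALSE)
  }
  tibble::tibble(state = raw$state, index_value = val)
}
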