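#' Scoring frameworks: the rubric as data
#'
#' A scoring framework declares the indicator rubric used to assess the
#' quality of public-health data reporting: which categories exist, which
#' metric/report-item cells are scoreable, which integer values each cell
#' may take, and which cells are structurally inapplicable (dashes in the
#' rubric). The default framework carries 45 indicators over four
#' categories — availability (15), accessibility (12), granularity (17)
#' and privacy (1) — spanning five report items (confirmed, deaths,
#' recovered, quarantine, ICU). Because the rubric is data, alternative
#' rubrics (for example a district-level adaptation) can be loaded from a
#' schema file without code changes.
#'
#' @name framework
#' @keywords internal
NULL

#' Construct a scoring framework from an indicator table
#'
#' Low-level constructor for custom rubrics. Most users will load a
#' rubric from a schema file with [read_framework()] instead.
#'
#' @param indicators data frame with columns `category`, `metric`,
#'   `item` and `domain` (a list column of integer vectors of allowed
#'   cell values).
#' @param structural_na data frame with columns `metric`, `item` listing
#'   cells that are structurally inapplicable.
#' @param roles named list of special-cell roles: `district_metric` (the
#'   metric whose cells are inapplicable to states without districts)
#'   and `privacy_category` (the category governed by the privacy-NA
#'   rule). May be empty.
#' @param name,version identification strings carried into provenance
#'   output.
#' @return a `cdrs_framework`.
#' @export
new_framework <- function(indicators,
                          structural_na = tibble::tibble(
                            metric = character(), item = character()),
                          roles = list(),
                          name = "custom", version = "0") {
  stopifnot(is.data.frame(indicators))
  indicators <- tibble::as_tibble(indicators)
  indicators$domain <- lapply(indicators$domain, function(d) sort(as.integer(d)))
  # empty domains are caught by validate_framework(), not here
  safe_bound <- function(f) {
    function(d) if (length(d)) f(d) else NA_integer_
  }
  indicators$dmin <- vapply(indicators$domain, safe_bound(min), integer(1))
  indicators$dmax <- vapply(indicators$domain, safe_bound(max), integer(1))
  indicators$id <- indicator_id(indicators$category, indicators$metric,
                                indicators$item)
  structure(
    list(
      name = name,
      version = version,
      indicators = indicators,
      structural_na = tibble::as_tibble(structural_na),
      roles = roles
    ),
    class = "cdrs_framework"
  )
}

#' @export
print.cdrs_framework <- function(x, ...) {
  counts <- table(x$indicators$category)
  cat(sprintf("<cdrs_framework '%s' v%s>\n", x$name, x$version))
  cat(sprintf("  %d indicators: %s\n", nrow(x$indicators),
              paste(sprintf("%s=%d", names(counts), counts), collapse = ", ")))
  cat(sprintf("  %d structural-NA cells\n", nrow(x$structural_na)))
  invisible(x)
}

#' Read a scoring framework from a schema file
#'
#' Parses a YAML rubric schema (categories, metrics, report items, allowed
#' cell values, structural-NA cells) into a framework object. The schema
#' dialect is the one used by the packaged default rubric; see
#' `system.file("extdata", "framework_default.yaml", package = "cdrscore")`
#' for a commented example.
#'
#' @param path path to a YAML schema file.
#' @return a `cdrs_framework` object.
#' @seealso [default_framework()], [validate_framework()]
#' @export
read_framework <- function(path) {
  if (!file.exists(path)) {
    stop("framework schema file not found: ", path, call. = FALSE)
  }
  sch <- yaml::read_yaml(path)
  report_items <- as.character(sch$report_items)
  rows <- list()
  for (cat_name in names(sch$categories)) {
    for (m in sch$categories[[cat_name]]) {
      items <- m$items
      if (identical(items, "category-wide")) {
        items <- CATEGORY_WIDE
      } else if (identical(items, "all")) {
        items <- report_items
      } else {
        items <- as.character(items)
      }
      overrides <- m$domain_overrides %||% list()
      for (it in items) {
        dom <- overrides[[it]] %||% m$domain
        rows[[length(rows) + 1L]] <- tibble::tibble(
          category = cat_name, metric = m$metric, item = it,
          domain = list(as.integer(dom))
        )
      }
    }
  }
  indicators <- do.call(rbind, rows)
  sna <- sch$structural_na %||% list()
  structural_na <- if (length(sna)) {
    tibble::tibble(
      metric = vapply(sna, function(p) p$metric, character(1)),
      item = vapply(sna, function(p) p$item, character(1))
    )
  } else {
    tibble::tibble(metric = character(), item = character())
  }
  fw <- new_framework(indicators, structural_na,
                      roles = sch$roles %||% list(),
                      name = sch$name %||% basename(path),
                      version = as.character(sch$version %||% "0"))
  diags <- validate_framework(fw)
  if (length(diags)) {
    stop("invalid framework schema:\n  ", paste(diags, collapse = "\n  "),
         call. = FALSE)
  }
  fw
}

#' Write a scoring framework to a schema file
#'
#' Serializes a framework back to the YAML schema dialect read by
#' [read_framework()]. Round-tripping preserves categories, metrics,
#' items, cell domains and structural-NA cells.
#'
#' @param framework a `cdrs_framework`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_framework <- function(framework, path) {
  ind <- framework$indicators
  cats <- list()
  for (cat_name in unique(ind$category)) {
    sub <- ind[ind$category == cat_name, ]
    metrics <- list()
    for (m in unique(sub$metric)) {
      cells <- sub[sub$metric == m, ]
      doms <- cells$domain
      keys <- vapply(doms, paste, character(1), collapse = ",")
      base_dom <- doms[[match(names(sort(table(keys), decreasing = TRUE))[1],
                              keys)]]
      entry <- list(metric = m)
      if (identical(cells$item, CATEGORY_WIDE)) {
        entry$items <- "category-wide"
      } else {
        entry$items <- as.list(cells$item)
      }
      entry$domain <- as.list(base_dom)
      ov <- cells[vapply(cells$domain, function(d) !identical(d, base_dom),
                         logical(1)), ]
      if (nrow(ov)) {
        entry$domain_overrides <- stats::setNames(
          lapply(ov$domain, as.list), ov$item
        )
      }
      metrics[[length(metrics) + 1L]] <- entry
    }
    cats[[cat_name]] <- metrics
  }
  sch <- list(
    name = framework$name,
    version = framework$version,
    report_items = as.list(setdiff(unique(ind$item), CATEGORY_WIDE)),
    categories = cats,
    structural_na = if (nrow(framework$structural_na)) {
      lapply(seq_len(nrow(framework$structural_na)), function(i) {
        list(metric = framework$structural_na$metric[i],
             item = framework$structural_na$item[i])
      })
    },
    roles = framework$roles
  )
  sch <- Filter(Negate(is.null), sch)
  yaml::write_yaml(sch, path)
  invisible(path)
}

.framework_cache <- new.env(parent = emptyenv())

#' The default 45-indicator scoring rubric
#'
#' Returns the packaged rubric: availability (total/daily/historical over
#' five report items), accessibility (ease of access and English
#' availability as category-wide cells, plus total and daily trend
#' graphics over five items), granularity (age/gender/comorbidity
#' stratification over four items — quarantine is a structural dash — and
#' district stratification over five items) and a single category-wide
#' privacy cell with domain \{-1, 1\}. All other cells have domain
#' \{0, 1\}, except deaths-by-comorbidities whose domain \{0, 1, 2\}
#' grants an extra point when patient-specific comorbidities are
#' reported.
#'
#' @return a `cdrs_framework` with 45 indicators.
#' @examples
#' fw <- default_framework()
#' nrow(fw$indicators)   # 45
#' max_min_points(fw)    # c(max = 46, min = -1)
#' @export
default_framework <- function() {
  if (is.null(.framework_cache$default)) {
    path <- system.file("extdata", "framework_default.yaml",
                        package = "cdrscore", mustWork = TRUE)
    .framework_cache$default <- read_framework(path)
  }
  .framework_cache$default
}

#' Enumerate the indicators of a framework
#'
#' Lists the scoreable cells of a framework in a deterministic order:
#' categories, then metrics, then report items, each in rubric
#' declaration order. Structural-NA cells are never listed.
#'
#' @param framework a `cdrs_framework`.
#' @param category a single category name, or `"all"` (default).
#' @return a tibble with columns `category`, `metric`, `item`, `domain`
#'   (list of allowed integers), `dmin`, `dmax`, `id`.
#' @export
enumerate_indicators <- function(framework, category = "all") {
  ind <- framework$indicators
  if (!identical(category, "all")) {
    if (!category %in% ind$category) {
      stop("unknown category: ", category, call. = FALSE)
    }
    ind <- ind[ind$category == category, ]
  }
  ind
}

#' Maximum and minimum attainable points
#'
#' Sums the domain maxima and minima of a set of applicable indicators.
#' These are the M and m bounds that enter the normalized category score
#' N = T / (M - m) and the CDRS denominator.
#'
#' @param framework a `cdrs_framework`.
#' @param applicable character vector of indicator ids (the `id` column of
#'   [enumerate_indicators()]), or `NULL` for all indicators.
#' @return named numeric vector `c(max = , min = )`.
#' @export
max_min_points <- function(framework, applicable = NULL) {
  ind <- framework$indicators
  if (!is.null(applicable)) {
    missing <- setdiff(applicable, ind$id)
    if (length(missing)) {
      stop("indicator(s) not in framework: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    ind <- ind[ind$id %in% applicable, ]
  }
  c(max = sum(ind$dmax), min = sum(ind$dmin))
}

#' Validate a framework's structural invariants
#'
#' Checks that every cell has a non-empty integer domain, that no cell is
#' declared twice (which would assign it to two categories), that
#' structural-NA cells carry no domain, and that report-item and category
#' names are well formed. Diagnostics are returned, not thrown, so a
#' schema author can see every problem at once.
#'
#' @param framework a `cdrs_framework`.
#' @return character vector of diagnostics; empty if the framework is
#'   valid.
#' @export
validate_framework <- function(framework) {
  diags <- character()
  ind <- framework$indicators
  empty <- vapply(ind$domain, length, integer(1)) == 0L
  if (any(empty)) {
    diags <- c(diags, paste0("empty domain for cell ", ind$id[empty]))
  }
  key <- paste(ind$metric, ind$item, sep = ":")
  dup <- duplicated(key)
  if (any(dup)) {
    diags <- c(diags, paste0(
      "cell declared more than once (possibly in two categories): ",
      key[dup]
    ))
  }
  if (nrow(framework$structural_na)) {
    sna_key <- paste(framework$structural_na$metric,
                     framework$structural_na$item, sep = ":")
    clash <- intersect(sna_key, key)
    if (length(clash)) {
      diags <- c(diags, paste0(
        "structural-NA cell also has a domain: ", clash
      ))
    }
  }
  bad_min <- !is.na(ind$dmin) & !is.na(ind$dmax) & ind$dmin > ind$dmax
  if (any(bad_min)) {
    diags <- c(diags, paste0("domain min > max for cell ", ind$id[bad_min]))
  }
  diags
}
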