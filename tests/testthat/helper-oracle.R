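# Independent brute-force scoring oracle and random-case generators.
#
# The oracle walks every framework cell with plain loops and per-cell
# lookups, accumulating T (total), M (sum of domain maxima) and m (sum of
# domain minima) over the non-NA cells of each category, then divides
# once. It shares no code with the scoring engine.

oracle_state_score <- function(framework, sheet) {
  ind <- framework$indicators
  cats <- unique(ind$category)
  per_category <- list()
  sum_T <- 0
  sum_M <- 0
  for (cc in cats) {
    T_ <- 0
    M_ <- 0
    m_ <- 0
    any_cell <- FALSE
    for (i in seq_len(nrow(ind))) {
      if (ind$category[i] != cc) next
      hit <- which(sheet$category == ind$category[i] &
                     sheet$metric == ind$metric[i] &
                     sheet$item == ind$item[i])
      v <- if (length(hit)) sheet$value[hit[1]] else NA_integer_
      if (is.na(v)) next
      any_cell <- TRUE
      T_ <- T_ + v
      M_ <- M_ + max(ind$domain[[i]])
      m_ <- m_ + min(ind$domain[[i]])
    }
    N_ <- if (any_cell && M_ > m_) T_ / (M_ - m_) else NA_real_
    per_category[[cc]] <- c(T = T_, M = M_, m = m_, N = N_)
    sum_T <- sum_T + T_
    sum_M <- sum_M + M_
  }
  list(per_category = per_category,
       cdrs = if (sum_M > 0) sum_T / sum_M else NA_real_)
}

# Small random framework with globally unique metric names and integer
# domains of 2-4 values drawn from -1..3. No privacy/district roles, so
# scores follow the plain NA-adjusted arithmetic.
random_framework <- function() {
  rows <- list()
  for (ci in seq_len(sample(2:4, 1))) {
    cat_name <- paste0("cat", ci)
    for (mi in seq_len(sample(1:3, 1))) {
      metric <- paste0("c", ci, "m", mi)
      for (it in paste0("item", seq_len(sample(1:4, 1)))) {
        # at least one positive value so the attainable maximum is > 0
        dom <- sort(unique(c(sample(1:3, 1),
                             sample(-1:3, sample(1:3, 1)))))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          category = cat_name, metric = metric, item = it,
          domain = list(as.integer(dom))
        )
      }
    }
  }
  new_framework(do.call(rbind, rows),
                structural_na = tibble::tibble(metric = character(),
                                               item = character()),
                roles = list(), name = "random")
}

# Random sheet for a framework: each cell drawn uniformly from its
# domain, a fraction of cells NA.
random_sheet <- function(framework, state = "s1", na_rate = 0.15) {
  ind <- framework$indicators
  value <- vapply(ind$domain, function(d) d[sample.int(length(d), 1)],
                  integer(1))
  value[stats::runif(nrow(ind)) < na_rate] <- NA_integer_
  if (all(is.na(value))) {  # keep at least one applicable cell
    i <- sample.int(nrow(ind), 1)
    value[i] <- ind$domain[[i]][1]
  }
  tibble::tibble(state = state, category = ind$category,
                 metric = ind$metric, item = ind$item, value = value)
}

# Random sheet for the default rubric that satisfies every NA-placement
# rule: district cells NA only for no-district states, privacy NA
# exactly when the state reports nothing.
random_valid_sheet <- function(framework, state = "s1",
                               has_districts = TRUE, p_report = 0.5) {
  ind <- framework$indicators
  priv_cat <- framework$roles$privacy_category
  district_metric <- framework$roles$district_metric
  value <- integer(nrow(ind))
  for (i in seq_len(nrow(ind))) {
    if (!is.null(priv_cat) && ind$category[i] == priv_cat) {
      value[i] <- NA_integer_  # filled after derivation below
    } else if (!has_districts && !is.null(district_metric) &&
                 ind$metric[i] == district_metric) {
      value[i] <- NA_integer_
    } else {
      d <- ind$domain[[i]]
      value[i] <- if (stats::runif(1) < p_report) max(d) else min(d)
    }
  }
  if (!is.null(priv_cat)) {
    non_priv <- ind$category != priv_cat
    reports <- any(!is.na(value[non_priv]) & value[non_priv] >= 1)
    value[!non_priv] <- if (reports) sample(c(-1L, 1L), 1) else NA_integer_
  }
  tibble::tibble(state = state, category = ind$category,
                 metric = ind$metric, item = ind$item, value = value)
}

# Random multi-state cohort for a role-free framework (used by the
# round-trip and tally properties).
random_cohort <- function(framework, n_states = 5) {
  sheets <- lapply(seq_len(n_states), function(i) {
    random_sheet(framework, state = sprintf("st%02d", i))
  })
  new_cohort(do.call(rbind, sheets))
}
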