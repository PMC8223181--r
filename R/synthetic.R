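#' Configuration for the synthetic-cohort generator
#'
#' The generator plants a simple quality structure: each state draws a
#' quality tier, and every applicable non-privacy cell is then an
#' independent Bernoulli draw at the tier's reporting probability.
#' Defaults emulate a cohort like the one assessed in the Indian
#' COVID-19 reporting study: about 29 states with strongly dispersed
#' quality (a couple of silent states, a broad middle, a handful of
#' dashboard-grade reporters), occasional privacy violations, and an
#' occasional state without districts.
#'
#' @param n_states number of states to generate.
#' @param tier_probs named numeric vector: per-indicator reporting
#'   probability of each quality tier, each in [0, 1].
#' @param tier_weights sampling weights over tiers (same names as
#'   `tier_probs`); normalized to sum to 1.
#' @param privacy_violation_rate probability that a data-reporting state
#'   violates privacy (privacy cell -1 instead of +1).
#' @param no_districts_rate probability that a state has no districts
#'   (its district-stratification cells become NA).
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return a validated `cdrs_synth_config` list.
#' @export
synthetic_config <- function(n_states = 29,
                             tier_probs = c(none = 0, low = 0.18,
                                            mid = 0.30, high = 0.50),
                             tier_weights = c(none = 2, low = 8,
                                              mid = 12, high = 7),
                             privacy_violation_rate = 2 / 27,
                             no_districts_rate = 1 / 29,
                             seed = 1) {
  if (n_states < 1) stop("n_states must be >= 1", call. = FALSE)
  if (is.null(names(tier_probs)) || is.null(names(tier_weights)) ||
      !setequal(names(tier_probs), names(tier_weights))) {
    stop("tier_probs and tier_weights must share the same tier names",
         call. = FALSE)
  }
  if (any(tier_probs < 0 | tier_probs > 1)) {
    stop("tier reporting probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(tier_weights < 0) || sum(tier_weights) <= 0) {
    stop("tier_weights must be non-negative and not all zero",
         call. = FALSE)
  }
  for (p in c(privacy_violation_rate, no_districts_rate)) {
    if (p < 0 || p > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(n_states = as.integer(n_states), tier_probs = tier_probs,
         tier_weights = tier_weights / sum(tier_weights),
         privacy_violation_rate = privacy_violation_rate,
         no_districts_rate = no_districts_rate,
         seed = as.integer(seed)),
    class = "cdrs_synth_config"
  )
}

# Draw one cell value: walk the domain from its maximum downward, taking
# each step with probability p. For {0,1} this is Bernoulli(p) on the
# maximum; for {0,1,2} it draws 2 w.p. p, else 1 w.p. p, else 0.
draw_cell <- function(domain, p) {
  vals <- sort(domain, decreasing = TRUE)
  for (v in vals[-length(vals)]) {
    if (stats::runif(1) < p) return(v)
  }
  vals[length(vals)]
}

#' Generate a synthetic cohort with planted quality structure
#'
#' Each state draws a tier from `tier_weights`; each applicable
#' non-privacy cell is set towards its domain maximum with the tier's
#' reporting probability (see the two-stage rule for three-valued
#' domains in [synthetic_config()]). District cells are NA for states
#' without districts. The privacy cell is -1 with
#' `privacy_violation_rate` among data-reporting states, +1 otherwise,
#' and NA for states that report nothing. The planted truth (tier,
#' violation flag, district flag) is returned alongside the cohort for
#' recovery tests.
#'
#' @param framework a `cdrs_framework`.
#' @param config a `cdrs_synth_config` from [synthetic_config()].
#' @return list with `cohort` (a `cdrs_cohort`) and `truth` (a tibble:
#'   `state`, `tier`, `tier_prob`, `privacy_violation`, `has_districts`,
#'   `seed`).
#' @export
generate_cohort <- function(framework, config = synthetic_config()) {
  stopifnot(inherits(config, "cdrs_synth_config"))
  ind <- enumerate_indicators(framework)
  district_metric <- framework$roles$district_metric
  priv_cat <- framework$roles$privacy_category
  non_priv <- if (is.null(priv_cat)) rep(TRUE, nrow(ind)) else
    ind$category != priv_cat
  with_seed(config$seed, {
    states <- sprintf("state%03d", seq_len(config$n_states))
    vals_list <- vector("list", config$n_states)
    truth_rows <- vector("list", config$n_states)
    meta_rows <- vector("list", config$n_states)
    for (i in seq_len(config$n_states)) {
      tier <- sample(names(config$tier_probs), 1,
                     prob = config$tier_weights[names(config$tier_probs)])
      p <- config$tier_probs[[tier]]
      has_districts <- stats::runif(1) >= config$no_districts_rate
      value <- rep(NA_integer_, nrow(ind))
      for (j in which(non_priv)) {
        if (!has_districts && !is.null(district_metric) &&
            ind$metric[j] == district_metric) {
          next  # stays NA: inapplicable cell
        }
        value[j] <- draw_cell(ind$domain[[j]], p)
      }
      violation <- stats::runif(1) < config$privacy_violation_rate
      reports_data <- any(!is.na(value[non_priv]) & value[non_priv] >= 1)
      if (!is.null(priv_cat)) {
        priv_idx <- which(ind$category == priv_cat)
        value[priv_idx] <- if (reports_data) {
          if (violation) -1L else 1L
        } else {
          NA_integer_
        }
      }
      confirmed <- max(10L, as.integer(round(stats::rlnorm(1, 6, 1.5))))
      vals_list[[i]] <- tibble::tibble(
        state = states[i], category = ind$category, metric = ind$metric,
        item = ind$item, value = value
      )
      truth_rows[[i]] <- tibble::tibble(
        state = states[i], tier = tier, tier_prob = p,
        privacy_violation = if (reports_data) violation else NA,
        has_districts = has_districts, seed = config$seed
      )
      meta_rows[[i]] <- tibble::tibble(
        state = states[i], has_districts = has_districts,
        confirmed_at_cutoff = confirmed
      )
    }
    list(
      cohort = new_cohort(do.call(rbind, vals_list),
                          do.call(rbind, meta_rows)),
      truth = do.call(rbind, truth_rows)
    )
  })
}

#' Generate a synthetic development index with planted correlation
#'
#' Builds an index on the 0-100 scale as an affine function of the CDRS
#' values plus Gaussian noise, calibrated so the population correlation
#' with the scores equals `target_r`: the noise standard deviation
#' solves sd_noise = sd_signal * sqrt(1 / r^2 - 1). If the raw values
#' overflow the 0-100 scale they are squeezed back in with a single
#' order-preserving affine map, which keeps the planted correlation
#' intact (truncating would attenuate it).
#'
#' @param scores tibble with `state` and `cdrs` columns.
#' @param target_r desired correlation, in [-1, 1].
#' @param noise_sd override the calibrated noise standard deviation (on
#'   the index scale); `NULL` (default) uses the closed-form
#'   calibration.
#' @param seed RNG seed.
#' @param center,signal_sd location and signal scale of the index on the
#'   0-100 scale.
#' @return tibble with `state`, `index_value`.
#' @export
generate_index <- function(scores, target_r, noise_sd = NULL, seed = 1,
                           center = 55, signal_sd = 12) {
  if (target_r < -1 || target_r > 1) {
    stop("target_r must lie in [-1, 1]", call. = FALSE)
  }
  s <- scores$cdrs
  sd_s <- stats::sd(s)
  if (is.na(sd_s) || sd_s == 0) {
    stop("scores have zero variance; cannot plant a correlation",
         call. = FALSE)
  }
  slope <- if (target_r == 0) 0 else sign(target_r) * signal_sd / sd_s
  if (is.null(noise_sd)) {
    noise_sd <- if (abs(target_r) == 1) {
      0
    } else if (target_r == 0) {
      signal_sd
    } else {
      signal_sd * sqrt(1 / target_r^2 - 1)
    }
  }
  with_seed(seed, {
    raw <- center + slope * (s - mean(s)) +
      stats::rnorm(length(s), 0, noise_sd)
    if (min(raw) < 0 || max(raw) > 100) {
      lo <- min(raw, 0)
      hi <- max(raw, 100)
      raw <- (raw - lo) / (hi - lo) * 100
    }
    tibble::tibble(state = scores$state, index_value = raw)
  })
}
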