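fw <- default_framework()

test_that("five-number summary follows the linear-interpolation quartile rule", {
  expect_equal(five_number_summary(0.61),
               c(min = 0.61, q1 = 0.61, median = 0.61, q3 = 0.61,
                 max = 0.61))
  expect_equal(five_number_summary(c(0, 1)),
               c(min = 0, q1 = 0.25, median = 0.5, q3 = 0.75, max = 1))
  expect_error(five_number_summary(numeric()), "non-empty")
  # permutation invariance and ordered output
  set.seed(5)
  x <- runif(29)
  fn <- five_number_summary(x)
  expect_equal(five_number_summary(sample(x)), fn)
  expect_true(all(diff(fn) >= 0))
  # the convention is configurable
  expect_equal(five_number_summary(c(0, 1), type = 1)[["q1"]], 0)
})

test_that("ranking is by decreasing CDRS with alphabetical ties", {
  scores <- tibble::tibble(state = c("A", "B"), cdrs = c(0.5, 0.61))
  expect_equal(rank_states(scores), c("B", "A"))
  tied <- tibble::tibble(state = c("B", "A"), cdrs = c(0.5, 0.5))
  expect_equal(rank_states(tied), c("A", "B"))
  set.seed(6)
  scores <- tibble::tibble(state = sprintf("s%02d", 1:10),
                           cdrs = round(runif(10), 1))
  expect_equal(rank_states(scores[10:1, ]), rank_states(scores))
  expect_error(rank_states(scores[0, ]), "no scores")
})

test_that("reporting counts agree with an independent tally", {
  # hand case: 3 sheets, 2 reporting total-confirmed
  sheets <- do.call(rbind, lapply(c("A", "B", "C"), function(s) {
    sh <- empty_sheet(fw, s)
    if (s != "C") {
      sh$value[sh$metric == "total" & sh$item == "confirmed"] <- 1L
    }
    sh
  }))
  counts <- reporting_counts(fw, new_cohort(sheets))
  expect_equal(
    counts$n_reporting[counts$id == "availability:total:confirmed"], 2L)
  expect_true(all(counts$n_reporting[
    counts$id != "availability:total:confirmed"] == 0L))
  # all-NA cohort counts nothing
  na_sheet <- perfect_sheet(fw, "A")
  na_sheet$value <- NA_integer_
  expect_true(all(reporting_counts(fw, new_cohort(na_sheet))$n_reporting
                  == 0L))
  # random cohorts against a brute-force tally
  set.seed(51)
  for (rep in 1:10) {
    framework <- random_framework()
    cohort <- random_cohort(framework, n_states = 6)
    got <- reporting_counts(framework, cohort)
    for (k in seq_len(nrow(got))) {
      tally <- 0L
      for (s in unique(cohort$values$state)) {
        v <- cohort$values
        hit <- v$state == s & v$category == got$category[k] &
          v$metric == got$metric[k] & v$item == got$item[k]
        if (any(hit) && !is.na(v$value[hit]) && v$value[hit] >= 1) {
          tally <- tally + 1L
        }
      }
      expect_equal(got$n_reporting[k], tally)
    }
    expect_true(all(got$n_reporting >= 0 &
                      got$n_reporting <= length(unique(cohort$values$state))))
  }
})

test_that("correlation recovers exact relationships and the hand-computed case", {
  x <- tibble::tibble(state = paste0("s", 1:5), cdrs = (1:5) / 10)
  idx_same <- tibble::tibble(state = x$state, index_value = x$cdrs * 100)
  res <- correlate_index(x, idx_same)
  expect_equal(res$pearson_r, 1)
  expect_equal(res$spearman_r, 1)
  expect_equal(res$n_pairs, 5L)
  idx_rev <- tibble::tibble(state = x$state,
                            index_value = c(90, 70, 50, 30, 10))
  expect_equal(correlate_index(x, idx_rev)$spearman_r, -1)
  # product-moment formula by hand: x = (1,2,3), y = (1,2,4) -> 0.982
  small <- tibble::tibble(state = c("a", "b", "c"), cdrs = c(1, 2, 3) / 10)
  idx <- tibble::tibble(state = small$state, index_value = c(1, 2, 4))
  expect_equal(correlate_index(small, idx)$pearson_r, 3 / sqrt(84 / 9),
               tolerance = 1e-12)
  expect_equal(round(correlate_index(small, idx)$pearson_r, 3), 0.982)
})

test_that("correlation p-values use the t transform on n - 2 degrees of freedom", {
  set.seed(61)
  x <- tibble::tibble(state = paste0("s", 1:29), cdrs = runif(29))
  idx <- tibble::tibble(state = x$state,
                        index_value = pmin(100, pmax(0, 50 + 30 * x$cdrs +
                                                       rnorm(29, 0, 8))))
  res <- correlate_index(x, idx)
  t_p <- res$pearson_r * sqrt((29 - 2) / (1 - res$pearson_r^2))
  expect_equal(res$pearson_p, 2 * stats::pt(-abs(t_p), 27))
  t_s <- res$spearman_r * sqrt((29 - 2) / (1 - res$spearman_r^2))
  expect_equal(res$spearman_p, 2 * stats::pt(-abs(t_s), 27))
  # seeded permutation p-values are reproducible and consistent
  perm1 <- correlate_index(x, idx, n_perm = 200, seed = 9)
  perm2 <- correlate_index(x, idx, n_perm = 200, seed = 9)
  expect_equal(perm1$pearson_p_perm, perm2$pearson_p_perm)
  expect_lt(perm1$pearson_p_perm, 0.05)
})

test_that("correlation is invariant under positive affine maps, Spearman under monotone maps", {
  set.seed(71)
  x <- tibble::tibble(state = paste0("s", 1:20), cdrs = runif(20))
  idx <- tibble::tibble(state = x$state, index_value = runif(20, 10, 90))
  base <- correlate_index(x, idx)
  shifted <- idx
  shifted$index_value <- idx$index_value * 0.5 + 20
  res_aff <- correlate_index(x, shifted)
  expect_equal(res_aff$pearson_r, base$pearson_r, tolerance = 1e-12)
  expect_equal(res_aff$spearman_r, base$spearman_r, tolerance = 1e-12)
  curved <- idx
  curved$index_value <- (idx$index_value / 100)^3 * 100  # strictly monotone
  expect_equal(correlate_index(x, curved)$spearman_r, base$spearman_r,
               tolerance = 1e-12)
})

test_that("the score-index join normalizes names, warns on mismatch, and needs 3 pairs", {
  x <- tibble::tibble(state = c("Tamil Nadu ", "KERALA", "Goa", "Assam"),
                      cdrs = c(0.5, 0.52, 0.3, 0.2))
  idx <- tibble::tibble(state = c("tamil  nadu", "kerala", "goa", "Delhi"),
                        index_value = c(70, 80, 60, 65))
  expect_warning(res <- correlate_index(x, idx), "one side of the join")
  expect_equal(res$n_pairs, 3L)
  two <- x[1:2, ]
  expect_error(suppressWarnings(correlate_index(two, idx[1:2, ])),
               "at least 3 matched")
  flat <- tibble::tibble(state = c("a", "b", "c"), cdrs = c(0.2, 0.2, 0.2))
  idx3 <- tibble::tibble(state = flat$state, index_value = c(10, 20, 30))
  expect_error(correlate_index(flat, idx3), "zero variance")
})

test_that("cohort_summary bundles n, five-number, ranking and category medians", {
  set.seed(81)
  sheets <- do.call(rbind, lapply(sprintf("st%02d", 1:9), function(s) {
    random_valid_sheet(fw, state = s)
  }))
  scores <- score_cohort(fw, new_cohort(sheets))
  s <- cohort_summary(scores)
  expect_equal(s$n, 9L)
  expect_equal(s$five_number, five_number_summary(scores$cdrs))
  expect_equal(s$ranking, rank_states(scores))
  expect_equal(unname(s$category_medians["availability"]),
               median(scores$availability, na.rm = TRUE))
  expect_error(cohort_summary(scores[0, ]), "empty")
})
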