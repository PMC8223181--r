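---
title: "Scoring the quality of epidemic data reporting: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the quality of epidemic data reporting: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrscore)
```

## What is being measured

`cdrscore` measures the *quality of data reporting* by a jurisdiction,
not the quality of the underlying data. The distinction matters: a
state could collect impeccable surveillance data and publish almost
none of it. The unit of assessment is therefore the public interface —
bulletins, dashboards, web pages — inspected against a fixed rubric of
binary (mostly) indicators: is the cumulative count of confirmed cases
published? a daily count? a trend graphic? is the total stratified by
age, gender, comorbidities, districts? is the page reachable from the
government site, available in English? does any published document leak
personally identifiable information?

Filling the rubric is a human audit; everything after that — scoring,
normalization, cohort summaries, external correlation — is mechanical,
and that mechanical part is what this package implements and tests.

## The scoring model

The default rubric has 45 indicators across four categories
(availability 15, accessibility 12, granularity 17, privacy 1) and five
report items (confirmed, deaths, recovered, quarantine, ICU). Each cell
has an integer domain: `{0, 1}` for most, `{0, 1, 2}` for deaths by
comorbidities (the 2 rewards patient-level comorbidity reporting), and
`{-1, 1}` for the single privacy cell.

For a state $s$ and category $c$, let $T(c,s)$ be the sum of the
state's non-NA cell values in $c$, and $M(c,s)$, $m(c,s)$ the sums of
the domain maxima and minima over the same cells. Then

$$N(c,s) = \frac{T(c,s)}{M(c,s) - m(c,s)}, \qquad
  \mathrm{CDRS}(s) = \frac{\sum_c T(c,s)}{\sum_c M(c,s)}.$$

Two consequences are worth spelling out:

* The privacy category has one cell with $M - m = 2$, so its normalized
  score is $+0.5$ (no violation) or $-0.5$ (violation) — a deliberate
  asymmetry with the other categories, which normalize to $[0, 1]$.
* The overall score divides by $\sum_c M$, not $\sum_c (M - m)$.
  The two choices coincide everywhere except the privacy cell. We
  implement the formula as printed; it is also the only variant under
  which a complete best-case sheet scores exactly 1 and a silent state
  exactly 0, which the test suite verifies.

With the default rubric the attainable totals are $\sum M = 46$ and
$\sum m = -1$ (verified by brute-force enumeration in the tests), so a
data-reporting state with a privacy violation and everything else
perfect scores $44/46 \approx 0.957$.

### NA adjustment

Cells can be inapplicable to a state, and the normalization adjusts for
it: an NA cell is excluded from $T$, $M$ and $m$ alike. Two
inapplicability rules are built in:

* **Districts.** The five district-stratification cells are NA for a
  state that has no districts (`has_districts = FALSE` in the
  metadata).
* **Privacy.** Privacy does not apply to a state that reports no data:
  if every non-privacy cell is 0 or NA, the privacy cell is treated as
  NA. This rule is *derived from sheet content*, never trusted from the
  input file; a file that contradicts the derivation triggers a
  warning. Deriving it makes it testable, and it is what confines CDRS
  to $[0, 1]$: without it a silent state with a recorded privacy
  violation would score $-1/46 < 0$.

The engine does not clamp. If a custom rubric makes negative scores
reachable, the engine warns and reports the value as computed.

A useful identity that the property tests exercise: marking a cell NA
is exactly equivalent to deleting that cell from the rubric. NA cells
are not "zero credit"; they shrink the scale.

### Exactness

$T$, $M$ and $m$ are integer sums; the only division happens last, so
scores are exact IEEE doubles of small rationals (multiples of $1/46$
and its NA-adjusted variants) with no accumulation error. Display
rounding (2 decimals in the CLI's `--digits 2` mode) never feeds back
into computation.

## Cohort statistics

* **Five-number summary.** Quartiles default to linear interpolation
  between order statistics (`stats::quantile` type 7). The convention
  is exposed (`type` argument, `--quantile-type` flag) because
  published five-number summaries rarely state which rule produced
  them, and at n around 30 the rules differ visibly in the quartiles.
* **Ranking.** Decreasing CDRS, ties broken alphabetically — a total,
  deterministic order regardless of input order.
* **Reporting counts.** For each indicator, the number of states with a
  value of at least 1. NA does not count, and neither does 0; for the
  three-valued death-comorbidity cell both 1 and 2 count as reporting.
* **External correlation.** CDRS is compared against a development
  index on the 0–100 scale (for the original study, the SDG India
  Index for good health and well-being) by Pearson and Spearman
  correlation. Both p-values are two-sided and use the t transform
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom; for Spearman
  this is the standard large-sample approximation, adequate at cohort
  sizes of a few dozen, and a seeded permutation p-value is available
  (`n_perm`) when n is small. The join is an inner join on case-folded,
  whitespace-collapsed state names; unmatched names are warned about,
  never silently dropped. At least 3 matched pairs are required.

## The inclusion filter

States reporting fewer than 10 cumulative confirmed cases at the study
cutoff are excluded from assessment — too little epidemic activity to
judge a reporting system by. "Fewer than 10" is strict: exactly 10 is
included. The packaged roster
`inst/extdata/india_states_meta_synthetic.csv` reproduces the original
study's 36-region roster and its 7 excluded regions; the per-state
counts in that file are synthetic stand-ins chosen only to respect the
published include/exclude split, which is why the filename labels the
file synthetic.

## The synthetic cohort generator

The generator exists so that every pipeline stage — parsing,
validation, scoring, summaries, correlation — has a test surface with
known ground truth and no external data. Its model:

1. Each state draws a quality **tier**; a tier is a single
   per-indicator reporting probability $p$.
2. Every applicable non-privacy cell is an independent draw toward its
   domain maximum with probability $p$ (the `{0,1,2}` cell draws 2 with
   probability $p$, else 1 with probability $p$, else 0).
3. District cells are NA with the configured no-district rate; the
   privacy cell is $-1$ with the configured violation rate among
   data-reporting states, $+1$ otherwise, NA for silent states.

Defaults emulate the original 29-state cohort: tiers
none/low/mid/high with $p = 0, 0.18, 0.30, 0.50$ and weights
$2/8/12/7$ out of 29 — a couple of silent states, a broad middle, a
handful of dashboard-grade reporters, giving CDRS dispersion from 0 to
the low 0.6s with a median near 0.3 — a privacy-violation rate of
$2/27$ (two violators among the study's 27 data-reporting states) and a
no-district rate of $1/29$ (one such region in the study cohort). These
were fixed once, from the study's description, not tuned to test
outcomes.

What the model deliberately does **not** reproduce: correlation between
indicators within a state (real dashboards are all-or-nothing — a state
with trend graphics for one item usually has them for all), geographic
structure, and any resemblance to specific real states. Passing
recovery tests therefore shows the pipeline recovers planted structure
under independence, not that real cohorts look like this.

The synthetic index generator plants a target correlation $r$ with the
scores by adding Gaussian noise to an affine map of CDRS onto the 0–100
scale, with the closed-form calibration
$\sigma_{noise} = \sigma_{signal}\sqrt{1/r^2 - 1}$
(signal scale 12 index points around a center of 55). If the raw values
overflow $[0, 100]$ they are squeezed back with a single
order-preserving affine map rather than truncated: truncation would
attenuate the planted correlation, and in the noise-free $r = 1$ case
would break exact recovery, while an affine squeeze preserves both
Pearson and Spearman correlations exactly.

## Numerical and design choices

* **Rubric as data.** The rubric is a YAML schema
  (`inst/extdata/framework_default.yaml`), validated on load
  (`validate_framework()` returns diagnostics, one per offending cell,
  rather than failing fast). Category-wide indicators (ease of access,
  English availability, privacy) are single cells under the sentinel
  item `ALL`, which is what keeps the indicator count at 45 as printed.
  Structural dashes (age/gender/comorbidity stratification of
  quarantine) are listed as `structural_na` and are unrepresentable in
  scoring sheets — a sheet mentioning them is a parse error, not a
  silent zero.
* **CSV dialects.** Sheets travel in long format
  (`state,category,metric,report_item,value`) with the literal token
  `NA`; long format was chosen over a wide table precisely so dash
  cells cannot be filled by accident. Round-trips are the identity,
  NA tokens included, and the tests check this property on random
  cohorts.
* **Degenerate inputs.** A sheet with no applicable cell at all has an
  undefined score and errors; `score_cohort()` collects such per-state
  failures into one warning instead of aborting the cohort. An empty
  category yields `N = NA`, as does a category whose applicable cells
  have $M = m$. Empty cohorts summarize to empty tables; a single-state
  cohort has a degenerate but well-defined five-number summary.
* **Determinism.** Everything downstream of data is deterministic;
  everything stochastic (generator, permutation test) is seeded, and
  the generators restore the caller's RNG state.
* **Problem sizes in the tests.** Property tests run the engine against
  an independent plain-loop oracle over 1000 random rubric/sheet pairs;
  recovery tests use two-tier cohorts of 400 states and
  planted-correlation checks at n = 1000, where the sampling standard
  deviation of $\hat r$ at $r = 0.6$ is about 0.02, so the ±0.05
  acceptance band is a 2.5-sigma check.

## Limitations

* Equal weights. Every indicator counts the same; the score has no
  notion of some items mattering more. Unequal weighting is possible in
  principle but choosing defensible weights is out of scope.
* The rubric scores presence, not quality-of-execution: a cluttered,
  misleading trend graphic scores like a good one.
* The audit step is human. Nothing here scrapes websites or decides
  what a state "reports"; inter-rater agreement is outside the
  package's reach.
* The Spearman p-value's t approximation is poor below roughly n = 10;
  use the permutation option there.
* Synthetic cohorts are independence-structured (see above); they
  validate the machinery, not the sociology of real reporting.
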