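# Default CDRS scoring rubric: 45 indicators across four categories.
# A cell's `domain` lists every integer value the cell may take.
# `items: all` expands to the five report items; `items: category-wide`
# declares a single cell spanning all items (stored under item ALL).
# `structural_na` lists metric/item pairs that are dashes in the rubric
# and are never scored for any state.
name: cdrs-default
version: "1.0"
report_items: [confirmed, deaths, recovered, quarantine, icu]
categories:
  availability:
    - metric: total
      items: all
      domain: [0, 1]
    - metric: daily
      items: all
      domain: [0, 1]
    - metric: historical
      items: all
      domain: [0, 1]
  accessibility:
    - metric: ease_of_access
      items: category-wide
      domain: [0, 1]
    - metric: english
      items: category-wide
      domain: [0, 1]
    - metric: trend_total
      items: all
      domain: [0, 1]
    - metric: trend_daily
      items: all
      domain: [0, 1]
  granularity:
    - metric: age
      items: [confirmed, deaths, recovered, icu]
      domain: [0, 1]
    - metric: gender
      items: [confirmed, deaths, recovered, icu]
      domain: [0, 1]
    - metric: comorbidities
      items: [confirmed, deaths, recovered, icu]
      domain: [0, 1]
      domain_overrides:
        deaths: [0, 1, 2]
    - metric: districts
      items: all
      domain: [0, 1]
  privacy:
    - metric: privacy
      items: category-wide
      domain: [-1, 1]
structural_na:
  - {metric: age, item: quarantine}
  - {metric: gender, item: quarantine}
  - {metric: comorbidities, item: quarantine}
roles:
  district_metric: districts
  privacy_category: privacy
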