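# Minimal daily data-reporting template

A jurisdiction filling in every field of this template each day, on an
easily reachable English-language page, satisfies every indicator of the
default rubric. Counts are cumulative unless marked "new today".

## Headline counts (total and new today)

| Report item | Total | New today |
|-------------|-------|-----------|
| Confirmed   |       |           |
| Deaths      |       |           |
| Recovered   |       |           |
| In quarantine |     |           |
| In ICU      |       |           |

## Trend graphics

One total-trend and one daily-trend graphic per report item above
(time on the x-axis).

## Stratified totals

For confirmed, deaths, recovered and ICU: totals disaggregated by age
band, by gender, and by comorbidity status (for deaths, list the
comorbidities of each deceased patient). For all five report items:
totals disaggregated by district.

## Archive and privacy

- Keep every previous day's bulletin reachable (historical data).
- Publish no personally identifiable information: no names, addresses
  or phone numbers. Use aggregated hotspot maps instead of household
  locations.
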