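# pvsignal

Disproportionality signal detection and time-to-onset analysis for
FAERS-style spontaneous adverse-event reports, with headache as the event
of interest.

Spontaneous-report databases such as the FDA Adverse Event Reporting System
(FAERS) distribute every revision of every safety report across quarterly
multi-table extracts (DEMO, DRUG, REAC, THER, joined on PRIMARYID). Turning
that raw feed into defensible drug–event signals requires a fixed sequence
of decisions: collapsing report versions to one record per case, restricting
to primary-suspect (PS) drug mentions, matching the event as an exact MedDRA
preferred term, and only then computing disproportionality statistics.
`pvsignal` implements that pipeline for pharmacoepidemiologists and
drug-safety analysts, together with a synthetic FAERS-like generator with
*planted* association strengths, so every stage can be validated against a
known truth without downloading anything.

## The statistics

For each drug (or ATC level-2 class), reports are cross-classified against
the event in a 2×2 table — `a`: drug of interest and headache, `b`: drug of
interest and other events, `c`: other drugs and headache, `d`: other drugs
and other events — and two disproportionality measures are computed:

- Reporting odds ratio: ROR = (a·d)/(b·c), with
  SE(ln ROR) = √(1/a + 1/b + 1/c + 1/d)
- Proportional reporting ratio: PRR = [a/(a+b)] / [c/(c+d)], with
  SE(ln PRR) = √(1/a − 1/(a+b) + 1/c − 1/(c+d))

Both get Wald 95% confidence intervals on the log scale,
exp(ln(estimate) ± 1.96·SE). A drug is flagged as a **signal** when both
point estimates exceed 1 and both lower 95% bounds exceed 1. Tables with a
zero cell yield an explicitly undefined estimate — no continuity
correction is applied. Time-to-onset is the day difference between the PS
drug's start date and the event date, kept only for complete calendar-day
date pairs and binned into ≤7, 8–28, 29–60, 61–90 and >90 days.

## Worked example

```r
library(pvsignal)

cfg <- default_generator_config(n_cases = 50000, seed = 42)
bundle <- generate_bundle(cfg)     # DEMO/DRUG/REAC/THER + truth table
res <- run_pipeline(bundle, atc_map = config_atc_map(cfg))

str(res$manifest$stages)
#> $ raw_report_versions           : int 66225
#> $ duplicates_removed            : int 16225
#> $ unique_reports                : int 50000
#> $ background_reports            : int 50000
#> $ event_reports                 : int 2035
#> ...

res$signals_drug[1:3, .(drug, a, ror, ror_low, prr, prr_low, signal)]
#>            drug     a       ror  ror_low       prr  prr_low signal
#> 1: SIGNALDIPINE   263 3.7100944 3.233075 3.3719754 2.984843   TRUE
#> 2:  CEPHALGINIB   204 2.1396376 1.840795 2.0494568 1.783256   TRUE
#> 3:     MIGRAMAB   183 1.8950971 1.619139 1.8311116 1.581455   TRUE
```

Of 66,225 generated report versions, 16,225 are older duplicates removed by
the CASEID/FDA_DT/PRIMARYID rule, leaving one report per case; 2,035 reports
carry the exact preferred term "Headache". The three drugs planted with
elevated headache odds (4.0, 2.5 and 2.0) surface as the three flagged
signals; the estimates sit slightly below the planted values because the
comparator pool itself contains the other two elevated drugs. Per-drug and
per-class time-to-onset tables and the Table-1-style demographic summary are
in `res$tto_drug`, `res$tto_atc` and `res$demographics`;
`write_pipeline_outputs(res, dir)` writes everything as TSV plus a JSON
manifest.

Real FAERS quarters in the dollar-delimited ASCII dialect are read with
`read_quarter()`, name-standardized via `normalize_drug_name()` /
`load_synonym_map()`, and classed via `load_atc_map()`.

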