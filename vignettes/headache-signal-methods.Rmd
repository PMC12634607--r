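---
title: "Methods: disproportionality and time-to-onset analysis of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality and time-to-onset analysis of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
library(data.table)
```

## The problem

Spontaneous adverse-event databases like FAERS are a stream of report
*versions*: each case (CASEID) may be resubmitted several times, each
version carrying its own PRIMARYID and FDA receipt date (FDA_DT). Reports
name multiple drugs in different roles — primary suspect (PS), secondary
suspect (SS), interacting (I), concomitant (C) — and code reactions as
MedDRA preferred terms (PTs). Disproportionality analysis asks whether an
event (here, the PT "Headache") is reported for a drug more often than the
rest of the database would predict. The answer is only as good as the
cohort construction that precedes it, so `pvsignal` fixes the whole chain:

1. **Deduplication.** Within a CASEID, keep the version with the latest
   FDA_DT; on ties, the highest PRIMARYID. This runs on the concatenation
   of all quarters before any filtering, so a case resubmitted across
   quarters still collapses to one record.
2. **PS-only background.** Each kept report contributes one
   (report, PS drug) unit. Reports without a PS drug are excluded and
   counted. SS/I/C mentions contribute nothing, neither to the drug of
   interest nor to the comparator — including them in the background would
   dilute the very signal being tested.
3. **Exact PT matching.** A report is an event report iff one of its PTs
   equals the target term after trimming and case folding. Substring
   matching is deliberately avoided: it would sweep "Tension headache" and
   "Migraine" into "Headache".
4. **Estimation.** Per drug and per ATC level-2 class, the 2×2 table
   (a, b, c, d) yields ROR = (a·d)/(b·c) and
   PRR = [a/(a+b)]/[c/(c+d)] with Wald 95% CIs on the log scale
   (SE(ln ROR) = √(1/a+1/b+1/c+1/d);
   SE(ln PRR) = √(1/a−1/(a+b)+1/c−1/(c+d)); quantile 1.96). A signal
   requires all four of: ROR > 1, PRR > 1, and both lower bounds > 1.
5. **Time-to-onset (TTO).** Days from the PS drug's start date to the
   event date, binned ≤7 / 8–28 / 29–60 / 61–90 / >90 days over complete
   date pairs only.

The analysis unit throughout is the *report*, not the drug–event pair:
the a–d cell definitions are report counts, and because every background
report carries exactly one PS drug, the per-drug `a` cells sum to the
total number of event reports.

## Numerical and edge-case choices

- **Zero cells.** Any empty ROR cell (or a = 0 / c = 0 for PRR) makes the
  estimate *undefined*, flagged as such, rather than Haldane–Anscombe
  0.5-corrected. A silent correction would reshuffle the ranking of rare
  drugs; an undefined estimate cannot be a signal. b = 0 is legal for the
  PRR (its SE terms 1/a − 1/(a+b) cancel).
- **Dedup tie-breaking.** PRIMARYIDs are compared numerically when the tie
  group is all-digit; otherwise the group falls back to lexicographic
  comparison with a logged warning. A missing FDA_DT sorts before any
  present date, so a dated version always wins. The result is invariant to
  input row order, and idempotent.
- **Multiple PS rows** on one report (rare but real) resolve to the lowest
  drug-sequence number — FAERS lists the primary suspect first — with an
  ambiguity counter in the pipeline manifest.
- **Date tokens.** FAERS dates are digit strings that may be truncated:
  8 valid digits → day, 6 → month, 4 → year, anything else (including
  impossible days like 20230230) → invalid. TTO uses day-resolution pairs
  only; truncated tokens are excluded with per-category counters
  (incomplete start, incomplete event, negative).
- **Start-date source.** FAERS carries therapy start dates both on the
  drug row and in THER. The DRUG row is preferred and THER (matched on the
  drug sequence) is the fallback; the order is fixed so runs are
  reproducible and the choice is visible here rather than buried in code.
- **Day-0 onsets** count in the ≤7 bin: same-day reactions (infusion-type)
  are real data, and the bins must partition the nonnegative integers.
  **Negative onsets** (event before therapy start) are excluded, not
  clamped — they indicate data errors or pre-existing events.
- **Rounding.** All reported percentages and the written estimate tables
  round half away from zero (`round_half_up()`), since base R's
  round-half-to-even would turn 1582/2014 = 78.55% into 78.5 rather than
  the conventional 78.6. Percentages use two decimals in the demographic
  table, one decimal in TTO tables; estimates and CI bounds use three
  decimals on disk. Every percentage column recomputes exactly from its
  count column under this rule, and TTO bin percentages are computed
  independently (no renormalization to force a 100.0 total).
- **Age bands** are <18, 18–30, 31–50, 51–65, >65 years with both integer
  ends closed (age 18 is in 18–30, age 65 in 51–65); FAERS mixed-unit age
  codes (YR/DEC/MON/WK/DY) are converted to years first, and unknown codes
  become Missing. "Unknown" sex (coded UNK) is tallied separately from
  blank (Missing).
- **No multiplicity adjustment** is applied to signal flags, and the run
  manifest says so: with hundreds of drugs, the expected false-positive
  count under the joint ROR/PRR lower-bound rule is nonzero by design.

## The synthetic generator

`generate_bundle()` emits linked DEMO/DRUG/REAC/THER tables in the FAERS
ASCII dialect plus a truth table for tests. Its central design decision is
the *planted odds model*: a case whose PS drug has planted value r receives
the event with odds r × the background odds. Because the ROR is an odds
ratio, this makes the estimator consistent for r whenever the comparator
drugs are neutral (r = 1) — planting a rate ratio instead would make the
"true" ROR depend on the background rate. One consequence worth knowing:
with several elevated drugs in one panel, each drug's comparator contains
the others, so estimated RORs sit slightly below their planted values; the
consistency and CI-coverage checks therefore use a single planted drug
against neutral fillers.

Defaults are chosen once to emulate the real headache corpus and are not
tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `background_headache_rate` | 0.033 | headache share of unique FAERS reports (313,166 / 9,536,756) |
| `dup_fraction` | 0.27 | duplicates removed ÷ total versions = f/(1+f) ≈ 21.5% |
| `missing_age_rate` / `missing_sex_rate` / `missing_weight_rate` | 0.366 / 0.10 / 0.733 | published cohort missingness |
| `partial_date_rate` | 0.25 | typical FAERS start-date incompleteness; exercises the TTO completeness filter |
| `onset_mixture` | (0.45, 0.13, 0.07, 0.04, 0.31) | a balanced early/late profile, ≈ the immunosuppressant class distribution |

Demographics (age bands, sex, weight, reporter occupation, country) are
drawn from the categorical distribution of the published 313,166-case
cohort, which makes the demographic summary a meaningful round-trip test.
Duplicate versions are emitted in three receipt-date patterns — increasing,
tied, and scrambled (latest date on a non-maximal PRIMARYID) — so both
dedup tie-break rules, and their interaction, are exercised; the truth
table marks the version the rule designates current. Partial dates truncate
YYYYMMDD to YYYYMM or YYYY, reproducing the real FAERS date dialects.

What the generator does **not** emulate: indication semantics and
channeling bias (a drug prescribed for migraine will inherit headache
reports through its indication — the classic confounder of
disproportionality), outcome severity, reporting waves after media
attention, MedDRA coding drift, or cross-CASEID duplicates that only
probabilistic record linkage would catch. Passing tests on synthetic data
therefore validate the *arithmetic and plumbing* of the pipeline, not the
epidemiological interpretability of real-data signals.

## Validation strategy and problem sizes

The test suite checks each stage against an independent oracle: dedup
against a re-application of the rule by independent code and against the
generator's truth markers; contingency cells against brute-force
enumeration of the truth table; ROR against a saturated logistic
regression (whose coefficient and Wald SE equal the cross-product ratio
and √Σ1/cell exactly); both estimators against direct arithmetic on 10,000
random tables; bins against interval membership for days 0–200. Two
stochastic properties run at scale: recovery of a planted ROR of 4.0
within the estimate's own 95% CI at 50,000 cases, and empirical coverage
of the ROR CI for a planted value of 2.0 over many replicates of 20,000
cases (750 in the acceptance script), expected in the 93–97% band around
the nominal 95%. These sizes keep the full suite within a few minutes
while leaving the binomial noise on the coverage estimate (≈0.8 points)
well inside the band's width.

## Limitations

Disproportionality measures are reporting associations, not incidence or
causation; the PS restriction reduces but does not remove confounding by
indication; exact-PT matching undercounts events coded to subtype terms;
and the Wald CIs are asymptotic — for very rare drug–event pairs the
undefined-on-zero policy means no estimate at all rather than a fragile
one. The pipeline deliberately reports these boundaries (exclusion
counters, ambiguity counters, undefined flags) instead of smoothing over
them.
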