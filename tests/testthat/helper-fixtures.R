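library(data.table)

# one planted drug against neutral background fillers: the single-drug
# configuration under which the ROR estimator is consistent for the
# planted value
single_drug_config <- function(seed, n_cases = 20000, target_ror = 2.0,
                               share = 0.2, ...) {
  generator_config(
    n_cases = n_cases,
    drugs = list(drug_spec("TESTDRUG", target_ror = target_ror,
                           marginal_share = share, atc_code = "L04")),
    seed = seed, ...)
}

# run the analysis path from a generated bundle down to one drug's ROR
pipeline_ror <- function(bundle, drug_name) {
  dd <- deduplicate(bundle$demo)
  bg <- build_background(dd$kept, bundle$drug)
  bg <- attach_event_flag(bg, bundle$reac)
  ror(build_contingency(drug_name, bg))
}

# independent 2x2 odds-ratio oracle on the generator truth table
truth_or <- function(truth, drug_name) {
  a <- sum(truth$ps_drug == drug_name & truth$headache)
  b <- sum(truth$ps_drug == drug_name & !truth$headache)
  cc <- sum(truth$ps_drug != drug_name & truth$headache)
  dd <- sum(truth$ps_drug != drug_name & !truth$headache)
  (a * dd) / (b * cc)
}

# hand-built demo table for dedup tests
demo_rows <- function(primaryid, caseid, fda_dt) {
  data.table(primaryid = primaryid, caseid = caseid, fda_dt = fda_dt)
}
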