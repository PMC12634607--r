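test_that("FAERS age codes convert to years", {
  expect_equal(age_to_years(c("40", "6", "24", "2", "730"),
                            c("YR", "DEC", "MON", "WK", "DY")),
               c(40, 60, 2, 2 / 52.1775, 730 / 365.25))
  expect_true(all(is.na(age_to_years(c("40", ""), c("", "YR")))))
  expect_true(is.na(age_to_years("40", "XX")))
})

test_that("a singleton cohort summarizes to 100% in its categories", {
  demo <- data.table(
    primaryid = "1", caseid = "C1", fda_dt = "20230101",
    event_dt = "20230101", age = "40", age_cod = "YR", sex = "M",
    wt = "80", wt_cod = "KG", occp_cod = "MD", reporter_country = "US")
  s <- demographic_summary(demo)
  expect_equal(s[characteristic == "Sex" & category == "Male", pct], 100)
  expect_equal(sum(s[characteristic == "Sex" & category != "Male", n]), 0)
  expect_equal(s[characteristic == "Age" & category == "31-50 years", n], 1L)
  expect_equal(s[characteristic == "Reporter Country" &
                   category == "United States", pct], 100)
})

test_that("age and weight band edges follow the stated conventions", {
  mk <- function(age, age_cod = "YR", wt = "", wt_cod = "") {
    data.table(primaryid = as.character(seq_along(age)),
               caseid = as.character(seq_along(age)),
               fda_dt = "20230101", event_dt = "", age = age,
               age_cod = age_cod, sex = "F", wt = wt, wt_cod = wt_cod,
               occp_cod = "CN", reporter_country = "US")
  }
  s <- demographic_summary(mk(c("17", "18", "30", "31", "50", "51", "65", "66")))
  age_n <- s[characteristic == "Age"]
  expect_equal(age_n[category == "<18 years", n], 1L)
  expect_equal(age_n[category == "18-30 years", n], 2L) # 18 and 30 inclusive
  expect_equal(age_n[category == "31-50 years", n], 2L)
  expect_equal(age_n[category == "51-65 years", n], 2L)
  expect_equal(age_n[category == ">65 years", n], 1L)

  s2 <- demographic_summary(mk(rep("40", 4), wt = c("50", "51", "100", "101"),
                               wt_cod = "KG"))
  wt_n <- s2[characteristic == "Weight"]
  expect_equal(wt_n[category == "<=50 kg", n], 1L)
  expect_equal(wt_n[category == ">50-<=100 kg", n], 2L)
  expect_equal(wt_n[category == ">100 kg", n], 1L)
})

test_that("every characteristic sums to the cohort total and percentages recompute", {
  cfg <- single_drug_config(seed = 61, n_cases = 3000)
  b <- generate_bundle(cfg)
  dd <- deduplicate(b$demo)
  s <- demographic_summary(dd$kept)
  for (ch in unique(s$characteristic))
    expect_equal(sum(s[characteristic == ch, n]), nrow(dd$kept), info = ch)
  expect_equal(s$pct, round_half_up(100 * s$n / nrow(dd$kept), 2))
})

test_that("the pipeline is deterministic end to end", {
  cfg <- single_drug_config(seed = 99, n_cases = 2000)
  am <- config_atc_map(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_pipeline(generate_bundle(cfg), atc_map = am, outdir = d1)
  run_pipeline(generate_bundle(cfg), atc_map = am, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("a bundle with no event reports completes with an empty cohort", {
  cfg <- single_drug_config(seed = 43, n_cases = 500)
  b <- generate_bundle(cfg)
  b$reac <- b$reac[toupper(trimws(pt)) != "HEADACHE"]
  res <- run_pipeline(b)
  expect_equal(res$manifest$stages$event_reports, 0L)
  expect_equal(nrow(res$demographics), 0L)
  expect_true(all(res$signals_drug$a == 0))
  expect_false(any(res$signals_drug$signal))
})

test_that("manifest stage counts decrease monotonically through the funnel", {
  cfg <- default_generator_config(n_cases = 5000, seed = 12)
  res <- run_pipeline(generate_bundle(cfg), atc_map = config_atc_map(cfg))
  st <- res$manifest$stages
  expect_gte(st$raw_report_versions, st$unique_reports)
  expect_gte(st$unique_reports, st$background_reports)
  expect_gte(st$background_reports, st$event_reports)
  expect_gte(st$event_reports, st$tto_complete_cases)
  expect_equal(st$raw_report_versions - st$duplicates_removed,
               st$unique_reports)
})

test_that("planted signals are flagged and neutral drugs rarely are", {
  # full study-scale default: 50,000 cases, 20-drug panel, 3 planted signals
  planted <- c("SIGNALDIPINE", "CEPHALGINIB", "MIGRAMAB")
  fp <- 0L; n_neutral <- 0L
  for (seed in 1:20) {
    cfg <- default_generator_config(n_cases = 50000, seed = 1000 + seed)
    res <- run_pipeline(generate_bundle(cfg), atc_map = config_atc_map(cfg))
    sd <- res$signals_drug
    expect_true(all(sd[drug %in% planted, signal]),
                info = paste("seed", seed))
    neutral <- sd[!drug %in% planted]
    fp <- fp + sum(neutral$signal)
    n_neutral <- n_neutral + nrow(neutral)
  }
  # a neutral drug trips the rule only when both lower bounds exceed 1
  # (~2.5% nominal); allow three sigma above nominal
  expect_lte(fp / n_neutral, 0.025 + 3 * sqrt(0.025 * 0.975 / n_neutral))
})

test_that("written signal tables round to three decimals and recompute", {
  cfg <- single_drug_config(seed = 71, n_cases = 4000)
  dir <- withr::local_tempdir()
  res <- run_pipeline(generate_bundle(cfg), atc_map = config_atc_map(cfg),
                      outdir = dir)
  disk <- data.table::fread(file.path(dir, "signals_drug.tsv"))
  m <- merge(disk[, .(drug, ror_disk = ror)],
             res$signals_drug[, .(drug, ror)], by = "drug")
  expect_equal(m$ror_disk, round_half_up(m$ror, 3))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$stages$unique_reports, 4000L)
})
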