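# Demographic summary, end-to-end pipeline driver and run manifest.

#' Convert FAERS age codes to years
#'
#' FAERS stores age with a unit code: `YR` years, `DEC` decades, `MON`
#' months, `WK` weeks, `DY` days. Unknown codes or unparseable values give
#' `NA` (treated as missing downstream).
#'
#' @param age character or numeric vector of age values.
#' @param age_cod character vector of unit codes.
#' @return numeric vector of ages in years.
#' @export
age_to_years <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(age_cod))
  factor_map <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 1 / 52.1775,
                  DY = 1 / 365.25)
  f <- factor_map[cod]
  out <- v * f
  out[is.na(f)] <- NA_real_
  unname(out)
}

.occp_labels <- c(CN = "Consumer", HP = "Health Professional",
                  MD = "Medical Doctor", PH = "Pharmacist",
                  LW = "Other Work", OT = "Others")
.country_labels <- c(US = "United States", CA = "Canada",
                     GB = "United Kingdom", DK = "Denmark")

#' Demographic and reporting characteristics of a cohort
#'
#' Tabulates age bands (`<18`, `18-30`, `31-50`, `51-65`, `>65`; the bands
#' are closed on both integer ends, e.g. 18 <= age <= 30), sex, weight
#' bands (`<=50 kg`, `>50-<=100 kg`, `>100 kg`), reporter occupation and
#' reporter country, with explicit Missing/Unknown categories, so that
#' every characteristic's counts sum to the cohort total. Percentages are
#' `100 * n / total` rounded half-up to two decimals.
#'
#' @param demo DEMO rows of the cohort (one row per report).
#' @return data.table `(characteristic, category, n, pct)`.
#' @export
demographic_summary <- function(demo) {
  dt <- as.data.table(demo)
  total <- nrow(dt)
  if (total == 0L)
    return(data.table(characteristic = character(0), category = character(0),
                      n = integer(0), pct = numeric(0)))

  age_y <- age_to_years(dt$age, dt$age_cod)
  age_cat <- rep("Missing", total)
  age_cat[!is.na(age_y) & age_y < 18] <- "<18 years"
  age_cat[!is.na(age_y) & age_y >= 18 & age_y <= 30] <- "18-30 years"
  age_cat[!is.na(age_y) & age_y > 30 & age_y <= 50] <- "31-50 years"
  age_cat[!is.na(age_y) & age_y > 50 & age_y <= 65] <- "51-65 years"
  age_cat[!is.na(age_y) & age_y > 65] <- ">65 years"

  sex <- toupper(trimws(dt$sex))
  sex_cat <- rep("Missing", total)
  sex_cat[sex == "F"] <- "Female"
  sex_cat[sex == "M"] <- "Male"
  sex_cat[sex == "UNK"] <- "Unknown"

  wt <- suppressWarnings(as.numeric(dt$wt))
  wt[!toupper(trimws(dt$wt_cod)) %in% "KG"] <- NA_real_
  wt_cat <- rep("Missing", total)
  wt_cat[!is.na(wt) & wt <= 50] <- "<=50 kg"
  wt_cat[!is.na(wt) & wt > 50 & wt <= 100] <- ">50-<=100 kg"
  wt_cat[!is.na(wt) & wt > 100] <- ">100 kg"

  occ <- toupper(trimws(dt$occp_cod))
  occ_cat <- rep("Not Available", total)
  known <- occ %in% names(.occp_labels)
  occ_cat[known] <- .occp_labels[occ[known]]
  occ_cat[!known & nzchar(occ)] <- "Others"

  ctry <- toupper(trimws(dt$reporter_country))
  ctry_cat <- rep("Others", total)
  named <- ctry %in% names(.country_labels)
  ctry_cat[named] <- .country_labels[ctry[named]]
  ctry_cat[!nzchar(ctry)] <- "Country Not Specified"

  tab <- function(char, cat, levels) {
    n <- vapply(levels, function(l) sum(cat == l), integer(1))
    data.table(characteristic = char, category = levels, n = n,
               pct = round_half_up(100 * n / total, 2))
  }
  rbind(
    tab("Age", age_cat, c("<18 years", "18-30 years", "31-50 years",
                          "51-65 years", ">65 years", "Missing")),
    tab("Sex", sex_cat, c("Female", "Male", "Missing", "Unknown")),
    tab("Weight", wt_cat, c("<=50 kg", ">50-<=100 kg", ">100 kg", "Missing")),
    tab("Occupation Reporter", occ_cat,
        c("Consumer", "Health Professional", "Medical Doctor", "Pharmacist",
          "Other Work", "Others", "Not Available")),
    tab("Reporter Country", ctry_cat,
        c("United States", "Canada", "United Kingdom", "Denmark",
          "Country Not Specified", "Others"))
  )
}

#' Run the full analysis pipeline on one or more quarter bundles
#'
#' Ingest, deduplicate, build the PS cohort, compute per-drug and per-ATC
#' disproportionality with signal flags, time-to-onset distributions and
#' the demographic summary, and assemble a run manifest with the row count
#' at every stage.
#'
#' @param bundles a `quarter_bundle`, a list of them, or a character vector
#'   of directories readable by [read_quarter()].
#' @param synonym_map optional named vector for [normalize_drug_name()].
#' @param atc_map optional data.table `(drug, atc)`; when `NULL`, ATC
#'   outputs are empty.
#' @param event_pt event preferred term (default `"Headache"`).
#' @param top_n number of drugs, ranked by event report frequency, kept in
#'   the drug signal table (default 100).
#' @param tto_top_k number of drugs in the per-drug TTO table (default 50).
#' @param outdir optional directory; when given, writes `demographics.tsv`,
#'   `signals_drug.tsv`, `signals_atc.tsv`, `tto_drug.tsv`, `tto_atc.tsv`
#'   and `manifest.json` there.
#' @return list with elements `manifest`, `demographics`, `signals_drug`,
#'   `signals_atc`, `tto_drug`, `tto_atc`, `background` (the flagged
#'   background set), `dedup_audit`.
#' @export
run_pipeline <- function(bundles, synonym_map = NULL, atc_map = NULL,
                         event_pt = "Headache", top_n = 100, tto_top_k = 50,
                         outdir = NULL) {
  if (inherits(bundles, "quarter_bundle")) bundles <- list(bundles)
  if (is.character(bundles)) bundles <- lapply(bundles, read_quarter)
  demo <- rbindlist(lapply(bundles, `[[`, "demo"))
  drug <- rbindlist(lapply(bundles, `[[`, "drug"))
  reac <- rbindlist(lapply(bundles, `[[`, "reac"))
  ther <- rbindlist(lapply(bundles, `[[`, "ther"))

  dd <- deduplicate(demo)
  bg <- build_background(dd$kept, drug, synonym_map)
  bg <- attach_event_flag(bg, reac, event_pt)

  cohort_ids <- bg$primaryid[bg$headache]
  demographics <- demographic_summary(dd$kept[primaryid %in% cohort_ids])

  tables <- contingency_tables(bg)
  signals_drug <- rank_top_n(signal_table(tables), top_n)

  if (!is.null(atc_map)) {
    signals_atc <- signal_table(atc_aggregate(bg, atc_map))
  } else {
    signals_atc <- signal_table(data.table(atc = character(0), n_drugs = integer(0),
                                           a = integer(0), b = integer(0),
                                           c = integer(0), d = integer(0)))
  }

  rec <- onset_records(bg, dd$kept, ther)
  tto_drug <- tto_distribution(rec, by = "drug")
  tto_drug <- tto_drug[seq_len(min(tto_top_k, nrow(tto_drug)))]
  if (!is.null(atc_map) && nrow(rec)) {
    rec_atc <- merge(rec, as.data.table(atc_map), by = "drug",
                     allow.cartesian = TRUE)
    tto_atc <- tto_distribution(rec_atc, by = "atc")
    ndr <- rec_atc[, .(n_drugs = uniqueN(drug)), by = atc]
    tto_atc <- merge(ndr, tto_atc, by = "atc")
    setorder(tto_atc, -n)
  } else {
    tto_atc <- tto_distribution(rec[0], by = "drug")
  }

  manifest <- list(
    tool = "pvsignal",
    version = as.character(utils::packageVersion("pvsignal")),
    event_pt = event_pt,
    top_n = top_n,
    tto_top_k = tto_top_k,
    stages = list(
      raw_report_versions = nrow(demo),
      duplicates_removed = dd$removed,
      unique_reports = nrow(dd$kept),
      no_primary_suspect_excluded = attr(bg, "n_no_ps"),
      multi_primary_suspect_resolved = attr(bg, "n_multi_ps"),
      background_reports = nrow(bg),
      event_reports = length(cohort_ids),
      distinct_ps_drugs = nrow(tables),
      tto_complete_cases = nrow(rec),
      tto_exclusions = as.list(attr(rec, "exclusions"))
    ),
    dedup = dedup_summary(nrow(demo), dd$removed),
    caveats = "No multiple-testing adjustment is applied to signal flags."
  )

  out <- list(manifest = manifest, demographics = demographics,
              signals_drug = signals_drug, signals_atc = signals_atc,
              tto_drug = tto_drug, tto_atc = tto_atc,
              background = bg, dedup_audit = dd$audit)
  if (!is.null(outdir)) write_pipeline_outputs(out, outdir)
  out
}

#' Write pipeline outputs as TSVs plus a JSON manifest
#'
#' Point estimates and CI bounds are rounded half-up to three decimals in
#' the written signal tables; the in-memory results keep full precision.
#'
#' @param results list returned by [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_pipeline_outputs <- function(results, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  round_sig <- function(dt) {
    dt <- copy(as.data.table(dt))
    for (col in intersect(c("ror", "ror_low", "ror_high",
                            "prr", "prr_low", "prr_high"), names(dt)))
      dt[, (col) := round_half_up(get(col), 3)]
    dt
  }
  paths <- c(
    demographics = file.path(outdir, "demographics.tsv"),
    signals_drug = file.path(outdir, "signals_drug.tsv"),
    signals_atc = file.path(outdir, "signals_atc.tsv"),
    tto_drug = file.path(outdir, "tto_drug.tsv"),
    tto_atc = file.path(outdir, "tto_atc.tsv")
  )
  fwrite(results$demographics, paths["demographics"], sep = "\t", quote = FALSE)
  fwrite(round_sig(results$signals_drug), paths["signals_drug"], sep = "\t",
         quote = FALSE)
  fwrite(round_sig(results$signals_atc), paths["signals_atc"], sep = "\t",
         quote = FALSE)
  fwrite(results$tto_drug, paths["tto_drug"], sep = "\t", quote = FALSE)
  fwrite(results$tto_atc, paths["tto_atc"], sep = "\t", quote = FALSE)
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(results$manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths["manifest"] <- mp
  invisible(paths)
}
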