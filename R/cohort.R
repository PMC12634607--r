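# Primary-suspect cohort construction and 2x2 contingency tables.
#
# The analysis unit is the report. Each deduplicated report contributes one
# (report, primary-suspect drug) pair to the background; secondary-suspect,
# interacting and concomitant mentions contribute nothing anywhere, which
# keeps the comparator ("all other drugs") clean of the drug under study.

#' Build the primary-suspect background set
#'
#' One row per kept report carrying a PS drug. Reports with no PS mention
#' are excluded and counted; a report with several PS rows keeps the one
#' with the lowest drug sequence number (FAERS lists the primary suspect
#' first) and increments an ambiguity counter.
#'
#' @param demo_kept deduplicated DEMO table ([deduplicate()] output).
#' @param drug DRUG table (all role codes; only PS rows are used).
#' @param synonym_map optional synonym map applied to drug names via
#'   [normalize_drug_name()].
#' @return data.table `(primaryid, caseid, ps_drug, drug_seq, start_dt)`,
#'   one row per background report, with attributes `n_no_ps` (reports
#'   lacking any PS drug) and `n_multi_ps` (reports with >1 PS row).
#' @export
build_background <- function(demo_kept, drug, synonym_map = NULL) {
  demo_kept <- as.data.table(demo_kept)
  drug <- as.data.table(drug)
  ps <- drug[role_cod == "PS" & primaryid %in% demo_kept$primaryid]
  ps[, ps_drug := normalize_drug_name(drugname, synonym_map)]
  ps <- ps[ps_drug != ""]

  ps[, seq_num := suppressWarnings(as.numeric(drug_seq))]
  ps[is.na(seq_num), seq_num := Inf]
  setorder(ps, primaryid, seq_num)
  n_multi <- sum(duplicated(ps$primaryid))
  ps <- unique(ps, by = "primaryid")

  bg <- ps[, .(primaryid, ps_drug, drug_seq, start_dt)]
  bg <- demo_kept[, .(primaryid, caseid)][bg, on = "primaryid"]
  n_no_ps <- nrow(demo_kept) - nrow(bg)
  setattr(bg, "n_no_ps", n_no_ps)
  setattr(bg, "n_multi_ps", n_multi)
  bg[]
}

#' Flag reports mentioning an event preferred term
#'
#' A report is flagged if any of its reaction preferred-term strings equals
#' `pt` after trimming and case folding. Matching is exact on the whole
#' string: subtype terms ("Migraine", "Tension headache") do not match
#' "Headache".
#'
#' @param reac REAC table with `primaryid` and `pt` columns.
#' @param pt MedDRA preferred term to match (default `"Headache"`).
#' @return character vector of `primaryid`s with at least one matching PT.
#' @export
flag_headache <- function(reac, pt = "Headache") {
  reac <- as.data.table(reac)
  target <- toupper(trimws(pt))
  unique(reac$primaryid[toupper(trimws(reac$pt)) == target])
}

#' Attach the event flag to a background set
#'
#' @param background output of [build_background()].
#' @param reac REAC table.
#' @param pt event preferred term.
#' @return the background with a logical `headache` column added.
#' @export
attach_event_flag <- function(background, reac, pt = "Headache") {
  bg <- copy(as.data.table(background))
  hits <- flag_headache(reac, pt)
  bg[, headache := primaryid %in% hits]
  bg[]
}

#' 2x2 contingency table for one drug against the background
#'
#' Cells follow the usual disproportionality layout: `a` = reports with the
#' drug of interest and the event, `b` = drug of interest and other events,
#' `c` = other drugs and the event, `d` = other drugs and other events.
#'
#' @param drug canonical drug name (or ATC class label when `background`
#'   carries class assignments).
#' @param background flagged background ([attach_event_flag()] output).
#' @return list of class `contingency_table`: `(drug, a, b, c, d)`.
#' @export
build_contingency <- function(drug, background) {
  bg <- as.data.table(background)
  if (!drug %in% bg$ps_drug)
    warning(sprintf("drug %s not present in background; a = b = 0", drug))
  on_drug <- bg$ps_drug == drug
  structure(list(
    drug = drug,
    a = sum(on_drug & bg$headache),
    b = sum(on_drug & !bg$headache),
    c = sum(!on_drug & bg$headache),
    d = sum(!on_drug & !bg$headache)
  ), class = "contingency_table")
}

#' All per-drug contingency tables at once
#'
#' @param background flagged background.
#' @return data.table `(drug, a, b, c, d)`, one row per distinct PS drug.
#' @export
contingency_tables <- function(background) {
  bg <- as.data.table(background)
  tot_event <- sum(bg$headache)
  tot <- nrow(bg)
  out <- bg[, .(a = sum(headache), b = sum(!headache)), by = .(drug = ps_drug)]
  out[, c := tot_event - a]
  out[, d := (tot - tot_event) - b]
  setorder(out, drug)
  out[]
}
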