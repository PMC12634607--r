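# Multi-version case deduplication.
#
# FAERS distributes every revision of a safety report: versions share a
# CASEID but carry distinct PRIMARYIDs and the FDA receipt date (FDA_DT) of
# each submission. Analyses must keep exactly one version per case. The
# rule implemented here: within a CASEID, keep the version with the latest
# FDA_DT; if FDA_DT ties, keep the highest PRIMARYID.

#' Collapse report versions to one report per case
#'
#' Keeps, within each `caseid` group, the row maximizing `(FDA_DT, then
#' numeric PRIMARYID)`. A missing or unparseable FDA_DT sorts before any
#' present date, so a dated version always beats an undated one. PRIMARYIDs
#' are compared numerically when all members of a tie group are digit
#' strings; otherwise the group falls back to lexicographic comparison and
#' a warning is logged. The result is independent of input row order.
#'
#' @param demo data.table (or data.frame) with at least `primaryid`,
#'   `caseid`, `fda_dt` columns; all other columns are carried through.
#' @return list with elements
#'   \describe{
#'     \item{kept}{data.table, one row per `caseid`, original columns}
#'     \item{removed}{integer, rows dropped}
#'     \item{audit}{data.table `(caseid, n_versions, kept_primaryid)`}
#'   }
#' @examples
#' demo <- data.frame(
#'   primaryid = c("100", "90", "100", "200"),
#'   caseid = c("C1", "C1", "C2", "C2"),
#'   fda_dt = c("20230101", "20230301", "20230101", "20230101")
#' )
#' deduplicate(demo)$kept # keeps C1/90 (later FDA_DT), C2/200 (higher id)
#' @export
deduplicate <- function(demo) {
  dt <- as.data.table(demo)
  if (!all(c("primaryid", "caseid", "fda_dt") %in% names(dt)))
    format_error("deduplicate needs columns primaryid, caseid, fda_dt")
  if (nrow(dt) == 0L)
    return(list(kept = dt, removed = 0L,
                audit = data.table(caseid = character(0),
                                   n_versions = integer(0),
                                   kept_primaryid = character(0))))

  ord <- dt[, .(primaryid, caseid)]
  # date key: numeric token value; missing/blank/non-digit sorts earliest
  fkey <- suppressWarnings(as.numeric(dt$fda_dt))
  fkey[is.na(fkey)] <- -Inf
  ord[, fkey := fkey]

  pid_num <- suppressWarnings(as.numeric(dt$primaryid))
  if (anyNA(pid_num)) {
    # identify caseid groups containing a non-numeric primaryid
    bad_groups <- unique(ord$caseid[is.na(pid_num)])
    warning(sprintf(
      "non-numeric PRIMARYID in %d case group(s); using lexicographic comparison there",
      length(bad_groups)))
    in_bad <- ord$caseid %in% bad_groups
    # rank within the union so numeric and string keys never mix in a group
    pid_key <- pid_num
    pid_key[in_bad] <- xtfrm(dt$primaryid[in_bad])
  } else {
    pid_key <- pid_num
  }
  ord[, pkey := pid_key]
  ord[, row := .I]

  setorder(ord, caseid, -fkey, -pkey)
  keep_rows <- ord[, row[1L], by = caseid]
  n_ver <- ord[, .N, by = caseid]

  kept <- dt[sort(keep_rows$V1)]
  audit <- data.table(caseid = keep_rows$caseid,
                      n_versions = n_ver[keep_rows, on = "caseid", N],
                      kept_primaryid = dt$primaryid[keep_rows$V1])
  setorder(audit, caseid)
  list(kept = kept, removed = nrow(dt) - nrow(kept), audit = audit)
}

#' Summarize a deduplication step
#'
#' @param before number of report versions before deduplication.
#' @param removed number of versions removed.
#' @return list `(before, removed, kept, removed_pct)`; `removed_pct` is
#'   `100 * removed / before` rounded half-up to one decimal, `NA` when
#'   `before` is zero.
#' @examples
#' dedup_summary(12150602, 2613846) # kept 9536756, removed_pct 21.5
#' @export
dedup_summary <- function(before, removed) {
  stopifnot(removed <= before, removed >= 0)
  list(before = before,
       removed = removed,
       kept = before - removed,
       removed_pct = if (before == 0) NA_real_ else
         round_half_up(100 * removed / before, 1))
}

#' Write the deduplication audit log
#'
#' @param audit the `audit` table from [deduplicate()].
#' @param path output TSV path.
#' @export
write_dedup_audit <- function(audit, path) {
  fwrite(audit, path, sep = "\t", quote = FALSE)
  invisible(path)
}
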