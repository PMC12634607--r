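# Time-to-onset (TTO): days from therapy start to the adverse-event date,
# binned into five clinically interpretable intervals.

.tto_bins <- c("<=7", "8-28", "29-60", "61-90", ">90")

#' Time-to-onset bin labels
#'
#' The five bins partition the nonnegative integers:
#' 0-7, 8-28, 29-60, 61-90, and 91 days or more.
#'
#' @return character vector of the five bin labels, in order.
#' @export
tto_bins <- function() .tto_bins

#' Onset in days from a start/event date-token pair
#'
#' Defined only when both tokens resolve to a full calendar day; truncated
#' (`YYYYMM`, `YYYY`), blank or impossible tokens exclude the pair, as do
#' negative differences (event before therapy start, indicating a data
#' error or a pre-existing event). Exclusions are categorized, never
#' silently dropped.
#'
#' @param start,event character vectors of raw FAERS date tokens (therapy
#'   start and adverse-event date), equal length.
#' @return data.table with columns `days` (integer, `NA` when excluded)
#'   and `status` (one of `"ok"`, `"incomplete_start"`,
#'   `"incomplete_event"`, `"negative"`).
#' @examples
#' onset_days("20240101", "20240101") # 0 days
#' onset_days("202401", "20240215")   # excluded: incomplete_start
#' @export
onset_days <- function(start, event) {
  stopifnot(length(start) == length(event))
  s <- parse_faers_date(start)
  e <- parse_faers_date(event)
  status <- rep("ok", nrow(s))
  status[e$resolution != "day"] <- "incomplete_event"
  status[s$resolution != "day"] <- "incomplete_start" # start takes precedence
  days <- rep(NA_integer_, nrow(s))
  both <- status == "ok"
  days[both] <- as.integer(e$value[both] - s$value[both])
  neg <- both & days < 0L
  status[neg] <- "negative"
  days[neg] <- NA_integer_
  data.table(days = days, status = status)
}

#' Assign onset days to the five TTO bins
#'
#' @param days integer vector of nonnegative onset days.
#' @return factor with levels `tto_bins()`.
#' @examples
#' bin_onset(c(0, 7, 8, 90, 91)) # <=7, <=7, 8-28, 61-90, >90
#' @export
bin_onset <- function(days) {
  if (any(days < 0, na.rm = TRUE)) stop("bin_onset: negative onset days")
  cut(days, breaks = c(-0.5, 7.5, 28.5, 60.5, 90.5, Inf),
      labels = .tto_bins)
}

#' Build onset records for an event cohort
#'
#' For each event-flagged background report, the PS drug's start date is
#' taken from the DRUG row when present and from the THER row matching the
#' drug sequence otherwise; the event date comes from DEMO. Only complete,
#' nonnegative date pairs yield a record.
#'
#' @param background flagged background ([attach_event_flag()]), restricted
#'   here to `headache == TRUE` rows.
#' @param demo deduplicated DEMO table (for `event_dt`).
#' @param ther THER table (start-date fallback).
#' @return data.table `(primaryid, drug, onset_days, bin)` with attribute
#'   `exclusions`, a named integer vector over
#'   `c("incomplete_start", "incomplete_event", "negative")`.
#' @export
onset_records <- function(background, demo, ther) {
  bg <- as.data.table(background)[headache == TRUE]
  demo <- as.data.table(demo)
  ther <- as.data.table(ther)

  rec <- bg[, .(primaryid, drug = ps_drug, drug_seq, start_dt)]
  rec <- demo[, .(primaryid, event_dt)][rec, on = "primaryid"]
  # fallback: THER start date for the same drug sequence
  th <- ther[, .(primaryid, drug_seq = dsg_drug_seq, ther_start = start_dt)]
  th <- unique(th, by = c("primaryid", "drug_seq"))
  rec <- th[rec, on = c("primaryid", "drug_seq")]
  blank <- is.na(rec$start_dt) | rec$start_dt == ""
  usable <- !is.na(rec$ther_start) & rec$ther_start != ""
  rec[blank & usable, start_dt := ther_start]

  od <- onset_days(rec$start_dt, rec$event_dt)
  excl <- c(incomplete_start = sum(od$status == "incomplete_start"),
            incomplete_event = sum(od$status == "incomplete_event"),
            negative = sum(od$status == "negative"))
  out <- rec[od$status == "ok", .(primaryid, drug)]
  out[, onset_days := od$days[od$status == "ok"]]
  out[, bin := bin_onset(onset_days)]
  setattr(out, "exclusions", excl)
  out[]
}

#' Tabulate the TTO distribution per group
#'
#' Per group: total complete cases `n`, then per-bin count and percentage
#' (`100 * count / n`, rounded half-up to one decimal). Percentages are
#' computed independently per bin; they are not forced to sum to 100.
#' Empty groups are omitted.
#'
#' @param records onset records ([onset_records()] output, or any table
#'   with a grouping column, and `bin`).
#' @param by name of the grouping column (default `"drug"`; use `"atc"`
#'   after joining class assignments).
#' @return data.table: group column, `n`, then `n_<bin>` and `pct_<bin>`
#'   for each of the five bins.
#' @examples
#' r <- data.table::data.table(
#'   drug = "X", bin = bin_onset(c(0, 3, 10, 95)))
#' tto_distribution(r) # n 4; <=7 50.0%, 8-28 25.0%, >90 25.0%
#' @export
tto_distribution <- function(records, by = "drug") {
  dt <- as.data.table(records)
  if (!by %in% names(dt)) format_error(sprintf("no grouping column '%s'", by))
  dt <- dt[!is.na(dt[[by]])]
  counts <- dcast(dt[, .N, by = c(by, "bin")],
                  stats::as.formula(paste(by, "~ bin")),
                  value.var = "N", fill = 0L, drop = c(TRUE, FALSE))
  for (bn in .tto_bins) if (!bn %in% names(counts)) counts[, (bn) := 0L]
  counts[, n := rowSums(.SD), .SDcols = .tto_bins]
  out <- counts[n > 0L, c(by, "n", .tto_bins), with = FALSE]
  for (bn in .tto_bins) {
    setnames(out, bn, paste0("n_", bn))
    out[, (paste0("pct_", bn)) :=
          round_half_up(100 * get(paste0("n_", bn)) / n, 1)]
  }
  setcolorder(out, c(by, "n",
                     as.vector(rbind(paste0("n_", .tto_bins),
                                     paste0("pct_", .tto_bins)))))
  setorder(out, -n)
  out[]
}
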