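# Disproportionality statistics on 2x2 report tables.
#
# ROR = (a*d)/(b*c), PRR = [a/(a+b)] / [c/(c+d)], each with a Wald 95% CI
# on the log scale (quantile 1.96). Zero cells make the ROR (any empty
# cell) or the PRR (a = 0 or c = 0) undefined; no continuity correction is
# applied — an undefined estimate is reported as such rather than a
# corrected value silently reshuffling the ranking.

#' Reporting odds ratio with 95% confidence interval
#'
#' `point = (a*d)/(b*c)`; `log_se = sqrt(1/a + 1/b + 1/c + 1/d)`;
#' `CI = exp(log(point) +/- 1.96 * log_se)`. Any zero among `a, b, c, d`
#' yields an undefined estimate with `zero_cell = TRUE`.
#'
#' @param table a `contingency_table` from [build_contingency()], or any
#'   list/row with numeric `a`, `b`, `c`, `d`.
#' @return list of class `signal_estimate`:
#'   `(measure, point, ci_low, ci_high, log_se, zero_cell, table)`;
#'   numeric fields are `NA` when undefined.
#' @examples
#' ror(list(a = 20, b = 80, c = 100, d = 900)) # point 2.25, CI [1.32, 3.83]
#' @export
ror <- function(table) {
  a <- table$a; b <- table$b; cc <- table$c; dd <- table$d
  if (min(a, b, cc, dd) == 0) return(undefined_estimate("ROR", table))
  point <- (a * dd) / (b * cc)
  log_se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / dd)
  make_estimate("ROR", point, log_se, table)
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' `point = (a/(a+b)) / (c/(c+d))`;
#' `log_se = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`. Undefined when `a = 0`
#' or `c = 0` (or an empty margin); `b = 0` is legal.
#'
#' @inheritParams ror
#' @return list of class `signal_estimate`, as for [ror()].
#' @examples
#' prr(list(a = 20, b = 80, c = 100, d = 900)) # point 2.0, CI [1.30, 3.09]
#' @export
prr <- function(table) {
  a <- table$a; b <- table$b; cc <- table$c; dd <- table$d
  if (a == 0 || cc == 0 || (a + b) == 0 || (cc + dd) == 0)
    return(undefined_estimate("PRR", table))
  point <- (a / (a + b)) / (cc / (cc + dd))
  log_se <- sqrt(1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + dd))
  make_estimate("PRR", point, log_se, table)
}

make_estimate <- function(measure, point, log_se, table) {
  structure(list(
    measure = measure,
    point = point,
    ci_low = exp(log(point) - 1.96 * log_se),
    ci_high = exp(log(point) + 1.96 * log_se),
    log_se = log_se,
    zero_cell = FALSE,
    table = table
  ), class = "signal_estimate")
}

undefined_estimate <- function(measure, table) {
  structure(list(
    measure = measure, point = NA_real_, ci_low = NA_real_,
    ci_high = NA_real_, log_se = NA_real_, zero_cell = TRUE, table = table
  ), class = "signal_estimate")
}

#' @export
print.signal_estimate <- function(x, ...) {
  if (x$zero_cell) {
    cat(sprintf("%s: undefined (zero cell)\n", x$measure))
  } else {
    cat(sprintf("%s %.3f (95%% CI %.3f-%.3f)\n",
                x$measure, x$point, x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Classify a drug-event pair as a signal
#'
#' Positive signal: both ROR and PRR point estimates exceed 1 and both
#' lower 95% confidence bounds exceed 1. Any undefined quantity gives
#' `is_signal = FALSE`.
#'
#' @param ror_est,prr_est `signal_estimate`s computed from the same table.
#' @return list `(drug, ror, prr, is_signal)`.
#' @export
classify_signal <- function(ror_est, prr_est) {
  ok <- !ror_est$zero_cell && !prr_est$zero_cell
  is_signal <- ok &&
    ror_est$point > 1 && prr_est$point > 1 &&
    ror_est$ci_low > 1 && prr_est$ci_low > 1
  list(drug = ror_est$table$drug %||% NA_character_,
       ror = ror_est, prr = prr_est, is_signal = isTRUE(is_signal))
}

#' Vectorized signal table over per-drug contingency rows
#'
#' @param tables data.table from [contingency_tables()] (columns `drug`,
#'   `a`, `b`, `c`, `d`; for ATC classes the first column may be `atc`).
#' @return data.table adding `ror`, `ror_low`, `ror_high`, `prr`,
#'   `prr_low`, `prr_high`, `signal` (logical), with estimate columns `NA`
#'   where undefined.
#' @export
signal_table <- function(tables) {
  dt <- copy(as.data.table(tables))
  a <- dt$a; b <- dt$b; cc <- dt$c; dd <- dt$d
  ror_ok <- a > 0 & b > 0 & cc > 0 & dd > 0
  pt <- ifelse(ror_ok, (a * dd) / (b * cc), NA_real_)
  se <- ifelse(ror_ok, sqrt(1 / a + 1 / b + 1 / cc + 1 / dd), NA_real_)
  dt[, ror := pt]
  dt[, ror_low := exp(log(pt) - 1.96 * se)]
  dt[, ror_high := exp(log(pt) + 1.96 * se)]
  prr_ok <- a > 0 & cc > 0 & (a + b) > 0 & (cc + dd) > 0
  pp <- ifelse(prr_ok, (a / (a + b)) / (cc / (cc + dd)), NA_real_)
  pse <- ifelse(prr_ok, sqrt(1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + dd)), NA_real_)
  dt[, prr := pp]
  dt[, prr_low := exp(log(pp) - 1.96 * pse)]
  dt[, prr_high := exp(log(pp) + 1.96 * pse)]
  dt[, signal := ror_ok & prr_ok &
       ror > 1 & prr > 1 & ror_low > 1 & prr_low > 1]
  dt[is.na(signal), signal := FALSE]
  dt[]
}

#' Rank drugs by report frequency
#'
#' Descending by the event-with-drug count `a`; ties broken alphabetically
#' by name. Mirrors "top N most frequently reported" selection.
#'
#' @param tables data.table with `a` and a name column (`drug` or `atc`).
#' @param n number of rows to keep (clamped to what is available).
#' @return the top-`n` rows, reordered.
#' @export
rank_top_n <- function(tables, n = 100) {
  dt <- as.data.table(tables)
  key <- if ("drug" %in% names(dt)) "drug" else "atc"
  ord <- order(-dt$a, dt[[key]])
  dt[ord[seq_len(min(n, nrow(dt)))]]
}

#' Pool per-drug counts into ATC level-2 class tables
#'
#' For each class, `a` and `b` are summed over member drugs present in the
#' background; `c` and `d` come from the complement (all reports whose PS
#' drug is outside the class). A drug mapped to several classes contributes
#' to each, with a warning, so class tables may overlap. Unmapped drugs are
#' excluded from every class table (but remain in each complement) and
#' counted.
#'
#' @param background flagged background ([attach_event_flag()]).
#' @param atc_map data.table `(drug, atc)`; see [load_atc_map()].
#' @return data.table `(atc, n_drugs, a, b, c, d)` with attribute
#'   `n_unmapped_drugs`.
#' @export
atc_aggregate <- function(background, atc_map) {
  bg <- as.data.table(background)
  atc_map <- unique(as.data.table(atc_map)[, .(drug, atc)])
  per_drug <- contingency_tables(bg)
  mapped <- atc_map[per_drug, on = "drug", nomatch = NULL]
  n_unmapped <- length(setdiff(per_drug$drug, atc_map$drug))
  multi <- atc_map[drug %in% per_drug$drug, .N, by = drug][N > 1L]
  if (nrow(multi))
    warning(sprintf("%d drug(s) map to more than one ATC class; class tables overlap",
                    nrow(multi)))
  tot_event <- sum(bg$headache)
  tot <- nrow(bg)
  out <- mapped[, .(n_drugs = uniqueN(drug), a = sum(a), b = sum(b)), by = atc]
  out[, c := tot_event - a]
  out[, d := (tot - tot_event) - b]
  setorder(out, atc)
  setattr(out, "n_unmapped_drugs", n_unmapped)
  out[]
}
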