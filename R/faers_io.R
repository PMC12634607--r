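# Reading/writing FAERS-style quarterly ASCII bundles, date-token parsing,
# and drug-name normalization.
#
# A "quarter bundle" is a list of four data.tables mirroring the FAERS
# quarterly extract: DEMO (one row per report version), DRUG (one row per
# drug mention), REAC (one row per reaction preferred term) and THER (therapy
# dates per drug sequence), all keyed by PRIMARYID. The synthetic generator
# additionally attaches a `truth` table used only by tests.

# canonical column sets; extra columns in input files are ignored
.bundle_cols <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "wt", "wt_cod", "occp_cod", "reporter_country"),
  drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname",
           "start_dt"),
  reac = c("primaryid", "caseid", "pt"),
  ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt", "end_dt")
)

.role_codes <- c("PS", "SS", "I", "C")

#' Parse FAERS numeric date tokens
#'
#' FAERS stores dates as digit strings that may be truncated: `YYYYMMDD`
#' (full day), `YYYYMM` (month known), `YYYY` (year known). Anything else —
#' empty, non-digit, or a nonexistent calendar day such as `"20230230"` —
#' is classified `invalid`. The function is total: it never errors.
#'
#' @param token character vector of raw date tokens (NA allowed).
#' @return a data.table with columns `raw` (the input as character),
#'   `resolution` (one of `"day"`, `"month"`, `"year"`, `"invalid"`) and
#'   `value` (a `Date`, non-NA only when `resolution == "day"`).
#' @examples
#' parse_faers_date(c("20240315", "202403", "2024", "20230230", ""))
#' @export
parse_faers_date <- function(token) {
  raw <- as.character(token)
  raw[is.na(raw)] <- ""
  raw <- trimws(raw)
  resolution <- rep("invalid", length(raw))
  value <- rep(as.Date(NA), length(raw))

  digits <- grepl("^[0-9]+$", raw)
  resolution[digits & nchar(raw) == 4L] <- "year"

  is6 <- digits & nchar(raw) == 6L
  mm <- substr(raw, 5L, 6L)
  resolution[is6 & mm >= "01" & mm <= "12"] <- "month"

  is8 <- which(digits & nchar(raw) == 8L)
  if (length(is8)) {
    d <- as.Date(raw[is8], format = "%Y%m%d") # NA for impossible days
    ok <- !is.na(d)
    resolution[is8[ok]] <- "day"
    value[is8[ok]] <- d[ok]
  }
  data.table(raw = raw, resolution = resolution, value = value)
}

#' Canonicalize and standardize drug names
#'
#' Verbatim FAERS drug strings mix brand and generic names, case, stray
#' whitespace and two conventions for combination products (`"A/B"` and
#' `"A\B"`). Canonical form is uppercase, trimmed, internal whitespace
#' collapsed, and combination components joined by a backslash. A synonym
#' map (brand or variant to canonical generic) is applied *after*
#' canonicalization and iterated to a fixed point, so the function is
#' idempotent even for chained map entries.
#'
#' @param raw character vector of verbatim drug names.
#' @param synonym_map named character vector mapping variant to canonical
#'   name (both sides are canonicalized before use), or `NULL` for none.
#'   See [load_synonym_map()].
#' @return character vector of canonical names.
#' @examples
#' normalize_drug_name("  Humira ", c(HUMIRA = "ADALIMUMAB"))
#' normalize_drug_name("glecaprevir/pibrentasvir")
#' @export
normalize_drug_name <- function(raw, synonym_map = NULL) {
  x <- canonicalize_name(raw)
  if (length(synonym_map)) {
    keys <- canonicalize_name(names(synonym_map))
    vals <- canonicalize_name(unname(synonym_map))
    for (i in 1:10) { # fixed point; cap guards accidental cycles
      hit <- match(x, keys)
      found <- !is.na(hit)
      if (!any(found)) break
      nxt <- x
      nxt[found] <- vals[hit[found]]
      if (identical(nxt, x)) break
      x <- nxt
    }
  }
  x
}

canonicalize_name <- function(raw) {
  x <- toupper(as.character(raw))
  x[is.na(x)] <- ""
  x <- gsub("[[:space:]]+", " ", trimws(x))
  # combination products: slash or backslash, with or without spaces -> "\"
  gsub("[[:space:]]*[/\\\\][[:space:]]*", "\\\\", x)
}

#' Load a drug synonym map from a two-column TSV
#'
#' @param path TSV file with columns `variant` and `canonical` (header
#'   required; extra columns ignored).
#' @return named character vector suitable for [normalize_drug_name()].
#' @export
load_synonym_map <- function(path) {
  if (!file.exists(path)) config_error(sprintf("synonym map not found: %s", path))
  m <- fread(path, sep = "\t", colClasses = "character", header = TRUE)
  if (!all(c("variant", "canonical") %in% names(m)))
    format_error(sprintf("synonym map %s must have columns 'variant' and 'canonical'", path))
  stats::setNames(canonicalize_name(m$canonical), canonicalize_name(m$variant))
}

#' Load a drug-to-ATC-class map from a two-column TSV
#'
#' @param path TSV file with columns `drug` (canonical drug name) and `atc`
#'   (ATC level-2 code, e.g. `"L04"`). A drug may appear on several rows if
#'   it belongs to more than one class.
#' @return data.table with columns `drug`, `atc`.
#' @export
load_atc_map <- function(path) {
  if (!file.exists(path)) config_error(sprintf("ATC map not found: %s", path))
  m <- fread(path, sep = "\t", colClasses = "character", header = TRUE)
  if (!all(c("drug", "atc") %in% names(m)))
    format_error(sprintf("ATC map %s must have columns 'drug' and 'atc'", path))
  out <- data.table(drug = canonicalize_name(m$drug), atc = toupper(trimws(m$atc)))
  unique(out)
}

#' Read one FAERS-style quarter into a bundle
#'
#' Accepts either a directory containing files whose names start with
#' `DEMO`, `DRUG`, `REAC`, `THER` (the FAERS ASCII dialect: dollar-delimited,
#' one header row), or a named list/vector of explicit paths. Rows missing
#' `primaryid`, and DRUG rows with a role code outside `PS/SS/I/C`, are
#' dropped and counted, never silently kept. Extra columns are ignored;
#' a missing mandatory column is a format error naming file and column.
#'
#' @param paths directory path, or named character vector with names among
#'   `demo`, `drug`, `reac`, `ther`.
#' @return an object of class `quarter_bundle`: a list with data.tables
#'   `demo`, `drug`, `reac`, `ther` (missing files yield zero-row tables),
#'   plus attributes `row_counts` and `dropped` (per-table drop counts).
#' @export
read_quarter <- function(paths) {
  if (length(paths) == 1L && is.null(names(paths)) && dir.exists(paths)) {
    files <- list.files(paths, full.names = TRUE)
    base <- toupper(basename(files))
    paths <- c(
      demo = files[startsWith(base, "DEMO")][1],
      drug = files[startsWith(base, "DRUG")][1],
      reac = files[startsWith(base, "REAC")][1],
      ther = files[startsWith(base, "THER")][1]
    )
    paths <- paths[!is.na(paths)]
  }
  if (is.null(names(paths)) || !any(names(paths) %in% names(.bundle_cols)))
    config_error("read_quarter needs a directory or paths named demo/drug/reac/ther")

  bundle <- list()
  dropped <- integer(0)
  for (tbl in names(.bundle_cols)) {
    want <- .bundle_cols[[tbl]]
    if (!tbl %in% names(paths) || is.na(paths[[tbl]])) {
      bundle[[tbl]] <- empty_table(tbl)
      dropped[tbl] <- 0L
      next
    }
    p <- paths[[tbl]]
    if (!file.exists(p)) config_error(sprintf("file not found: %s", p))
    dt <- fread(p, sep = "$", colClasses = "character", header = TRUE,
                fill = TRUE, na.strings = NULL)
    missing_cols <- setdiff(want, names(dt))
    if (length(missing_cols))
      format_error(sprintf("file %s is missing mandatory column(s): %s",
                           p, paste(missing_cols, collapse = ", ")))
    dt <- dt[, want, with = FALSE]
    n0 <- nrow(dt)
    dt <- dt[!is.na(primaryid) & primaryid != ""]
    if (tbl == "drug") dt <- dt[role_cod %in% .role_codes]
    dropped[tbl] <- n0 - nrow(dt)
    bundle[[tbl]] <- dt
  }
  as_quarter_bundle(bundle, dropped = dropped)
}

empty_table <- function(tbl) {
  cols <- .bundle_cols[[tbl]]
  dt <- as.data.table(stats::setNames(rep(list(character(0)), length(cols)), cols))
  dt
}

as_quarter_bundle <- function(x, dropped = NULL) {
  stopifnot(all(names(.bundle_cols) %in% names(x)))
  structure(x,
            class = "quarter_bundle",
            row_counts = vapply(x[names(.bundle_cols)], nrow, integer(1)),
            dropped = dropped)
}

#' @export
print.quarter_bundle <- function(x, ...) {
  n <- attr(x, "row_counts")
  cat("<quarter_bundle>",
      sprintf(" %s: %d rows", names(n), n), sep = "\n")
  if (!is.null(x$truth)) cat(sprintf(" truth: %d cases\n", nrow(x$truth)))
  invisible(x)
}

#' Write a bundle as FAERS-style dollar-delimited quarter files
#'
#' Emits `DEMO<q>.txt`, `DRUG<q>.txt`, `REAC<q>.txt`, `THER<q>.txt` into
#' `dir`, plus `truth_<q>.tsv` when the bundle carries a generator truth
#' table. Output is plain text with one header row, readable back with
#' [read_quarter()].
#'
#' @param bundle a `quarter_bundle`.
#' @param dir output directory (created if needed).
#' @param quarter quarter tag used in file names, e.g. `"24Q1"`.
#' @return invisibly, the named vector of written paths.
#' @export
write_quarter <- function(bundle, dir, quarter = "24Q1") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c()
  for (tbl in names(.bundle_cols)) {
    p <- file.path(dir, sprintf("%s%s.txt", toupper(tbl), quarter))
    fwrite(bundle[[tbl]], p, sep = "$", quote = FALSE, na = "")
    paths[tbl] <- p
  }
  if (!is.null(bundle$truth)) {
    p <- file.path(dir, sprintf("truth_%s.tsv", quarter))
    fwrite(bundle$truth, p, sep = "\t", quote = FALSE, na = "")
    paths["truth"] <- p
  }
  invisible(paths)
}
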