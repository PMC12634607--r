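# Synthetic FAERS-like report generator with planted association strengths.
#
# Every downstream stage (dedup, cohort, disproportionality, TTO,
# demographics) is validated against bundles produced here, where the truth
# is known by construction. Headache is planted through an odds model: a
# case whose primary-suspect (PS) drug has planted reporting odds ratio r
# receives headache with odds r times the background odds, so the ROR
# estimated from the 2x2 table is consistent for r whenever the comparator
# drugs carry r = 1.

# Table-1-shaped categorical distributions for demographics (counts from a
# 313,166-case headache cohort; used as realistic sampling weights).
.demo_dists <- list(
  age_bands = c("<18" = 9184, "18-30" = 17472, "31-50" = 56794,
                "51-65" = 66862, ">65" = 48343),
  sex = c(F = 208746, M = 72601, UNK = 345),
  weight_bands = c("<=50" = 6533, "50-100" = 66462, ">100" = 10548),
  occupation = stats::setNames(
    c(171354, 49874, 46659, 16296, 1601, 20337, 7045),
    c("CN", "HP", "MD", "PH", "LW", "OT", "")), # "" = not available
  country = stats::setNames(
    c(206270, 37782, 12904, 7381, 8271, 40558),
    c("US", "CA", "GB", "DK", "", "OTHER")) # "" = country not specified
)
.other_countries <- c("FR", "DE", "IT", "JP", "AU", "NL", "ES", "BR")

# precomputed YYYYMMDD tokens (date formatting dominates generation cost)
.tok_origin <- as.Date("2016-01-01")
.tok_cache <- format(seq(.tok_origin, as.Date("2026-12-31"), by = "day"),
                     "%Y%m%d")
date_token <- function(d) {
  o <- as.integer(d - .tok_origin) + 1L
  out <- .tok_cache[o]
  slow <- is.na(out) & !is.na(d) # outside the cached range
  if (any(slow)) out[slow] <- format(d[slow], "%Y%m%d")
  out
}
.other_pts <- c("Nausea", "Fatigue", "Dizziness", "Rash", "Pyrexia",
                "Migraine", "Tension headache", "Arthralgia", "Diarrhoea")

#' Specify one synthetic drug
#'
#' @param name drug name (canonicalized internally).
#' @param target_ror planted reporting odds ratio for headache (> 0); 1
#'   means no association.
#' @param marginal_share fraction of reports carrying this drug as PS, in
#'   (0, 1).
#' @param atc_code ATC level-2 class code, e.g. `"L04"`.
#' @param onset_mixture optional length-5 probability vector over the TTO
#'   bins `tto_bins()`; falls back to the config default.
#' @return list of class `drug_spec`.
#' @export
drug_spec <- function(name, target_ror = 1, marginal_share = 0.05,
                      atc_code = "L04", onset_mixture = NULL) {
  name <- canonicalize_name(name)
  if (!nzchar(name)) config_error("drug name must be nonempty", "name")
  if (!is.numeric(target_ror) || target_ror <= 0)
    config_error("target_ror must be > 0", "target_ror")
  if (marginal_share <= 0 || marginal_share >= 1)
    config_error("marginal_share must be in (0,1)", "marginal_share")
  if (!is.null(onset_mixture)) check_mixture(onset_mixture, name)
  structure(list(name = name, target_ror = target_ror,
                 marginal_share = marginal_share, atc_code = atc_code,
                 onset_mixture = onset_mixture),
            class = "drug_spec")
}

check_mixture <- function(w, who) {
  if (length(w) != 5L || any(w < 0) || abs(sum(w) - 1) > 1e-9)
    config_error(sprintf("onset mixture for %s must be 5 nonnegative weights summing to 1", who),
                 "onset_mixture")
  invisible(w)
}

#' Configure the synthetic report generator
#'
#' Defaults emulate the FAERS headache corpus: a ~3.3% background headache
#' reporting rate, a duplicate-version fraction chosen so that roughly a
#' fifth of all report versions are removed at deduplication, and
#' demographic missingness at the rates seen in large headache cohorts
#' (37% age, 10% sex, 73% weight). If the drugs' marginal shares sum to
#' less than 1, the remainder is split over ten neutral background drugs
#' (`target_ror = 1`, unmapped ATC).
#'
#' @param n_cases number of distinct cases (>= 1).
#' @param drugs list of [drug_spec()] objects.
#' @param background_headache_rate probability of headache for a case whose
#'   PS drug has `target_ror = 1`, in (0, 1).
#' @param dup_fraction fraction of cases emitted as >= 2 report versions,
#'   in \[0, 1).
#' @param missing_age_rate,missing_sex_rate,missing_weight_rate
#'   demographic missingness probabilities, in \[0, 1\].
#' @param partial_date_rate probability that a start or event date token is
#'   truncated to `YYYYMM` or `YYYY`, in \[0, 1\].
#' @param onset_mixture default length-5 TTO bin mixture for drugs that do
#'   not set their own.
#' @param seed integer RNG seed; generation is byte-identical for a fixed
#'   seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_cases,
                             drugs,
                             background_headache_rate = 0.033,
                             dup_fraction = 0.27,
                             missing_age_rate = 0.366,
                             missing_sex_rate = 0.10,
                             missing_weight_rate = 0.733,
                             partial_date_rate = 0.25,
                             onset_mixture = c(0.45, 0.13, 0.07, 0.04, 0.31),
                             seed = 1L) {
  if (!is.numeric(n_cases) || n_cases < 1)
    config_error("n_cases must be >= 1", "n_cases")
  if (!length(drugs) || !all(vapply(drugs, inherits, TRUE, "drug_spec")))
    config_error("drugs must be a list of drug_spec objects", "drugs")
  if (background_headache_rate <= 0 || background_headache_rate >= 1)
    config_error("background_headache_rate must be in (0,1)",
                 "background_headache_rate")
  if (dup_fraction < 0 || dup_fraction >= 1)
    config_error("dup_fraction must be in [0,1)", "dup_fraction")
  for (f in c("missing_age_rate", "missing_sex_rate", "missing_weight_rate",
              "partial_date_rate")) {
    v <- get(f)
    if (v < 0 || v > 1) config_error(sprintf("%s must be in [0,1]", f), f)
  }
  check_mixture(onset_mixture, "config default")
  shares <- vapply(drugs, `[[`, 0, "marginal_share")
  if (sum(shares) > 1 + 1e-9)
    config_error("drug marginal shares sum to more than 1", "drugs")
  nm <- vapply(drugs, `[[`, "", "name")
  if (anyDuplicated(nm)) config_error("duplicate drug names", "drugs")

  rest <- 1 - sum(shares)
  if (rest > 1e-9) {
    fillers <- lapply(1:10, function(i)
      drug_spec(sprintf("BACKGROUND DRUG %02d", i), target_ror = 1,
                marginal_share = rest / 10, atc_code = ""))
    drugs <- c(drugs, fillers)
  }
  structure(list(
    n_cases = as.integer(n_cases), drugs = drugs,
    background_headache_rate = background_headache_rate,
    dup_fraction = dup_fraction,
    missing_age_rate = missing_age_rate,
    missing_sex_rate = missing_sex_rate,
    missing_weight_rate = missing_weight_rate,
    partial_date_rate = partial_date_rate,
    onset_mixture = onset_mixture,
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' Default study-scale configuration
#'
#' 50,000 cases over a 20-drug panel: three planted headache signals
#' (odds ratios 4, 2.5 and 2), seventeen neutral drugs across several ATC
#' classes, plus the background filler pool.
#'
#' @param n_cases number of cases (default 50000).
#' @param seed RNG seed.
#' @return a `generator_config`.
#' @export
default_generator_config <- function(n_cases = 50000, seed = 1L) {
  early <- c(0.70, 0.15, 0.06, 0.03, 0.06)
  late <- c(0.16, 0.12, 0.07, 0.05, 0.60)
  panel <- list(
    drug_spec("SIGNALDIPINE", 4.0, 0.04, "C08", early),
    drug_spec("CEPHALGINIB", 2.5, 0.05, "L01", late),
    drug_spec("MIGRAMAB", 2.0, 0.05, "L04"),
    drug_spec("ADALIMUMAB", 1, 0.06, "L04", late),
    drug_spec("APREMILAST", 1, 0.05, "L04"),
    drug_spec("TREPROSTINIL", 1, 0.04, "B01", late),
    drug_spec("DUPILUMAB", 1, 0.04, "D11"),
    drug_spec("OFATUMUMAB", 1, 0.04, "L04", early),
    drug_spec("SECUKINUMAB", 1, 0.04, "L04"),
    drug_spec("METHOTREXATE", 1, 0.04, "L04"),
    drug_spec("SEMAGLUTIDE", 1, 0.04, "A10", early),
    drug_spec("ACETAMINOPHEN", 1, 0.04, "N02", early),
    drug_spec("IBUPROFEN", 1, 0.03, "M01", early),
    drug_spec("SERTRALINE", 1, 0.03, "N06"),
    drug_spec("AMLODIPINE BESYLATE", 1, 0.03, "C08"),
    drug_spec("LEVOTHYROXINE SODIUM", 1, 0.03, "H03"),
    drug_spec("GLECAPREVIR\\PIBRENTASVIR", 1, 0.02, "J05"),
    drug_spec("RITUXIMAB", 1, 0.02, "L01"),
    drug_spec("OCRELIZUMAB", 1, 0.02, "L04"),
    drug_spec("ETANERCEPT", 1, 0.02, "L04")
  )
  generator_config(n_cases = n_cases, drugs = panel, seed = seed)
}

#' ATC map implied by a generator configuration
#'
#' @param config a `generator_config`.
#' @return data.table `(drug, atc)` covering drugs with a nonempty class.
#' @export
config_atc_map <- function(config) {
  out <- data.table(
    drug = vapply(config$drugs, `[[`, "", "name"),
    atc = vapply(config$drugs, `[[`, "", "atc_code"))
  out[atc != ""]
}

#' Generate a synthetic quarter bundle
#'
#' Produces linked DEMO/DRUG/REAC/THER tables plus a `truth` table for
#' tests (`caseid`, current `primaryid`, PS drug, headache flag, true onset
#' days and bin). Every DRUG/REAC/THER row joins to a DEMO row; each case
#' carries exactly one PS drug; headache is Bernoulli with odds =
#' background odds x the PS drug's `target_ror`. When `dup_fraction > 0`,
#' [inject_duplicates()] is applied as the final step.
#'
#' @param config a [generator_config()].
#' @return a `quarter_bundle` with a `truth` element.
#' @export
generate_bundle <- function(config) {
  if (!inherits(config, "generator_config"))
    config_error("config must be a generator_config")
  with_seed(config$seed, {
    bundle <- generate_single_versions(config)
    if (config$dup_fraction > 0)
      bundle <- inject_duplicates(bundle, config$dup_fraction, seed = NULL)
    bundle
  })
}

generate_single_versions <- function(config) {
  n <- config$n_cases
  drugs <- config$drugs
  nm <- vapply(drugs, `[[`, "", "name")
  shares <- vapply(drugs, `[[`, 0, "marginal_share")
  rors <- vapply(drugs, `[[`, 0, "target_ror")

  caseid <- sprintf("%08d", 10000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  idx <- sample.int(length(drugs), n, replace = TRUE, prob = shares)
  bg_odds <- config$background_headache_rate / (1 - config$background_headache_rate)
  odds <- bg_odds * rors[idx]
  headache <- stats::rbinom(n, 1L, odds / (1 + odds)) == 1L

  # onset days from the per-drug bin mixture, uniform within bin
  mix <- t(vapply(drugs, function(d) d$onset_mixture %||% config$onset_mixture,
                  numeric(5)))
  bin_idx <- integer(n)
  for (j in seq_along(drugs)) {
    sel <- idx == j
    if (any(sel))
      bin_idx[sel] <- sample.int(5L, sum(sel), replace = TRUE, prob = mix[j, ])
  }
  lo <- c(0L, 8L, 29L, 61L, 91L)[bin_idx]
  hi <- c(7L, 28L, 60L, 90L, 365L)[bin_idx]
  onset <- lo + floor(stats::runif(n) * (hi - lo + 1L))

  event_date <- as.Date("2018-01-01") +
    floor(stats::runif(n) * as.integer(as.Date("2024-12-31") - as.Date("2018-01-01") + 1L))
  start_date <- event_date - onset
  fda_date <- event_date + floor(stats::runif(n) * 61)

  # demographics sampled from Table-1-shaped categorical distributions
  age_band <- sample(names(.demo_dists$age_bands), n, replace = TRUE,
                     prob = .demo_dists$age_bands)
  age <- band_uniform(age_band)
  age_cod <- rep("YR", n)
  to_mon <- stats::runif(n) < 0.05
  age[to_mon] <- age[to_mon] * 12L
  age_cod[to_mon] <- "MON"
  miss_age <- stats::runif(n) < config$missing_age_rate

  sex <- sample(names(.demo_dists$sex), n, replace = TRUE,
                prob = .demo_dists$sex)
  miss_sex <- stats::runif(n) < config$missing_sex_rate

  wband <- sample(names(.demo_dists$weight_bands), n, replace = TRUE,
                  prob = .demo_dists$weight_bands)
  wt <- weight_uniform(wband)
  miss_wt <- stats::runif(n) < config$missing_weight_rate

  occp <- sample(names(.demo_dists$occupation), n, replace = TRUE,
                 prob = .demo_dists$occupation)
  country <- sample(names(.demo_dists$country), n, replace = TRUE,
                    prob = .demo_dists$country)
  other <- country == "OTHER"
  country[other] <- sample(.other_countries, sum(other), replace = TRUE)

  demo <- data.table(
    primaryid = primaryid, caseid = caseid,
    fda_dt = date_token(fda_date),
    event_dt = truncate_tokens(date_token(event_date),
                               config$partial_date_rate),
    age = ifelse(miss_age, "", as.character(age)),
    age_cod = ifelse(miss_age, "", age_cod),
    sex = ifelse(miss_sex, "", sex),
    wt = ifelse(miss_wt, "", as.character(wt)),
    wt_cod = ifelse(miss_wt, "", "KG"),
    occp_cod = occp,
    reporter_country = country
  )

  # DRUG: one PS row per case (verbatim name styled to exercise
  # normalization), plus 0-2 secondary-suspect rows
  start_tok <- truncate_tokens(date_token(start_date),
                               config$partial_date_rate)
  blank_in_drug <- stats::runif(n) < 0.10 # THER carries the date instead
  style <- stats::runif(n)
  verbatim <- nm[idx]
  lower <- style < 0.2
  verbatim[lower] <- tolower(verbatim[lower])
  slashy <- style >= 0.2 & style < 0.3
  verbatim[slashy] <- gsub("\\\\", "/", verbatim[slashy])
  drug_ps <- data.table(
    primaryid = primaryid, caseid = caseid, drug_seq = "1",
    role_cod = "PS", drugname = verbatim,
    start_dt = ifelse(blank_in_drug, "", start_tok)
  )
  n_ss <- stats::rbinom(n, 2L, 0.25)
  ss_case <- rep.int(seq_len(n), n_ss)
  drug_ss <- if (length(ss_case)) {
    seq_within <- sequence(n_ss) + 1L
    data.table(
      primaryid = primaryid[ss_case], caseid = caseid[ss_case],
      drug_seq = as.character(seq_within),
      role_cod = sample(c("SS", "I", "C"), length(ss_case), replace = TRUE,
                        prob = c(0.6, 0.1, 0.3)),
      drugname = nm[sample.int(length(nm), length(ss_case), replace = TRUE)],
      start_dt = ""
    )
  } else NULL
  drug <- rbind(drug_ps, drug_ss)
  setorder(drug, primaryid, drug_seq)

  # REAC: headache cases carry the PT plus 0-2 others; controls 1-2 others
  n_extra <- stats::rbinom(n, 2L, 0.3)
  n_extra[!headache & n_extra == 0L] <- 1L
  extra_case <- rep.int(seq_len(n), n_extra)
  reac <- rbind(
    data.table(primaryid = primaryid[headache], caseid = caseid[headache],
               pt = "Headache"),
    data.table(primaryid = primaryid[extra_case], caseid = caseid[extra_case],
               pt = sample(.other_pts, length(extra_case), replace = TRUE))
  )
  setorder(reac, primaryid, pt)

  ther <- data.table(
    primaryid = primaryid, caseid = caseid, dsg_drug_seq = "1",
    start_dt = start_tok,
    end_dt = date_token(event_date + 14L)
  )

  truth <- data.table(
    caseid = caseid, kept_primaryid = primaryid,
    ps_drug = nm[idx], headache = headache,
    onset_days = onset, bin = as.character(bin_onset(onset))
  )

  b <- list(demo = demo, drug = drug, reac = reac, ther = ther, truth = truth)
  as_quarter_bundle(b)
}

band_uniform <- function(band) {
  lo <- c("<18" = 1L, "18-30" = 18L, "31-50" = 31L, "51-65" = 51L, ">65" = 66L)
  hi <- c("<18" = 17L, "18-30" = 30L, "31-50" = 50L, "51-65" = 65L, ">65" = 90L)
  lo[band] + floor(stats::runif(length(band)) * (hi[band] - lo[band] + 1L))
}

weight_uniform <- function(band) {
  lo <- c("<=50" = 30L, "50-100" = 51L, ">100" = 101L)
  hi <- c("<=50" = 50L, "50-100" = 100L, ">100" = 150L)
  lo[band] + floor(stats::runif(length(band)) * (hi[band] - lo[band] + 1L))
}

truncate_tokens <- function(tok, rate) {
  u <- stats::runif(length(tok))
  to_month <- u < rate / 2
  to_year <- u >= rate / 2 & u < rate
  tok[to_month] <- substr(tok[to_month], 1L, 6L)
  tok[to_year] <- substr(tok[to_year], 1L, 4L)
  tok
}

#' Inject duplicate report versions into a bundle
#'
#' A fraction of cases is re-emitted as 2-3 versions sharing the CASEID
#' with strictly increasing PRIMARYIDs. Version receipt dates follow three
#' patterns: increasing FDA_DT (newest version last), tied FDA_DT (the
#' highest PRIMARYID is current), and a scrambled pattern where the latest
#' FDA_DT sits on a non-maximal PRIMARYID. The bundle's truth table is
#' updated to mark the version that the receipt-date/identifier rule
#' designates as current.
#'
#' @param bundle a `quarter_bundle` with one version per case.
#' @param dup_fraction fraction of cases to duplicate, in \[0, 1).
#' @param seed integer seed, or `NULL` to draw from the current RNG state
#'   (used internally by [generate_bundle()]).
#' @return the augmented `quarter_bundle`.
#' @export
inject_duplicates <- function(bundle, dup_fraction, seed = 1L) {
  if (dup_fraction < 0 || dup_fraction >= 1)
    config_error("dup_fraction must be in [0,1)", "dup_fraction")
  if (dup_fraction == 0) return(bundle)
  run <- function() {
    demo <- as.data.table(bundle$demo)
    pick <- which(stats::runif(nrow(demo)) < dup_fraction)
    if (!length(pick)) return(bundle)
    kvec <- 2L + (stats::runif(length(pick)) < 0.2) # 2 or 3 versions
    scenario <- sample(c("inc", "tie", "scramble"), length(pick),
                       replace = TRUE, prob = c(0.6, 0.2, 0.2))
    # for scrambled cases the latest receipt sits on version j < k
    jver <- 1L + (stats::runif(length(pick)) < 0.5 & kvec == 3L)

    grp <- rep.int(seq_along(pick), kvec) # one row per emitted version
    ver <- sequence(kvec)
    versions <- demo[pick][grp]
    versions[, primaryid := paste0(caseid, ver)] # strictly increasing
    base_date <- as.Date(demo$fda_dt[pick], format = "%Y%m%d")
    base_date[is.na(base_date)] <- as.Date("2020-01-01")
    off <- 30L * (ver - 1L)
    off[scenario[grp] == "tie"] <- 0L
    scr <- scenario[grp] == "scramble"
    # swap offsets of version j and version k within scrambled groups
    is_j <- scr & ver == jver[grp]
    is_k <- scr & ver == kvec[grp]
    off[is_j] <- 30L * (kvec[grp][is_j] - 1L)
    off[is_k] <- 30L * (jver[grp][is_k] - 1L)
    versions[, fda_dt := date_token(base_date[grp] + off)]

    # current version per case: latest FDA_DT, ties to highest PRIMARYID
    kept_ver <- ifelse(scenario == "scramble", jver, kvec)
    kept_map <- data.table(caseid = demo$caseid[pick],
                           kept = paste0(demo$caseid[pick], kept_ver))

    pick_case <- demo$caseid[pick]
    demo <- rbind(demo[-pick], versions)
    setorder(demo, primaryid)

    ver_map <- versions[, .(caseid, new_pid = primaryid)]
    expand <- function(tbl) {
      tbl <- as.data.table(tbl)
      hit <- tbl[caseid %in% pick_case]
      if (!nrow(hit)) return(tbl)
      hit[, primaryid := NULL]
      hit <- merge(hit, ver_map, by = "caseid", allow.cartesian = TRUE)
      setnames(hit, "new_pid", "primaryid")
      setcolorder(hit, names(tbl))
      rbind(tbl[!caseid %in% pick_case], hit)
    }
    drug <- expand(bundle$drug)
    reac <- expand(bundle$reac)
    ther <- expand(bundle$ther)
    setorder(drug, primaryid, drug_seq)
    setorder(reac, primaryid, pt)
    setorder(ther, primaryid, dsg_drug_seq)

    truth <- copy(as.data.table(bundle$truth))
    truth[kept_map, on = "caseid", kept_primaryid := i.kept]
    as_quarter_bundle(list(demo = demo, drug = drug, reac = reac,
                           ther = ther, truth = truth))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
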