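#' Study configuration
#'
#' Bundles the country-specific eligibility rules and window lengths used
#' throughout the pipeline. Month-based durations from the study design are
#' fixed as day counts so that every rule is exact and testable: 12 months of
#' washout = 365 days, 13 months of follow-up = 395 days, 3-month windows =
#' 90 days, 10 months = 300 days. All are configurable.
#'
#' @param country `"NL"` or `"BE"`. Also selects the anticholinergic list:
#'   trihexyphenidyl and biperiden in the Netherlands; those plus procyclidine
#'   in Belgium.
#' @param inclusion_start,inclusion_end Dates bounding eligible index dates.
#' @param lookback_days New-initiator washout: no purchase of the index drug
#'   within this many days before the index date.
#' @param followup_days Observation window after the index date.
#' @param pre_window_days Window before index for baseline-treatment
#'   classification.
#' @param post_window_days Window after computed discontinuation for
#'   sequel-treatment classification.
#' @param activity_window_days NL activity filter: at least one transaction of
#'   any drug within this many days after index (window closed at the bound).
#' @param sequel_max_days Sequel analysis restricted to episodes shorter than
#'   this (ten months).
#' @param index_drugs The four depot products under study.
#' @param laap_drugs All drugs counted as long-acting injectable
#'   antipsychotics when classifying prior/subsequent treatment (the index
#'   drugs plus other marketed depot products).
#' @param anticholinergics Optional override of the country list.
#' @param initiation_window_days Named per-drug initiation-scheme windows
#'   (days); see [build_episodes()].
#' @param olanzapine_300_days Pack scheme for olanzapine pamoate 300 mg (14 or
#'   28); required before episodes involving that strength can be built.
#' @param month_block_days Length of the "month" blocks used for the month-1 /
#'   month-6 combination-therapy windows.
#' @return A list of class `study_config`.
#' @export
study_config <- function(country = c("NL", "BE"),
                         inclusion_start = as.Date("2011-05-01"),
                         inclusion_end = as.Date("2012-04-30"),
                         lookback_days = 365,
                         followup_days = 395,
                         pre_window_days = 90,
                         post_window_days = 90,
                         activity_window_days = 90,
                         sequel_max_days = 300,
                         index_drugs = c("pp1m", "risperidone_microspheres",
                                         "haloperidol_decanoate",
                                         "olanzapine_pamoate"),
                         laap_drugs = c(index_drugs,
                                        "flupentixol_decanoate",
                                        "zuclopenthixol_decanoate",
                                        "bromperidol_decanoate"),
                         anticholinergics = NULL,
                         initiation_window_days = c(pp1m = 14),
                         olanzapine_300_days = NULL,
                         month_block_days = 28) {
  country <- match.arg(country)
  if (is.null(anticholinergics)) {
    anticholinergics <- if (country == "NL") {
      c("trihexyphenidyl", "biperiden")
    } else {
      c("trihexyphenidyl", "biperiden", "procyclidine")
    }
  }
  structure(list(
    country = country,
    inclusion_start = as.Date(inclusion_start),
    inclusion_end = as.Date(inclusion_end),
    lookback_days = lookback_days,
    followup_days = followup_days,
    pre_window_days = pre_window_days,
    post_window_days = post_window_days,
    activity_window_days = activity_window_days,
    sequel_max_days = sequel_max_days,
    index_drugs = index_drugs,
    laap_drugs = laap_drugs,
    anticholinergics = anticholinergics,
    initiation_window_days = initiation_window_days,
    olanzapine_300_days = olanzapine_300_days,
    month_block_days = month_block_days
  ), class = "study_config")
}

#' Pharmacy transmission-continuity filter
#'
#' Panel pharmacies occasionally fail to transmit a month of data; patients of
#' such pharmacies cannot be followed reliably. In the Netherlands only
#' pharmacies that transmitted every month of the horizon are kept. In Belgium
#' at most two missing months are tolerated overall, and within that no more
#' than one missing month in any 12 consecutive calendar months.
#'
#' @param log Transmission log data.frame with columns `pharmacy_id`, `month`
#'   (`"YYYY-MM"`), `transmitted` (logical). Every pharmacy must have a row
#'   for every month of the horizon.
#' @param country `"NL"` or `"BE"`.
#' @param horizon Character vector of `"YYYY-MM"` months (see [month_seq()]),
#'   or `NULL` to use all months present in the log.
#' @return Character vector of eligible pharmacy ids.
#' @export
filter_pharmacies <- function(log, country = c("NL", "BE"), horizon = NULL) {
  country <- match.arg(country)
  horizon <- sort(horizon %||% unique(log$month))
  log <- log[log$month %in% horizon, , drop = FALSE]
  ph <- sort(unique(log$pharmacy_id))
  n_mon <- length(horizon)
  cnt <- table(log$pharmacy_id)
  if (any(cnt[as.character(ph)] != n_mon)) {
    stop("transmission log must cover every horizon month for every pharmacy",
         call. = FALSE)
  }
  if (country == "BE" && n_mon < 12) {
    stop("BE rolling 12-month rule undefined on a horizon shorter than ",
         "12 months", call. = FALSE)
  }
  # missingness indicator matrix, pharmacies x months in horizon order
  miss <- with(log, tapply(!transmitted,
                           list(factor(pharmacy_id, ph),
                                factor(month, horizon)),
                           any))
  storage.mode(miss) <- "integer"
  if (country == "NL") {
    return(ph[rowSums(miss) == 0])
  }
  total_ok <- rowSums(miss) <= 2
  roll_ok <- rep(TRUE, length(ph))
  for (s in seq_len(n_mon - 11L)) {
    roll_ok <- roll_ok & rowSums(miss[, s:(s + 11L), drop = FALSE]) <= 1
  }
  ph[total_ok & roll_ok]
}

#' Identify new initiators of an index drug
#'
#' A patient enters a cohort at the first purchase of an index drug inside the
#' inclusion period that is not preceded by any purchase of the *same* drug in
#' the previous `lookback_days` (the washout that defines a new initiator). A
#' patient qualifying on more than one index drug contributes a single cohort
#' record at the earliest qualifying initiation.
#'
#' @param transactions Transaction table restricted to eligible pharmacies.
#' @param config A [study_config()].
#' @return Data.frame with columns `patient_id`, `index_drug`, `index_date`.
#' @export
identify_new_initiators <- function(transactions, config) {
  tx <- transactions[transactions$drug %in% config$index_drugs, , drop = FALSE]
  if (!nrow(tx)) {
    return(data.frame(patient_id = character(), index_drug = character(),
                      index_date = as.Date(character())))
  }
  tx <- tx[order(tx$patient_id, tx$drug, tx$date), , drop = FALSE]
  # first in-window purchase per patient x drug
  in_win <- tx$date >= config$inclusion_start & tx$date <= config$inclusion_end
  cand <- tx[in_win, , drop = FALSE]
  cand <- cand[!duplicated(cand[, c("patient_id", "drug")]), , drop = FALSE]
  if (!nrow(cand)) {
    return(data.frame(patient_id = character(), index_drug = character(),
                      index_date = as.Date(character())))
  }
  # washout: any same-drug purchase in [index - lookback, index)?
  dates_by <- split(tx$date, paste(tx$patient_id, tx$drug))
  key_cand <- paste(cand$patient_id, cand$drug)
  washed <- vapply(seq_len(nrow(cand)), function(i) {
    prior <- dates_by[[key_cand[i]]]
    !any(prior >= cand$date[i] - config$lookback_days & prior < cand$date[i])
  }, logical(1))
  cand <- cand[washed, , drop = FALSE]
  # one record per patient: earliest qualifying initiation; date ties broken
  # by index-drug order in the configuration
  cand$drug_rank <- match(cand$drug, config$index_drugs)
  cand <- cand[order(cand$patient_id, cand$date, cand$drug_rank), , drop = FALSE]
  cand <- cand[!duplicated(cand$patient_id), , drop = FALSE]
  data.frame(patient_id = cand$patient_id,
             index_drug = cand$drug,
             index_date = cand$date,
             stringsAsFactors = FALSE)
}

#' Patient-activity filters
#'
#' Removes patients who only incidentally visit a panel pharmacy and so
#' cannot be followed longitudinally. Netherlands: keep a patient only if at
#' least one transaction of any drug (the index drug or any other) falls in
#' `(index, index + activity_window_days]`. Belgium: drop a patient who has
#' exactly one index-drug transaction in follow-up *and* fewer than three
#' units of any other drug in the 365 days before index.
#'
#' @param cohort Output of [identify_new_initiators()].
#' @param transactions Full transaction table (eligible pharmacies).
#' @param config A [study_config()].
#' @return The filtered cohort.
#' @export
filter_patient_activity <- function(cohort, transactions, config) {
  if (!nrow(cohort)) return(cohort)
  tx <- transactions[transactions$patient_id %in% cohort$patient_id, ,
                     drop = FALSE]
  m <- match(tx$patient_id, cohort$patient_id)
  day <- as.integer(tx$date - cohort$index_date[m])
  if (config$country == "NL") {
    active <- day > 0 & day <= config$activity_window_days
    keep_id <- unique(tx$patient_id[active])
    cohort[cohort$patient_id %in% keep_id, , drop = FALSE]
  } else {
    is_index <- tx$drug == cohort$index_drug[m]
    idx_fup <- is_index & day >= 0 & day < config$followup_days
    n_index <- tapply(idx_fup, tx$patient_id, sum)
    other_prior <- !is_index & day >= -config$lookback_days & day < 0
    prior_units <- tapply(tx$units * other_prior, tx$patient_id, sum)
    n_index <- n_index[cohort$patient_id]
    prior_units <- prior_units[cohort$patient_id]
    n_index[is.na(n_index)] <- 0
    prior_units[is.na(prior_units)] <- 0
    drop <- n_index == 1 & prior_units < 3
    cohort[!drop, , drop = FALSE]
  }
}

#' Classify baseline (pre-index) treatment
#'
#' Priority classification of purchases in `[index - pre_window_days, index)`:
#' any long-acting injectable antipsychotic → `"prior-LAAP"`; otherwise any
#' antipsychotic (ATC class N5A, the index drug itself cannot appear because
#' of the washout) → `"prior-other-AP"`; otherwise `"no-AP"`. Classes are
#' mutually exclusive and exhaustive.
#'
#' @inheritParams filter_patient_activity
#' @return The cohort with a `baseline_class` factor column.
#' @export
classify_baseline <- function(cohort, transactions, config) {
  lv <- c("prior-LAAP", "prior-other-AP", "no-AP")
  if (!nrow(cohort)) {
    cohort$baseline_class <- factor(character(), levels = lv)
    return(cohort)
  }
  tx <- transactions[transactions$patient_id %in% cohort$patient_id, ,
                     drop = FALSE]
  m <- match(tx$patient_id, cohort$patient_id)
  day <- as.integer(tx$date - cohort$index_date[m])
  pre <- day >= -config$pre_window_days & day < 0
  laap <- pre & tx$drug %in% config$laap_drugs
  ap <- pre & startsWith(tx$atc, "N5A")
  has_laap <- cohort$patient_id %in% tx$patient_id[laap]
  has_ap <- cohort$patient_id %in% tx$patient_id[ap]
  cls <- ifelse(has_laap, "prior-LAAP",
                ifelse(has_ap, "prior-other-AP", "no-AP"))
  cohort$baseline_class <- factor(cls, levels = lv)
  cohort
}

#' Median 5-year age band of a cohort
#'
#' Ages are recorded only as 5-year bands; the reported cohort age is the band
#' containing the median patient when patients are ordered by band. With an
#' even count and the middle pair in different bands, the lower band is
#' reported.
#'
#' @param bands Character vector of band labels, or a cohort data.frame with
#'   an `age_band` column.
#' @param levels Band labels in ascending order; defaults to [age_band_levels()].
#' @return A single band label.
#' @export
median_age_band <- function(bands, levels = age_band_levels()) {
  if (is.data.frame(bands)) bands <- bands$age_band
  if (!length(bands)) stop("empty cohort", call. = FALSE)
  f <- factor(bands, levels = levels, ordered = TRUE)
  if (anyNA(f)) stop("unknown age band label(s)", call. = FALSE)
  s <- sort(f)
  as.character(s[floor((length(s) + 1) / 2)])
}

#' @rdname median_age_band
#' @export
age_band_levels <- function() {
  c("18-22", "23-27", "28-32", "33-37", "38-42", "43-47",
    "48-52", "53-57", "58-62", "63-67", "68+")
}
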