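#' Dose at start and end of treatment, and average dose per 28 days
#'
#' Computed only for episodes with more than one qualifying purchase day.
#' The start dose is the strength of the first injection purchased — unless
#' the drug has a configured SmPC initiation scheme (loading doses), in which
#' case the first injection *after* the initiation window defines the start
#' dose. The end dose is the strength of the last injection inside the
#' continuous episode. The average dose per 28 days is
#'
#' \deqn{avg = \frac{\sum strength \times units}{t} \times 28}
#'
#' summed over qualifying purchases, with `t` the time to discontinuation
#' (supply end) in days; set `denominator = "last_purchase"` to divide by the
#' last purchase offset instead.
#'
#' @param episodes,purchases The two components returned by
#'   [build_episodes()].
#' @param config A [study_config()] (only `followup_days` is used here; the
#'   initiation flags are already on `purchases`).
#' @param denominator `"discontinuation"` (default) or `"last_purchase"`.
#' @return Data.frame with one row per episode with >1 purchase day:
#'   `patient_id`, `index_drug`, `start_dose_mg`, `end_dose_mg`,
#'   `avg_dose_per_28d`, `dose_change` (`"up"`/`"down"`/`"flat"`), plus
#'   `fallback_start_mg` (first-purchase strength, populated for every
#'   episode so single-purchase patients can still be covariate-adjusted).
#' @export
dose_table <- function(episodes, purchases,
                       config = study_config(),
                       denominator = c("discontinuation", "last_purchase")) {
  denominator <- match.arg(denominator)
  q <- purchases[purchases$qualifying, , drop = FALSE]
  q <- q[order(q$patient_id, q$day, -q$coverage_days * q$units,
               -q$strength_mg), , drop = FALSE]
  first_any <- q[!duplicated(q$patient_id), c("patient_id", "strength_mg")]

  m <- match(episodes$patient_id, first_any$patient_id)
  out <- data.frame(patient_id = episodes$patient_id,
                    index_drug = episodes$index_drug,
                    stringsAsFactors = FALSE)
  out$fallback_start_mg <- first_any$strength_mg[m]

  multi <- episodes$patient_id[episodes$n_purchases > 1]
  qm <- q[q$patient_id %in% multi, , drop = FALSE]
  if (nrow(qm)) {
    post <- qm[!qm$initiation, , drop = FALSE]
    start <- post[!duplicated(post$patient_id), c("patient_id", "strength_mg")]
    last <- qm[order(qm$patient_id, -qm$day), , drop = FALSE]
    last <- last[!duplicated(last$patient_id), c("patient_id", "strength_mg")]
    total_mg <- tapply(qm$strength_mg * qm$units, qm$patient_id, sum)

    i <- match(out$patient_id, names(total_mg))
    out$start_dose_mg <- start$strength_mg[match(out$patient_id,
                                                 start$patient_id)]
    # all purchases inside the initiation window: fall back to the first one
    no_post <- is.na(out$start_dose_mg) & !is.na(i)
    out$start_dose_mg[no_post] <- out$fallback_start_mg[no_post]
    out$end_dose_mg <- last$strength_mg[match(out$patient_id,
                                              last$patient_id)]
    t_days <- if (denominator == "discontinuation") {
      episodes$time_to_discontinuation
    } else {
      pmax(episodes$last_day, 1)
    }
    out$avg_dose_per_28d <- as.numeric(total_mg[i]) / t_days * 28
    out$dose_change <- ifelse(out$end_dose_mg > out$start_dose_mg, "up",
                       ifelse(out$end_dose_mg < out$start_dose_mg, "down",
                              "flat"))
  } else {
    out$start_dose_mg <- NA_real_
    out$end_dose_mg <- NA_real_
    out$avg_dose_per_28d <- NA_real_
    out$dose_change <- NA_character_
  }
  out
}

#' Dose metrics for a single episode
#'
#' Single-patient counterpart of [dose_table()], operating on an
#' `index_episode` from [build_episode()]. Episodes with a single qualifying
#' purchase day are excluded from the dose analysis and return `NULL`.
#'
#' @param episode An `index_episode`.
#' @param denominator See [dose_table()].
#' @return A list with `start_dose_mg`, `end_dose_mg`, `avg_dose_per_28d`,
#'   `dose_change`, or `NULL` when excluded.
#' @export
dose_summary <- function(episode,
                         denominator = c("discontinuation", "last_purchase")) {
  stopifnot(inherits(episode, "index_episode"))
  denominator <- match.arg(denominator)
  if (episode$n_purchases < 2) return(NULL)
  q <- episode$purchases[episode$purchases$qualifying, , drop = FALSE]
  q <- q[order(q$day, -q$coverage_days * q$units, -q$strength_mg), ,
         drop = FALSE]
  post <- q[!q$initiation, , drop = FALSE]
  start <- if (nrow(post)) post$strength_mg[1] else q$strength_mg[1]
  end <- q$strength_mg[which.max(q$day)]
  t_days <- if (denominator == "discontinuation") {
    episode$time_to_discontinuation
  } else {
    max(episode$last_day, 1)
  }
  list(start_dose_mg = start,
       end_dose_mg = end,
       avg_dose_per_28d = sum(q$strength_mg * q$units) / t_days * 28,
       dose_change = if (end > start) "up" else if (end < start) "down"
                     else "flat")
}

#' Combination-therapy and anticholinergic status at months 1 and 6
#'
#' "Month k" is the 28-day block `[(k-1)*28, k*28)` counted from the index
#' date (configurable via `month_block_days`). A patient is `"combined"` in a
#' month if any antipsychotic other than the index drug (ATC class N5A) was
#' purchased in that block, `"monotherapy"` otherwise. Month-1 status is
#' defined for every episode; month-6 status only for patients still on their
#' index therapy through the end of the month-6 block, otherwise
#' `"not-on-treatment"`. Anticholinergic use (country-specific list:
#' trihexyphenidyl/biperiden in NL, plus procyclidine in BE) is flagged per
#' month the same way.
#'
#' @param episodes Episodes data.frame from [build_episodes()].
#' @param transactions Full transaction table.
#' @param config A [study_config()].
#' @return Data.frame `patient_id`, `month1`, `month6`,
#'   `anticholinergic_month1`, `anticholinergic_month6`.
#' @export
comed_table <- function(episodes, transactions, config = study_config()) {
  b <- config$month_block_days
  tx <- transactions[transactions$patient_id %in% episodes$patient_id, ,
                     drop = FALSE]
  m <- match(tx$patient_id, episodes$patient_id)
  day <- as.integer(tx$date - episodes$index_date[m])
  other_ap <- startsWith(tx$atc, "N5A") & tx$drug != episodes$index_drug[m]
  acho <- tx$drug %in% config$anticholinergics

  in_block <- function(k) day >= (k - 1) * b & day < k * b
  flag <- function(sel) episodes$patient_id %in% tx$patient_id[sel]

  out <- data.frame(patient_id = episodes$patient_id,
                    stringsAsFactors = FALSE)
  out$month1 <- factor(ifelse(flag(other_ap & in_block(1)),
                              "combined", "monotherapy"),
                       levels = c("monotherapy", "combined"))
  on6 <- episodes$time_to_discontinuation >= 6 * b
  m6 <- ifelse(!on6, "not-on-treatment",
               ifelse(flag(other_ap & in_block(6)), "combined", "monotherapy"))
  out$month6 <- factor(m6, levels = c("monotherapy", "combined",
                                      "not-on-treatment"))
  out$anticholinergic_month1 <- flag(acho & in_block(1))
  out$anticholinergic_month6 <- ifelse(!on6, NA, flag(acho & in_block(6)))
  out
}
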