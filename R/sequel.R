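#' Classify treatment in the three months following discontinuation
#'
#' For patients who discontinued the index drug after less than ten months on
#' treatment, purchases in the 90 days after the computed discontinuation time
#' (the supply end, not the last pharmacy visit) are classified by priority:
#' any purchase of the index drug → `"restart"`; otherwise any other
#' long-acting injectable antipsychotic → `"other-LAAP"`; otherwise any other
#' antipsychotic (ATC N5A) → `"other-oral-AP"`; otherwise `"no-AP"`. Censored
#' episodes and episodes of ten months or longer are ineligible and carry no
#' class. Sequel purchases never re-open the episode: the episode's
#' discontinuation time is computed first and is unaffected.
#'
#' @param episodes Episodes data.frame from [build_episodes()].
#' @param transactions Full transaction table.
#' @param config A [study_config()] (`sequel_max_days`, `post_window_days`,
#'   `laap_drugs`).
#' @return Data.frame with columns `patient_id`, `eligible` (logical) and
#'   `sequel_class` (factor, `NA` when ineligible).
#' @export
classify_sequel <- function(episodes, transactions, config) {
  lv <- c("restart", "other-LAAP", "other-oral-AP", "no-AP")
  out <- data.frame(patient_id = episodes$patient_id,
                    stringsAsFactors = FALSE)
  out$eligible <- episodes$event == 1L &
    episodes$time_to_discontinuation < config$sequel_max_days
  out$sequel_class <- factor(rep(NA_character_, nrow(out)), levels = lv)
  el <- which(out$eligible)
  if (!length(el)) return(out)

  tx <- transactions[transactions$patient_id %in% out$patient_id[el], ,
                     drop = FALSE]
  m <- match(tx$patient_id, episodes$patient_id)
  day <- as.integer(tx$date - episodes$index_date[m])
  t_disc <- episodes$time_to_discontinuation[m]
  in_win <- day > t_disc & day <= t_disc + config$post_window_days
  restart <- in_win & tx$drug == episodes$index_drug[m]
  laap <- in_win & tx$drug %in% config$laap_drugs &
    tx$drug != episodes$index_drug[m]
  ap <- in_win & startsWith(tx$atc, "N5A") &
    tx$drug != episodes$index_drug[m] & !tx$drug %in% config$laap_drugs

  pid <- out$patient_id[el]
  cls <- ifelse(pid %in% tx$patient_id[restart], "restart",
         ifelse(pid %in% tx$patient_id[laap], "other-LAAP",
         ifelse(pid %in% tx$patient_id[ap], "other-oral-AP", "no-AP")))
  out$sequel_class[el] <- factor(cls, levels = lv)
  out
}
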