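#' Build a continuous-treatment episode from index-drug purchases
#'
#' Scans a patient's purchases of the index drug in follow-up order and keeps
#' the episode alive while each inter-purchase interval is at most the
#' permissible gap of the immediately preceding purchase
#' (`coverage_days * units + grace_days`, see [permissible_gap()]). At the
#' first interval that exceeds it the episode ends by *interruption* at the
#' last qualifying purchase; if no further purchase exists in the follow-up
#' window the episode ends by *complete stop*. In both cases the time to
#' discontinuation is
#'
#' \deqn{t = day\ of\ last\ qualifying\ purchase + coverage\_days \times units}
#'
#' i.e. the day its supply runs out — the grace period never extends the
#' reported time. If that supply end reaches the end of follow-up the patient
#' is censored at `followup_days` instead.
#'
#' Supply does not stockpile across purchases: each interval is judged only
#' against the gap permitted by the purchase that opened it. Purchases on the
#' same day of the same strength are merged by summing units; when two
#' strengths are picked up on one day the one providing the longer supply
#' governs the gap (all same-day purchases still count toward dose totals in
#' [dose_summary()]).
#'
#' @param dates Purchase dates (`Date`) or integer day offsets from the index
#'   date; the earliest purchase defines day 0. Unsorted input is sorted.
#' @param strength_mg,units Strength (mg per unit) and unit count per
#'   purchase; `units` is recycled.
#' @param drug,country,scenario,rules,grace See [permissible_gap()].
#' @param followup_days Length of the observation window (default 395 days,
#'   thirteen 30.4-day months rounded to the day-count used throughout).
#'   Purchases on or after day `followup_days` are ignored.
#' @param initiation_window_days Days from index during which purchases are
#'   flagged as part of an SmPC initiation (loading-dose) scheme; used by the
#'   dosing module, not by the gap scan.
#' @return An object of class `index_episode`: a list with
#'   `time_to_discontinuation`, `event` (`1` discontinued / `0` censored),
#'   `mode` (`"interruption"`, `"complete_stop"` or `"none"`),
#'   `n_purchases` (qualifying purchase days) and a `purchases` data.frame
#'   with per-strength rows carrying `qualifying` and `initiation` flags.
#' @export
#' @examples
#' rules <- coverage_rules()
#' # two purchases 30 days apart, then nothing: complete stop at 30 + 28
#' build_episode(c(0, 30), 100, 1, "pp1m")$time_to_discontinuation  # 58
#' # a 70-day gap exceeds the base permissible gap of 56: interruption at day 0
#' build_episode(c(0, 70), 100, 1, "pp1m")$time_to_discontinuation  # 28
build_episode <- function(dates, strength_mg, units = 1, drug,
                          country = "NL", scenario = "base",
                          followup_days = 395,
                          rules = coverage_rules(),
                          grace = grace_scenarios(),
                          initiation_window_days = 0) {
  if (!length(dates)) stop("episode needs at least one purchase", call. = FALSE)
  day <- as.integer(dates - min(dates))
  units <- rep_len(as.integer(units), length(day))
  strength_mg <- rep_len(strength_mg, length(day))
  o <- order(day, strength_mg)
  day <- day[o]; strength_mg <- strength_mg[o]; units <- units[o]
  keep <- day < followup_days
  day <- day[keep]; strength_mg <- strength_mg[keep]; units <- units[keep]
  if (!length(day)) stop("no purchase inside the follow-up window", call. = FALSE)

  # merge same-day same-strength rows
  grp_new <- !duplicated(cbind(day, strength_mg))
  gid <- cumsum(grp_new)
  u <- as.vector(rowsum(units, gid))
  day <- day[grp_new]; strength_mg <- strength_mg[grp_new]; units <- u

  cov <- lookup_coverage(rep(drug, length(day)), strength_mg,
                         rep(country, length(day)), rules)
  gr <- lookup_grace(rep(drug, length(day)), cov, scenario, grace)
  supply <- cov * units

  # one row per day: the purchase with the longest supply governs the gap
  o2 <- order(day, -supply, -strength_mg)
  rep_row <- o2[!duplicated(day[o2])]
  rep_row <- sort(rep_row)
  d_day <- day[rep_row]; d_sup <- supply[rep_row]; d_gr <- gr[rep_row]

  sc <- episode_scan(d_day, d_sup, d_gr, followup_days)
  last_day <- d_day[sc$last]
  purchases <- data.frame(
    day = day, strength_mg = strength_mg, units = units,
    coverage_days = cov,
    qualifying = day <= last_day,
    initiation = day < initiation_window_days
  )
  structure(list(
    index_drug = drug,
    scenario = scenario,
    time_to_discontinuation = sc$time,
    event = sc$event,
    mode = sc$mode,
    n_purchases = sc$last,
    last_day = last_day,
    purchases = purchases
  ), class = "index_episode")
}

# Core gap scan on day-merged vectors. `day` ascending, day[1] == 0.
episode_scan <- function(day, supply, grace, followup_days) {
  n <- length(day)
  last <- n
  mode <- "complete_stop"
  if (n > 1L) {
    v <- which(diff(day) > supply[-n] + grace[-n])
    if (length(v)) {
      last <- v[1L]
      mode <- "interruption"
    }
  }
  t_disc <- day[last] + supply[last]
  if (t_disc >= followup_days) {
    list(time = as.numeric(followup_days), event = 0L, mode = "none", last = last)
  } else {
    list(time = as.numeric(t_disc), event = 1L, mode = mode, last = last)
  }
}

#' @export
print.index_episode <- function(x, ...) {
  cat("<index_episode> ", x$index_drug, " [", x$scenario, "]\n", sep = "")
  cat("  time to discontinuation:", x$time_to_discontinuation, "days;",
      if (x$event == 1L) paste0("discontinued (", x$mode, ")") else "censored",
      "\n")
  cat("  qualifying purchase days:", x$n_purchases, "\n")
  invisible(x)
}

#' Build episodes for a whole cohort
#'
#' Vectorised cohort-level wrapper around the gap scan of [build_episode()].
#' Transactions are restricted to each patient's index drug and to purchase
#' days in `[0, followup_days)` relative to the index date.
#'
#' @param transactions Transaction data.frame with columns `patient_id`,
#'   `date` (`Date`), `drug`, `strength_mg`, `units`.
#' @param cohort Cohort data.frame with columns `patient_id`, `index_drug`,
#'   `index_date` (one row per patient).
#' @param scenario,country,followup_days,rules,grace See [build_episode()].
#' @param initiation_window_days Named vector of per-drug initiation-scheme
#'   windows in days (drugs not named get 0). Default: 14 days for PP1M,
#'   whose SmPC defines deltoid loading doses in the first two weeks.
#' @return A list with `episodes` (one row per patient: `patient_id`,
#'   `index_drug`, `index_date`, `scenario`, `time_to_discontinuation`,
#'   `event`, `mode`, `n_purchases`, `last_day`) and `purchases` (per-strength
#'   purchase rows with `qualifying` and `initiation` flags, for the dosing
#'   module).
#' @export
build_episodes <- function(transactions, cohort, scenario = "base",
                           country = "NL", followup_days = 395,
                           rules = coverage_rules(),
                           grace = grace_scenarios(),
                           initiation_window_days = c(pp1m = 14)) {
  stopifnot(nrow(cohort) > 0)
  tx <- merge(transactions[, c("patient_id", "date", "drug", "strength_mg", "units")],
              cohort[, c("patient_id", "index_drug", "index_date")],
              by = "patient_id")
  tx <- tx[tx$drug == tx$index_drug, , drop = FALSE]
  tx$day <- as.integer(tx$date - tx$index_date)
  tx <- tx[tx$day >= 0 & tx$day < followup_days, , drop = FALSE]
  missing_pid <- setdiff(cohort$patient_id, tx$patient_id)
  if (length(missing_pid)) {
    stop("no index-drug purchase in follow-up for patient(s): ",
         paste(utils::head(missing_pid, 5), collapse = ", "), call. = FALSE)
  }

  # merge same-day same-strength purchases (sum units)
  o <- order(tx$patient_id, tx$day, tx$strength_mg)
  tx <- tx[o, , drop = FALSE]
  grp_new <- !duplicated(tx[, c("patient_id", "day", "strength_mg")])
  gid <- cumsum(grp_new)
  u <- as.vector(rowsum(tx$units, gid))
  agg <- tx[grp_new, c("patient_id", "index_drug", "day", "strength_mg")]
  agg$units <- u

  agg$coverage_days <- lookup_coverage(agg$index_drug, agg$strength_mg,
                                       rep(country, nrow(agg)), rules)
  agg$supply <- agg$coverage_days * agg$units
  agg$grace_days <- lookup_grace(agg$index_drug, agg$coverage_days,
                                 scenario, grace)
  iw <- initiation_window_days[agg$index_drug]
  iw[is.na(iw)] <- 0
  agg$initiation <- agg$day < iw

  # one governing row per patient-day (longest supply wins)
  o2 <- order(agg$patient_id, agg$day, -agg$supply, -agg$strength_mg)
  dl <- agg[o2, , drop = FALSE]
  dl <- dl[!duplicated(dl[, c("patient_id", "day")]), , drop = FALSE]
  dl <- dl[order(dl$patient_id, dl$day), , drop = FALSE]

  r <- rle(dl$patient_id)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  np <- length(starts)
  time <- numeric(np); event <- integer(np); mode <- character(np)
  n_purch <- integer(np); last_day <- integer(np)
  for (p in seq_len(np)) {
    i <- starts[p]:ends[p]
    sc <- episode_scan(dl$day[i], dl$supply[i], dl$grace_days[i], followup_days)
    time[p] <- sc$time; event[p] <- sc$event; mode[p] <- sc$mode
    n_purch[p] <- sc$last; last_day[p] <- dl$day[i][sc$last]
  }
  ep <- data.frame(patient_id = r$values, stringsAsFactors = FALSE)
  m <- match(ep$patient_id, cohort$patient_id)
  ep$index_drug <- cohort$index_drug[m]
  ep$index_date <- cohort$index_date[m]
  ep$scenario <- scenario
  ep$time_to_discontinuation <- time
  ep$event <- event
  ep$mode <- mode
  ep$n_purchases <- n_purch
  ep$last_day <- last_day

  mlast <- match(agg$patient_id, ep$patient_id)
  agg$qualifying <- agg$day <= ep$last_day[mlast]
  rownames(ep) <- rownames(agg) <- NULL
  list(episodes = ep, purchases = agg)
}

#' Kaplan-Meier continuation fraction at a horizon
#'
#' Product-limit survival of the time-to-discontinuation distribution at
#' `horizon_days`. With no censoring before the horizon this reduces to the
#' simple proportion of episodes still on treatment.
#'
#' @param episodes Episodes data.frame from [build_episodes()] (columns
#'   `time_to_discontinuation`, `event`), or an `index_episode` list.
#' @param horizon_days Horizon in days (e.g. 365 for "after 12 months").
#' @return Survival probability in `[0, 1]`.
#' @export
continuation_fraction <- function(episodes, horizon_days) {
  if (!nrow(episodes)) stop("no episodes", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(episodes$time_to_discontinuation, episodes$event) ~ 1
  )
  s <- summary(fit, times = horizon_days, extend = TRUE)
  as.numeric(s$surv)
}
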