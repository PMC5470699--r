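#' Configuration for the synthetic dispensing-data generator
#'
#' Defines a simulated retail-pharmacy panel: patients initiating one of the
#' four index depot antipsychotics, their refill streams up to a latent
#' discontinuation day, prior-medication history, co-medication,
#' restart-after-discontinuation behaviour, and pharmacy-level monthly
#' transmission gaps. Every latent quantity is recorded so downstream
#' parameter-recovery checks have exact ground truth.
#'
#' Discontinuation follows a per-drug Weibull hazard with
#' `S(t) = exp(-(h t)^k)`; the default shape `k = 1` gives a constant
#' (exponential) hazard so that true pairwise hazard ratios equal the ratios
#' of the configured rates exactly. Refill intervals are the coverage period
#' of the dispensed strength times units, plus rounded Gaussian jitter,
#' floored at 7 days (a depot is not redispensed within a week).
#'
#' @param country `"NL"` or `"BE"` (drives olanzapine coverage and the
#'   anticholinergic list).
#' @param n_pharmacies,n_patients Panel size; both must be at least 1.
#' @param inclusion_start,inclusion_end Index dates are uniform on this
#'   window.
#' @param drug_mix Named fractions over index drugs; must sum to 1.
#' @param hazard Per-drug discontinuation rate per day (> 0).
#' @param weibull_shape Shape `k` of the latent time distribution (1 =
#'   exponential).
#' @param jitter_sd Per-drug SD (days) of refill-interval jitter; a scalar is
#'   recycled.
#' @param restart_probability Per-drug probability that a discontinuer
#'   repurchases the index drug within 90 days after the supply end (drawn
#'   uniformly on days 29-90 after it, i.e. beyond the base grace period).
#' @param prior_laap_fraction,prior_oap_fraction Per-drug probabilities of a
#'   prior depot (drawn from non-index depot products) or, failing that,
#'   prior oral antipsychotic history in the 90-day pre-window.
#' @param comed_probability Probability of concurrent oral-antipsychotic
#'   purchases (roughly monthly) during the episode.
#' @param anticholinergic_probability Probability of concurrent
#'   anticholinergic purchases during the episode.
#' @param background_activity Probability that the patient buys unrelated
#'   (non-psychiatric) drugs at the panel pharmacy, which exercises the
#'   patient-activity filters.
#' @param pharmacy_missingness Per-pharmacy, per-calendar-month probability
#'   of failing to transmit; all transactions at that pharmacy-month are
#'   removed from the observed table (they happened but are unobserved).
#' @param offpanel_probability Per-purchase probability of an off-panel
#'   pharmacy visit (purchase unobserved); 0 by default — patient-pharmacy
#'   loyalty is assumed complete, and this knob exists to study the
#'   underestimation bias a leaky panel would cause.
#' @param uptitration_probability Probability that the maintenance strength
#'   moves one rung up the dose ladder at some purchase.
#' @param multi_unit_probability Probability that a purchase dispenses two
#'   units instead of one (0 by default).
#' @param loading_probability Probability that a PP1M initiator follows the
#'   SmPC initiation scheme (150 mg day 0, 100 mg day 7, maintenance from
#'   ~day 35).
#' @param dose_ladder,start_dose_probs Available strengths per drug and the
#'   sampling weights of the starting strength.
#' @param gender_probs,age_band_probs Demographic sampling weights (age over
#'   [age_band_levels()]).
#' @param followup_days Retrieval window after index; transactions beyond it
#'   are not generated (they would never be retrieved).
#' @param rules Coverage table; the default resolves olanzapine pamoate
#'   300 mg to the 28-day pack explicitly.
#' @param seed RNG seed; a fixed seed makes the output byte-identical.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(country = c("NL", "BE"),
                       n_pharmacies = 100,
                       n_patients = 2000,
                       inclusion_start = as.Date("2011-05-01"),
                       inclusion_end = as.Date("2012-04-30"),
                       drug_mix = c(pp1m = 0.40,
                                    risperidone_microspheres = 0.34,
                                    haloperidol_decanoate = 0.21,
                                    olanzapine_pamoate = 0.05),
                       hazard = c(pp1m = 0.0022,
                                  risperidone_microspheres = 0.0035,
                                  haloperidol_decanoate = 0.0032,
                                  olanzapine_pamoate = 0.0030),
                       weibull_shape = 1,
                       jitter_sd = 4,
                       restart_probability = c(pp1m = 0.35,
                                               risperidone_microspheres = 0.22,
                                               haloperidol_decanoate = 0.25,
                                               olanzapine_pamoate = 0.25),
                       prior_laap_fraction = c(pp1m = 0.32,
                                               risperidone_microspheres = 0.02,
                                               haloperidol_decanoate = 0.03,
                                               olanzapine_pamoate = 0.03),
                       prior_oap_fraction = c(pp1m = 0.19,
                                              risperidone_microspheres = 0.25,
                                              haloperidol_decanoate = 0.29,
                                              olanzapine_pamoate = 0.33),
                       comed_probability = 0.30,
                       anticholinergic_probability = 0.15,
                       background_activity = 0.85,
                       pharmacy_missingness = 0.02,
                       offpanel_probability = 0,
                       uptitration_probability = 0.15,
                       multi_unit_probability = 0,
                       loading_probability = 0.5,
                       dose_ladder = list(
                         pp1m = c(50, 75, 100, 150),
                         risperidone_microspheres = c(25, 37.5, 50),
                         haloperidol_decanoate = c(50, 100, 150),
                         olanzapine_pamoate = c(210, 300, 405)),
                       start_dose_probs = list(
                         pp1m = c(0.10, 0.25, 0.45, 0.20),
                         risperidone_microspheres = c(0.25, 0.45, 0.30),
                         haloperidol_decanoate = c(0.30, 0.50, 0.20),
                         olanzapine_pamoate = c(0.30, 0.20, 0.50)),
                       gender_probs = c(M = 0.60, F = 0.38, unknown = 0.02),
                       age_band_probs = c(0.02, 0.08, 0.13, 0.14, 0.14, 0.12,
                                          0.11, 0.09, 0.07, 0.05, 0.05),
                       followup_days = 395,
                       rules = coverage_rules(olanzapine_300_days = 28),
                       seed = 1L) {
  country <- match.arg(country)
  drugs <- names(drug_mix)
  if (is.null(drugs) || any(drugs == "")) {
    stop("`drug_mix` must be a named vector", call. = FALSE)
  }
  if (n_patients < 1 || n_pharmacies < 1) {
    stop("need at least one patient and one pharmacy", call. = FALSE)
  }
  if (abs(sum(drug_mix) - 1) > 1e-8) {
    stop("`drug_mix` fractions must sum to 1", call. = FALSE)
  }
  expand <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) x <- stats::setNames(rep(x, length(drugs)), drugs)
    if (!all(drugs %in% names(x))) {
      stop("`", what, "` must name every drug in `drug_mix`", call. = FALSE)
    }
    x[drugs]
  }
  hazard <- expand(hazard, "hazard")
  jitter_sd <- expand(jitter_sd, "jitter_sd")
  restart_probability <- expand(restart_probability, "restart_probability")
  prior_laap_fraction <- expand(prior_laap_fraction, "prior_laap_fraction")
  prior_oap_fraction <- expand(prior_oap_fraction, "prior_oap_fraction")
  probs <- c(restart_probability, prior_laap_fraction, prior_oap_fraction,
             comed_probability, anticholinergic_probability,
             background_activity, pharmacy_missingness, offpanel_probability,
             uptitration_probability, multi_unit_probability,
             loading_probability)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(hazard <= 0)) stop("hazards must be positive", call. = FALSE)
  if (any(jitter_sd < 0)) stop("jitter SDs must be non-negative", call. = FALSE)
  rm(expand, probs, drugs)
  structure(as.list(environment()), class = "sim_config")
}

#' Read a generator configuration from a YAML file
#'
#' Scalar and per-drug fields of [sim_config()] map one-to-one to YAML keys;
#' dates are ISO-8601 strings.
#'
#' @param path YAML file.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  for (f in c("inclusion_start", "inclusion_end")) {
    if (!is.null(y[[f]])) y[[f]] <- as.Date(y[[f]])
  }
  for (f in c("drug_mix", "hazard", "jitter_sd", "restart_probability",
              "prior_laap_fraction", "prior_oap_fraction", "gender_probs")) {
    if (!is.null(y[[f]])) y[[f]] <- unlist(y[[f]])
  }
  if (!is.null(y$olanzapine_300_days)) {
    y$rules <- coverage_rules(olanzapine_300_days = y$olanzapine_300_days)
    y$olanzapine_300_days <- NULL
  }
  do.call(sim_config, y)
}

#' Simulate an LRx-like dispensing panel
#'
#' Generates the latent transaction stream implied by a [sim_config()],
#' applies pharmacy-month transmission gaps (and off-panel visits, if
#' enabled) to produce the observed table, and returns both together with the
#' transmission log, a patient demographics table, and the ground truth.
#'
#' @param config A [sim_config()].
#' @return A list of class `lrx_sim`:
#' \describe{
#'   \item{transactions}{Observed dispensings: `patient_id`, `pharmacy_id`,
#'     `date`, `drug`, `atc`, `strength_mg`, `units`.}
#'   \item{latent_transactions}{Same, before deletion of non-transmitted
#'     pharmacy-months; the observed table is always a subset.}
#'   \item{transmission_log}{`pharmacy_id`, `month` (`"YYYY-MM"`),
#'     `transmitted` for every pharmacy and horizon month.}
#'   \item{patients}{`patient_id`, `gender`, `age_band`.}
#'   \item{truth}{Ground truth: per-drug `hazard`, `hazard_ratio` (vs the
#'     first drug of `drug_mix`), `restart_probability`, and a per-patient
#'     table with the latent discontinuation day, the supply-end day implied
#'     by the generated purchases, the restart draw and the assigned
#'     prior-treatment class.}
#' }
#' @export
simulate_lrx <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  set.seed(cf$seed)
  n <- cf$n_patients
  drugs <- names(cf$drug_mix)
  drug <- sample(drugs, n, TRUE, prob = as.numeric(cf$drug_mix))
  pharmacy <- sprintf("PH%04d", sample.int(cf$n_pharmacies, n, TRUE))
  span <- as.integer(cf$inclusion_end - cf$inclusion_start)
  index_date <- cf$inclusion_start + sample.int(span + 1L, n, TRUE) - 1L
  gender <- sample(names(cf$gender_probs), n, TRUE, as.numeric(cf$gender_probs))
  age_band <- sample(age_band_levels(), n, TRUE, cf$age_band_probs)
  pid <- sprintf("P%06d", seq_len(n))

  # latent discontinuation day: S(t) = exp(-(h t)^k)
  k <- cf$weibull_shape
  t_lat <- stats::rweibull(n, shape = k, scale = 1 / cf$hazard[drug])

  cov_of <- function(d, s) {
    lookup_coverage(rep(d, length(s)), s, rep(cf$country, length(s)), cf$rules)
  }

  # maintenance strength trajectories (rung index, one optional up-titration)
  m <- ceiling(cf$followup_days / 7) + 2L
  r0 <- integer(n)
  for (d in drugs) {
    rows <- which(drug == d)
    r0[rows] <- sample.int(length(cf$dose_ladder[[d]]), length(rows), TRUE,
                           prob = cf$start_dose_probs[[d]])
  }
  tit <- stats::runif(n) < cf$uptitration_probability
  tit_at <- sample(2:6, n, TRUE)
  jmat <- matrix(seq_len(m), n, m, byrow = TRUE)
  ri <- r0 + (tit & jmat >= tit_at)
  ladder_len <- vapply(cf$dose_ladder, length, integer(1))[drug]
  ri <- pmin(ri, ladder_len)
  S <- matrix(NA_real_, n, m)
  for (d in drugs) {
    rows <- which(drug == d)
    S[rows, ] <- cf$dose_ladder[[d]][ri[rows, ]]
  }

  # PP1M SmPC initiation scheme: 150 mg day 0, 100 mg day 7, then maintenance
  loader <- drug == "pp1m" & stats::runif(n) < cf$loading_probability
  lr <- which(loader)
  if (length(lr) && m > 2) {
    S[lr, 3:m] <- S[lr, 1:(m - 2), drop = FALSE]
    S[lr, 1] <- 150
    S[lr, 2] <- 100
  }

  U <- matrix(1L, n, m)
  if (cf$multi_unit_probability > 0) {
    U <- matrix(1L + stats::rbinom(n * m, 1L, cf$multi_unit_probability), n, m)
  }
  if (length(lr)) U[lr, 1:2] <- 1L

  C <- matrix(NA_real_, n, m)
  for (d in drugs) {
    rows <- which(drug == d)
    C[rows, ] <- cov_of(d, as.vector(S[rows, , drop = FALSE]))
  }

  E <- matrix(round(stats::rnorm(n * m, 0, sd = cf$jitter_sd[drug])), n, m)
  intv <- C * U + E
  intv[intv < 7] <- 7
  if (length(lr)) intv[lr, 1] <- 7

  D <- matrix(0, n, m)
  for (j in 2:m) D[, j] <- D[, j - 1] + intv[, j - 1]
  K <- D <= t_lat & D < cf$followup_days
  lastcol <- rowSums(K)  # >= 1: day 0 always kept
  last_ix <- cbind(seq_len(n), lastcol)
  supply_end <- D[last_ix] + C[last_ix] * U[last_ix]

  tx_parts <- list()
  add_tx <- function(p, day, dr, atc, s, u) {
    data.frame(patient_id = pid[p], pharmacy_id = pharmacy[p],
               date = index_date[p] + as.integer(day),
               drug = dr, atc = atc, strength_mg = s, units = as.integer(u),
               stringsAsFactors = FALSE)
  }
  w <- which(K, arr.ind = TRUE)
  tx_parts$index <- add_tx(w[, 1], D[w], drug[w[, 1]], "N5A1", S[w], U[w])

  # restart stream: first repurchase 29-90 days after the supply end
  restarted <- stats::runif(n) < cf$restart_probability[drug]
  rr <- which(restarted)
  if (length(rr)) {
    u_gap <- sample(29:90, length(rr), TRUE)
    nrp <- pmin(1L + stats::rpois(length(rr), 1), 4L)
    p_rep <- rep(rr, nrp)
    o_rep <- sequence(nrp) - 1L
    rday <- supply_end[p_rep] + u_gap[rep(seq_along(rr), nrp)] +
      o_rep * (C[last_ix][p_rep] * 1)
    ok <- rday < cf$followup_days
    if (any(ok)) {
      tx_parts$restart <- add_tx(p_rep[ok], rday[ok], drug[p_rep[ok]], "N5A1",
                                 S[last_ix][p_rep][ok], 1L)
    }
  }

  # prior-treatment history in the 90-day pre-window
  laap_pool <- data.frame(
    drug = c("flupentixol_decanoate", "zuclopenthixol_decanoate",
             "bromperidol_decanoate"),
    strength = c(40, 200, 150))
  oap_pool <- data.frame(
    drug = c("olanzapine_oral", "risperidone_oral", "haloperidol_oral",
             "quetiapine_oral"),
    strength = c(10, 2, 5, 300))
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  has_plaap <- u1 < cf$prior_laap_fraction[drug]
  has_poap <- !has_plaap & u2 < cf$prior_oap_fraction[drug]
  prior_class <- ifelse(has_plaap, "prior-LAAP",
                        ifelse(has_poap, "prior-other-AP", "no-AP"))
  pl <- which(has_plaap)
  if (length(pl)) {
    npl <- sample(1:2, length(pl), TRUE)
    sel <- sample.int(nrow(laap_pool), length(pl), TRUE)
    p_rep <- rep(pl, npl)
    s_rep <- rep(sel, npl)
    tx_parts$prior_laap <- add_tx(p_rep, -sample.int(90, length(p_rep), TRUE),
                                  laap_pool$drug[s_rep], "N5A1",
                                  laap_pool$strength[s_rep], 1L)
  }
  po <- which(has_poap)
  if (length(po)) {
    npo <- sample(1:3, length(po), TRUE)
    sel <- sample.int(nrow(oap_pool), length(po), TRUE)
    p_rep <- rep(po, npo)
    s_rep <- rep(sel, npo)
    tx_parts$prior_oap <- add_tx(p_rep, -sample.int(90, length(p_rep), TRUE),
                                 oap_pool$drug[s_rep], "N5A9",
                                 oap_pool$strength[s_rep], 1L)
  }

  # co-medication (other oral AP, ~monthly while on the index drug)
  stream_days <- function(rows, start_day, every) {
    end <- pmin(floor(supply_end[rows]), cf$followup_days - 1)
    cnt <- pmax(0L, (end - start_day) %/% every + 1L)
    keep <- cnt > 0L
    list(p = rep(rows[keep], cnt[keep]),
         day = start_day + (sequence(cnt[keep]) - 1L) * every,
         who = rep(seq_along(rows)[keep], cnt[keep]))
  }
  cm <- which(stats::runif(n) < cf$comed_probability)
  if (length(cm)) {
    sel <- sample.int(nrow(oap_pool), length(cm), TRUE)
    sd <- stream_days(cm, 3L, 30L)
    if (length(sd$p)) {
      tx_parts$comed <- add_tx(sd$p, sd$day, oap_pool$drug[sel][sd$who],
                               "N5A9", oap_pool$strength[sel][sd$who], 1L)
    }
  }

  # anticholinergics for extrapyramidal side effects (country-specific list)
  acho_pool <- if (cf$country == "NL") {
    c("trihexyphenidyl", "biperiden")
  } else {
    c("trihexyphenidyl", "biperiden", "procyclidine")
  }
  ac <- which(stats::runif(n) < cf$anticholinergic_probability)
  if (length(ac)) {
    sel <- sample(acho_pool, length(ac), TRUE)
    sd <- stream_days(ac, 10L, 30L)
    if (length(sd$p)) {
      tx_parts$acho <- add_tx(sd$p, sd$day, sel[sd$who], "N4A0", 4, 1L)
    }
  }

  # unrelated background prescriptions (exercise the activity filters)
  bg_pool <- data.frame(drug = c("metformin", "omeprazole", "simvastatin"),
                        atc = c("A10A", "A02B", "C10A"),
                        strength = c(500, 20, 40))
  bg <- which(stats::runif(n) < cf$background_activity)
  if (length(bg)) {
    nbg <- 1L + stats::rpois(length(bg), 1.5)
    p_rep <- rep(bg, nbg)
    sel <- sample.int(nrow(bg_pool), length(p_rep), TRUE)
    bdays <- sample(-365:(cf$followup_days - 1), length(p_rep), TRUE)
    tx_parts$background <- add_tx(p_rep, bdays, bg_pool$drug[sel],
                                  bg_pool$atc[sel], bg_pool$strength[sel], 1L)
  }

  latent <- do.call(rbind, tx_parts)
  latent <- latent[order(latent$patient_id, latent$date, latent$drug,
                         latent$strength_mg), , drop = FALSE]
  rownames(latent) <- NULL

  # pharmacy transmission log over the full data horizon
  months <- month_seq(cf$inclusion_start - 370, cf$inclusion_end + cf$followup_days)
  ph_ids <- sprintf("PH%04d", seq_len(cf$n_pharmacies))
  log <- data.frame(
    pharmacy_id = rep(ph_ids, each = length(months)),
    month = rep(months, cf$n_pharmacies),
    stringsAsFactors = FALSE)
  log$transmitted <- stats::runif(nrow(log)) >= cf$pharmacy_missingness

  gone <- log[!log$transmitted, , drop = FALSE]
  obs_key <- paste(latent$pharmacy_id, month_label(latent$date))
  observed <- latent[!obs_key %in% paste(gone$pharmacy_id, gone$month), ,
                     drop = FALSE]
  if (cf$offpanel_probability > 0) {
    observed <- observed[stats::runif(nrow(observed)) >=
                           cf$offpanel_probability, , drop = FALSE]
  }
  rownames(observed) <- NULL

  truth <- list(
    reference_drug = drugs[1],
    hazard = cf$hazard,
    hazard_ratio = cf$hazard / cf$hazard[[1]],
    restart_probability = cf$restart_probability,
    patients = data.frame(
      patient_id = pid, pharmacy_id = pharmacy, index_drug = drug,
      index_date = index_date, gender = gender, age_band = age_band,
      latent_disc_day = t_lat, supply_end_day = supply_end,
      n_index_purchases = lastcol, restart_drawn = restarted,
      prior_class = prior_class, loading_scheme = loader,
      stringsAsFactors = FALSE)
  )
  structure(list(
    transactions = observed,
    latent_transactions = latent,
    transmission_log = log,
    patients = data.frame(patient_id = pid, gender = gender,
                          age_band = age_band, stringsAsFactors = FALSE),
    truth = truth,
    config = cf
  ), class = "lrx_sim")
}

#' @export
print.lrx_sim <- function(x, ...) {
  cat("<lrx_sim>", nrow(x$truth$patients), "patients,",
      x$config$n_pharmacies, "pharmacies,",
      nrow(x$transactions), "observed /", nrow(x$latent_transactions),
      "latent transactions\n")
  invisible(x)
}

#' Write a simulated panel to plain-text files
#'
#' Emits `transactions.csv` (ISO-8601 dates), `transmission_log.csv`,
#' `patients.csv` and `sim_truth.json` into `dir`.
#'
#' @param sim An `lrx_sim` from [simulate_lrx()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_lrx <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(sim$transactions, file.path(dir, "transactions.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$transmission_log,
                   file.path(dir, "transmission_log.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE, quote = FALSE)
  truth <- sim$truth
  truth$patients$index_date <- as.character(truth$patients$index_date)
  jsonlite::write_json(truth, file.path(dir, "sim_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read transaction and transmission-log CSV files
#'
#' Accepts the dialect written by [write_lrx()]; real panel extracts with the
#' same columns load identically.
#'
#' @param path CSV file.
#' @return A data.frame with `date` parsed as `Date` (transactions) or
#'   `transmitted` as logical (log).
#' @export
read_transactions <- function(path) {
  tx <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "pharmacy_id", "date", "drug", "atc",
            "strength_mg", "units")
  if (!all(need %in% names(tx))) {
    stop("transaction file must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  tx$date <- as.Date(tx$date)
  tx
}

#' @rdname read_transactions
#' @export
read_transmission_log <- function(path) {
  log <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("pharmacy_id", "month", "transmitted")
  if (!all(need %in% names(log))) {
    stop("transmission log must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  log$transmitted <- as.logical(log$transmitted)
  log
}
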