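#' Run the full persistence pipeline
#'
#' Orchestrates the analysis end to end: (optionally) simulate a dispensing
#' panel, apply the pharmacy transmission filter, select new initiators and
#' apply the patient-activity filter, classify baseline treatment, build
#' episodes under each grace scenario, classify post-discontinuation sequels,
#' compute dose and combination-therapy metrics, and fit the comparative
#' models (Kaplan-Meier, Cox vs the reference drug — on the full cohort and
#' on the subgroup without prior depot exposure — and the logistic restart
#' model). Multiple inclusion periods are plain configuration entries: the
#' pipeline loops over `periods` and reports each separately.
#'
#' Any stage failure aborts with the stage name and the patient counts that
#' survived each preceding filter, so eligibility rules stay auditable.
#'
#' @param sim A [sim_config()] used to generate data, or `NULL` when
#'   `transactions` et al. are supplied.
#' @param transactions,transmission_log,patients Pre-loaded tables (see
#'   [read_transactions()]); ignored when `sim` is given.
#' @param periods Named list of [study_config()]s, one per inclusion period.
#' @param scenarios Grace scenarios to run (episodes are built for all of
#'   them; sequel/dose/model stages use `base_scenario`).
#' @param base_scenario Scenario feeding the sequel, dosing and model stages.
#' @param reference_drug Reference cohort for hazard and odds ratios.
#' @param out_dir If non-`NULL`, [report_tables()] writes all report files
#'   there (one subdirectory per period).
#' @return A list of class `run_manifest`: `seed`, `scenarios`, and per
#'   period the filter-chain `counts`, `cohort`, `episodes` (per scenario),
#'   `sequel`, `doses`, `comed`, `covariates`, `continuation`, `km`,
#'   `cox`, `cox_subgroup`, `restart` and the ground `truth` when simulated.
#' @export
run_pipeline <- function(sim = sim_config(),
                         transactions = NULL,
                         transmission_log = NULL,
                         patients = NULL,
                         periods = list(main = study_config()),
                         scenarios = grace_scenario_names(),
                         base_scenario = "base",
                         reference_drug = "pp1m",
                         out_dir = NULL) {
  stage <- "simulate"
  counts <- list()
  fail <- function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         "\n  filter-chain counts so far: ",
         paste(names(counts), unlist(counts), sep = "=", collapse = ", "),
         call. = FALSE)
  }
  tryCatch({
    truth <- NULL
    if (!is.null(sim)) {
      s <- simulate_lrx(sim)
      transactions <- s$transactions
      transmission_log <- s$transmission_log
      patients <- s$patients
      truth <- s$truth
      seed <- sim$seed
    } else {
      if (is.null(transactions) || is.null(transmission_log) ||
          is.null(patients)) {
        stop("supply either `sim` or all of transactions/transmission_log/",
             "patients")
      }
      seed <- NA_integer_
    }
    counts$transactions_observed <- nrow(transactions)
  }, error = fail)

  out <- list(seed = if (exists("seed")) seed else NA_integer_,
              scenarios = scenarios, periods = list())

  for (pname in names(periods)) {
    study <- periods[[pname]]
    pcounts <- counts
    rules <- coverage_rules(olanzapine_300_days = study$olanzapine_300_days)
    res <- list(study = study)

    stage <- paste0(pname, ":filter_pharmacies")
    tryCatch({
      elig_ph <- filter_pharmacies(transmission_log, study$country)
      pcounts$pharmacies_total <- length(unique(transmission_log$pharmacy_id))
      pcounts$pharmacies_eligible <- length(elig_ph)
      tx <- transactions[transactions$pharmacy_id %in% elig_ph, , drop = FALSE]
      pcounts$transactions_eligible_pharmacies <- nrow(tx)
    }, error = fail)

    stage <- paste0(pname, ":identify_new_initiators")
    tryCatch({
      cohort <- identify_new_initiators(tx, study)
      pcounts$initiators <- nrow(cohort)
    }, error = fail)

    stage <- paste0(pname, ":filter_patient_activity")
    tryCatch({
      cohort <- filter_patient_activity(cohort, tx, study)
      pcounts$after_activity_filter <- nrow(cohort)
    }, error = fail)

    stage <- paste0(pname, ":classify_baseline")
    tryCatch({
      cohort <- classify_baseline(cohort, tx, study)
      m <- match(cohort$patient_id, patients$patient_id)
      cohort$gender <- patients$gender[m]
      cohort$age_band <- patients$age_band[m]
      pcounts$cohort <- nrow(cohort)
    }, error = fail)
    if (!nrow(cohort)) {
      stage <- paste0(pname, ":cohort")
      tryCatch(stop("empty cohort after filtering"), error = fail)
    }

    stage <- paste0(pname, ":episodes")
    tryCatch({
      eps <- lapply(scenarios, function(sc) {
        build_episodes(tx, cohort, scenario = sc, country = study$country,
                       followup_days = study$followup_days, rules = rules,
                       initiation_window_days = study$initiation_window_days)
      })
      names(eps) <- scenarios
    }, error = fail)
    base <- eps[[base_scenario]]

    stage <- paste0(pname, ":sequel")
    tryCatch({
      seq_tab <- classify_sequel(base$episodes, tx, study)
      seq_tab$index_drug <- base$episodes$index_drug
    }, error = fail)

    stage <- paste0(pname, ":dosing")
    tryCatch({
      doses <- dose_table(base$episodes, base$purchases, study)
      comed <- comed_table(base$episodes, tx, study)
    }, error = fail)

    stage <- paste0(pname, ":models")
    tryCatch({
      cov <- build_covariates(base$episodes, patients, doses, comed)
      cont <- continuation_table(eps, rules)
      km <- km_curve(base$episodes, by_drug = TRUE)
      two_plus <- length(unique(base$episodes$index_drug)) >= 2
      cox <- if (two_plus) cox_hr(base$episodes, cov, reference_drug)
      no_plaap <- cohort$patient_id[cohort$baseline_class != "prior-LAAP"]
      sub_eps <- base$episodes[base$episodes$patient_id %in% no_plaap, ,
                               drop = FALSE]
      cox_sub <- if (length(unique(sub_eps$index_drug)) >= 2 &&
                     any(sub_eps$event == 1L)) {
        cox_hr(sub_eps, cov, reference_drug)
      }
      restart <- if (two_plus && sum(seq_tab$eligible) > 0) {
        restart_logit(seq_tab, cov, reference_drug)
      }
    }, error = fail)

    res$counts <- pcounts
    res$cohort <- cohort
    res$episodes <- eps
    res$sequel <- seq_tab
    res$doses <- doses
    res$comed <- comed
    res$covariates <- cov
    res$continuation <- cont
    res$km <- km
    res$cox <- cox
    res$cox_subgroup <- cox_sub
    res$restart <- restart
    out$periods[[pname]] <- res
  }
  out$truth <- truth
  class(out) <- "run_manifest"
  if (!is.null(out_dir)) report_tables(out, out_dir)
  out
}

# Continuation summary across scenarios: KM at 6/12 months plus the two
# readings of "after one injection" (refill share and KM at one coverage
# period of the drug's modal pack).
continuation_table <- function(eps, rules) {
  parts <- list()
  for (sc in names(eps)) {
    e <- eps[[sc]]$episodes
    p <- eps[[sc]]$purchases
    for (d in sort(unique(e$index_drug))) {
      ed <- e[e$index_drug == d, , drop = FALSE]
      cov_d <- p$coverage_days[p$index_drug == d]
      modal_cov <- as.numeric(names(sort(table(cov_d), decreasing = TRUE))[1])
      parts[[length(parts) + 1L]] <- data.frame(
        scenario = sc, index_drug = d, n = nrow(ed),
        after_one_injection_refill =
          mean(ed$n_purchases >= 2 | ed$event == 0L),
        after_one_injection_km = continuation_fraction(ed, modal_cov),
        after_6_months = continuation_fraction(ed, 180),
        after_12_months = continuation_fraction(ed, 365),
        events = sum(ed$event))
    }
  }
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write the report files of a pipeline run
#'
#' Emits, per inclusion period: a baseline-demographics table (N, gender,
#' median age band, prior-treatment classes), a continuation table (per
#' scenario and drug), hazard- and odds-ratio tables, sequel-class counts,
#' dose/combination summaries, Kaplan-Meier curve points, the per-patient
#' cohort/episode/sequel/dose tables, and a JSON manifest with the
#' filter-chain counts.
#'
#' @param manifest A `run_manifest` from [run_pipeline()].
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
report_tables <- function(manifest, out_dir) {
  stopifnot(inherits(manifest, "run_manifest"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(x, f) {
    utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  }
  meta <- list(seed = manifest$seed, scenarios = manifest$scenarios)
  for (pname in names(manifest$periods)) {
    res <- manifest$periods[[pname]]
    if (is.null(res$counts)) stop("missing upstream output for period '",
                                  pname, "'", call. = FALSE)
    tag <- function(f) paste0(pname, "_", f)
    ch <- res$cohort
    demo <- do.call(rbind, lapply(split(ch, ch$index_drug), function(g) {
      data.frame(
        index_drug = g$index_drug[1], n = nrow(g),
        men = sum(g$gender == "M"), women = sum(g$gender == "F"),
        unknown_gender = sum(!g$gender %in% c("M", "F")),
        median_age_band = median_age_band(g),
        prior_laap = sum(g$baseline_class == "prior-LAAP"),
        prior_other_ap = sum(g$baseline_class == "prior-other-AP"),
        no_ap = sum(g$baseline_class == "no-AP"))
    }))
    wcsv(demo, tag("baseline_demographics.csv"))
    wcsv(res$continuation, tag("continuation.csv"))
    wcsv(res$km, tag("km_curves.csv"))
    if (!is.null(res$cox)) {
      cox_all <- rbind(cbind(cohort = "all", as.data.frame(res$cox)),
                       if (!is.null(res$cox_subgroup)) {
                         cbind(cohort = "excluding-prior-LAAP",
                               as.data.frame(res$cox_subgroup))
                       })
      wcsv(cox_all, tag("cox_hr.csv"))
    }
    if (!is.null(res$restart)) {
      wcsv(as.data.frame(res$restart), tag("restart_or.csv"))
    }
    sq <- res$sequel[res$sequel$eligible, , drop = FALSE]
    if (nrow(sq)) {
      seq_sum <- as.data.frame.matrix(table(sq$index_drug, sq$sequel_class))
      seq_sum <- cbind(index_drug = rownames(seq_sum),
                       eligible_n = rowSums(seq_sum), seq_sum)
      rownames(seq_sum) <- NULL
      wcsv(seq_sum, tag("sequel_classes.csv"))
    }
    dc <- merge(res$doses, res$comed, by = "patient_id")
    ds <- do.call(rbind, lapply(split(dc, dc$index_drug), function(g) {
      on6 <- g$month6 %in% c("monotherapy", "combined")
      data.frame(
        index_drug = g$index_drug[1],
        n_dose_analysed = sum(!is.na(g$start_dose_mg)),
        median_start_mg = stats::median(g$start_dose_mg, na.rm = TRUE),
        median_end_mg = stats::median(g$end_dose_mg, na.rm = TRUE),
        mean_avg_dose_28d = mean(g$avg_dose_per_28d, na.rm = TRUE),
        pct_up = mean(g$dose_change == "up", na.rm = TRUE) * 100,
        pct_monotherapy_m1 = mean(g$month1 == "monotherapy") * 100,
        pct_monotherapy_m6 =
          if (any(on6)) mean(g$month6[on6] == "monotherapy") * 100 else NA,
        pct_anticholinergic_m1 = mean(g$anticholinergic_month1) * 100)
    }))
    wcsv(ds, tag("dose_comed_summary.csv"))
    wcsv(ch, tag("cohort.csv"))
    for (sc in names(res$episodes)) {
      wcsv(res$episodes[[sc]]$episodes, tag(paste0("episodes_", sc, ".csv")))
    }
    wcsv(res$sequel, tag("sequel_patients.csv"))
    wcsv(dc, tag("dose_comed_patients.csv"))
    meta$counts[[pname]] <- res$counts
  }
  jsonlite::write_json(meta, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed", x$seed, "-", length(x$periods), "period(s)\n")
  for (pname in names(x$periods)) {
    p <- x$periods[[pname]]
    cat("  ", pname, ": ",
        paste(names(p$counts), unlist(p$counts), sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
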