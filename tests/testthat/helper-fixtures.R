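# Small in-code fixtures shared across tests.

# Build a transaction table from day offsets relative to a reference date.
ref_date <- as.Date("2011-08-01")

make_tx <- function(patient_id, day, drug, strength_mg = 100, units = 1,
                    atc = "N5A1", pharmacy_id = "PH0001",
                    origin = ref_date) {
  n <- max(length(patient_id), length(day), length(drug))
  data.frame(
    patient_id = rep_len(patient_id, n),
    pharmacy_id = rep_len(pharmacy_id, n),
    date = origin + rep_len(day, n),
    drug = rep_len(drug, n),
    atc = rep_len(atc, n),
    strength_mg = rep_len(strength_mg, n),
    units = rep_len(as.integer(units), n),
    stringsAsFactors = FALSE
  )
}

# Transmission log for one pharmacy over `n_months` months with the given
# (1-based) months missing.
make_log <- function(pharmacy_id = "PH0001", n_months = 24, missing = integer(),
                     start = "2011-01") {
  months <- month_seq(paste0(start, "-01"),
                      seq(as.Date(paste0(start, "-01")), by = "month",
                          length.out = n_months)[n_months])
  data.frame(pharmacy_id = pharmacy_id,
             month = months,
             transmitted = !(seq_len(n_months) %in% missing),
             stringsAsFactors = FALSE)
}

test_study <- function(...) {
  study_config(inclusion_start = ref_date - 30,
               inclusion_end = ref_date + 395,
               olanzapine_300_days = 28, ...)
}

# Trimmed generator configuration for deterministic pipeline tests: two-arm
# panel with all optional behaviour switched off unless overridden.
bare_sim <- function(n_patients = 500, seed = 1, ...) {
  args <- list(
    n_patients = n_patients,
    drug_mix = c(pp1m = 0.5, haloperidol_decanoate = 0.5),
    hazard = c(pp1m = 0.004, haloperidol_decanoate = 0.004),
    pharmacy_missingness = 0, restart_probability = 0,
    prior_laap_fraction = 0, prior_oap_fraction = 0,
    comed_probability = 0, anticholinergic_probability = 0,
    background_activity = 0, loading_probability = 0,
    uptitration_probability = 0, jitter_sd = 0, seed = seed
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

# a valid strength for each index drug
modal_strength <- function(drug) {
  c(pp1m = 100, risperidone_microspheres = 37.5,
    haloperidol_decanoate = 100, olanzapine_pamoate = 405)[[drug]]
}

truth_cohort <- function(sim) {
  sim$truth$patients[, c("patient_id", "index_drug", "index_date")]
}
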