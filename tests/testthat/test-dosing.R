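test_that("average dose per 28 days follows the episode formula", {
  # two 100 mg purchases, episode 0..56: 200 mg / 56 d x 28 = 100
  e <- build_episode(c(0, 28), 100, 1, "pp1m")
  d <- dose_summary(e)
  expect_equal(e$time_to_discontinuation, 56)
  expect_equal(d$avg_dose_per_28d, 100)
  expect_equal(d$start_dose_mg, 100)
  expect_equal(d$end_dose_mg, 100)
  expect_equal(d$dose_change, "flat")
  # alternative denominator: last purchase offset
  d2 <- dose_summary(e, denominator = "last_purchase")
  expect_equal(d2$avg_dose_per_28d, 200 / 28 * 28)
})

test_that("the SmPC initiation scheme shifts the start dose past the loading window", {
  e <- build_episode(c(0, 7, 35), c(150, 100, 75), 1, "pp1m",
                     initiation_window_days = 14)
  d <- dose_summary(e)
  expect_equal(d$start_dose_mg, 75)
  expect_equal(d$end_dose_mg, 75)
  # without a configured scheme the first purchase defines the start dose
  e0 <- build_episode(c(0, 7, 35), c(150, 100, 75), 1, "pp1m")
  expect_equal(dose_summary(e0)$start_dose_mg, 150)
})

test_that("dose direction and single-purchase exclusion behave as defined", {
  e <- build_episode(c(0, 30), c(100, 150), 1, "pp1m")
  expect_equal(dose_summary(e)$dose_change, "up")
  e <- build_episode(c(0, 30), c(150, 100), 1, "pp1m")
  expect_equal(dose_summary(e)$dose_change, "down")
  expect_null(dose_summary(build_episode(0, 100, 1, "pp1m")))
})

test_that("steady dosing at exact coverage spacing reproduces the strength", {
  # PP1M, one 100 mg unit every 28 days: avg per 28 d equals the strength
  for (n in 2:6) {
    e <- build_episode(seq(0, by = 28, length.out = n), 100, 1, "pp1m")
    expect_equal(dose_summary(e)$avg_dose_per_28d, 100)
  }
})

test_that("cohort dose table matches single-episode summaries", {
  sim <- simulate_lrx(bare_sim(n_patients = 200, seed = 41, jitter_sd = 4,
                               uptitration_probability = 0.3,
                               loading_probability = 0.5))
  rules <- coverage_rules(olanzapine_300_days = 28)
  b <- build_episodes(sim$transactions, truth_cohort(sim), rules = rules)
  st <- study_config(olanzapine_300_days = 28)
  dt <- dose_table(b$episodes, b$purchases, st)
  for (i in sample(nrow(b$episodes), 20)) {
    pid <- b$episodes$patient_id[i]
    tx <- sim$transactions
    tx <- tx[tx$patient_id == pid & tx$drug == b$episodes$index_drug[i], ]
    e <- build_episode(as.integer(tx$date - b$episodes$index_date[i]),
                       tx$strength_mg, tx$units, b$episodes$index_drug[i],
                       rules = rules,
                       initiation_window_days =
                         if (b$episodes$index_drug[i] == "pp1m") 14 else 0)
    d <- dose_summary(e)
    row <- dt[dt$patient_id == pid, ]
    if (is.null(d)) {
      expect_true(is.na(row$start_dose_mg))
    } else {
      expect_equal(row$start_dose_mg, d$start_dose_mg)
      expect_equal(row$end_dose_mg, d$end_dose_mg)
      expect_equal(row$avg_dose_per_28d, d$avg_dose_per_28d)
    }
  }
})

test_that("up-titration frequency tracks the configured probability", {
  p_up <- 0.3
  sim <- simulate_lrx(bare_sim(n_patients = 1200, seed = 42,
                               hazard = 0.002,
                               drug_mix = c(pp1m = 1),
                               uptitration_probability = p_up))
  rules <- coverage_rules(olanzapine_300_days = 28)
  b <- build_episodes(sim$transactions, truth_cohort(sim), rules = rules)
  dt <- dose_table(b$episodes, b$purchases, study_config(olanzapine_300_days = 28))
  ok <- !is.na(dt$dose_change)
  # an up-titration registers unless it was scheduled after the episode end
  # or the starter was already at the top strength (150 mg: 20% of starters)
  drawn_up <- mean(dt$dose_change[ok] == "up")
  expect_gt(drawn_up, 0.10)
  expect_lt(drawn_up, p_up + 0.05)
})

test_that("combination and anticholinergic status use the month windows and country lists", {
  st <- test_study()
  ep <- data.frame(patient_id = "A", index_drug = "pp1m",
                   index_date = ref_date, time_to_discontinuation = 200,
                   event = 1L, stringsAsFactors = FALSE)
  base_tx <- make_tx("A", c(0, 28, 56, 84, 112, 140), "pp1m")
  # oral quetiapine on day 10: combined in month 1, not month 6
  tx <- rbind(base_tx, make_tx("A", 10, "quetiapine_oral", 300, atc = "N5A9"))
  cs <- comed_table(ep, tx, st)
  expect_equal(as.character(cs$month1), "combined")
  expect_equal(as.character(cs$month6), "monotherapy")
  # biperiden on day 150 (inside days 140-167), NL list
  tx <- rbind(base_tx, make_tx("A", 150, "biperiden", 4, atc = "N4A0"))
  cs <- comed_table(ep, tx, st)
  expect_true(cs$anticholinergic_month6)
  expect_false(cs$anticholinergic_month1)
  # procyclidine is only on the Belgian list
  tx <- rbind(base_tx, make_tx("A", 10, "procyclidine", 5, atc = "N4A0"))
  expect_false(comed_table(ep, tx, st)$anticholinergic_month1)
  st_be <- test_study(country = "BE")
  expect_true(comed_table(ep, tx, st_be)$anticholinergic_month1)
  # the index drug itself never counts as combination
  expect_equal(as.character(comed_table(ep, base_tx, st)$month1),
               "monotherapy")
})

test_that("month-6 status only exists for patients still on therapy", {
  st <- test_study()
  ep <- data.frame(patient_id = c("A", "B"), index_drug = "pp1m",
                   index_date = ref_date,
                   time_to_discontinuation = c(150, 168), event = 1L,
                   stringsAsFactors = FALSE)
  tx <- rbind(make_tx("A", c(0, 28), "pp1m"),
              make_tx("B", c(0, 28, 56, 84, 112, 140), "pp1m"))
  cs <- comed_table(ep, tx, st)
  expect_equal(as.character(cs$month6), c("not-on-treatment", "monotherapy"))
  expect_true(is.na(cs$anticholinergic_month6[1]))
  # the two on-treatment classes partition the survivors
  on6 <- ep$time_to_discontinuation >= 168
  expect_equal(sum(cs$month6 %in% c("monotherapy", "combined")), sum(on6))
})
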