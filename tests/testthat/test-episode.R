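test_that("discontinuation time is last qualifying purchase plus its supply", {
  # complete stop: 30-day gap tolerated, time = 30 + 28
  e <- build_episode(c(0, 30), 100, 1, "pp1m")
  expect_equal(e$time_to_discontinuation, 58)
  expect_equal(e$event, 1L)
  expect_equal(e$mode, "complete_stop")
  expect_equal(e$n_purchases, 2L)

  # interruption: 70 > 56, the day-70 purchase is outside the episode
  e <- build_episode(c(0, 70), 100, 1, "pp1m")
  expect_equal(e$time_to_discontinuation, 28)
  expect_equal(e$mode, "interruption")
  expect_equal(e$n_purchases, 1L)

  # single purchase: complete stop at one coverage period
  e <- build_episode(0, 100, 1, "pp1m")
  expect_equal(e$time_to_discontinuation, 28)
  expect_equal(e$mode, "complete_stop")

  # units scale the supply: 2 units cover 56 days, so a 60-day gap holds
  # (permissible 56 + 28 = 84) and the final supply runs 60 + 28
  e <- build_episode(c(0, 60), 100, c(2, 1), "pp1m")
  expect_equal(e$time_to_discontinuation, 88)
})

test_that("supply reaching the end of follow-up censors the episode", {
  e <- build_episode(c(0, 370), 100, 1, "pp1m", scenario = "upper")
  expect_equal(e$event, 0L)
  expect_equal(e$mode, "none")
  expect_equal(e$time_to_discontinuation, 395)
  # purchases on/after day 395 are outside the retrieval window
  e <- build_episode(c(0, 30, 395), 100, 1, "pp1m")
  expect_equal(e$n_purchases, 2L)
  expect_equal(e$time_to_discontinuation, 58)
})

test_that("same-day purchases merge and the longer supply governs the gap", {
  # two 1-unit purchases on day 0 merge to 2 units: permissible 84
  e <- build_episode(c(0, 0, 80), 100, 1, "pp1m")
  expect_equal(e$n_purchases, 2L)
  expect_equal(e$time_to_discontinuation, 80 + 28)
  # different strengths on one day: both counted, larger supply governs
  e <- build_episode(c(0, 0, 40), c(150, 100, 100), c(1, 2, 1), "pp1m")
  expect_equal(e$time_to_discontinuation, 40 + 28)
  expect_equal(nrow(e$purchases), 3L)
})

test_that("mid-episode strength changes use each purchase's own coverage", {
  # NL olanzapine: 210 mg covers 28 d (gap 56), 405 mg covers 14 d (gap 42)
  e <- build_episode(c(0, 50, 90), c(210, 405, 405), 1, "olanzapine_pamoate")
  expect_equal(e$time_to_discontinuation, 90 + 14)
  # after the switch the shorter permissible gap applies: 50 d gap now breaks
  e <- build_episode(c(0, 50, 100), c(210, 405, 405), 1, "olanzapine_pamoate")
  expect_equal(e$mode, "interruption")
  expect_equal(e$time_to_discontinuation, 50 + 14)
})

test_that("episode time never includes the grace period", {
  set.seed(401)
  rules <- coverage_rules(olanzapine_300_days = 28)
  grace <- grace_scenarios()
  for (i in 1:200) {
    drug <- sample(c("pp1m", "risperidone_microspheres",
                     "haloperidol_decanoate"), 1)
    days <- sort(sample(0:250, sample(1:5, 1)))
    days <- unique(c(0, days))
    sc <- sample(grace_scenario_names(), 1)
    e <- build_episode(days, modal_strength(drug), 1, drug, scenario = sc,
                       rules = rules, grace = grace)
    if (e$event == 1L) {
      q <- e$purchases[e$purchases$qualifying, ]
      lastq <- q[which.max(q$day), ]
      expect_equal(e$time_to_discontinuation,
                   lastq$day + lastq$coverage_days * lastq$units)
    } else {
      expect_equal(e$time_to_discontinuation, 395)
    }
    expect_true(xor(e$event == 1L, e$mode == "none"))
  }
})

test_that("time to discontinuation is non-decreasing in the grace period", {
  set.seed(402)
  ordering <- c("lower", "base", "sensitivity", "upper")
  for (i in 1:100) {
    drug <- sample(c("pp1m", "risperidone_microspheres",
                     "haloperidol_decanoate", "olanzapine_pamoate"), 1)
    country <- sample(c("NL", "BE"), 1)
    days <- unique(c(0, sort(sample(1:380, sample(1:6, 1)))))
    t_sc <- vapply(ordering, function(sc) {
      build_episode(days, modal_strength(drug), 1, drug, country = country,
                    scenario = sc)$time_to_discontinuation
    }, numeric(1))
    expect_true(all(diff(t_sc) >= 0),
                info = paste(drug, country, paste(days, collapse = ",")))
  }
})

test_that("gap scan matches the brute-force day-by-day oracle on random cases", {
  set.seed(403)
  rules <- coverage_rules(olanzapine_300_days = 28)
  grace <- grace_scenarios()
  for (i in 1:300) {
    drug <- sample(c("pp1m", "risperidone_microspheres",
                     "haloperidol_decanoate", "olanzapine_pamoate"), 1)
    country <- sample(c("NL", "BE"), 1)
    sc <- sample(grace_scenario_names(), 1)
    strength <- if (drug == "olanzapine_pamoate") {
      sample(c(210, 300, 405), 1)
    } else modal_strength(drug)
    days <- unique(c(0, sort(sample(1:300, sample(0:5, 1)))))
    units <- sample(1:2, length(days), replace = TRUE)
    e <- build_episode(days, strength, units, drug, country = country,
                       scenario = sc, rules = rules, grace = grace)
    cov <- lookup_coverage(rep(drug, length(days)), rep(strength, length(days)),
                           rep(country, length(days)), rules)
    gr <- lookup_grace(rep(drug, length(days)), cov, sc, grace)
    o <- oracle_episode(days, cov * units, gr, 395)
    expect_equal(e$time_to_discontinuation, o$time)
    expect_equal(e$event, o$event)
    expect_equal(e$mode, o$mode)
  }
})

test_that("cohort-level episode builder agrees with the single-episode path", {
  sim <- simulate_lrx(bare_sim(n_patients = 150, seed = 9, jitter_sd = 4,
                               restart_probability = 0.3))
  co <- truth_cohort(sim)
  rules <- coverage_rules(olanzapine_300_days = 28)
  built <- build_episodes(sim$transactions, co, rules = rules)
  for (i in sample(nrow(co), 25)) {
    p <- co$patient_id[i]
    tx <- sim$transactions
    tx <- tx[tx$patient_id == p & tx$drug == co$index_drug[i], ]
    days <- as.integer(tx$date - co$index_date[i])
    e <- build_episode(days, tx$strength_mg, tx$units, co$index_drug[i],
                       rules = rules)
    row <- built$episodes[built$episodes$patient_id == p, ]
    expect_equal(row$time_to_discontinuation, e$time_to_discontinuation)
    expect_equal(row$event, e$event)
    expect_equal(row$mode, e$mode)
  }
})

test_that("continuation fraction reduces to a proportion without censoring", {
  eps <- data.frame(time_to_discontinuation = c(30, 100, 190, 200, 210, 300,
                                                350, 360, 370, 380),
                    event = 1L)
  expect_equal(continuation_fraction(eps, 180), 0.8)
  expect_equal(continuation_fraction(eps, 365), 0.2)
  all_cens <- data.frame(time_to_discontinuation = rep(395, 5), event = 0L)
  expect_equal(continuation_fraction(all_cens, 365), 1.0)
  expect_error(continuation_fraction(all_cens[0, ], 365), "no episodes")
})

test_that("degenerate inputs raise explicit errors", {
  expect_error(build_episode(numeric(0), 100, 1, "pp1m"), "at least one")
  expect_error(build_episode(400, 100, 1, "pp1m", followup_days = 395),
               NA) # offsets are normalised to the earliest purchase
})
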