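test_that("annual treatment cost reproduces the printed totals", {
  cfg <- paper_cfg()
  # comparator: 25.8 + 8.2 + 5.1 + 8.2 = 47.3 CNY/day
  comp <- annual_treatment_cost(cfg$arm_comparator, cfg$econ$days_per_year)
  expect_equal(comp, 47.3 * 365.25)
  expect_lt(abs(comp - 17277), 2)  # printed annual total, +/- rounding
  expect_equal(annual_treatment_cost(cfg$arm_intervention, 365.25),
               37.6 * 365.25)
  zero <- cfg$arm_intervention
  zero$drug_cost_daily <- 0; zero$needle_cost_daily <- 0
  zero$smbg_cost_daily <- 0
  expect_equal(annual_treatment_cost(zero, 365.25), 0)
})

test_that("complication costs follow the event/state convention", {
  cfg <- paper_cfg()
  states <- c("ren_none", "microalb", "macroalb", "esrd")
  occ <- matrix(0, 2, 4, dimnames = list(NULL, states))
  inc <- matrix(0, 2, 4, dimnames = list(NULL, states))
  # full mass enters ESRD in cycle 2 and occupies it the same year
  occ[1, "ren_none"] <- 1
  occ[2, "esrd"] <- 1
  inc[2, "esrd"] <- 1
  sim <- fake_sim(states, occ, inc, alive_end = c(1, 1))
  led <- accrue_complication_costs(sim, cfg$costs)
  expect_equal(unname(led[2, "renal"]), 158396 + 127391)
  expect_equal(led[, "background"], c(3349, 3349))

  # occupancy without incidence: state cost only, linear in mass
  states_e <- c("eye_none", "bdr", "pdr", "me", "pdrme", "svl")
  occ_e <- matrix(0, 1, 6, dimnames = list(NULL, states_e))
  occ_e[1, "me"] <- 0.5; occ_e[1, "eye_none"] <- 0.5
  inc_e <- matrix(0, 1, 6, dimnames = list(NULL, states_e))
  sim_e <- fake_sim(states_e, occ_e, inc_e, alive_end = 1, submodel_id = "eye")
  led_e <- accrue_complication_costs(sim_e, cfg$costs)
  expect_equal(unname(led_e[1, "eye"]), 0.5 * 2163)
})

test_that("hypoglycemia streams are linear in rates", {
  cfg <- paper_cfg()
  path <- data.frame(cycle = 0, hypo_nonsevere_rate = 0.06,
                     hypo_severe_rate = 0)
  h <- accrue_hypoglycemia(path, 1, cfg$costs, cfg$utilities)
  expect_equal(h$cost, 0.06 * 880)            # 52.8 CNY
  expect_equal(h$disutility, 0.06 * -0.014)   # -0.00084 QALY
  path2 <- path; path2$hypo_nonsevere_rate <- 0.12
  h2 <- accrue_hypoglycemia(path2, 1, cfg$costs, cfg$utilities)
  expect_equal(h2$cost, 2 * h$cost)
  expect_equal(h2$disutility, 2 * h$disutility)
  path0 <- path; path0$hypo_nonsevere_rate <- 0
  h0 <- accrue_hypoglycemia(path0, 1, cfg$costs, cfg$utilities)
  expect_equal(h0$cost, 0)
  expect_equal(h0$disutility, 0)
})

test_that("cycle utility is additive with the published decrements", {
  cfg <- paper_cfg()
  states <- list(
    heart_failure = c(hf_none = 1, hf = 0)
  )
  cov <- baseline_covariates(cfg$cohort)
  row <- data.frame(bmi = 35.9, injections_per_day = 0,
                    hypo_nonsevere_rate = 0, hypo_severe_rate = 0)
  # baseline-profile patient, no complications, no injections
  expect_equal(utility_for_cycle(states, cov, row, cfg$utilities, cfg$cohort),
               0.936)
  # heart failure: 0.936 - 0.186
  states$heart_failure <- c(hf_none = 0, hf = 1)
  expect_equal(utility_for_cycle(states, cov, row, cfg$utilities, cfg$cohort),
               0.936 - 0.186)
  # +10 years of age and duration: extra -0.024 - 0.016
  cov10 <- cov; cov10["age"] <- 71; cov10["duration"] <- 24.1
  states$heart_failure <- c(hf_none = 1, hf = 0)
  expect_equal(utility_for_cycle(states, cov10, row, cfg$utilities,
                                 cfg$cohort),
               0.936 - 0.024 - 0.016)
  # one injection per day
  row1 <- row; row1$injections_per_day <- 1
  expect_equal(utility_for_cycle(states, cov, row1, cfg$utilities,
                                 cfg$cohort),
               0.936 - 0.00805)
  # the floor: absurd decrements cannot push utility below zero
  ut <- cfg$utilities
  ut$state_decrements$hf <- -0.99
  states$heart_failure <- c(hf_none = 0, hf = 1)
  cov99 <- cov; cov99["age"] <- 101; cov99["duration"] <- 54.1
  expect_equal(utility_for_cycle(states, cov99, row, ut, cfg$cohort), 0)
})

test_that("discounting matches its closed form", {
  expect_equal(discount_stream(c(3, 4, 5), 0), 12)
  expect_equal(discount_stream(c(0, 100), 0.05), 100 / 1.05)
  rates <- seq(0, 0.2, by = 0.04)
  pv <- vapply(rates, function(r) discount_stream(rep(100, 10), r),
               numeric(1))
  expect_true(all(diff(pv) < 0))
  # alternative convention: exponent starts at 1
  expect_equal(discount_stream(c(100, 0), 0.05, from = 1), 100 / 1.05)
})

test_that("cost accrual is linear in the cost catalog", {
  cfg <- paper_cfg()
  k <- 3
  scaled <- cfg
  for (nm in names(scaled$costs)) {
    scaled$costs[[nm]]$event_cost <- k * scaled$costs[[nm]]$event_cost
    scaled$costs[[nm]]$state_cost <- k * scaled$costs[[nm]]$state_cost
  }
  sim <- run_cohort(cfg, "intervention")
  led1 <- build_ledger(sim, cfg)
  led2 <- build_ledger(sim, scaled)
  cats <- setdiff(colnames(led1$categories), "treatment")
  expect_equal(led2$categories[, cats], k * led1$categories[, cats])
  expect_equal(led2$categories[, "treatment"], led1$categories[, "treatment"])
})

test_that("ledgers are internally consistent and obey the discount limit", {
  cfg <- paper_cfg()
  sim <- run_cohort(cfg, "comparator")
  led <- build_ledger(sim, cfg)
  expect_equal(rowSums(led$categories), led$total_cost, tolerance = 1e-6)
  expect_true(all(led$categories_disc <= led$categories + 1e-12))
  expect_true(all(led$qaly_disc <= led$qaly + 1e-12))

  cfg0 <- config_set_path(cfg, "econ.discount_rate_cost", 0)
  cfg0 <- config_set_path(cfg0, "econ.discount_rate_qaly", 0)
  led0 <- build_ledger(run_cohort(cfg0, "comparator"), cfg0)
  expect_equal(sum(led0$total_cost_disc), sum(led0$total_cost))
  expect_equal(sum(led0$qaly_disc), sum(led0$qaly))
})

test_that("incremental summary reproduces the printed arithmetic and verdicts", {
  econ <- paper_cfg()$econ
  res <- summarize_ce(fake_ledger(412494, 5.685),
                      fake_ledger(446748, 5.249), econ)
  expect_equal(res$d_qaly, 0.436)
  expect_equal(res$d_cost, -34254)
  expect_equal(res$verdict, "dominant")
  expect_true(is.na(res$icer))
  expect_equal(res$nmb, 85698 * 0.436 + 34254)

  eq <- summarize_ce(fake_ledger(100, 1), fake_ledger(100, 1), econ)
  expect_equal(eq$verdict, "equivalent")

  ic <- summarize_ce(fake_ledger(200, 2), fake_ledger(100, 1), econ)
  expect_equal(ic$verdict, "icer")
  expect_equal(ic$icer, 100)

  dom <- summarize_ce(fake_ledger(200, 1), fake_ledger(100, 2), econ)
  expect_equal(dom$verdict, "dominated")
})

test_that("dominance classification matches a brute-force quadrant oracle", {
  econ <- paper_cfg()$econ
  set.seed(7)
  for (i in 1:60) {
    dc <- round(rnorm(1, 0, 100))
    dq <- round(rnorm(1, 0, 1), 2)
    res <- summarize_ce(fake_ledger(1000 + dc, 5 + dq),
                        fake_ledger(1000, 5), econ)
    oracle <- if (dc < 0 && dq > 0) "dominant"
      else if (dc > 0 && dq < 0) "dominated"
      else if (dc == 0 && dq == 0) "equivalent"
      else "icer"
    expect_equal(res$verdict, oracle)
    if (oracle == "icer") expect_equal(res$icer, dc / dq)
  }
})
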