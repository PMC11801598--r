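test_that("transition matrices are row-stochastic and renormalize competing exits", {
  cov <- baseline_covariates(paper_cfg()$cohort)

  # zero-rate equations give the identity
  sm <- list(submodel_id = "t", states = list("a", "b", "c"),
             transitions = list(
               list(from = "a", to = "b", equation = "z"),
               list(from = "b", to = "c", equation = "z")))
  P <- build_transition_probabilities(sm, cov, list(z = const_eq("z", 0)))
  expect_equal(P, diag(3), ignore_attr = TRUE)

  # competing exits 0.7 + 0.6 > 1: proportional renormalization with warning
  sm2 <- list(submodel_id = "t", states = list("a", "b", "c"),
              transitions = list(
                list(from = "a", to = "b", equation = "p7"),
                list(from = "a", to = "c", equation = "p6")))
  eqs <- list(p7 = const_eq("p7", 0.7), p6 = const_eq("p6", 0.6))
  expect_warning(P2 <- build_transition_probabilities(sm2, cov, eqs),
                 "renormalized")
  expect_equal(sum(P2["a", ]), 1)
  expect_equal(P2["a", "b"] / P2["a", "c"], 0.7 / 0.6)
  expect_equal(P2["a", "a"], 0)

  # 3-state chain with constant rates matches the hand-built matrix
  sm3 <- list(submodel_id = "t", states = list("a", "b", "c"),
              transitions = list(
                list(from = "a", to = "b", equation = "p2"),
                list(from = "b", to = "c", equation = "p5")))
  eqs3 <- list(p2 = const_eq("p2", 0.2), p5 = const_eq("p5", 0.5))
  P3 <- build_transition_probabilities(sm3, cov, eqs3)
  hand <- matrix(c(0.8, 0.2, 0,
                   0, 0.5, 0.5,
                   0, 0, 1), 3, 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(P3, hand)
})

test_that("propagation conserves mass and matches the toy closed form", {
  P <- matrix(c(0.7, 0.3, 0, 1), 2, 2, byrow = TRUE)
  occ <- c(1, 0)
  for (i in 1:3) occ <- propagate_cycle(occ, P)
  expect_equal(occ, c(0.7^3, 1 - 0.7^3))

  toy <- make_toy_submodel(2, 0.3)
  cfg <- make_toy_config(toy, horizon = 3)
  sim <- run_cohort(cfg, "intervention")
  expect_equal(unname(sim$occupancy$toy[3, ]), c(0.343, 0.657))
  expect_equal(cumulative_incidence(sim, "toy_s1"), 65.7)
})

test_that("cohort propagation equals brute-force matrix powering (oracle)", {
  cov0 <- baseline_covariates(paper_cfg()$cohort)
  for (n_states in 2:4) {
    for (p in c(0.05, 0.3, 0.9)) {
      toy <- make_toy_submodel(n_states, p)
      cfg <- make_toy_config(toy, horizon = 40)
      sim <- run_cohort(cfg, "intervention")
      P <- build_transition_probabilities(toy$submodel, cov0, toy$equations)
      for (cyc in c(1, 7, 40)) {
        expect_equal(unname(sim$occupancy$toy[cyc, ]),
                     matrix_power_occupancy(P, cyc), tolerance = 1e-9)
      }
    }
  }
})

test_that("total probability mass is conserved every cycle", {
  for (arm in c("intervention", "comparator")) {
    sim <- run_cohort(paper_cfg(), arm)
    total <- sim$alive_end + cumsum(sim$deaths_other + sim$deaths_cv)
    expect_true(all(abs(total - 1) < 1e-10))
    # each sub-model's conditional occupancy sums to 1 (the alive mass)
    for (sm in names(sim$states)) {
      expect_true(all(abs(rowSums(sim$occupancy[[sm]]) - 1) < 1e-10))
    }
    expect_true(all(diff(sim$alive_end) <= 1e-12))  # survival monotone
    expect_true(all(sim$incident >= -1e-15))
  }
})

test_that("zero hazards give zero incidence and zero mortality", {
  toy <- make_toy_submodel(3, 0)
  cfg <- make_toy_config(toy, horizon = 10)
  sim <- run_cohort(cfg, "comparator")
  expect_equal(sum(sim$incident), 0)
  expect_equal(sim$cum_mortality, 0)
  expect_equal(sim$alive_end, rep(1, 10))
})

test_that("horizon above the 40-year engine limit is refused", {
  cfg <- paper_cfg()
  # bypass config validation to hit the engine's own guard
  cfg$econ$horizon_years <- 41L
  expect_error(run_cohort(cfg, "intervention"), "40-year")
})

test_that("cumulative incidence is monotone in the horizon and errors on unknown states", {
  toy <- make_toy_submodel(2, 0.2)
  ci <- vapply(c(2, 5, 9), function(h) {
    sim <- run_cohort(make_toy_config(toy, horizon = h), "intervention")
    cumulative_incidence(sim, "toy_s1")
  }, numeric(1))
  expect_true(all(diff(ci) > 0))
  sim <- run_cohort(make_toy_config(toy, horizon = 2), "intervention")
  expect_error(cumulative_incidence(sim, "gondor"), "unknown state")
})

test_that("relative risk matches printed two-decimal convention", {
  expect_equal(as.numeric(relative_risk(26.32, 34.81)), 0.76)
  expect_equal(as.numeric(relative_risk(2.27, 3.86)), 0.59)
  expect_equal(as.numeric(relative_risk(5, 5)), 1.00)
  expect_equal(attr(relative_risk(1, 3), "raw"), 1 / 3)
  expect_error(relative_risk(1, 0), "undefined")
})

test_that("lower intervention HbA1c lowers incidence, and swapping arms reverses it", {
  cfg <- paper_cfg()
  si <- run_cohort(cfg, "intervention")
  sc <- run_cohort(cfg, "comparator")
  hba1c_sensitive <- c("bdr", "pdr", "me", "pdrme", "svl",
                       "microalb", "macroalb", "esrd", "neuropathy")
  for (s in hba1c_sensitive) {
    expect_lt(cumulative_incidence(si, s), cumulative_incidence(sc, s))
  }
  expect_lt(si$cum_mortality, sc$cum_mortality)

  # swap the arms' HbA1c: the direction reverses
  swapped <- config_set_path(cfg, "arm_intervention.hba1c_on_treatment", 8.3)
  swapped <- config_set_path(swapped, "arm_comparator.hba1c_on_treatment", 7.6)
  si2 <- run_cohort(swapped, "intervention")
  sc2 <- run_cohort(swapped, "comparator")
  for (s in hba1c_sensitive) {
    expect_gt(cumulative_incidence(si2, s), cumulative_incidence(sc2, s))
  }
})

test_that("tidy export has one row per cycle, sub-model and state", {
  toy <- make_toy_submodel(3, 0.1)
  sim <- run_cohort(make_toy_config(toy, horizon = 5), "intervention")
  df <- as.data.frame(sim)
  expect_equal(nrow(df), 5 * 3)
  expect_named(df, c("cycle", "arm", "submodel", "state", "occupancy",
                     "incident_probability"))
  expect_equal(sum(df$occupancy[df$cycle == 4]), 1)
})
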