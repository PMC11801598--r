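test_that("beta moment matching is exact and rejects infeasible moments", {
  sh <- beta_from_moments(0.936, 0.120)
  nu <- 0.936 * 0.064 / 0.120^2 - 1
  expect_equal(unname(sh["alpha"]), 0.936 * nu)  # 2.958
  expect_equal(unname(sh["beta"]), 0.064 * nu)   # 0.202
  expect_equal(round(unname(sh["alpha"]), 3), 2.958)
  expect_equal(round(unname(sh["beta"]), 3), 0.202)
  # analytic round-trip: parameters give back the requested moments exactly
  m <- sh["alpha"] / (sh["alpha"] + sh["beta"])
  v <- sh["alpha"] * sh["beta"] /
    ((sh["alpha"] + sh["beta"])^2 * (sh["alpha"] + sh["beta"] + 1))
  expect_equal(unname(m), 0.936)
  expect_equal(unname(sqrt(v)), 0.120)

  # degenerate limit: tiny se concentrates at the mean
  sh0 <- beta_from_moments(0.5, 1e-6)
  expect_gt(sh0["alpha"], 1e10)
  expect_equal(unname(sh0["alpha"] / (sh0["alpha"] + sh0["beta"])), 0.5)

  expect_error(beta_from_moments(0.936, 0.3), "infeasible")
  expect_error(beta_from_moments(1.2, 0.1), "mean")
})

test_that("gamma moment matching is exact", {
  sh <- gamma_from_moments(100, 10)
  expect_equal(unname(sh), c(100, 1))
  sh2 <- gamma_from_moments(3349, 334.9)
  expect_equal(unname(sh2["shape"]), 100)
  expect_equal(unname(sh2["scale"]), 33.49)
  # mean is preserved exactly for arbitrary inputs
  for (m in c(0.5, 880, 158396)) {
    s <- gamma_from_moments(m, 0.1 * m)
    expect_equal(unname(s["shape"] * s["scale"]), m)
    expect_equal(unname(sqrt(s["shape"]) * s["scale"]), 0.1 * m)
  }
  expect_error(gamma_from_moments(-1, 1), "positive")
  expect_error(gamma_from_moments(1, 0), "positive")
})

test_that("default PSA distributions cover the published uncertain inputs", {
  cfg <- paper_cfg()
  d <- default_psa_distributions(cfg)
  expect_true(all(d$family %in% c("beta", "gamma", "normal")))
  expect_equal(d$family[d$path == "utilities.baseline_utility"], "beta")
  expect_equal(d$family[d$path == "costs.esrd.event_cost"], "gamma")
  expect_equal(d$se[d$path == "costs.esrd.event_cost"], 15839.6)  # 10% rule
  expect_equal(d$se[d$path == "arm_intervention.hba1c_on_treatment"], 0.102)
  # administered drug prices are not sampled
  expect_false(any(grepl("drug_cost_daily", d$path)))
  expect_identical(d$path, sort(d$path))  # fixed draw order
})

test_that("PSA with fixed distributions reproduces the base case; seeds reproduce", {
  cfg <- paper_cfg()
  base <- run_ce(cfg)$result
  fixed <- data.frame(
    path = c("utilities.baseline_utility", "costs.esrd.event_cost"),
    family = "fixed",
    mean = c(0.936, 158396), se = c(0, 0))
  psa <- run_psa(cfg, fixed, n = 3, seed = 11)
  expect_equal(psa$draws$d_cost, rep(base$d_cost, 3))
  expect_equal(psa$draws$d_qaly, rep(base$d_qaly, 3))

  d <- default_psa_distributions(cfg)
  p1 <- run_psa(cfg, d, n = 4, seed = 99)
  p2 <- run_psa(cfg, d, n = 4, seed = 99)
  expect_identical(p1$draws, p2$draws)
  expect_identical(p1$params, p2$params)
  p3 <- run_psa(cfg, d, n = 4, seed = 100)
  expect_false(identical(p1$draws, p3$draws))

  # infeasible distribution fails before any simulation
  bad <- data.frame(path = "utilities.baseline_utility", family = "beta",
                    mean = 0.936, se = 0.9)
  expect_error(run_psa(cfg, bad, n = 2, seed = 1), "infeasible")
})

test_that("CEAC equals brute-force counting and is monotone for positive dQALY", {
  draws <- data.frame(d_cost = c(-100, 50, 200, -20),
                      d_qaly = c(0.1, 0.02, 0.05, 0.3))
  grid <- c(0, 1000, 4000, 10000)
  cc <- ceac(draws, grid)
  oracle <- vapply(grid, function(l) {
    sum(l * draws$d_qaly - draws$d_cost > 0) / nrow(draws)
  }, numeric(1))
  expect_equal(cc$probability, oracle)
  expect_true(all(diff(cc$probability) >= 0))  # all dQALY > 0

  dominant <- data.frame(d_cost = c(-5, -10), d_qaly = c(0.1, 0.2))
  expect_equal(ceac(dominant, c(0, 85698))$probability, c(1, 1))

  sym <- data.frame(d_cost = c(-1, 1), d_qaly = c(0, 0))
  expect_equal(ceac(sym, 100)$probability, 0.5)

  expect_error(ceac(data.frame(d_cost = numeric(0), d_qaly = numeric(0))),
               "empty")
})

test_that("one-way sensitivity floats discount rates 0-8% and others +/-10%", {
  cfg <- paper_cfg()
  r <- default_owsa_ranges(cfg)
  dr <- r[grepl("discount_rate", r$path), ]
  expect_equal(dr$low, c(0, 0))
  expect_equal(dr$high, c(0.08, 0.08))
  other <- r[!grepl("discount_rate", r$path), ]
  base_vals <- vapply(other$path, function(p) config_get_path(cfg, p),
                      numeric(1))
  expect_equal(other$low, unname(0.9 * base_vals))
  expect_equal(other$high, unname(1.1 * base_vals))
})

test_that("tornado bars: zero-influence parameters, independence of order, failed bounds", {
  cfg <- paper_cfg()
  ranges <- data.frame(
    path = c("cohort.tg_mmol",                 # unused by any equation
             "costs.esrd.event_cost",
             "utilities.baseline_utility"),    # high bound 1.03 is invalid
    low = c(2.42 * 0.9, 158396 * 0.9, 0.936 * 0.9),
    high = c(2.42 * 1.1, 158396 * 1.1, 0.936 * 1.1),
    stringsAsFactors = FALSE)
  tor <- one_way_sensitivity(cfg, ranges)
  expect_equal(tor$width[tor$parameter == "cohort.tg_mmol"], 0)
  expect_gt(tor$width[tor$parameter == "costs.esrd.event_cost"], 0)
  bu <- tor[tor$parameter == "utilities.baseline_utility", ]
  expect_equal(bu$status, "invalid_bound")
  expect_true(is.na(bu$width))

  tor2 <- one_way_sensitivity(cfg, ranges[c(2, 3, 1), ])
  for (p in ranges$path) {
    expect_equal(tor$width[tor$parameter == p],
                 tor2$width[tor2$parameter == p])
  }
  expect_error(one_way_sensitivity(cfg, ranges[0, ]), "empty")
})
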