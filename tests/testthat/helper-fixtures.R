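# Shared fixtures. The reference config is loaded once per test run; toy
# fixtures are built in code (no stored data).

paper_cfg <- local({
  cfg <- NULL
  function() {
    if (is.null(cfg)) cfg <<- default_paper_config()
    cfg
  }
})

# a bare constant-rate equation spec with probability p per cycle
const_eq <- function(id, p) {
  list(id = id, form = "constant",
       intercept = if (p >= 1) Inf else -log(1 - p), shape = NA_real_,
       coefs = stats::setNames(numeric(0), character(0)),
       centers = stats::setNames(numeric(0), character(0)))
}

# brute-force oracle: occupancy after n cycles by matrix powering
matrix_power_occupancy <- function(P, n) {
  occ <- c(1, rep(0, nrow(P) - 1))
  for (i in seq_len(n)) occ <- as.vector(occ %*% P)
  occ
}

# minimal hand-built cea_sim-like object for economics unit tests
fake_sim <- function(states, occupancy, incident, alive_end,
                     submodel_id = "renal") {
  horizon <- length(alive_end)
  structure(list(
    arm = "intervention", strategy = "fake", horizon = horizon,
    states = stats::setNames(list(states), submodel_id),
    submodel_of = stats::setNames(rep(submodel_id, length(states)), states),
    occupancy = stats::setNames(list(occupancy), submodel_id),
    incident = incident, alive_end = alive_end,
    alive_start = rep(1, horizon), deaths_other = rep(0, horizon),
    deaths_cv = rep(0, horizon)
  ), class = "cea_sim")
}

# single-cycle ledgers with prescribed discounted totals, for dominance tests
fake_ledger <- function(cost, qaly, ly = 1) {
  structure(list(
    arm = "x", horizon = 1L,
    categories = matrix(cost, 1, 1, dimnames = list(NULL, "treatment")),
    categories_disc = matrix(cost, 1, 1, dimnames = list(NULL, "treatment")),
    total_cost = cost, total_cost_disc = cost,
    life_years = ly, life_years_disc = ly,
    qaly = qaly, qaly_disc = qaly, hypo_events = 0
  ), class = "cea_ledger")
}
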