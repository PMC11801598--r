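# Synthetic fixtures: toy sub-models with closed-form occupancy, perturbed
# configurations, and emulated parameter catalogs. Everything is generated
# in code (seeded where random) so the test suite needs no stored data.

#' Toy linear-chain sub-model with closed-form occupancy
#'
#' A chain of `n_states` states where every non-terminal state advances to
#' the next with the same probability each cycle. The number of advances
#' after n cycles is Binomial(n, leave_prob) truncated at the terminal
#' state, which gives an exact closed-form occupancy for any cycle --- the
#' independent oracle for the cohort engine.
#'
#' @param n_states Number of states (2--4).
#' @param leave_prob Per-cycle advance probability in \[0, 1\].
#' @param seed Unused (the fixture is deterministic); kept for signature
#'   stability with the other generators.
#' @return A list: `submodel` (engine-loadable spec), `equations` (named
#'   list of constant-rate equations), `occupancy(cycle)` (closed-form
#'   oracle returning the occupancy vector after `cycle` cycles),
#'   `n_states`, `leave_prob`.
#' @export
make_toy_submodel <- function(n_states, leave_prob, seed = NULL) {
  if (n_states < 2 || n_states > 4) {
    stop("n_states must be between 2 and 4", call. = FALSE)
  }
  if (leave_prob < 0 || leave_prob > 1) {
    stop("leave_prob must be in [0, 1]", call. = FALSE)
  }
  states <- paste0("toy_s", seq_len(n_states) - 1L)
  rate <- if (leave_prob >= 1) Inf else -log(1 - leave_prob)
  eq <- list(id = "toy_leave", form = "constant", intercept = rate,
             shape = NA_real_,
             coefs = stats::setNames(numeric(0), character(0)),
             centers = stats::setNames(numeric(0), character(0)))
  transitions <- lapply(seq_len(n_states - 1L), function(i) {
    list(from = states[i], to = states[i + 1L], equation = "toy_leave")
  })
  submodel <- list(submodel_id = "toy", states = as.list(states),
                   transitions = transitions)
  p <- leave_prob
  occupancy <- function(cycle) {
    k <- seq_len(n_states) - 1L
    probs <- stats::dbinom(k, size = cycle, prob = p)
    probs[n_states] <- 1 - stats::pbinom(n_states - 2L, size = cycle,
                                         prob = p)
    stats::setNames(probs, states)
  }
  list(submodel = submodel, equations = list(toy_leave = eq),
       occupancy = occupancy, n_states = n_states, leave_prob = leave_prob)
}

#' Minimal runnable configuration around a toy sub-model
#'
#' Wraps a toy sub-model (or any single sub-model spec plus equations) into a
#' complete, validated configuration with zero mortality, zero costs and
#' neutral utilities, so the full pipeline (engine, economics, reporting) can
#' run against the closed-form oracle.
#'
#' @param toy Result of [make_toy_submodel()].
#' @param horizon Cycles to simulate (default 10).
#' @param mortality_rate Constant annual death rate (default 0).
#' @return A validated `cea_config`.
#' @export
make_toy_config <- function(toy, horizon = 10, mortality_rate = 0) {
  states <- unlist(toy$submodel$states)
  strategy <- list(
    name = "toy therapy", hba1c_on_treatment = 7, bmi_on_treatment = 25,
    sbp_on_treatment = 120, dbp_on_treatment = 80,
    hypo_nonsevere_rate = 0, hypo_severe_rate = 0,
    drug_cost_daily = 0, needle_cost_daily = 0, smbg_cost_daily = 0,
    injections_per_day = 0L
  )
  zero_cost <- list(event_cost = 0, state_cost = 0)
  costs <- c(
    list(background = list(event_cost = 0, state_cost = 0),
         hypo_nonsevere = list(event_cost = 0, state_cost = 0),
         hypo_severe = list(event_cost = 0, state_cost = 0)),
    stats::setNames(rep(list(zero_cost), length(states) - 1L), states[-1])
  )
  decs <- stats::setNames(rep(list(0), length(states) - 1L), states[-1])
  mort_eq <- list(id = "toy_mort", form = "constant",
                  intercept = if (mortality_rate > 0)
                    -log(1 - mortality_rate) else 0,
                  shape = NA_real_,
                  coefs = stats::setNames(numeric(0), character(0)),
                  centers = stats::setNames(numeric(0), character(0)))
  config <- list(
    schema_version = 1,
    cohort = list(age_years = 60, duration_years = 10, prop_female = 0.5,
                  prop_smoker = 0.2, hba1c_pct = 7, sbp_mmHg = 120,
                  dbp_mmHg = 80, tc_mmol = 4.5, ldl_mmol = 2.5,
                  hdl_mmol = 1.2, tg_mmol = 1.5, bmi = 25,
                  heart_rate_bpm = 70, wbc = 6, egfr = 90),
    arm_intervention = strategy,
    arm_comparator = strategy,
    switch_rule = list(hba1c_threshold_pct = 99, post_switch_strategy = strategy),
    hba1c_drift_per_year = 0,
    risk_equations_file = "risk_equations.csv",
    case_fatality = stats::setNames(list(), character(0)),
    submodels = list(
      toy$submodel,
      list(submodel_id = "mortality",
           states = list("alive", "dead_cv", "dead_other"),
           transitions = list(
             list(from = "alive", to = "dead_other", equation = "toy_mort"),
             list(from = "alive", to = "dead_cv", equation = "case_fatality")
           ))
    ),
    costs = costs,
    utilities = list(
      baseline_utility = 0.9,
      state_decrements = decs,
      demographic_decrements = list(age_per_10y = 0, female = 0,
                                    duration_per_10y = 0, bmi_per_unit = 0),
      bmi_anchor = 25,
      event_disutilities = list(hypo_nonsevere = 0, hypo_severe = 0),
      injection_disutilities = list("0" = 0)
    ),
    uncertainty = list(cost_se_fraction = 0.1,
                       utility_se = list(baseline_utility = 0.1),
                       efficacy = list(
                         hba1c_intervention = list(mean = 7, se = 0.1),
                         sbp_intervention = list(mean = 120, se = 1),
                         hypo_rr = list(mean = 1, se = 0.1))),
    econ = list(horizon_years = as.integer(horizon),
                discount_rate_cost = 0.05, discount_rate_qaly = 0.05,
                wtp_threshold = 85698, days_per_year = 365.25,
                discount_from_cycle = 0, half_cycle_correction = FALSE)
  )
  equations <- c(toy$equations, list(toy_mort = mort_eq))
  equations <- equations[order(names(equations))]
  validate_model_config(config, equations)
  structure(config, class = "cea_config", equations = equations)
}

# dotted paths of numeric leaves eligible for perturbation
perturbable_paths <- function(config) {
  skip <- c("schema_version", "injections_per_day", "discount_from_cycle",
            "half_cycle_correction", "name", "submodels",
            "risk_equations_file", "risk_equations", "horizon_years")
  walk2 <- function(node, prefix) {
    out <- character(0)
    for (nm in names(node)) {
      if (nm %in% skip) next
      child <- node[[nm]]
      path <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      if (is.list(child)) {
        out <- c(out, walk2(child, path))
      } else if (is.numeric(child) && length(child) == 1) {
        out <- c(out, path)
      }
    }
    out
  }
  walk2(unclass(config), "")
}

# clamp a perturbed value back into its feasible range, by path pattern
clamp_param <- function(path, value, config) {
  clamp <- function(v, lo, hi) min(max(v, lo), hi)
  if (grepl("^cohort\\.prop_", path)) return(clamp(value, 0, 1))
  if (grepl("hba1c_on_treatment$", path)) return(clamp(value, 3, 20))
  if (grepl("bmi_on_treatment$", path)) return(clamp(value, 10, 80))
  if (grepl("sbp_on_treatment$", path)) return(clamp(value, 60, 260))
  if (grepl("dbp_on_treatment$", path)) return(clamp(value, 30, 160))
  if (path == "utilities.baseline_utility") return(clamp(value, 1e-6, 1))
  if (path == "utilities.bmi_anchor") return(clamp(value, 10, 80))
  if (grepl("decrement|disutilit", path)) return(min(value, 0))
  if (grepl("^case_fatality\\.", path)) return(clamp(value, 0, 1))
  if (grepl("^econ\\.discount_rate", path)) return(clamp(value, 0, 0.2))
  if (path == "econ.days_per_year") return(clamp(value, 1, 366.25))
  if (path == "econ.wtp_threshold") return(max(value, 1e-6))
  if (path == "uncertainty.cost_se_fraction") return(clamp(value, 0, 1))
  max(value, 0)  # remaining parameters are non-negative quantities
}

#' Randomly perturb a configuration
#'
#' Every numeric parameter (counts, flags and structural fields excepted) is
#' multiplied by an independent factor uniform in
#' \[1 - spread, 1 + spread\]; values are then clamped back into their
#' feasible ranges (with a `message()` per clamp) so the result always
#' validates.
#'
#' @param config A `cea_config`.
#' @param relative_spread Spread >= 0; 0 returns the config unchanged.
#' @param seed Integer seed.
#' @return A perturbed, validated `cea_config`.
#' @export
perturb_config <- function(config, relative_spread, seed = 1) {
  stopifnot(relative_spread >= 0)
  if (relative_spread == 0) return(config)
  set.seed(seed)
  paths <- sort(perturbable_paths(config))
  factors <- stats::runif(length(paths), 1 - relative_spread,
                          1 + relative_spread)
  for (i in seq_along(paths)) {
    v <- config_get_path(config, paths[i]) * factors[i]
    v2 <- clamp_param(paths[i], v, config)
    if (v2 != v) {
      message("perturb_config: clamped ", paths[i], " from ",
              signif(v, 6), " to ", signif(v2, 6))
    }
    config <- config_set_path(config, paths[i], v2, revalidate = FALSE)
  }
  validate_model_config(config)
  config
}

#' Emulate the statistical shape of the cost and utility catalogs
#'
#' Utilities: a baseline in (0.8, 1.0) with a beta-feasible SE, and
#' decrements in (-0.2, 0) with SE one tenth of the magnitude. Costs: event
#' and state costs log-uniform in \[1e2, 1e5\] CNY with 10\% SE. All rows
#' are beta/gamma-feasible by construction.
#'
#' @param n_states Number of utility-decrement rows (>= 1).
#' @param n_costs Number of cost rows (>= 1).
#' @param seed Integer seed.
#' @return A list of two data.frames: `utilities` (`name`, `mean`, `se`) with
#'   the baseline as the first row, and `costs` (`name`, `event_cost`,
#'   `state_cost`, `se_fraction`).
#' @export
emulate_parameter_catalog <- function(n_states, n_costs, seed = 1) {
  stopifnot(n_states >= 1, n_costs >= 1)
  set.seed(seed)
  baseline <- stats::runif(1, 0.8, 0.999)
  base_se <- 0.5 * sqrt(baseline * (1 - baseline))
  decs <- -stats::runif(n_states, 0.001, 0.2)
  utilities <- data.frame(
    name = c("baseline", paste0("state_", seq_len(n_states))),
    mean = c(baseline, decs),
    se = c(base_se, abs(decs) / 10),
    stringsAsFactors = FALSE
  )
  logu <- function(n) 10^stats::runif(n, 2, 5)
  costs <- data.frame(
    name = paste0("state_", seq_len(n_costs)),
    event_cost = logu(n_costs),
    state_cost = logu(n_costs),
    se_fraction = 0.1,
    stringsAsFactors = FALSE
  )
  list(utilities = utilities, costs = costs)
}
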