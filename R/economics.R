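# Cost and QALY accrual, discounting, and incremental cost-effectiveness.
#
# Conventions: event costs accrue on incidence (including events that prove
# fatal in the same year); state costs accrue on end-of-cycle occupancy,
# so the event year also carries the state cost. The dead accrue nothing
# from their cycle of death onward. Discounting divides cycle t (0-based)
# by (1+r)^t, i.e. the first year is undiscounted; a config flag moves the
# exponent start to 1, and an optional half-cycle correction shifts it by
# 0.5.

#' Annual glucose-lowering treatment cost of a strategy
#'
#' (drug + needle + SMBG daily costs) x days per year.
#'
#' @param strategy Strategy sub-list of a config.
#' @param days_per_year Days per model year (default 365.25, which
#'   reproduces the published comparator annual total to within 2 CNY).
#' @return CNY per year.
#' @export
annual_treatment_cost <- function(strategy, days_per_year = 365.25) {
  strategy_daily_cost(strategy) * days_per_year
}

#' Present value of a per-cycle stream
#'
#' @param stream Numeric vector, one value per cycle (cycle 0 first).
#' @param rate Annual discount rate (>= 0).
#' @param from Exponent of the first cycle: 0 (default, first year
#'   undiscounted) or 1.
#' @param half_cycle Add 0.5 to every exponent (half-cycle correction).
#' @return Scalar present value.
#' @export
discount_stream <- function(stream, rate, from = 0, half_cycle = FALSE) {
  stopifnot(rate >= 0)
  expo <- seq_along(stream) - 1 + from + if (half_cycle) 0.5 else 0
  sum(stream / (1 + rate)^expo)
}

# per-cycle discount factors for a config
discount_factors <- function(econ, horizon, which = c("cost", "qaly")) {
  which <- match.arg(which)
  rate <- if (which == "cost") econ$discount_rate_cost else
    econ$discount_rate_qaly
  expo <- seq_len(horizon) - 1 + econ$discount_from_cycle +
    if (isTRUE(econ$half_cycle_correction)) 0.5 else 0
  (1 + rate)^(-expo)
}

#' Expected utility per alive cohort member for one cycle
#'
#' Strictly additive combination: baseline utility, demographic progression
#' relative to the baseline profile (age and diabetes duration per 10 years,
#' BMI per unit relative to the anchor, cohort female fraction), injection
#' disutility, occupancy-weighted state decrements summed across the parallel
#' sub-models, and rate-weighted hypoglycemia event disutilities. The result
#' is floored at 0.
#'
#' @param occ Named list of conditional occupancy vectors (one per sub-model).
#' @param cov Covariate vector for the cycle (supplies age and duration).
#' @param path_row One row of a risk-factor path (BMI, hypoglycemia rates,
#'   injections).
#' @param utilities `utilities` sub-list of a config.
#' @param cohort `cohort` sub-list (the demographic reference point).
#' @return Utility in \[0, 1\] per alive cohort member.
#' @export
utility_for_cycle <- function(occ, cov, path_row, utilities, cohort) {
  dd <- utilities$demographic_decrements
  u <- utilities$baseline_utility +
    dd$age_per_10y * (cov[["age"]] - cohort$age_years) / 10 +
    dd$duration_per_10y * (cov[["duration"]] - cohort$duration_years) / 10 +
    dd$bmi_per_unit * (path_row$bmi - utilities$bmi_anchor) +
    dd$female * 0  # cohort composition is fixed at the baseline fraction
  inj <- utilities$injection_disutilities[[
    as.character(path_row$injections_per_day)]]
  u <- u + inj
  dec <- utilities$state_decrements
  for (sm in names(occ)) {
    present <- intersect(names(occ[[sm]]), names(dec))
    if (length(present) > 0) {
      u <- u + sum(occ[[sm]][present] * unlist(dec[present]))
    }
  }
  ed <- utilities$event_disutilities
  u <- u + path_row$hypo_nonsevere_rate * ed$hypo_nonsevere +
    path_row$hypo_severe_rate * ed$hypo_severe
  max(u, 0)
}

#' Hypoglycemia cost and disutility streams
#'
#' Cycle t cost = alive mass x (non-severe rate x unit cost + severe rate x
#' unit cost); the disutility stream is analogous with the per-event
#' decrements.
#'
#' @param path Risk-factor path ([hba1c_trajectory()]).
#' @param alive_mass Per-cycle alive mass (end of cycle).
#' @param costs `costs` sub-list of a config.
#' @param utilities `utilities` sub-list of a config.
#' @return A list with per-cycle `cost`, `disutility` and expected `events`
#'   (non-severe + severe) streams.
#' @export
accrue_hypoglycemia <- function(path, alive_mass, costs, utilities) {
  ns <- path$hypo_nonsevere_rate
  sev <- path$hypo_severe_rate
  list(
    cost = alive_mass * (ns * costs$hypo_nonsevere$event_cost +
                           sev * costs$hypo_severe$event_cost),
    disutility = alive_mass *
      (ns * utilities$event_disutilities$hypo_nonsevere +
         sev * utilities$event_disutilities$hypo_severe),
    events = alive_mass * (ns + sev)
  )
}

#' Complication cost streams from a simulation
#'
#' Cycle t cost for state s = incident probability x event cost + end-of-cycle
#' occupancy x state cost (the event year carries both). Background treatment
#' cost accrues on all alive mass.
#'
#' @param result A `cea_sim` object.
#' @param costs `costs` sub-list of a config.
#' @return Matrix of per-cycle undiscounted costs, one column per category:
#'   `background` plus one per complication sub-model.
#' @export
accrue_complication_costs <- function(result, costs) {
  horizon <- result$horizon
  cats <- c("background", names(result$states))
  out <- matrix(0, horizon, length(cats), dimnames = list(NULL, cats))
  out[, "background"] <- result$alive_end * costs$background$state_cost
  for (sm in names(result$states)) {
    for (s in result$states[[sm]]) {
      ce <- costs[[s]]
      if (is.null(ce)) {
        if (s %in% colnames(result$incident) &&
            any(result$incident[, s] > 0)) {
          stop("no cost entry for incident state '", s, "'", call. = FALSE)
        }
        next
      }
      occ_u <- result$occupancy[[sm]][, s] * result$alive_end
      out[, sm] <- out[, sm] + result$incident[, s] * ce$event_cost +
        occ_u * ce$state_cost
    }
  }
  out
}

#' Build the economic ledger for one simulated arm
#'
#' @param result A `cea_sim` object.
#' @param config The `cea_config` it was run under.
#' @return A `cea_ledger`: per-cycle undiscounted and discounted cost streams
#'   by category (treatment, background, hypoglycemia, one per complication
#'   sub-model), life-year and QALY streams.
#' @export
build_ledger <- function(result, config) {
  horizon <- result$horizon
  econ <- config$econ
  path <- result$path

  comp <- accrue_complication_costs(result, config$costs)
  hypo <- accrue_hypoglycemia(path, result$alive_end, config$costs,
                              config$utilities)
  treatment <- result$alive_end * path$daily_treatment_cost *
    econ$days_per_year

  categories <- cbind(treatment = treatment,
                      hypoglycemia = hypo$cost,
                      comp)

  qaly <- numeric(horizon)
  for (t in seq_len(horizon)) {
    occ_t <- lapply(names(result$states), function(sm) {
      stats::setNames(result$occupancy[[sm]][t, ], result$states[[sm]])
    })
    names(occ_t) <- names(result$states)
    u <- utility_for_cycle(occ_t, result$cov_trace[t, ], path[t, ],
                           config$utilities, config$cohort)
    qaly[t] <- result$alive_end[t] * u
  }
  ly <- result$alive_end

  df_cost <- discount_factors(econ, horizon, "cost")
  df_qaly <- discount_factors(econ, horizon, "qaly")

  structure(list(
    arm = result$arm, horizon = horizon,
    categories = categories,
    categories_disc = categories * df_cost,
    total_cost = rowSums(categories),
    total_cost_disc = rowSums(categories) * df_cost,
    life_years = ly, life_years_disc = ly * df_qaly,
    qaly = qaly, qaly_disc = qaly * df_qaly,
    hypo_events = hypo$events
  ), class = "cea_ledger")
}

#' Incremental cost-effectiveness summary
#'
#' Increments are intervention minus comparator of the discounted totals.
#' Verdict: `"dominant"` iff the intervention costs less and yields more
#' QALYs; `"dominated"` iff the reverse; `"equivalent"` when both increments
#' are zero; otherwise the ICER (CNY/QALY) is reported. Net monetary benefit
#' is WTP x dQALY - dCost.
#'
#' @param int_ledger,comp_ledger `cea_ledger` objects for the two arms.
#' @param econ `econ` sub-list of the config.
#' @return A `cea_result` list: per-arm life expectancy, QALYs and costs
#'   (total and by category, discounted), increments, `verdict`, `icer`
#'   (NA unless reportable) and `nmb`.
#' @export
summarize_ce <- function(int_ledger, comp_ledger, econ) {
  if (int_ledger$horizon != comp_ledger$horizon) {
    stop("ledgers span different horizons", call. = FALSE)
  }
  arm_summary <- function(l) {
    list(
      life_years = sum(l$life_years_disc),
      qaly = sum(l$qaly_disc),
      cost = sum(l$total_cost_disc),
      cost_by_category = colSums(l$categories_disc)
    )
  }
  a <- arm_summary(int_ledger)
  b <- arm_summary(comp_ledger)
  d_cost <- a$cost - b$cost
  d_qaly <- a$qaly - b$qaly
  d_ly <- a$life_years - b$life_years

  verdict <- if (d_cost < 0 && d_qaly > 0) {
    "dominant"
  } else if (d_cost > 0 && d_qaly < 0) {
    "dominated"
  } else if (d_cost == 0 && d_qaly == 0) {
    "equivalent"
  } else {
    "icer"
  }
  icer <- if (verdict == "icer") d_cost / d_qaly else NA_real_
  nmb <- econ$wtp_threshold * d_qaly - d_cost

  structure(list(
    intervention = a, comparator = b,
    d_cost = d_cost, d_qaly = d_qaly, d_life_years = d_ly,
    verdict = verdict, icer = icer, nmb = nmb,
    wtp = econ$wtp_threshold
  ), class = "cea_result")
}

#' Run both arms and summarize cost-effectiveness
#'
#' @param config A validated `cea_config`.
#' @return A list with the two `cea_sim`s, the two `cea_ledger`s and the
#'   `cea_result`.
#' @export
run_ce <- function(config) {
  sim_int <- run_cohort(config, "intervention")
  sim_comp <- run_cohort(config, "comparator")
  led_int <- build_ledger(sim_int, config)
  led_comp <- build_ledger(sim_comp, config)
  list(
    sim_intervention = sim_int, sim_comparator = sim_comp,
    ledger_intervention = led_int, ledger_comparator = led_comp,
    result = summarize_ce(led_int, led_comp, config$econ)
  )
}

#' @export
print.cea_result <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 0, big.mark = ",")
  cat("<cea_result>\n")
  cat(sprintf("  QALYs:  %.3f vs %.3f  (d = %+.3f)\n",
              x$intervention$qaly, x$comparator$qaly, x$d_qaly))
  cat(sprintf("  Costs:  %s vs %s CNY  (d = %s)\n",
              fmt(x$intervention$cost), fmt(x$comparator$cost),
              fmt(x$d_cost)))
  if (x$verdict == "icer") {
    cat(sprintf("  ICER: %s CNY/QALY\n", fmt(x$icer)))
  } else {
    cat("  Verdict:", x$verdict, "\n")
  }
  cat(sprintf("  NMB at WTP %s: %s CNY\n", fmt(x$wtp), fmt(x$nmb)))
  invisible(x)
}
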