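# Deterministic cohort propagation through parallel Markov sub-models.
#
# Each complication process (eye, lower extremity, renal, IHD, MI, stroke,
# heart failure) is a separate chain over its own states; chains interact
# only through shared covariates and shared mortality. Occupancy is stored
# conditional on being alive (each chain's mass sums to 1); a scalar alive
# mass ties the chains together. Within a cycle, background mortality is
# applied first, survivors undergo sub-model transitions, and incident
# MI/stroke events carry an event-year case fatality that forms the
# cardiovascular death stream.

#' Per-cycle transition matrix for one sub-model
#'
#' Evaluates every governing risk equation at the given covariates and
#' assembles a row-stochastic matrix. The stay probability is the complement
#' of the exits; if competing exits from one state sum to more than 1 they
#' are proportionally renormalized with a warning.
#'
#' @param submodel One element of `config$submodels`.
#' @param cov Named covariate vector (start-of-cycle values).
#' @param equations Named equation list (`attr(config, "equations")`).
#' @param warn Emit a warning when renormalizing competing exits.
#' @return A `states x states` transition matrix.
#' @export
build_transition_probabilities <- function(submodel, cov, equations,
                                           warn = TRUE) {
  states <- unlist(submodel$states)
  n <- length(states)
  P <- matrix(0, n, n, dimnames = list(states, states))
  for (tr in submodel$transitions) {
    p <- switch(tr$equation,
      always = 1,
      never = 0,
      case_fatality = 0,  # engine-managed, not part of the chain
      annual_event_probability(equations[[tr$equation]], cov)
    )
    if (is.na(p) || p < 0) {
      stop("negative or undefined transition probability for ",
           tr$from, " -> ", tr$to, call. = FALSE)
    }
    P[tr$from, tr$to] <- P[tr$from, tr$to] + p
  }
  for (i in seq_len(n)) {
    out <- sum(P[i, ]) - P[i, i]
    if (out > 1) {
      if (warn) {
        warning("submodel ", submodel$submodel_id, ", state ", states[i],
                ": competing exit probabilities sum to ",
                format(out, digits = 4), " > 1; renormalized", call. = FALSE)
      }
      P[i, ] <- P[i, ] / out
      out <- 1
    }
    P[i, i] <- 1 - out
  }
  P
}

#' Propagate occupancy one cycle
#'
#' @param occ Occupancy vector (conditional on alive; sums to 1).
#' @param transitions Transition matrix from
#'   [build_transition_probabilities()].
#' @return Updated occupancy vector.
#' @export
propagate_cycle <- function(occ, transitions) {
  as.vector(occ %*% transitions)
}

# set path row `cycle`'s modifiable risk factors into a covariate vector
apply_path_row <- function(cov, path, cycle) {
  row <- path[path$cycle == cycle, ]
  cov["hba1c"] <- row$hba1c
  cov["bmi"] <- row$bmi
  cov["sbp"] <- row$sbp
  cov["dbp"] <- row$dbp
  cov
}

#' Run the cohort simulation for one arm
#'
#' Deterministic: no randomness anywhere in the cohort engine. All sub-model
#' occupancies are tracked conditional on survival; `alive_end[t]` is the
#' alive mass after the deaths of cycle `t` (0-based).
#'
#' @param config A validated `cea_config`.
#' @param arm `"intervention"` or `"comparator"`.
#' @return A `cea_sim` object: per-cycle conditional occupancy per sub-model,
#'   unconditional incident-event matrix, death streams split into
#'   cardiovascular (event-year case fatality of MI/stroke) and other,
#'   cumulative incidences (percent), the risk-factor path, and the
#'   start-of-cycle covariate trace.
#' @export
run_cohort <- function(config, arm = c("intervention", "comparator")) {
  arm <- match.arg(arm)
  strategy <- if (arm == "intervention") config$arm_intervention else
    config$arm_comparator
  equations <- attr(config, "equations")
  horizon <- config$econ$horizon_years
  if (horizon > 40) {
    stop("horizon exceeds the engine's 40-year upper limit", call. = FALSE)
  }

  path <- hba1c_trajectory(strategy, config$hba1c_drift_per_year,
                           config$switch_rule, horizon)
  cov <- apply_path_row(baseline_covariates(config$cohort), path, 0)

  submodels <- Filter(function(s) s$submodel_id != "mortality",
                      config$submodels)
  mort <- Filter(function(s) s$submodel_id == "mortality",
                 config$submodels)[[1]]
  mort_eq_id <- NULL
  for (tr in mort$transitions) {
    if (!identical(tr$equation, "case_fatality")) mort_eq_id <- tr$equation
  }
  mort_eq <- if (mort_eq_id %in% reserved_equation_ids()) {
    mort_eq_id  # "never" etc., handled below
  } else {
    equations[[mort_eq_id]]
  }
  eval_mort <- function(cov) {
    if (is.character(mort_eq)) {
      if (mort_eq == "never") 0 else 1
    } else {
      annual_event_probability(mort_eq, cov)
    }
  }

  cf <- unlist_named(config$case_fatality)
  sm_ids <- vapply(submodels, function(s) s$submodel_id, character(1))
  sm_states <- lapply(submodels, function(s) unlist(s$states))
  names(sm_states) <- sm_ids
  all_states <- unlist(sm_states, use.names = FALSE)
  submodel_of <- rep(sm_ids, lengths(sm_states))
  names(submodel_of) <- all_states

  occ <- lapply(sm_states, function(st) {
    stats::setNames(c(1, rep(0, length(st) - 1)), st)
  })

  occupancy <- lapply(sm_states, function(st) {
    matrix(0, horizon, length(st), dimnames = list(NULL, st))
  })
  incident <- matrix(0, horizon, length(all_states),
                     dimnames = list(NULL, all_states))
  alive_start <- alive_end <- deaths_other <- deaths_cv <- numeric(horizon)
  cov_trace <- matrix(0, horizon, length(cov),
                      dimnames = list(NULL, names(cov)))

  alive <- 1
  for (t in seq_len(horizon)) {
    cov_trace[t, ] <- cov
    alive_start[t] <- alive

    p_bg <- eval_mort(cov)
    deaths_other[t] <- alive * p_bg
    survivors <- alive - deaths_other[t]

    fatal_total <- 0
    histories <- numeric(0)
    for (i in seq_along(submodels)) {
      sm <- submodels[[i]]
      id <- sm_ids[i]
      P <- build_transition_probabilities(sm, cov, equations)
      inflow <- as.vector(occ[[id]] %*% (P - diag(diag(P))))
      names(inflow) <- sm_states[[id]]
      new_occ <- propagate_cycle(occ[[id]], P)
      names(new_occ) <- sm_states[[id]]
      incident[t, sm_states[[id]]] <- survivors * inflow

      # event-year case fatality (cardiovascular deaths)
      fatal_sm <- 0
      for (es in intersect(names(cf), sm_states[[id]])) {
        dead_here <- inflow[es] * cf[[es]]
        new_occ[es] <- new_occ[es] - dead_here
        fatal_sm <- fatal_sm + dead_here
      }
      if (fatal_sm > 0) new_occ <- new_occ / (1 - fatal_sm)
      fatal_total <- fatal_total + fatal_sm

      occ[[id]] <- new_occ
      occupancy[[id]][t, ] <- new_occ
      if (!is.null(sm$history_covariate)) {
        histories[sm$history_covariate] <-
          sum(new_occ[unlist(sm$history_states)])
      }
    }
    deaths_cv[t] <- survivors * fatal_total
    alive <- survivors - deaths_cv[t]
    alive_end[t] <- alive

    if (t < horizon) {
      cov <- update_covariates(cov, path, t, histories)
    }
  }

  cum_incidence <- colSums(incident) * 100
  structure(list(
    arm = arm, strategy = strategy$name, horizon = horizon,
    states = sm_states, submodel_of = submodel_of,
    occupancy = occupancy, incident = incident,
    alive_start = alive_start, alive_end = alive_end,
    deaths_other = deaths_other, deaths_cv = deaths_cv,
    cum_incidence = cum_incidence,
    cum_mortality = (1 - alive_end[horizon]) * 100,
    cum_cv_mortality = sum(deaths_cv) * 100,
    path = path, switch_cycle = attr(path, "switch_cycle"),
    cov_trace = cov_trace
  ), class = "cea_sim")
}

#' Cumulative incidence of a state, in percent
#'
#' Sum over cycles of the unconditional incident probability of entering the
#' state, times 100. Entries through different routes in the same cycle all
#' count; re-entries (subsequent events) accumulate.
#'
#' @param result A `cea_sim` object.
#' @param state State id.
#' @return Cumulative incidence in \[0, 100\] (subsequent-event states can
#'   exceed 100 in principle since re-entries accumulate).
#' @export
cumulative_incidence <- function(result, state) {
  if (!state %in% colnames(result$incident)) {
    stop("unknown state: ", state, call. = FALSE)
  }
  unname(result$cum_incidence[state])
}

#' Relative risk of two cumulative incidences
#'
#' @param ci_intervention,ci_comparator Cumulative incidences in percent.
#' @param digits Rounding for the reported ratio (default 2, as printed in
#'   incidence tables); the raw ratio is attached as `attr(, "raw")`.
#' @return Rounded ratio with the raw ratio as an attribute.
#' @export
relative_risk <- function(ci_intervention, ci_comparator, digits = 2) {
  if (ci_comparator == 0) {
    stop("relative risk undefined: comparator incidence is zero",
         call. = FALSE)
  }
  raw <- ci_intervention / ci_comparator
  structure(round(raw, digits), raw = raw)
}

#' Tidy per-cycle export of a simulation
#'
#' @param x A `cea_sim` object.
#' @param ... Unused.
#' @return A data.frame with columns `cycle`, `arm`, `submodel`, `state`,
#'   `occupancy` (conditional on alive), `incident_probability`
#'   (unconditional).
#' @export
as.data.frame.cea_sim <- function(x, ...) {
  out <- do.call(rbind, lapply(names(x$states), function(id) {
    st <- x$states[[id]]
    data.frame(
      cycle = rep(seq_len(x$horizon) - 1L, times = length(st)),
      arm = x$arm, submodel = id,
      state = rep(st, each = x$horizon),
      occupancy = as.vector(x$occupancy[[id]]),
      incident_probability = as.vector(x$incident[, st]),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.cea_sim <- function(x, ...) {
  cat("<cea_sim> arm:", x$arm, "(", x$strategy, "),", x$horizon, "cycles\n")
  cat("  cumulative mortality:", sprintf("%.2f%%", x$cum_mortality),
      "| CV:", sprintf("%.2f%%", x$cum_cv_mortality), "\n")
  cat("  switch cycle:", x$switch_cycle, "\n")
  invisible(x)
}
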