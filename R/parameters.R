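# Model configuration: loading, validation, serialization.
#
# A model configuration is a nested named list (class "cea_config") parsed
# from a JSON document. The JSON file is the single source of truth for every
# model input: cohort profile, treatment strategies, switch rule, sub-model
# structure, risk-equation reference, costs, utilities, uncertainty inputs
# and economic settings. All currency is 2022 CNY.

#' Covariate names understood by the risk-equation engine
#'
#' `hist_*` covariates are event-history prevalences (fractions of the alive
#' cohort with a history of the event), updated each cycle from sub-model
#' occupancy.
#'
#' @return Character vector of covariate names.
#' @export
covariate_names <- function() {
  c("age", "female", "smoker", "duration", "hba1c", "sbp", "dbp",
    "tc", "ldl", "hdl", "tg", "bmi", "heart_rate", "wbc", "egfr",
    "hist_mi", "hist_stroke", "hist_ihd", "hist_hf", "hist_amp", "hist_esrd")
}

# Reserved equation ids resolved by the engine rather than the coefficient
# table: "always" is a certain transition (event -> history bookkeeping),
# "never" a zero-probability one, "case_fatality" the engine-managed
# cardiovascular death route.
reserved_equation_ids <- function() c("always", "never", "case_fatality")

cost_special_keys <- function() c("background", "hypo_nonsevere", "hypo_severe")

config_top_level_keys <- function() {
  c("schema_version", "cohort", "arm_intervention", "arm_comparator",
    "switch_rule", "hba1c_drift_per_year", "risk_equations_file",
    "risk_equations", "case_fatality", "submodels", "costs", "utilities",
    "uncertainty", "econ")
}

cohort_field_names <- function() {
  c("age_years", "duration_years", "prop_female", "prop_smoker", "hba1c_pct",
    "sbp_mmHg", "dbp_mmHg", "tc_mmol", "ldl_mmol", "hdl_mmol", "tg_mmol",
    "bmi", "heart_rate_bpm", "wbc", "egfr")
}

strategy_field_names <- function() {
  c("name", "hba1c_on_treatment", "bmi_on_treatment", "sbp_on_treatment",
    "dbp_on_treatment", "hypo_nonsevere_rate", "hypo_severe_rate",
    "drug_cost_daily", "needle_cost_daily", "smbg_cost_daily",
    "injections_per_day")
}

#' Load and validate a model configuration
#'
#' Reads a JSON configuration document, resolves the risk-equation coefficient
#' table it references, validates every field and cross-reference, and returns
#' a `cea_config` object. Unknown keys are rejected.
#'
#' @param path Path to a JSON configuration file.
#' @return A validated `cea_config` object. The parsed risk-equation table is
#'   attached as the `"equations"` attribute; it is not part of the serialized
#'   document beyond the file reference.
#' @seealso [default_paper_config()], [save_model_config()]
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file does not exist: ", path, call. = FALSE)
  }
  config <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  equations <- resolve_risk_equations(config, dirname(path))
  eq_path <- attr(equations, "source")
  attr(equations, "source") <- NULL
  validate_model_config(config, equations)
  structure(config, class = "cea_config", equations = equations,
            equations_path = eq_path)
}

#' The bundled reference parameterization
#'
#' Returns the package's default model configuration: the published Chinese
#' type-2 diabetes cohort (age 61, duration 14.1 years), IDegLira versus
#' GLP-1RA + basal insulin strategies, the HbA1c > 8.5\% switch rule, all
#' complication costs and utility decrements, 30-year horizon, 5\% discount
#' rates and a willingness-to-pay threshold of 85,698 CNY/QALY.
#'
#' @return A validated `cea_config` object.
#' @export
default_paper_config <- function() {
  load_model_config(system.file("extdata", "default_config.json",
                                package = "t2dcea", mustWork = TRUE))
}

#' Serialize a model configuration
#'
#' Writes the configuration back to the same JSON dialect read by
#' [load_model_config()]. Save followed by load is the identity on every
#' valid configuration.
#'
#' @param config A `cea_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_model_config <- function(config, path) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, path)
  # keep the coefficient table reachable from the saved document's directory
  src <- attr(config, "equations_path")
  if (!is.null(src)) {
    dest <- file.path(dirname(path), config$risk_equations_file)
    if (!file.exists(dest)) file.copy(src, dest)
  }
  invisible(path)
}

#' Compute a strategy's total daily drug cost
#'
#' `drug_cost_daily` may be stored as a named breakdown (e.g. GLP-1RA and
#' basal insulin components); components are summed here, preserving the
#' published per-component prices in the document.
#'
#' @param strategy A strategy sub-list of a `cea_config`.
#' @return Total drug cost, CNY/day.
#' @export
strategy_drug_cost <- function(strategy) {
  dc <- strategy$drug_cost_daily
  if (is.numeric(dc)) return(sum(dc))
  sum(vapply(dc, as.numeric, numeric(1)))
}

# total daily cost of a strategy (drug + needles + SMBG), CNY/day
strategy_daily_cost <- function(strategy) {
  strategy_drug_cost(strategy) + strategy$needle_cost_daily +
    strategy$smbg_cost_daily
}

# ---- risk-equation coefficient table -----------------------------------

# Read the columnar coefficient file referenced by the config, then apply any
# inline "risk_equations" overrides. Returns a named list of equation specs:
# list(id, form, intercept, shape, coefs = named numeric, centers = named
# numeric).
resolve_risk_equations <- function(config, config_dir) {
  file <- config[["risk_equations_file"]]
  if (is.null(file)) stop("missing field: risk_equations_file", call. = FALSE)
  candidate <- file.path(config_dir, file)
  if (!file.exists(candidate)) {
    candidate <- system.file("extdata", file, package = "t2dcea")
  }
  if (!nzchar(candidate) || !file.exists(candidate)) {
    stop("risk-equation file not found: ", file, call. = FALSE)
  }
  tab <- utils::read.csv(candidate, stringsAsFactors = FALSE)
  needed <- c("equation_id", "form", "term", "covariate", "value")
  if (!all(needed %in% names(tab))) {
    stop("risk-equation file must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  eqs <- lapply(split(tab, tab$equation_id), parse_equation_rows)
  # inline overrides (full replacement per equation id)
  for (ov in config[["risk_equations"]]) {
    eq <- list(
      id = ov$equation_id, form = ov$form,
      intercept = as.numeric(ov$intercept),
      shape = if (is.null(ov$shape)) NA_real_ else as.numeric(ov$shape),
      coefs = unlist_named(ov$coefficients),
      centers = unlist_named(ov$centers)
    )
    check_equation(eq)
    eqs[[eq$id]] <- eq
  }
  eqs <- eqs[order(names(eqs))]
  attr(eqs, "source") <- candidate
  eqs
}

unlist_named <- function(x) {
  if (is.null(x) || length(x) == 0) {
    return(stats::setNames(numeric(0), character(0)))
  }
  vapply(x, as.numeric, numeric(1))
}

parse_equation_rows <- function(rows) {
  id <- rows$equation_id[1]
  form <- unique(rows$form)
  if (length(form) != 1) {
    stop("equation ", id, ": inconsistent functional form", call. = FALSE)
  }
  grab <- function(term) rows[rows$term == term, , drop = FALSE]
  ic <- grab("intercept")
  if (nrow(ic) != 1) {
    stop("equation ", id, ": exactly one intercept row required", call. = FALSE)
  }
  sh <- grab("shape")
  co <- grab("coef")
  ce <- grab("center")
  eq <- list(
    id = id, form = form, intercept = ic$value,
    shape = if (nrow(sh) == 1) sh$value else NA_real_,
    coefs = stats::setNames(co$value, co$covariate),
    centers = stats::setNames(ce$value, ce$covariate)
  )
  check_equation(eq)
  eq
}

check_equation <- function(eq) {
  forms <- c("constant", "exponential", "weibull", "logistic")
  if (!eq$form %in% forms) {
    stop("equation ", eq$id, ": unknown form '", eq$form, "' (expected one of ",
         paste(forms, collapse = ", "), ")", call. = FALSE)
  }
  if (eq$form == "weibull" && (is.na(eq$shape) || eq$shape <= 0)) {
    stop("equation ", eq$id, ": weibull form requires a positive shape",
         call. = FALSE)
  }
  bad <- setdiff(names(eq$coefs), covariate_names())
  if (length(bad) > 0) {
    stop("equation ", eq$id, ": unknown covariate(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(eq)
}

# ---- validation ---------------------------------------------------------

fail <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE) {
  if (is.null(x)) fail("missing field: ", name)
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    fail("field ", name, " must be a single finite number")
  }
  if (x < lower || x > upper) {
    fail("field ", name, " = ", x, " outside [", lower, ", ", upper, "]")
  }
  if (integer && x != round(x)) fail("field ", name, " must be an integer")
  invisible(x)
}

check_field_set <- function(x, required, optional = character(0), where) {
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    fail(where, ": missing field(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(x), c(required, optional))
  if (length(extra) > 0) {
    fail(where, ": unknown field(s): ", paste(extra, collapse = ", "))
  }
  invisible(x)
}

validate_strategy <- function(s, where) {
  check_field_set(s, strategy_field_names(), where = where)
  check_scalar(s$hba1c_on_treatment, paste0(where, ".hba1c_on_treatment"), 3, 20)
  check_scalar(s$bmi_on_treatment, paste0(where, ".bmi_on_treatment"), 10, 80)
  check_scalar(s$sbp_on_treatment, paste0(where, ".sbp_on_treatment"), 60, 260)
  check_scalar(s$dbp_on_treatment, paste0(where, ".dbp_on_treatment"), 30, 160)
  check_scalar(s$hypo_nonsevere_rate, paste0(where, ".hypo_nonsevere_rate"), 0)
  check_scalar(s$hypo_severe_rate, paste0(where, ".hypo_severe_rate"), 0)
  if (is.numeric(s$drug_cost_daily)) {
    check_scalar(s$drug_cost_daily, paste0(where, ".drug_cost_daily"), 0)
  } else {
    for (nm in names(s$drug_cost_daily)) {
      check_scalar(s$drug_cost_daily[[nm]],
                   paste0(where, ".drug_cost_daily.", nm), 0)
    }
  }
  check_scalar(s$needle_cost_daily, paste0(where, ".needle_cost_daily"), 0)
  check_scalar(s$smbg_cost_daily, paste0(where, ".smbg_cost_daily"), 0)
  check_scalar(s$injections_per_day, paste0(where, ".injections_per_day"),
               0, 20, integer = TRUE)
  invisible(s)
}

#' Validate a model configuration
#'
#' Structural and semantic validation: exact field sets (unknown keys are
#' errors), numeric ranges, and cross-references (transitions to known states,
#' equations that exist, a cost entry for every complication state, a utility
#' decrement -- possibly an explicit zero -- for every costed state).
#'
#' @param config Parsed configuration list.
#' @param equations Parsed risk-equation list (defaults to the attribute
#'   attached by [load_model_config()]).
#' @return `config`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_model_config <- function(config, equations = attr(config, "equations")) {
  required <- setdiff(config_top_level_keys(), "risk_equations")
  check_field_set(config, required, optional = "risk_equations",
                  where = "config")

  co <- config$cohort
  check_field_set(co, cohort_field_names(), where = "cohort")
  for (nm in cohort_field_names()) {
    check_scalar(co[[nm]], paste0("cohort.", nm), lower = 0)
  }
  check_scalar(co$prop_female, "cohort.prop_female", 0, 1)
  check_scalar(co$prop_smoker, "cohort.prop_smoker", 0, 1)

  validate_strategy(config$arm_intervention, "arm_intervention")
  validate_strategy(config$arm_comparator, "arm_comparator")
  check_field_set(config$switch_rule,
                  c("hba1c_threshold_pct", "post_switch_strategy"),
                  where = "switch_rule")
  check_scalar(config$switch_rule$hba1c_threshold_pct,
               "switch_rule.hba1c_threshold_pct", lower = 1e-9)
  validate_strategy(config$switch_rule$post_switch_strategy,
                    "switch_rule.post_switch_strategy")
  check_scalar(config$hba1c_drift_per_year, "hba1c_drift_per_year", 0, 2)

  ec <- config$econ
  check_field_set(ec, c("horizon_years", "discount_rate_cost",
                        "discount_rate_qaly", "wtp_threshold", "days_per_year",
                        "discount_from_cycle", "half_cycle_correction"),
                  where = "econ")
  check_scalar(ec$horizon_years, "econ.horizon_years", 1, 40, integer = TRUE)
  check_scalar(ec$discount_rate_cost, "econ.discount_rate_cost", 0, 0.2)
  check_scalar(ec$discount_rate_qaly, "econ.discount_rate_qaly", 0, 0.2)
  check_scalar(ec$wtp_threshold, "econ.wtp_threshold", lower = 1e-9)
  check_scalar(ec$days_per_year, "econ.days_per_year", 1, 366.25)
  check_scalar(ec$discount_from_cycle, "econ.discount_from_cycle", 0, 1,
               integer = TRUE)
  if (!is.logical(ec$half_cycle_correction)) {
    fail("field econ.half_cycle_correction must be logical")
  }
  if (co$age_years + ec$horizon_years > 120) {
    fail("cohort.age_years + econ.horizon_years exceeds 120")
  }

  # sub-model structure
  sms <- config$submodels
  ids <- vapply(sms, function(s) s$submodel_id, character(1))
  if (anyDuplicated(ids)) fail("duplicate submodel_id")
  if (sum(ids == "mortality") != 1) {
    fail("exactly one 'mortality' sub-model is required")
  }
  all_states <- character(0)
  for (sm in sms) {
    check_field_set(sm, c("submodel_id", "states", "transitions"),
                    optional = c("history_covariate", "history_states"),
                    where = paste0("submodel ", sm$submodel_id))
    states <- unlist(sm$states)
    if (length(states) < 2 || anyDuplicated(states)) {
      fail("submodel ", sm$submodel_id, ": needs >= 2 unique states")
    }
    if (any(states %in% all_states)) {
      fail("state id reused across sub-models: ",
           paste(intersect(states, all_states), collapse = ", "))
    }
    all_states <- c(all_states, states)
    for (tr in sm$transitions) {
      if (!all(c(tr$from, tr$to) %in% states)) {
        fail("submodel ", sm$submodel_id, ": transition references unknown ",
             "state: ", tr$from, " -> ", tr$to)
      }
      if (identical(tr$from, tr$to)) {
        fail("submodel ", sm$submodel_id, ": explicit self-transition; the ",
             "stay probability is implicit")
      }
      if (!tr$equation %in% c(names(equations), reserved_equation_ids())) {
        fail("submodel ", sm$submodel_id, ": unknown equation '",
             tr$equation, "'")
      }
    }
    if (!is.null(sm$history_covariate)) {
      if (!sm$history_covariate %in% covariate_names()) {
        fail("submodel ", sm$submodel_id, ": unknown history covariate '",
             sm$history_covariate, "'")
      }
      if (!all(unlist(sm$history_states) %in% states)) {
        fail("submodel ", sm$submodel_id, ": history_states not a subset of ",
             "states")
      }
    }
  }

  for (nm in names(config$case_fatality)) {
    if (!nm %in% all_states) {
      fail("case_fatality: unknown state '", nm, "'")
    }
    check_scalar(config$case_fatality[[nm]], paste0("case_fatality.", nm), 0, 1)
  }

  # costs: keys known; every complication state costed; decrement coverage
  costs <- config$costs
  known_cost_keys <- c(all_states, cost_special_keys())
  for (nm in names(costs)) {
    if (!nm %in% known_cost_keys) fail("costs: unknown state '", nm, "'")
    check_field_set(costs[[nm]], c("event_cost", "state_cost"),
                    where = paste0("costs.", nm))
    check_scalar(costs[[nm]]$event_cost, paste0("costs.", nm, ".event_cost"), 0)
    check_scalar(costs[[nm]]$state_cost, paste0("costs.", nm, ".state_cost"), 0)
  }
  for (sm in sms) {
    if (sm$submodel_id == "mortality") next
    for (st in unlist(sm$states)[-1]) {
      if (!st %in% names(costs)) {
        fail("costs: no entry for complication state '", st, "'")
      }
    }
  }

  ut <- config$utilities
  check_field_set(ut, c("baseline_utility", "state_decrements",
                        "demographic_decrements", "bmi_anchor",
                        "event_disutilities", "injection_disutilities"),
                  where = "utilities")
  check_scalar(ut$baseline_utility, "utilities.baseline_utility", 1e-9, 1)
  for (nm in names(ut$state_decrements)) {
    if (!nm %in% all_states) {
      fail("utilities.state_decrements: unknown state '", nm, "'")
    }
    check_scalar(ut$state_decrements[[nm]],
                 paste0("utilities.state_decrements.", nm), upper = 0)
  }
  for (nm in setdiff(names(costs), cost_special_keys())) {
    if (!nm %in% names(ut$state_decrements)) {
      fail("utilities.state_decrements: no entry (not even an explicit zero) ",
           "for costed state '", nm, "'")
    }
  }
  check_field_set(ut$demographic_decrements,
                  c("age_per_10y", "female", "duration_per_10y",
                    "bmi_per_unit"),
                  where = "utilities.demographic_decrements")
  for (nm in names(ut$demographic_decrements)) {
    check_scalar(ut$demographic_decrements[[nm]],
                 paste0("utilities.demographic_decrements.", nm), upper = 0)
  }
  check_field_set(ut$event_disutilities, c("hypo_nonsevere", "hypo_severe"),
                  where = "utilities.event_disutilities")
  for (strat in list(config$arm_intervention, config$arm_comparator,
                     config$switch_rule$post_switch_strategy)) {
    key <- as.character(strat$injections_per_day)
    if (!key %in% names(ut$injection_disutilities)) {
      fail("utilities.injection_disutilities: no entry for ", key,
           " injections/day (used by strategy '", strat$name, "')")
    }
  }
  check_scalar(ut$bmi_anchor, "utilities.bmi_anchor", 10, 80)

  unc <- config$uncertainty
  check_field_set(unc, c("cost_se_fraction", "utility_se", "efficacy"),
                  where = "uncertainty")
  check_scalar(unc$cost_se_fraction, "uncertainty.cost_se_fraction", 0, 1)

  invisible(config)
}

# ---- generic path access (used by OWSA / PSA / perturbation) ------------

#' Read a numeric parameter from a configuration by dotted path
#'
#' @param config A `cea_config`.
#' @param path Dotted path, e.g. `"costs.esrd.event_cost"` or
#'   `"utilities.baseline_utility"`.
#' @return The numeric value at the path.
#' @export
config_get_path <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    if (is.null(node[[k]])) stop("no such config path: ", path, call. = FALSE)
    node <- node[[k]]
  }
  if (!is.numeric(node)) stop("config path is not numeric: ", path,
                              call. = FALSE)
  node
}

#' Set a numeric parameter in a configuration by dotted path
#'
#' Returns a modified copy; the risk-equation attribute is preserved, and the
#' result is re-validated.
#'
#' @inheritParams config_get_path
#' @param value Replacement value.
#' @param revalidate Re-run full validation (default `TRUE`).
#' @return Modified `cea_config`.
#' @export
config_set_path <- function(config, path, value, revalidate = TRUE) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  config_get_path(config, path)  # errors if absent / non-numeric
  config[[keys]] <- value
  if (revalidate) validate_model_config(config)
  config
}

# md5 of the canonical serialized document (run metadata / reproducibility)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.cea_config <- function(x, ...) {
  n_states <- sum(vapply(x$submodels, function(s) length(s$states), integer(1)))
  cat("<cea_config> ", x$arm_intervention$name, " vs ",
      x$arm_comparator$name, "\n", sep = "")
  cat("  horizon: ", x$econ$horizon_years, " years, discount ",
      x$econ$discount_rate_cost * 100, "% / ",
      x$econ$discount_rate_qaly * 100, "%\n", sep = "")
  cat("  sub-models: ", length(x$submodels), " (", n_states, " states), ",
      length(attr(x, "equations")), " risk equations\n", sep = "")
  invisible(x)
}
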