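# Risk-factor trajectories and per-cycle event probabilities.
#
# Cycle length is one year. Covariates entering the equations are the
# start-of-cycle values; age and diabetes duration advance by exactly one
# year per cycle. Modifiable risk factors take the arm's on-treatment values
# until the switch cycle and the (shared) post-switch strategy's values
# thereafter, so any between-arm difference vanishes at the later of the two
# switch cycles.

#' Risk-factor path under a treatment strategy and switch rule
#'
#' HbA1c starts at the strategy's on-treatment value and drifts upward
#' linearly; the first cycle whose start-of-cycle HbA1c exceeds the switch
#' threshold is the switch cycle, from which point every field (HbA1c, BMI,
#' blood pressure, hypoglycemia rates, injections, daily costs) takes the
#' post-switch strategy's values. After the switch HbA1c is held at the
#' post-switch value: the model has a single treatment line beyond the
#' intensification.
#'
#' @param strategy Strategy sub-list (see `arm_intervention` in a config).
#' @param drift HbA1c drift, percentage points per year (>= 0).
#' @param rule `switch_rule` sub-list of a config.
#' @param horizon Number of annual cycles (>= 1).
#' @return A data.frame with one row per cycle (`cycle` = 0-based index) and
#'   columns `hba1c`, `bmi`, `sbp`, `dbp`, `hypo_nonsevere_rate`,
#'   `hypo_severe_rate`, `injections_per_day`, `daily_treatment_cost`,
#'   `treatment`; the switch cycle (or `NA` if never crossed) is in
#'   `attr(, "switch_cycle")`.
#' @export
hba1c_trajectory <- function(strategy, drift, rule, horizon) {
  stopifnot(horizon >= 1, drift >= 0)
  cycles <- seq_len(horizon) - 1L
  hba1c_pre <- strategy$hba1c_on_treatment + drift * cycles
  crossed <- hba1c_pre > rule$hba1c_threshold_pct
  switch_cycle <- if (any(crossed)) cycles[which(crossed)[1]] else NA_integer_

  post <- rule$post_switch_strategy
  on_post <- !is.na(switch_cycle) & cycles >= switch_cycle

  field <- function(pre_value, post_value) {
    ifelse(on_post, post_value, pre_value)
  }
  path <- data.frame(
    cycle = cycles,
    hba1c = field(hba1c_pre, post$hba1c_on_treatment),
    bmi = field(strategy$bmi_on_treatment, post$bmi_on_treatment),
    sbp = field(strategy$sbp_on_treatment, post$sbp_on_treatment),
    dbp = field(strategy$dbp_on_treatment, post$dbp_on_treatment),
    hypo_nonsevere_rate = field(strategy$hypo_nonsevere_rate,
                                post$hypo_nonsevere_rate),
    hypo_severe_rate = field(strategy$hypo_severe_rate, post$hypo_severe_rate),
    injections_per_day = field(strategy$injections_per_day,
                               post$injections_per_day),
    daily_treatment_cost = field(strategy_daily_cost(strategy),
                                 strategy_daily_cost(post)),
    treatment = ifelse(on_post, post$name, strategy$name),
    stringsAsFactors = FALSE
  )
  attr(path, "switch_cycle") <- switch_cycle
  path
}

#' Baseline covariate vector from a cohort profile
#'
#' Event-history prevalences start at zero. Modifiable risk factors are
#' immediately replaced by the arm's on-treatment values when a path is
#' applied (cycle 0 of [update_covariates()]).
#'
#' @param cohort `cohort` sub-list of a config.
#' @return Named numeric vector over [covariate_names()].
#' @export
baseline_covariates <- function(cohort) {
  cov <- c(
    age = cohort$age_years,
    female = cohort$prop_female,
    smoker = cohort$prop_smoker,
    duration = cohort$duration_years,
    hba1c = cohort$hba1c_pct,
    sbp = cohort$sbp_mmHg,
    dbp = cohort$dbp_mmHg,
    tc = cohort$tc_mmol,
    ldl = cohort$ldl_mmol,
    hdl = cohort$hdl_mmol,
    tg = cohort$tg_mmol,
    bmi = cohort$bmi,
    heart_rate = cohort$heart_rate_bpm,
    wbc = cohort$wbc,
    egfr = cohort$egfr,
    hist_mi = 0, hist_stroke = 0, hist_ihd = 0, hist_hf = 0,
    hist_amp = 0, hist_esrd = 0
  )
  cov[covariate_names()]
}

#' Advance a covariate vector by one cycle
#'
#' Age and duration increase by one year; modifiable risk factors are replaced
#' by the path's values at `cycle`; event-history prevalences are merged
#' monotonically (history can only accumulate).
#'
#' @param cov Named covariate vector.
#' @param path A risk-factor path from [hba1c_trajectory()].
#' @param cycle 0-based cycle index whose path values to apply; the engine
#'   calls this with the index of the cycle being entered.
#' @param histories Optional named vector of updated history prevalences.
#' @return Updated covariate vector.
#' @export
update_covariates <- function(cov, path, cycle, histories = NULL) {
  if (cycle > max(path$cycle)) stop("cycle beyond path horizon", call. = FALSE)
  cov["age"] <- cov["age"] + 1
  cov["duration"] <- cov["duration"] + 1
  row <- path[path$cycle == cycle, ]
  cov["hba1c"] <- row$hba1c
  cov["bmi"] <- row$bmi
  cov["sbp"] <- row$sbp
  cov["dbp"] <- row$dbp
  if (!is.null(histories)) {
    for (nm in names(histories)) {
      cov[nm] <- max(cov[nm], histories[[nm]])  # once acquired, never lost
    }
  }
  cov
}

#' Annual event probability from a risk equation
#'
#' Functional forms:
#' \describe{
#'   \item{constant}{rate given directly by the intercept;
#'     p = 1 - exp(-rate).}
#'   \item{exponential}{proportional-hazards with constant hazard
#'     h = exp(lp); p = 1 - exp(-h).}
#'   \item{weibull}{proportional-hazards with duration-dependent cumulative
#'     hazard; the cycle increment is
#'     exp(lp) * ((d+1)^shape - d^shape) with d = diabetes duration.}
#'   \item{logistic}{p = plogis(lp).}
#' }
#' where lp = intercept + sum over coefficients of beta * (x - center).
#'
#' @param eq One equation spec (an element of `attr(config, "equations")`).
#' @param cov Named covariate vector.
#' @return Probability in \[0, 1\].
#' @export
annual_event_probability <- function(eq, cov) {
  lp <- eq$intercept
  if (length(eq$coefs) > 0) {
    missing <- setdiff(names(eq$coefs), names(cov))
    if (length(missing) > 0) {
      stop("equation ", eq$id, ": missing covariate(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    x <- cov[names(eq$coefs)]
    centers <- rep(0, length(eq$coefs))
    names(centers) <- names(eq$coefs)
    centers[names(eq$centers)] <- eq$centers
    lp <- lp + sum(eq$coefs * (x - centers))
  }
  p <- switch(eq$form,
    constant = {
      if (eq$intercept < 0) stop("equation ", eq$id,
                                 ": constant form needs rate >= 0",
                                 call. = FALSE)
      1 - exp(-eq$intercept)
    },
    exponential = 1 - exp(-exp(lp)),
    weibull = {
      d <- max(cov[["duration"]], 0)
      1 - exp(-exp(lp) * ((d + 1)^eq$shape - d^eq$shape))
    },
    logistic = stats::plogis(lp),
    stop("unknown equation form: ", eq$form, call. = FALSE)
  )
  min(max(p, 0), 1)
}
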