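# Deterministic (one-way) and probabilistic sensitivity analysis.
#
# PSA follows the conventional second-order Monte Carlo design: parameters
# are drawn independently from distributions matched to published means and
# standard errors (beta for the baseline utility, gamma for costs, normal for
# utility decrements and treatment effects), both arms are run
# deterministically per draw, and the paired (dCost, dQALY) sample feeds the
# CEAC. Drug acquisition prices are administered (reimbursement /
# procurement) prices and are therefore fixed in PSA; they are varied in the
# one-way analysis instead.

#' Beta shape parameters from mean and standard error
#'
#' Method of moments: nu = mean(1-mean)/se^2 - 1, alpha = mean * nu,
#' beta = (1-mean) * nu.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error with se^2 < mean(1-mean).
#' @return Named vector `c(alpha, beta)`.
#' @export
beta_from_moments <- function(mean, se) {
  if (mean <= 0 || mean >= 1) {
    stop("beta_from_moments: mean must be in (0,1)", call. = FALSE)
  }
  if (se <= 0 || se^2 >= mean * (1 - mean)) {
    stop("beta_from_moments: infeasible moments (need 0 < se^2 < mean(1-mean))",
         call. = FALSE)
  }
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Gamma shape and scale from mean and standard error
#'
#' shape = mean^2/se^2, scale = se^2/mean; shape * scale = mean exactly.
#'
#' @param mean Positive mean.
#' @param se Positive standard error.
#' @return Named vector `c(shape, scale)`.
#' @export
gamma_from_moments <- function(mean, se) {
  if (mean <= 0 || se <= 0) {
    stop("gamma_from_moments: mean and se must be positive", call. = FALSE)
  }
  c(shape = mean^2 / se^2, scale = se^2 / mean)
}

#' Default PSA parameter distributions for a configuration
#'
#' Baseline utility: beta. Complication costs (nonzero means): gamma with
#' se = `uncertainty$cost_se_fraction` x mean. Utility decrements (state,
#' demographic, event, injection): normal with the published SEs, truncated
#' at 0 from above on sampling. Treatment effects: normal on the intervention
#' arm's on-treatment HbA1c and SBP (SE from the published 95\% CIs,
#' sd = width/3.92) and on the hypoglycemia rate ratio (applied
#' multiplicatively to the comparator rate).
#'
#' @param config A `cea_config`.
#' @return data.frame with columns `path`, `family`, `mean`, `se`, sorted by
#'   path (the fixed draw order).
#' @export
default_psa_distributions <- function(config) {
  unc <- config$uncertainty
  use <- unc$utility_se
  rows <- list()
  add <- function(path, family, mean, se) {
    rows[[length(rows) + 1]] <<- data.frame(
      path = path, family = family, mean = mean, se = se,
      stringsAsFactors = FALSE)
  }

  add("utilities.baseline_utility", "beta",
      config$utilities$baseline_utility, use$baseline_utility)

  for (nm in names(config$utilities$state_decrements)) {
    m <- config$utilities$state_decrements[[nm]]
    if (m < 0 && !is.null(use[[nm]])) {
      add(paste0("utilities.state_decrements.", nm), "normal", m, use[[nm]])
    }
  }
  for (nm in names(config$utilities$demographic_decrements)) {
    if (!is.null(use[[nm]])) {
      add(paste0("utilities.demographic_decrements.", nm), "normal",
          config$utilities$demographic_decrements[[nm]], use[[nm]])
    }
  }
  for (nm in names(config$utilities$event_disutilities)) {
    if (!is.null(use[[nm]])) {
      add(paste0("utilities.event_disutilities.", nm), "normal",
          config$utilities$event_disutilities[[nm]], use[[nm]])
    }
  }

  frac <- unc$cost_se_fraction
  for (nm in names(config$costs)) {
    for (fld in c("event_cost", "state_cost")) {
      m <- config$costs[[nm]][[fld]]
      if (m > 0 && frac > 0) {
        add(paste0("costs.", nm, ".", fld), "gamma", m, frac * m)
      }
    }
  }

  eff <- unc$efficacy
  add("arm_intervention.hba1c_on_treatment", "normal",
      eff$hba1c_intervention$mean, eff$hba1c_intervention$se)
  add("arm_intervention.sbp_on_treatment", "normal",
      eff$sbp_intervention$mean, eff$sbp_intervention$se)
  add("efficacy.hypo_rr", "normal", eff$hypo_rr$mean, eff$hypo_rr$se)

  out <- do.call(rbind, rows)
  out[order(out$path), , drop = FALSE]
}

# draw one value from a distribution row (uses the current RNG stream)
draw_param <- function(family, mean, se) {
  switch(family,
    fixed = mean,
    beta = {
      sh <- beta_from_moments(mean, se)
      stats::rbeta(1, sh["alpha"], sh["beta"])
    },
    gamma = {
      sh <- gamma_from_moments(mean, se)
      stats::rgamma(1, shape = sh["shape"], scale = sh["scale"])
    },
    normal = stats::rnorm(1, mean, se),
    stop("unknown distribution family: ", family, call. = FALSE)
  )
}

# apply one sampled parameter to a config; handles the derived-parameter
# paths that do not map 1:1 onto a document field
apply_psa_param <- function(config, path, value) {
  if (path == "efficacy.hypo_rr") {
    rr <- max(value, 0)
    return(config_set_path(
      config, "arm_intervention.hypo_nonsevere_rate",
      config$arm_comparator$hypo_nonsevere_rate * rr, revalidate = FALSE))
  }
  if (grepl("decrement|disutilit", path)) value <- min(value, 0)
  if (grepl("^costs\\.", path)) value <- max(value, 0)
  config_set_path(config, path, value, revalidate = FALSE)
}

#' Second-order Monte Carlo probabilistic sensitivity analysis
#'
#' For each draw, every parameter is sampled independently (in fixed
#' sorted-path order from a single seeded generator), both arms are run
#' deterministically, and the discounted (dCost, dQALY) pair is recorded.
#' Bit-reproducible under a fixed seed.
#'
#' @param config A `cea_config`.
#' @param distributions data.frame as from [default_psa_distributions()].
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @return A `cea_psa` object: `draws` (data.frame with `draw`, `d_cost`,
#'   `d_qaly`), the per-draw parameter matrix, the seed and the
#'   distributions used.
#' @export
run_psa <- function(config, distributions = default_psa_distributions(config),
                    n = 1000, seed = 1) {
  stopifnot(n >= 1)
  distributions <- distributions[order(distributions$path), , drop = FALSE]
  # pre-flight feasibility before any simulation
  for (i in seq_len(nrow(distributions))) {
    d <- distributions[i, ]
    if (d$family == "beta") beta_from_moments(d$mean, d$se)
    if (d$family == "gamma") gamma_from_moments(d$mean, d$se)
    if (!d$family %in% c("beta", "gamma", "normal", "fixed")) {
      stop("unknown distribution family: ", d$family, call. = FALSE)
    }
  }
  set.seed(seed)
  npar <- nrow(distributions)
  params <- matrix(NA_real_, n, npar,
                   dimnames = list(NULL, distributions$path))
  d_cost <- d_qaly <- numeric(n)
  for (k in seq_len(n)) {
    cfg <- config
    for (i in seq_len(npar)) {
      v <- draw_param(distributions$family[i], distributions$mean[i],
                      distributions$se[i])
      params[k, i] <- v
      cfg <- apply_psa_param(cfg, distributions$path[i], v)
    }
    ce <- run_ce(cfg)$result
    d_cost[k] <- ce$d_cost
    d_qaly[k] <- ce$d_qaly
  }
  structure(list(
    draws = data.frame(draw = seq_len(n), d_cost = d_cost, d_qaly = d_qaly),
    params = params, seed = seed, n = n, distributions = distributions,
    wtp = config$econ$wtp_threshold
  ), class = "cea_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' P(lambda) = fraction of PSA draws with positive net monetary benefit
#' lambda x dQALY - dCost at willingness-to-pay lambda.
#'
#' @param draws A `cea_psa` object (or a data.frame with `d_cost`, `d_qaly`).
#' @param thresholds Willingness-to-pay grid; defaults to 0 to 3x the
#'   config's WTP in 61 steps.
#' @return data.frame with `threshold` and `probability`.
#' @export
ceac <- function(draws, thresholds = NULL) {
  df <- if (inherits(draws, "cea_psa")) draws$draws else draws
  if (is.null(df) || nrow(df) == 0) stop("empty PSA draws", call. = FALSE)
  if (is.null(thresholds)) {
    wtp <- if (inherits(draws, "cea_psa")) draws$wtp else 85698
    thresholds <- seq(0, 3 * wtp, length.out = 61)
  }
  prob <- vapply(thresholds, function(l) {
    mean(l * df$d_qaly - df$d_cost > 0)
  }, numeric(1))
  data.frame(threshold = thresholds, probability = prob)
}

#' Default one-way sensitivity ranges
#'
#' Discount rates are floated from 0\% to 8\%; every other selected parameter
#' (treatment prices, complication costs, utilities, efficacy values, HbA1c
#' drift) is floated to 0.9x and 1.1x its base value.
#'
#' @param config A `cea_config`.
#' @return data.frame with `path`, `low`, `high`.
#' @export
default_owsa_ranges <- function(config) {
  rows <- list()
  add <- function(path, low, high) {
    rows[[length(rows) + 1]] <<- data.frame(path = path, low = low,
                                            high = high,
                                            stringsAsFactors = FALSE)
  }
  add("econ.discount_rate_cost", 0, 0.08)
  add("econ.discount_rate_qaly", 0, 0.08)
  pm10 <- function(path) {
    v <- config_get_path(config, path)
    add(path, 0.9 * v, 1.1 * v)
  }
  for (arm in c("arm_intervention", "arm_comparator",
                "switch_rule.post_switch_strategy")) {
    strat <- config_get_path_node(config, arm)
    for (comp in names(strat$drug_cost_daily)) {
      pm10(paste0(arm, ".drug_cost_daily.", comp))
    }
    pm10(paste0(arm, ".needle_cost_daily"))
    pm10(paste0(arm, ".smbg_cost_daily"))
    pm10(paste0(arm, ".hypo_nonsevere_rate"))
    if (strat$hypo_severe_rate > 0) pm10(paste0(arm, ".hypo_severe_rate"))
  }
  pm10("arm_intervention.hba1c_on_treatment")
  pm10("arm_intervention.sbp_on_treatment")
  pm10("hba1c_drift_per_year")
  pm10("utilities.baseline_utility")
  for (nm in names(config$utilities$state_decrements)) {
    if (config$utilities$state_decrements[[nm]] < 0) {
      pm10(paste0("utilities.state_decrements.", nm))
    }
  }
  for (nm in names(config$costs)) {
    for (fld in c("event_cost", "state_cost")) {
      if (config$costs[[nm]][[fld]] > 0) pm10(paste0("costs.", nm, ".", fld))
    }
  }
  do.call(rbind, rows)
}

# non-numeric node access (internal)
config_get_path_node <- function(config, path) {
  node <- config
  for (k in strsplit(path, ".", fixed = TRUE)[[1]]) node <- node[[k]]
  node
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' One full deterministic model run per bound. The primary outcome metric is
#' incremental net monetary benefit at the configured willingness-to-pay
#' (the base case is dominant, so a raw ICER is ill-defined); the ICER is
#' also reported for bounds where it exists. A bound that yields an invalid
#' configuration is recorded as a failed entry, never silently dropped.
#'
#' @param config A `cea_config`.
#' @param ranges data.frame with `path`, `low`, `high`; defaults to
#'   [default_owsa_ranges()].
#' @return data.frame (one row per parameter) with bound values, NMB and
#'   ICER at each bound, bar `width` = |NMB(high) - NMB(low)|, and a
#'   `status` column; sorted by descending width.
#' @export
one_way_sensitivity <- function(config, ranges = default_owsa_ranges(config)) {
  if (is.null(ranges) || nrow(ranges) == 0) {
    stop("empty one-way sensitivity ranges", call. = FALSE)
  }
  eval_bound <- function(path, value) {
    tryCatch({
      cfg <- config_set_path(config, path, value, revalidate = TRUE)
      res <- run_ce(cfg)$result
      list(nmb = res$nmb, icer = res$icer, ok = TRUE)
    }, error = function(e) list(nmb = NA_real_, icer = NA_real_, ok = FALSE))
  }
  out <- lapply(seq_len(nrow(ranges)), function(i) {
    r <- ranges[i, ]
    lo <- eval_bound(r$path, r$low)
    hi <- eval_bound(r$path, r$high)
    data.frame(
      parameter = r$path, low = r$low, high = r$high,
      nmb_low = lo$nmb, nmb_high = hi$nmb,
      icer_low = lo$icer, icer_high = hi$icer,
      width = if (lo$ok && hi$ok) abs(hi$nmb - lo$nmb) else NA_real_,
      status = if (lo$ok && hi$ok) "ok" else "invalid_bound",
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  out <- out[order(out$width, decreasing = TRUE, na.last = TRUE), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.cea_psa <- function(x, ...) {
  q <- mean(x$draws$d_cost < 0 & x$draws$d_qaly > 0)
  cat("<cea_psa>", x$n, "draws, seed", x$seed, "\n")
  cat(sprintf("  mean dCost %.0f CNY, mean dQALY %.4f; %.1f%% dominant\n",
              mean(x$draws$d_cost), mean(x$draws$d_qaly), 100 * q))
  invisible(x)
}
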