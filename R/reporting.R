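# Report bundles and CSV emission mirroring the published output tables:
# cumulative incidence with relative risks, cost breakdown by category,
# base-case summary, tornado table, PSA scatter and CEAC data. CSV output
# uses UTF-8, '.' decimals and no thousands separators; the pretty printer
# adds thousands commas for reading only.

# state ids in published table order, with display labels
incidence_rows <- function(sim) {
  states <- unlist(sim$states, use.names = FALSE)
  states[!grepl("_none$|^eye_none$", states)]
}

#' Run the deterministic base case and assemble the report bundle
#'
#' @param config A `cea_config` or a path to a config file.
#' @return A `cea_report`: `incidence_table` (per-state cumulative incidence
#'   with a 2-decimal relative-risk column), `cost_table` (per-category
#'   discounted costs with increments), `base_case_table` (life expectancy,
#'   QALYs, grouped costs, verdict), the underlying `cea_result`, and run
#'   metadata (config hash, package version).
#' @export
run_base_case <- function(config) {
  if (is.character(config)) config <- load_model_config(config)
  ce <- run_ce(config)
  si <- ce$sim_intervention
  sc <- ce$sim_comparator

  states <- incidence_rows(si)
  inc <- data.frame(
    state = c("cumulative_mortality", "cv_mortality", states),
    submodel = c("mortality", "mortality",
                 unname(si$submodel_of[states])),
    intervention = c(si$cum_mortality, si$cum_cv_mortality,
                     unname(si$cum_incidence[states])),
    comparator = c(sc$cum_mortality, sc$cum_cv_mortality,
                   unname(sc$cum_incidence[states])),
    stringsAsFactors = FALSE
  )
  inc$relative_risk <- ifelse(
    inc$comparator > 0,
    round(inc$intervention / inc$comparator, 2), NA_real_)

  li <- ce$ledger_intervention
  lc <- ce$ledger_comparator
  cats <- colnames(li$categories_disc)
  cost <- data.frame(
    category = c(cats, "total"),
    intervention = c(colSums(li$categories_disc), sum(li$total_cost_disc)),
    comparator = c(colSums(lc$categories_disc), sum(lc$total_cost_disc)),
    stringsAsFactors = FALSE
  )
  cost$increment <- cost$intervention - cost$comparator

  res <- ce$result
  grp <- function(s, catset) sum(s$cost_by_category[catset])
  micro <- c("eye", "lower_extremity", "renal")
  macro <- c("ihd", "mi", "stroke", "heart_failure")
  treat <- c("treatment", "background", "hypoglycemia")
  base <- data.frame(
    metric = c("life_expectancy_years", "qalys", "total_cost",
               "treatment_costs", "microvascular_costs",
               "macrovascular_costs", "icer"),
    intervention = c(res$intervention$life_years, res$intervention$qaly,
                     res$intervention$cost,
                     grp(res$intervention, treat),
                     grp(res$intervention, micro),
                     grp(res$intervention, macro), NA),
    comparator = c(res$comparator$life_years, res$comparator$qaly,
                   res$comparator$cost,
                   grp(res$comparator, treat),
                   grp(res$comparator, micro),
                   grp(res$comparator, macro), NA),
    stringsAsFactors = FALSE
  )
  base$increment <- base$intervention - base$comparator
  base$note <- ""
  base$note[base$metric == "icer"] <-
    if (res$verdict == "icer") sprintf("%.0f", res$icer) else res$verdict

  structure(list(
    incidence_table = inc, cost_table = cost, base_case_table = base,
    result = res,
    metadata = list(config_hash = config_hash(config),
                    package_version = as.character(
                      utils::packageVersion("t2dcea")),
                    horizon = config$econ$horizon_years)
  ), class = "cea_report")
}

#' Write a report bundle as CSV files
#'
#' @param bundle A `cea_report`.
#' @param out_dir Output directory (created if needed).
#' @return Paths of the files written, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    incidence = file.path(out_dir, "incidence.csv"),
    costs = file.path(out_dir, "costs.csv"),
    base_case = file.path(out_dir, "base_case.csv"),
    metadata = file.path(out_dir, "metadata.json")
  )
  utils::write.csv(bundle$incidence_table, paths["incidence"],
                   row.names = FALSE)
  utils::write.csv(bundle$cost_table, paths["costs"], row.names = FALSE)
  utils::write.csv(bundle$base_case_table, paths["base_case"],
                   row.names = FALSE)
  writeLines(jsonlite::toJSON(bundle$metadata, auto_unbox = TRUE,
                              pretty = TRUE),
             paths["metadata"])
  invisible(paths)
}

#' One-way sensitivity analysis with CSV emission
#'
#' @param config A `cea_config` or config file path.
#' @param ranges Optional ranges data.frame (`path`, `low`, `high`); defaults
#'   to [default_owsa_ranges()]. May also be a path to a CSV file with those
#'   columns.
#' @param out Optional output CSV path.
#' @return The tornado data.frame (sorted by descending bar width).
#' @export
run_owsa <- function(config, ranges = NULL, out = NULL) {
  if (is.character(config)) config <- load_model_config(config)
  if (is.character(ranges)) {
    ranges <- utils::read.csv(ranges, stringsAsFactors = FALSE)
    if (nrow(ranges) == 0) stop("empty one-way sensitivity ranges",
                                call. = FALSE)
  }
  if (is.null(ranges)) ranges <- default_owsa_ranges(config)
  tor <- one_way_sensitivity(config, ranges)
  if (!is.null(out)) {
    dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(tor, out, row.names = FALSE)
  }
  tor
}

#' Probabilistic sensitivity analysis with CSV emission
#'
#' Writes the (dQALY, dCost) scatter (one row per draw) and the CEAC grid.
#'
#' @param config A `cea_config` or config file path.
#' @param n Number of draws (>= 1).
#' @param seed Integer seed.
#' @param out_dir Optional output directory for `psa_scatter.csv` and
#'   `ceac.csv`.
#' @return A list with the `cea_psa` object and the CEAC data.frame.
#' @export
run_psa_cmd <- function(config, n = 1000, seed = 1, out_dir = NULL) {
  if (is.character(config)) config <- load_model_config(config)
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  psa <- run_psa(config, n = n, seed = seed)
  cc <- ceac(psa)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(
      data.frame(draw = psa$draws$draw, d_qaly = psa$draws$d_qaly,
                 d_cost = psa$draws$d_cost),
      file.path(out_dir, "psa_scatter.csv"), row.names = FALSE)
    utils::write.csv(cc, file.path(out_dir, "ceac.csv"), row.names = FALSE)
  }
  list(psa = psa, ceac = cc)
}

#' @export
print.cea_report <- function(x, ...) {
  fmt <- function(v) formatC(v, format = "f", digits = 0, big.mark = ",")
  cat("<cea_report> config", substr(x$metadata$config_hash, 1, 8),
      "| horizon", x$metadata$horizon, "years\n\n")
  b <- x$base_case_table
  for (i in seq_len(nrow(b))) {
    if (b$metric[i] == "icer") {
      cat(sprintf("  %-24s %s\n", "ICER (CNY/QALY)", b$note[i]))
    } else if (b$metric[i] %in% c("life_expectancy_years", "qalys")) {
      cat(sprintf("  %-24s %8.3f %8.3f  %+8.3f\n", b$metric[i],
                  b$intervention[i], b$comparator[i], b$increment[i]))
    } else {
      cat(sprintf("  %-24s %8s %8s  %8s\n", b$metric[i],
                  fmt(b$intervention[i]), fmt(b$comparator[i]),
                  fmt(b$increment[i])))
    }
  }
  invisible(x)
}
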