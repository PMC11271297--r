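# Model parameter store: a flat named value vector plus a distribution table,
# with settings (clock, discounting, thresholds) and epidemiology held separately.
# Accessors build the typed views (strategies, life table, cost schedules) that
# the engine consumes.

STRATEGY_IDS <- c("S1", "S2", "S3", "S4", "S5")

STRATEGY_LABELS <- c(
  S1 = "Neoadjuvant TC + adjuvant T (comparator)",
  S2 = "Neoadjuvant PTC + adjuvant T",
  S3 = "Neoadjuvant LTC + adjuvant T",
  S4 = "Neoadjuvant PTC + adjuvant PT",
  S5 = "Neoadjuvant LTC + adjuvant LT"
)

HEALTH_STATES <- c("EVENT_FREE", "LOCOREGIONAL", "METASTASIS", "REMISSION", "DEAD")

# Life-table age bands (years, lower edges; last band is open-ended 85+)
LIFETABLE_BANDS <- data.frame(
  age_low  = c(50, 55, 60, 65, 70, 75, 80, 85),
  age_high = c(55, 60, 65, 70, 75, 80, 85, Inf),
  name = c("mort_50_54", "mort_55_59", "mort_60_64", "mort_65_69",
           "mort_70_74", "mort_75_79", "mort_80_84", "mort_85_plus"),
  stringsAsFactors = FALSE
)

# one row per sampled (or fixed) model parameter
base_case_table <- function() {
  r <- function(name, mean, family, se = NA_real_,
                ci_low = NA_real_, ci_high = NA_real_, label = name) {
    data.frame(name = name, mean = mean, family = family, se = se,
               ci_low = ci_low, ci_high = ci_high, label = label,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # --- transition probabilities (per monthly cycle), Beta ---
    r("tp_ef_event_adjT_0_60", 0.01015, "BETA", 0.00102,
      label = "TP event-free to event, adjuvant-T regimens (months 0-60)"),
    r("tp_ef_event_s4_y1", 0.00118, "BETA", 0.00012,
      label = "TP event-free to event, S4 year 1"),
    r("tp_ef_event_s4_y2", 0.00229, "BETA", 0.00023,
      label = "TP event-free to event, S4 year 2"),
    r("tp_ef_event_s4_y3", 0.00220, "BETA", 0.00022,
      label = "TP event-free to event, S4 year 3"),
    r("tp_ef_event_s4_y4", 0.00220, "BETA", 0.00022,
      label = "TP event-free to event, S4 years 4-5"),
    r("tp_ef_event_s5_0_60", 0.00798, "BETA", 0.00080,
      label = "TP event-free to event, S5 (months 0-60)"),
    r("tp_ef_event_after_60", 0.01015, "BETA", 0.00102,
      label = "TP event-free to event, all regimens after month 60"),
    r("share_event_lrr", 0.25, "BETA", 0.02500,
      label = "Share of events that are locoregional recurrences"),
    r("share_event_met", 0.75, "BETA", 0.07500,
      label = "Share of events that are metastatic recurrences"),
    r("tp_lrr_met", 0.02317, "BETA", 0.00232,
      label = "TP locoregional recurrence to metastasis"),
    r("tp_lrr_death", 0.01064, "BETA", 0.00106,
      label = "TP locoregional recurrence to death"),
    r("tp_lrr_rem", 0.96619, "BETA", 0.09662,
      label = "TP locoregional recurrence to remission"),
    r("tp_rem_met", 0.0076, "BETA", 0.00076,
      label = "TP remission to metastasis"),
    r("mort_50_54", 0.00027, "BETA", 0.00003,
      label = "Background monthly mortality, ages 50-54"),
    r("mort_55_59", 0.00041, "BETA", 0.00004,
      label = "Background monthly mortality, ages 55-59"),
    r("mort_60_64", 0.00067, "BETA", 0.00007,
      label = "Background monthly mortality, ages 60-64"),
    r("mort_65_69", 0.00120, "BETA", 0.00012,
      label = "Background monthly mortality, ages 65-69"),
    r("mort_70_74", 0.00226, "BETA", 0.00023,
      label = "Background monthly mortality, ages 70-74"),
    r("mort_75_79", 0.00379, "BETA", 0.00038,
      label = "Background monthly mortality, ages 75-79"),
    r("mort_80_84", 0.00708, "BETA", 0.00071,
      label = "Background monthly mortality, ages 80-84"),
    r("mort_85_plus", 0.00708, "BETA", 0.00071,
      label = "Background monthly mortality, ages 85+"),
    r("tp_met_death", 0.04672, "BETA", 0.00467,
      label = "TP metastasis to death"),
    # --- efficacy hazard ratios vs comparator, LogNormal from 95% CI ---
    r("hr_s2", 0.54, "LOGNORMAL", ci_low = 0.32, ci_high = 0.91,
      label = "Hazard ratio S2 vs S1"),
    r("hr_s3", 0.85, "LOGNORMAL", ci_low = 0.60, ci_high = 1.22,
      label = "Hazard ratio S3 vs S1"),
    r("hr_s4", 0.54, "LOGNORMAL", ci_low = 0.32, ci_high = 0.91,
      label = "Hazard ratio S4 vs S1"),
    r("hr_s5", 0.85, "LOGNORMAL", ci_low = 0.60, ci_high = 1.22,
      label = "Hazard ratio S5 vs S1"),
    # --- utilities, Beta with table-specific SEs ---
    r("u_ef_y1", 0.81, "BETA", 0.0183, label = "Utility event free, year 1"),
    r("u_ef_after", 0.85, "BETA", 0.0102, label = "Utility event free, after year 1"),
    r("u_lrr", 0.72, "BETA", 0.0198, label = "Utility locoregional recurrence"),
    r("u_rem", 0.82, "BETA", 0.0174, label = "Utility remission"),
    r("u_met", 0.70, "BETA", 0.0266, label = "Utility metastasis"),
    # --- direct medical costs, LKR, Gamma (SE = 10% of mean) ---
    r("dmc_neoadj_s1", 403337.46, "GAMMA", 40333.75,
      label = "DMC neoadjuvant treatment, S1"),
    r("dmc_neoadj_s2", 2591980.99, "GAMMA", 259198.10,
      label = "DMC neoadjuvant treatment, S2"),
    r("dmc_neoadj_s3", 712164.10, "GAMMA", 71216.41,
      label = "DMC neoadjuvant treatment, S3"),
    r("dmc_neoadj_s4", 2591980.99, "GAMMA", 259198.10,
      label = "DMC neoadjuvant treatment, S4"),
    r("dmc_neoadj_s5", 712164.10, "GAMMA", 71216.41,
      label = "DMC neoadjuvant treatment, S5"),
    r("dmc_ef_y1_s1", 66740.23, "GAMMA", 6674.02,
      label = "DMC event free year 1 (monthly), S1"),
    r("dmc_ef_y1_s2", 66819.49, "GAMMA", 6681.95,
      label = "DMC event free year 1 (monthly), S2"),
    r("dmc_ef_y1_s3", 66740.23, "GAMMA", 6674.02,
      label = "DMC event free year 1 (monthly), S3"),
    r("dmc_ef_y1_s4", 576956.06, "GAMMA", 57695.61,
      label = "DMC event free year 1 (monthly), S4"),
    r("dmc_ef_y1_s5", 157203.06, "GAMMA", 15720.31,
      label = "DMC event free year 1 (monthly), S5"),
    r("dmc_ef_y2_5", 1097.03, "GAMMA", 109.70,
      label = "DMC event free years 2-5 (monthly)"),
    r("dmc_ef_y6_10", 876.94, "GAMMA", 87.69,
      label = "DMC event free years 6-10 (monthly)"),
    r("dmc_ef_after10", 404.15, "GAMMA", 40.42,
      label = "DMC event free after year 10 (monthly)"),
    r("dmc_lrr_y1", 307205.83, "GAMMA", 30720.58,
      label = "DMC locoregional recurrence year 1 (monthly)"),
    r("dmc_lrr_after", 263124.47, "GAMMA", 26312.44,
      label = "DMC locoregional recurrence year 2+ (monthly)"),
    r("dmc_rem_y1", 67429.98, "GAMMA", 6743.00,
      label = "DMC remission year 1 (monthly)"),
    r("dmc_rem_y2_5", 742.72, "GAMMA", 74.27,
      label = "DMC remission years 2-5 (monthly)"),
    r("dmc_rem_y6_10", 1137.50, "GAMMA", 113.75,
      label = "DMC remission years 6-10 (monthly)"),
    r("dmc_rem_after10", 664.71, "GAMMA", 66.47,
      label = "DMC remission after year 10 (monthly)"),
    r("dmc_met", 111356.35, "GAMMA", 11135.63,
      label = "DMC metastasis (monthly)"),
    # --- direct non-medical costs, LKR, Gamma ---
    r("dnmc_neoadj", 61575.58, "GAMMA", 6157.56,
      label = "DNMC neoadjuvant treatment"),
    r("dnmc_ef_y1", 9045.57, "GAMMA", 904.56,
      label = "DNMC event free year 1 (monthly)"),
    r("dnmc_ef_after", 1768.42, "GAMMA", 176.84,
      label = "DNMC event free year 2+ (monthly)"),
    r("dnmc_lrr", 103098.78, "GAMMA", 10309.88,
      label = "DNMC locoregional recurrence (monthly)"),
    r("dnmc_rem_y1", 6189.48, "GAMMA", 618.95,
      label = "DNMC remission year 1 (monthly)"),
    r("dnmc_rem_after", 1768.42, "GAMMA", 176.84,
      label = "DNMC remission year 2+ (monthly)"),
    r("dnmc_met", 9172.73, "GAMMA", 917.27,
      label = "DNMC metastasis (monthly)")
  ))
}

#' Base-case model parameter set
#'
#' Returns the complete packaged parameter set for the five-strategy
#' neoadjuvant/adjuvant HER2-targeted therapy comparison in Sri Lanka:
#' per-cycle transition probabilities, efficacy hazard ratios with 95% CIs,
#' state utilities, per-state direct medical (DMC) and non-medical (DNMC)
#' costs in 2021 LKR, the national female life table collapsed to 5-year
#' age bands, epidemiological counts for the budget impact analysis, and the
#' sampling-distribution specification for every uncertain parameter.
#'
#' @return An object of class `parameter_set` with elements
#'   \describe{
#'     \item{values}{named numeric vector of all parameter point values}
#'     \item{dists}{data frame of sampling distributions (`name`, `mean`,
#'       `family` in BETA/GAMMA/LOGNORMAL/FIXED, `se`, `ci_low`, `ci_high`,
#'       `label`)}
#'     \item{settings}{model clock and valuation settings: start age 50,
#'       horizon age 100, 1-month cycles, 3% annual discounting for costs and
#'       outcomes, willingness-to-pay LKR 758,680/QALY, 194.78 LKR/USD,
#'       efficacy effect capped at 144 months, efficacy composition mode}
#'     \item{epi}{epidemiology for budget impact: 13,647 prevalent and 4,447
#'       annual incident breast cancer cases, 66% early stage, 22% HER2+}
#'   }
#' @export
base_case_parameters <- function() {
  tab <- base_case_table()
  values <- stats::setNames(tab$mean, tab$name)
  ps <- structure(list(
    values = values,
    dists = tab[, c("name", "mean", "family", "se", "ci_low", "ci_high", "label")],
    settings = list(
      start_age_years = 50,
      horizon_age_years = 100,
      cycle_months = 1,
      discount_costs_annual = 0.03,
      discount_outcomes_annual = 0.03,
      wtp_lkr = 758680,
      lkr_per_usd = 194.78,
      effect_duration_months = 144,
      efficacy_mode = "hr_on_baseline",
      tunnel_cap_months = 121
    ),
    epi = list(
      prevalent_cases_5yr = 13647,
      annual_incident_cases = 4447,
      pct_early = 0.66,
      pct_her2_positive = 0.22
    )
  ), class = "parameter_set")
  validate_parameter_set(ps)
  ps
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set>\n")
  cat(sprintf("  %d parameters (%s)\n", length(x$values),
              paste(sprintf("%d %s", table(x$dists$family),
                            names(table(x$dists$family))), collapse = ", ")))
  cat(sprintf("  cohort: age %g to %g, %g-month cycles, discount %g%%/yr\n",
              x$settings$start_age_years, x$settings$horizon_age_years,
              x$settings$cycle_months, 100 * x$settings$discount_costs_annual))
  cat(sprintf("  WTP: LKR %s per QALY; efficacy mode '%s'\n",
              format(x$settings$wtp_lkr, big.mark = ","),
              x$settings$efficacy_mode))
  invisible(x)
}

required_parameter_names <- function() base_case_table()$name

#' Validate a parameter set
#'
#' Checks structural completeness and all model invariants: every required
#' parameter present, probabilities and utilities in \[0, 1\], costs
#' non-negative, event-split shares summing to 1, locoregional-recurrence
#' exit probabilities summing to at most 1, a contiguous non-decreasing life
#' table, horizon beyond start age, and a family-appropriate distribution
#' specification for each parameter. Errors name the offending key.
#'
#' @param ps a `parameter_set`
#' @return `ps` invisibly if valid; otherwise an error is thrown.
#' @export
validate_parameter_set <- function(ps) {
  if (!inherits(ps, "parameter_set"))
    stop("not a parameter_set object")
  v <- ps$values
  need <- required_parameter_names()
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop("missing parameter(s): ", paste(miss, collapse = ", "))

  s <- ps$settings
  for (key in c("start_age_years", "horizon_age_years", "cycle_months",
                "discount_costs_annual", "discount_outcomes_annual",
                "wtp_lkr", "lkr_per_usd", "effect_duration_months"))
    if (is.null(s[[key]]) || !is.finite(s[[key]]))
      stop("settings: ", key, " required")
  if (s$horizon_age_years <= s$start_age_years)
    stop("settings: horizon_age_years must exceed start_age_years")
  if (s$discount_costs_annual < 0 || s$discount_outcomes_annual < 0)
    stop("settings: discount rates must be >= 0")
  if (s$effect_duration_months <= 0)
    stop("settings: effect_duration_months must be > 0")
  if (!s$efficacy_mode %in% c("hr_on_baseline", "baseline_then_hr",
                              "hr_throughout", "trial_only"))
    stop("settings: unknown efficacy_mode '", s$efficacy_mode, "'")

  prob_names <- grep("^(tp_|share_|mort_)", need, value = TRUE)
  bad <- prob_names[v[prob_names] < 0 | v[prob_names] > 1]
  if (length(bad))
    stop("probability out of [0,1]: ", paste(bad, collapse = ", "))
  util_names <- grep("^u_", need, value = TRUE)
  bad <- util_names[v[util_names] < 0 | v[util_names] > 1]
  if (length(bad))
    stop("utility out of [0,1]: ", paste(bad, collapse = ", "))
  cost_names <- grep("^(dmc_|dnmc_)", need, value = TRUE)
  bad <- cost_names[v[cost_names] < 0]
  if (length(bad))
    stop("negative cost: ", paste(bad, collapse = ", "))
  hr_names <- grep("^hr_", need, value = TRUE)
  bad <- hr_names[v[hr_names] <= 0]
  if (length(bad))
    stop("hazard ratio must be > 0: ", paste(bad, collapse = ", "))

  if (abs(v[["share_event_lrr"]] + v[["share_event_met"]] - 1) > 1e-9)
    stop("share_event_lrr + share_event_met must equal 1")
  lrr_exit <- v[["tp_lrr_met"]] + v[["tp_lrr_death"]] + v[["tp_lrr_rem"]]
  if (lrr_exit > 1 + 1e-9)
    stop("tp_lrr_met + tp_lrr_death + tp_lrr_rem exceeds 1")

  mort <- v[LIFETABLE_BANDS$name]
  if (any(diff(mort) < -1e-12))
    stop("life_table: monthly death probabilities must be non-decreasing with age")

  if (is.null(ps$epi) || is.null(ps$epi$prevalent_cases_5yr))
    stop("life_table and epidemiology required: epi$prevalent_cases_5yr missing")
  ep <- ps$epi
  if (ep$prevalent_cases_5yr <= 0 || ep$annual_incident_cases <= 0)
    stop("epi: case counts must be > 0")
  if (ep$pct_early < 0 || ep$pct_early > 1 || ep$pct_her2_positive < 0 ||
      ep$pct_her2_positive > 1)
    stop("epi: percentages must lie in [0,1]")

  d <- ps$dists
  if (!all(need %in% d$name))
    stop("dists: missing distribution spec for ",
         paste(setdiff(need, d$name), collapse = ", "))
  for (i in seq_len(nrow(d))) {
    fam <- d$family[i]
    if (!fam %in% c("BETA", "GAMMA", "LOGNORMAL", "FIXED"))
      stop("dists: unknown family '", fam, "' for ", d$name[i])
    if (fam %in% c("BETA", "GAMMA") && (is.na(d$se[i]) || d$se[i] < 0))
      stop("dists: se required for ", d$name[i])
    if (fam == "BETA" && (d$mean[i] <= 0 || d$mean[i] >= 1))
      stop("dists: BETA mean must lie in (0,1) for ", d$name[i])
    if (fam == "GAMMA" && d$mean[i] <= 0)
      stop("dists: GAMMA mean must be > 0 for ", d$name[i])
    if (fam == "LOGNORMAL" && (is.na(d$ci_low[i]) || is.na(d$ci_high[i])))
      stop("dists: ci_low/ci_high required for ", d$name[i])
  }
  invisible(ps)
}

#' Strategy specification view
#'
#' Assembles the per-strategy slice of a parameter set: neoadjuvant lump-sum
#' costs, the strategy-specific event-free year-1 monthly DMC, the baseline
#' event transition schedule, and the efficacy hazard ratio (none for the
#' comparator S1).
#'
#' @param ps a `parameter_set`
#' @param id strategy id, one of `"S1"` to `"S5"`
#' @return list with fields `id`, `label`, `neoadjuvant_dmc`,
#'   `neoadjuvant_dnmc`, `ef_year1_monthly_dmc`, `hr` (NA for S1), `hr_ci`,
#'   `effect_duration_months`.
#' @export
strategy_spec <- function(ps, id) {
  id <- match.arg(id, STRATEGY_IDS)
  v <- ps$values
  low <- tolower(id)
  hr_name <- paste0("hr_", low)
  has_hr <- hr_name %in% names(v)
  d <- ps$dists
  list(
    id = id,
    label = STRATEGY_LABELS[[id]],
    neoadjuvant_dmc = unname(v[paste0("dmc_neoadj_", low)]),
    neoadjuvant_dnmc = unname(v["dnmc_neoadj"]),
    ef_year1_monthly_dmc = unname(v[paste0("dmc_ef_y1_", low)]),
    hr = if (has_hr) unname(v[hr_name]) else NA_real_,
    hr_ci = if (has_hr)
      c(d$ci_low[d$name == hr_name], d$ci_high[d$name == hr_name])
    else c(NA_real_, NA_real_),
    effect_duration_months = ps$settings$effect_duration_months
  )
}

#' Life table view
#'
#' @param ps a `parameter_set`
#' @return data frame with `age_low`, `age_high` (years) and
#'   `monthly_death_probability` for the eight age bands from the model start
#'   age to the open-ended 85+ band.
#' @export
life_table <- function(ps) {
  data.frame(
    age_low = LIFETABLE_BANDS$age_low,
    age_high = LIFETABLE_BANDS$age_high,
    monthly_death_probability = unname(ps$values[LIFETABLE_BANDS$name])
  )
}

#' Per-state cost schedule in long form
#'
#' Emits the cost schedule the engine applies for one strategy as a table
#' with one row per (state, clock piece): the clock is `MODEL_TIME` for the
#' event-free state, `TIME_IN_STATE` for locoregional recurrence and
#' remission, and a single open-ended piece for metastasis and death.
#'
#' @param ps a `parameter_set`
#' @param strategy strategy id `"S1"`..`"S5"`
#' @return data frame with columns `state`, `clock`, `start_month`,
#'   `end_month` (exclusive; `Inf` for open-ended), `monthly_dmc_lkr`,
#'   `monthly_dnmc_lkr`.
#' @export
cost_schedule_table <- function(ps, strategy) {
  strategy <- match.arg(strategy, STRATEGY_IDS)
  v <- ps$values
  ef_y1 <- unname(v[paste0("dmc_ef_y1_", tolower(strategy))])
  row <- function(state, clock, s, e, dmc, dnmc)
    data.frame(state = state, clock = clock, start_month = s, end_month = e,
               monthly_dmc_lkr = dmc, monthly_dnmc_lkr = dnmc,
               stringsAsFactors = FALSE)
  rbind(
    row("EVENT_FREE", "MODEL_TIME", 0, 12, ef_y1, v[["dnmc_ef_y1"]]),
    row("EVENT_FREE", "MODEL_TIME", 12, 60, v[["dmc_ef_y2_5"]], v[["dnmc_ef_after"]]),
    row("EVENT_FREE", "MODEL_TIME", 60, 120, v[["dmc_ef_y6_10"]], v[["dnmc_ef_after"]]),
    row("EVENT_FREE", "MODEL_TIME", 120, Inf, v[["dmc_ef_after10"]], v[["dnmc_ef_after"]]),
    row("LOCOREGIONAL", "TIME_IN_STATE", 0, 12, v[["dmc_lrr_y1"]], v[["dnmc_lrr"]]),
    row("LOCOREGIONAL", "TIME_IN_STATE", 12, Inf, v[["dmc_lrr_after"]], v[["dnmc_lrr"]]),
    row("REMISSION", "TIME_IN_STATE", 0, 12, v[["dmc_rem_y1"]], v[["dnmc_rem_y1"]]),
    row("REMISSION", "TIME_IN_STATE", 12, 60, v[["dmc_rem_y2_5"]], v[["dnmc_rem_after"]]),
    row("REMISSION", "TIME_IN_STATE", 60, 120, v[["dmc_rem_y6_10"]], v[["dnmc_rem_after"]]),
    row("REMISSION", "TIME_IN_STATE", 120, Inf, v[["dmc_rem_after10"]], v[["dnmc_rem_after"]]),
    row("METASTASIS", "MODEL_TIME", 0, Inf, v[["dmc_met"]], v[["dnmc_met"]]),
    row("DEAD", "MODEL_TIME", 0, Inf, 0, 0)
  )
}

#' Utility weights view
#'
#' @param ps a `parameter_set`
#' @return named list: `ef_year1`, `ef_after_year1`, `lrr`, `remission`,
#'   `metastasis`, `dead` (fixed 0).
#' @export
utility_set <- function(ps) {
  v <- ps$values
  list(ef_year1 = unname(v["u_ef_y1"]), ef_after_year1 = unname(v["u_ef_after"]),
       lrr = unname(v["u_lrr"]), remission = unname(v["u_rem"]),
       metastasis = unname(v["u_met"]), dead = 0)
}

# ---- sampling-distribution constructors (method of moments / CI width) ----

#' Beta parameters from a mean and standard error
#'
#' Method-of-moments construction: with \eqn{\nu = m(1-m)/se^2 - 1}, returns
#' \eqn{\alpha = m\nu} and \eqn{\beta = (1-m)\nu}, so the Beta's first two
#' moments match the inputs.
#'
#' @param mean mean in (0, 1)
#' @param se standard error; must satisfy `se^2 < mean * (1 - mean)`
#' @return named numeric vector `c(alpha, beta)`
#' @export
beta_from_mean_se <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop("beta_from_mean_se: mean must lie in (0,1)")
  if (!is.finite(se) || se <= 0)
    stop("beta_from_mean_se: se must be > 0")
  if (se^2 >= mean * (1 - mean))
    stop("beta_from_mean_se: se too large for a Beta (variance exceeds Bernoulli bound)")
  nu <- mean * (1 - mean) / se^2 - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Gamma parameters from a mean and standard error
#'
#' Method of moments: `shape = (mean/se)^2`, `scale = se^2/mean`.
#'
#' @param mean mean, > 0
#' @param se standard error, > 0
#' @return named numeric vector `c(shape, scale)`
#' @export
gamma_from_mean_se <- function(mean, se) {
  if (!is.finite(mean) || mean <= 0) stop("gamma_from_mean_se: mean must be > 0")
  if (!is.finite(se) || se <= 0) stop("gamma_from_mean_se: se must be > 0")
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Log-normal parameters from a point estimate and 95% CI
#'
#' `mu = log(point)`; `sigma` is the log-scale 95% CI width divided by
#' `2 * qnorm(0.975)`. Used for the efficacy hazard ratios, whose uncertainty
#' is reported as a 95% confidence interval.
#'
#' @param point point estimate, > 0
#' @param ci_low,ci_high 95% CI bounds, `0 < ci_low <= point <= ci_high`
#' @return named numeric vector `c(mu, sigma)`
#' @export
lognormal_from_ci <- function(point, ci_low, ci_high) {
  if (!all(is.finite(c(point, ci_low, ci_high))) || ci_low <= 0)
    stop("lognormal_from_ci: bounds must be positive")
  if (ci_low > point || point > ci_high)
    stop("lognormal_from_ci: require ci_low <= point <= ci_high")
  c(mu = log(point),
    sigma = (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975)))
}
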