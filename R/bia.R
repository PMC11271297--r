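# Budget impact analysis: five fiscal years, public healthcare system
# perspective, combining the eligible treated population with the engine's
# undiscounted per-cycle cost streams.

#' Treated patients per fiscal year
#'
#' Year 1 covers implementation for both prevalent and newly incident cases;
#' later years cover the new incident cohort only. The eligibility filter is
#' multiplicative: early-stage share, HER2-positive share, then programme
#' coverage. Fractional patient counts are retained.
#'
#' @param epi epidemiology list with `prevalent_cases_5yr`,
#'   `annual_incident_cases`, `pct_early`, `pct_her2_positive` (e.g.
#'   `base_case_parameters()$epi`)
#' @param coverage programme coverage fraction (the analysis uses 0.60 and
#'   0.20)
#' @param years number of fiscal years (default 5)
#' @return numeric vector of treated patients entering treatment in each
#'   fiscal year
#' @export
eligible_cohorts <- function(epi, coverage, years = 5) {
  if (coverage < 0 || coverage > 1)
    stop("eligible_cohorts: coverage must lie in [0,1]")
  filt <- epi$pct_early * epi$pct_her2_positive * coverage
  c((epi$prevalent_cases_5yr + epi$annual_incident_cases) * filt,
    rep(epi$annual_incident_cases * filt, years - 1))
}

#' Five-fiscal-year budget impact
#'
#' Each fiscal year's treated cohort contributes its undiscounted
#' public-perspective per-cycle cost stream from the cohort model, aligned to
#' its start year; the fiscal-year budget for a strategy is the sum over all
#' active cohorts of that year's 12-month slice. Reports, per strategy and
#' year, the budget, the incremental budget versus the comparator, and the
#' budget ratio, in LKR and USD.
#'
#' @param ps a `parameter_set`
#' @param epi epidemiology inputs (default `ps$epi`)
#' @param coverage programme coverage fraction
#' @param years number of fiscal years (default 5)
#' @param comparator comparator strategy id (default `"S1"`)
#' @return a `bia_result` data frame: `strategy`, `year`, `budget_lkr`,
#'   `budget_usd`, `incremental_lkr`, `incremental_usd`, `budget_ratio`
#' @export
run_bia <- function(ps, epi = ps$epi, coverage = 0.6, years = 5,
                    comparator = "S1") {
  if (years < 1) stop("run_bia: years must be >= 1")
  cohorts <- eligible_cohorts(epi, coverage, years)
  rate <- ps$settings$lkr_per_usd

  streams <- lapply(STRATEGY_IDS, function(s)
    evaluate_strategy(ps, s, "public")$per_cycle_cost_stream)
  names(streams) <- STRATEGY_IDS

  budget <- sapply(STRATEGY_IDS, function(s) {
    st <- streams[[s]]
    vapply(seq_len(years), function(y) {
      # cohorts started in years j = 1..y contribute months (y-j)*12+1 .. +12
      sum(vapply(seq_len(y), function(j) {
        idx <- ((y - j) * 12 + 1):((y - j) * 12 + 12)
        idx <- idx[idx <= length(st)]
        cohorts[j] * sum(st[idx])
      }, 0))
    }, 0)
  })
  budget <- matrix(budget, nrow = years,
                   dimnames = list(NULL, STRATEGY_IDS))

  out <- do.call(rbind, lapply(STRATEGY_IDS, function(s) {
    data.frame(strategy = s, year = seq_len(years),
               budget_lkr = budget[, s],
               budget_usd = to_usd(budget[, s], rate),
               incremental_lkr = budget[, s] - budget[, comparator],
               incremental_usd = to_usd(budget[, s] - budget[, comparator], rate),
               budget_ratio = budget[, s] / budget[, comparator],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "coverage") <- coverage
  class(out) <- c("bia_result", "data.frame")
  out
}
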