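# Report tables mirroring the published layouts, and CSV writers that embed
# the resolved parameter fingerprint so every output is traceable to its
# inputs.

#' Cost-effectiveness table (base-case layout)
#'
#' Full deterministic results for one perspective: totals, increments versus
#' the comparator, pairwise ICERs, and the sequential ICER from the
#' ascending-cost incremental analysis, dual-reported in LKR and USD.
#'
#' @param ps a `parameter_set`
#' @param perspective `"public"` or `"societal"`
#' @param comparator comparator strategy id (default `"S1"`)
#' @return data frame, one row per strategy in ascending cost order
#' @export
ce_table <- function(ps, perspective = c("public", "societal"),
                     comparator = "S1") {
  perspective <- match.arg(perspective)
  res <- evaluate_strategies(ps, perspective)
  inc <- incremental_analysis(res, wtp = ps$settings$wtp_lkr,
                              comparator = comparator)
  rate <- ps$settings$lkr_per_usd
  data.frame(
    strategy = inc$strategy,
    label = unname(STRATEGY_LABELS[inc$strategy]),
    perspective = perspective,
    total_ly = inc$ly,
    total_qaly = inc$qaly,
    total_cost_lkr = inc$cost,
    total_cost_usd = to_usd(inc$cost, rate),
    incr_cost_lkr = inc$cost - inc$cost[inc$strategy == comparator],
    incr_qaly = inc$qaly - inc$qaly[inc$strategy == comparator],
    icer_vs_comparator_lkr = inc$icer_vs_comparator,
    icer_vs_comparator_usd = to_usd(inc$icer_vs_comparator, rate),
    sequential_icer_lkr = inc$sequential_icer,
    sequential_icer_usd = to_usd(inc$sequential_icer, rate),
    dominance = inc$dominance,
    cost_effective = inc$cost_effective,
    stringsAsFactors = FALSE
  )
}

#' Budget impact table (fiscal-year layout)
#'
#' Pivots a [run_bia()] result to the published layout: incremental budgets
#' in LKR and USD millions and the budget ratio versus the comparator, one
#' row per strategy, one column per fiscal year.
#'
#' @param bia a `bia_result` from [run_bia()]
#' @return list of three data frames: `incremental_lkr_millions`,
#'   `incremental_usd_millions`, `budget_ratio`
#' @export
bia_table <- function(bia) {
  years <- sort(unique(bia$year))
  pivot <- function(col, scale = 1) {
    m <- sapply(years, function(y)
      bia[[col]][bia$year == y][match(STRATEGY_IDS,
                                      bia$strategy[bia$year == y])] / scale)
    out <- data.frame(strategy = STRATEGY_IDS, m, stringsAsFactors = FALSE)
    names(out) <- c("strategy", paste0("year", years))
    out
  }
  list(
    incremental_lkr_millions = pivot("incremental_lkr", 1e6),
    incremental_usd_millions = pivot("incremental_usd", 1e6),
    budget_ratio = pivot("budget_ratio")
  )
}

#' Write a report table as CSV with provenance header
#'
#' Writes the data frame with a leading comment line recording the resolved
#' parameter-set fingerprint (see [parameter_hash()]) and, optionally, the
#' seed, so the file is traceable to its inputs. Read back with
#' `read.csv(path, comment.char = "#")`.
#'
#' @param df data frame to write
#' @param path output path
#' @param ps the `parameter_set` the results were computed from
#' @param seed optional seed to record
#' @return `path`, invisibly
#' @export
write_report_csv <- function(df, path, ps, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# parameter_hash: %s%s", parameter_hash(ps),
                     if (is.null(seed)) "" else sprintf("; seed: %d", seed)),
             con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
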