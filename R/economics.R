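# Incremental cost-effectiveness analysis: pairwise and sequential ICERs,
# dominance assessment, net monetary benefit, currency conversion, and the
# threshold (price-reduction) analysis.

#' Incremental cost-effectiveness ratio between two strategies
#'
#' `(cost_new - cost_ref) / (qaly_new - qaly_ref)`, in LKR per QALY gained
#' (and per life-year gained). A strategy that is cheaper and at least as
#' effective than the reference (or dearer and less effective) is a dominance
#' case, flagged instead of reported as a ratio.
#'
#' @param result_new,result_ref `econ_result` objects under the same
#'   perspective
#' @return list with `delta_cost`, `delta_qaly`, `delta_ly`, `per_qaly`,
#'   `per_ly` (NA under dominance) and `dominance` (`"NONE"`,
#'   `"NEW_DOMINATES"`, `"REF_DOMINATES"`)
#' @export
icer <- function(result_new, result_ref) {
  if (!identical(result_new$perspective, result_ref$perspective))
    stop("icer: results must share a perspective")
  dc <- result_new$cost_discounted - result_ref$cost_discounted
  dq <- result_new$qaly_discounted - result_ref$qaly_discounted
  dl <- result_new$ly_discounted - result_ref$ly_discounted
  if (dq == 0 && dc == 0)
    stop("icer: identical results, ICER undefined")
  if (dq == 0)
    stop("icer: zero QALY difference, ICER undefined")
  dominance <- if (dq > 0 && dc <= 0) "NEW_DOMINATES"
    else if (dq < 0 && dc >= 0) "REF_DOMINATES"
    else "NONE"
  list(delta_cost = dc, delta_qaly = dq, delta_ly = dl,
       per_qaly = if (dominance == "NONE") dc / dq else NA_real_,
       per_ly = if (dominance == "NONE" && dl != 0) dc / dl else NA_real_,
       dominance = dominance)
}

#' Net monetary benefit
#'
#' `qaly * wtp - cost`. The strategy with the highest net monetary benefit at
#' a threshold is the cost-effective choice at that threshold.
#'
#' @param result an `econ_result`
#' @param wtp willingness to pay, LKR per QALY (>= 0)
#' @return net monetary benefit in LKR
#' @export
nmb <- function(result, wtp) {
  if (wtp < 0) stop("nmb: wtp must be >= 0")
  result$qaly_discounted * wtp - result$cost_discounted
}

#' Convert LKR to USD
#'
#' @param lkr amount in Sri Lankan rupees
#' @param rate exchange rate, LKR per USD (default: the 2021 rate 194.78)
#' @return amount in USD
#' @export
to_usd <- function(lkr, rate = 194.78) lkr / rate

#' Incremental (frontier) analysis of all strategies
#'
#' Orders strategies by ascending discounted total cost and computes, for
#' every adjacent pair, the incremental cost per incremental QALY relative to
#' the next least-costly strategy (the sequential ICER), alongside the
#' pairwise ICER of each strategy against the designated comparator. Strictly
#' dominated strategies (some cheaper strategy achieves at least as many
#' QALYs) and extendedly dominated strategies (a higher sequential ICER than
#' the next strategy up the frontier) are flagged but not removed, so the
#' table retains one row per strategy.
#'
#' @param results list of `econ_result`, one per strategy, same perspective
#' @param wtp willingness-to-pay threshold used to mark cost-effective rows
#' @param comparator strategy id used for the pairwise ICER column
#' @return data frame (class `incremental_table`) ordered by ascending cost
#'   with columns `strategy`, `cost`, `qaly`, `ly`, `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `sequential_icer`, `icer_vs_comparator`,
#'   `dominance` and `cost_effective`
#' @export
incremental_analysis <- function(results, wtp = NULL, comparator = "S1") {
  ids <- vapply(results, `[[`, "", "strategy")
  if (anyDuplicated(ids)) stop("incremental_analysis: duplicate strategies")
  if (!comparator %in% ids) stop("incremental_analysis: comparator not in results")
  persp <- unique(vapply(results, `[[`, "", "perspective"))
  if (length(persp) != 1)
    stop("incremental_analysis: results must share a perspective")

  tab <- data.frame(
    strategy = ids,
    cost = vapply(results, `[[`, 0, "cost_discounted"),
    qaly = vapply(results, `[[`, 0, "qaly_discounted"),
    ly = vapply(results, `[[`, 0, "ly_discounted"),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(tab$cost, tab$qaly), ]
  rownames(tab) <- NULL
  n <- nrow(tab)

  tab$delta_cost <- c(NA, diff(tab$cost))
  tab$delta_qaly <- c(NA, diff(tab$qaly))
  tab$delta_ly <- c(NA, diff(tab$ly))
  tab$sequential_icer <- tab$delta_cost / tab$delta_qaly
  tab$sequential_icer[c(FALSE, tab$delta_qaly[-1] <= 0)] <- NA_real_

  ref <- results[[match(comparator, ids)]]
  tab$icer_vs_comparator <- vapply(seq_len(n), function(i) {
    if (tab$strategy[i] == comparator) return(NA_real_)
    r <- results[[match(tab$strategy[i], ids)]]
    ic <- icer(r, ref)
    if (ic$dominance == "NONE") ic$per_qaly else NA_real_
  }, 0)

  # strict dominance: a weakly cheaper strategy has at least as many QALYs
  dominated <- vapply(seq_len(n), function(i) {
    any(tab$qaly[seq_len(i - 1)] >= tab$qaly[i])
  }, logical(1))
  # extended dominance on the strictly non-dominated set: sequential ICERs
  # over the surviving frontier must be increasing
  ext <- rep(FALSE, n)
  repeat {
    keep <- which(!dominated & !ext)
    if (length(keep) < 3) break
    ic_seq <- diff(tab$cost[keep]) / diff(tab$qaly[keep])
    worse <- which(diff(ic_seq) < 0)
    if (!length(worse)) break
    ext[keep[worse[1] + 1]] <- TRUE
  }
  tab$dominance <- ifelse(dominated, "DOMINATED",
                          ifelse(ext, "EXTENDEDLY_DOMINATED", "NONE"))
  tab$cost_effective <- if (is.null(wtp)) NA else
    !is.na(tab$icer_vs_comparator) & tab$icer_vs_comparator <= wtp |
      tab$strategy == comparator
  class(tab) <- c("incremental_table", "data.frame")
  tab
}

#' Threshold (price-reduction) analysis
#'
#' Finds the smallest reduction of the named cost components of a strategy
#' that makes its ICER against a reference fall at or below the
#' willingness-to-pay threshold. Components:
#' \describe{
#'   \item{`NEOADJUVANT`}{the one-time neoadjuvant-phase cost as accounted in
#'     the analysis perspective (direct medical cost, plus the neoadjuvant
#'     direct non-medical cost under the societal perspective).}
#'   \item{`ADJUVANT_EF_YEAR1`}{the strategy's event-free year-1 monthly DMC
#'     excess over its single-HER2-adjuvant counterpart (S4 over S2, S5 over
#'     S3, otherwise over S1) — the continuation component of dual adjuvant
#'     therapy.}
#' }
#' With `method = "grid"` the answer is the smallest multiple of `step`;
#' `method = "bisect"` refines to `tol`.
#'
#' @param ps a `parameter_set`
#' @param strategy strategy whose costs are reduced
#' @param reference comparator strategy (must differ)
#' @param perspective `"public"` or `"societal"`
#' @param wtp willingness to pay, LKR/QALY (default: the parameter set's)
#' @param components character subset of `c("NEOADJUVANT", "ADJUVANT_EF_YEAR1")`
#' @param step grid granularity as a fraction (default 0.05); must divide 1
#' @param method `"grid"` or `"bisect"`
#' @param tol bisection tolerance (default 0.001)
#' @return list with `reduction` (fraction, or NA), `achievable` (logical),
#'   `icer_at_reduction`, and the searched `components`
#' @export
threshold_reduction <- function(ps, strategy, reference = "S1",
                                perspective = c("societal", "public"),
                                wtp = NULL,
                                components = "NEOADJUVANT",
                                step = 0.05,
                                method = c("grid", "bisect"),
                                tol = 0.001) {
  perspective <- match.arg(perspective)
  method <- match.arg(method)
  strategy <- match.arg(strategy, STRATEGY_IDS)
  reference <- match.arg(reference, STRATEGY_IDS)
  if (strategy == reference)
    stop("threshold_reduction: reference equals strategy")
  components <- match.arg(components, c("NEOADJUVANT", "ADJUVANT_EF_YEAR1"),
                          several.ok = TRUE)
  if (is.null(wtp)) wtp <- ps$settings$wtp_lkr
  if (method == "grid" && abs(1 / step - round(1 / step)) > 1e-9)
    stop("threshold_reduction: step must divide 100%")

  reduced_ps <- function(r) {
    p2 <- ps
    low <- tolower(strategy)
    if ("NEOADJUVANT" %in% components) {
      key <- paste0("dmc_neoadj_", low)
      p2$values[[key]] <- (1 - r) * ps$values[[key]]
      if (perspective == "societal")
        p2$values[["dnmc_neoadj"]] <- (1 - r) * ps$values[["dnmc_neoadj"]]
    }
    if ("ADJUVANT_EF_YEAR1" %in% components) {
      partner <- c(S2 = "s1", S3 = "s1", S4 = "s2", S5 = "s3")[[strategy]]
      key <- paste0("dmc_ef_y1_", low)
      excess <- ps$values[[key]] - ps$values[[paste0("dmc_ef_y1_", partner)]]
      p2$values[[key]] <- ps$values[[key]] - r * max(excess, 0)
    }
    p2
  }
  res_ref <- evaluate_strategy(ps, reference, perspective)
  icer_at <- function(r) {
    res <- evaluate_strategy(reduced_ps(r), strategy, perspective)
    ic <- icer(res, res_ref)
    if (ic$dominance == "NEW_DOMINATES") -Inf else
      if (ic$dominance == "REF_DOMINATES") Inf else ic$per_qaly
  }

  if (icer_at(1) > wtp)
    return(list(reduction = NA_real_, achievable = FALSE,
                icer_at_reduction = icer_at(1), components = components))
  if (method == "grid") {
    for (r in seq(0, 1, by = step)) {
      ic <- icer_at(r)
      if (ic <= wtp)
        return(list(reduction = r, achievable = TRUE,
                    icer_at_reduction = ic, components = components))
    }
  } else {
    lo <- 0; hi <- 1
    if (icer_at(0) <= wtp)
      return(list(reduction = 0, achievable = TRUE,
                  icer_at_reduction = icer_at(0), components = components))
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (icer_at(mid) <= wtp) hi <- mid else lo <- mid
    }
    return(list(reduction = hi, achievable = TRUE,
                icer_at_reduction = icer_at(hi), components = components))
  }
  list(reduction = NA_real_, achievable = FALSE,
       icer_at_reduction = icer_at(1), components = components)
}
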