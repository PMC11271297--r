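# One-way deterministic sensitivity analysis: vary one parameter at a time
# between its lower and upper bound, recompute the ICER of a strategy against
# a reference, and rank parameters by the width of the resulting ICER range
# (tornado-diagram data).

dsa_bounds <- function(d, convention = c("quantile", "pct20"), level = 0.95) {
  convention <- match.arg(convention)
  lo_p <- (1 - level) / 2; hi_p <- 1 - lo_p
  if (convention == "pct20")
    return(c(d$mean * 0.8, d$mean * 1.2))
  switch(d$family,
    FIXED = c(d$mean, d$mean),
    BETA = {
      if (d$se == 0) return(c(d$mean, d$mean))
      ab <- beta_from_mean_se(d$mean, d$se)
      stats::qbeta(c(lo_p, hi_p), ab[["alpha"]], ab[["beta"]])
    },
    GAMMA = {
      if (d$se == 0) return(c(d$mean, d$mean))
      sh <- gamma_from_mean_se(d$mean, d$se)
      stats::qgamma(c(lo_p, hi_p), shape = sh[["shape"]], scale = sh[["scale"]])
    },
    LOGNORMAL = c(d$ci_low, d$ci_high))  # printed 95% CI used directly
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' For each uncertain parameter in turn, sets it to its lower and to its
#' upper bound (all else at base case), recomputes the ICER of `strategy`
#' versus `reference`, and reports parameters ranked by descending ICER
#' range. Bounds are the 2.5th/97.5th percentiles of the parameter's
#' sampling distribution; hazard-ratio bounds are the printed 95% CI; the
#' annual discount rates (costs and outcomes) are varied between
#' `discount_bounds` (default 0% and 6%). Dominance reversals at a bound
#' (negative incremental QALYs) are flagged and the signed ratio retained.
#'
#' @param ps a `parameter_set`
#' @param strategy intervention strategy id
#' @param reference comparator strategy id (must differ)
#' @param perspective `"public"` or `"societal"`
#' @param top_k number of parameters to return (default 10; `Inf` for all)
#' @param bound_convention `"quantile"` (default) or `"pct20"` (mean ±20%)
#' @param discount_bounds length-2 numeric, bounds for the discount rates
#' @return a `tornado_table` data frame: `parameter`, `label`, `low_bound`,
#'   `high_bound`, `icer_at_low`, `icer_at_high`, `icer_range`,
#'   `dominance_at_bound`, sorted by descending range
#' @export
one_way_dsa <- function(ps, strategy, reference = "S1",
                        perspective = c("societal", "public"),
                        top_k = 10,
                        bound_convention = c("quantile", "pct20"),
                        discount_bounds = c(0, 0.06)) {
  perspective <- match.arg(perspective)
  bound_convention <- match.arg(bound_convention)
  strategy <- match.arg(strategy, STRATEGY_IDS)
  reference <- match.arg(reference, STRATEGY_IDS)
  if (strategy == reference) stop("one_way_dsa: strategy equals reference")

  icer_with <- function(ps2) {
    ic <- icer(evaluate_strategy(ps2, strategy, perspective),
               evaluate_strategy(ps2, reference, perspective))
    # dominance reversals keep the signed ratio, flagged by the caller
    list(value = ic$delta_cost / ic$delta_qaly, dominance = ic$dominance)
  }

  set_value <- function(nm, x) {
    p2 <- ps
    p2$values[[nm]] <- x
    if (nm == "share_event_lrr") p2$values[["share_event_met"]] <- 1 - x
    if (nm == "share_event_met") p2$values[["share_event_lrr"]] <- 1 - x
    if (nm %in% LIFETABLE_BANDS$name) {
      mort <- p2$values[LIFETABLE_BANDS$name]
      p2$values[LIFETABLE_BANDS$name] <- cummax(mort)
    }
    if (nm %in% c("tp_lrr_met", "tp_lrr_death")) {
      # the remission exit (the row's complement) absorbs the variation
      p2$values[["tp_lrr_rem"]] <- max(0, min(
        ps$values[["tp_lrr_rem"]],
        1 - p2$values[["tp_lrr_met"]] - p2$values[["tp_lrr_death"]]))
    }
    if (nm == "tp_lrr_rem") {
      cap <- 1 - p2$values[["tp_lrr_met"]] - p2$values[["tp_lrr_death"]]
      p2$values[["tp_lrr_rem"]] <- min(x, cap)  # keep the row on the simplex
    }
    p2
  }

  d <- ps$dists
  rows <- lapply(seq_len(nrow(d)), function(i) {
    di <- as.list(d[i, ])
    b <- dsa_bounds(di, bound_convention)
    lo <- icer_with(set_value(di$name, b[1]))
    hi <- icer_with(set_value(di$name, b[2]))
    data.frame(parameter = di$name, label = di$label,
               low_bound = b[1], high_bound = b[2],
               icer_at_low = lo$value, icer_at_high = hi$value,
               dominance_at_bound = lo$dominance != "NONE" ||
                 hi$dominance != "NONE",
               stringsAsFactors = FALSE)
  })

  disc <- lapply(c("discount_costs_annual", "discount_outcomes_annual"),
                 function(key) {
    at <- function(x) {
      p2 <- ps
      p2$settings[[key]] <- x
      icer_with(p2)
    }
    lo <- at(discount_bounds[1]); hi <- at(discount_bounds[2])
    data.frame(parameter = key,
               label = if (key == "discount_costs_annual")
                 "Annual discount rate, costs" else
                 "Annual discount rate, outcomes",
               low_bound = discount_bounds[1], high_bound = discount_bounds[2],
               icer_at_low = lo$value, icer_at_high = hi$value,
               dominance_at_bound = lo$dominance != "NONE" ||
                 hi$dominance != "NONE",
               stringsAsFactors = FALSE)
  })

  tab <- do.call(rbind, c(rows, disc))
  tab$icer_range <- abs(tab$icer_at_high - tab$icer_at_low)
  tab <- tab[order(-tab$icer_range), ]
  rownames(tab) <- NULL
  if (is.finite(top_k)) tab <- utils::head(tab, top_k)
  class(tab) <- c("tornado_table", "data.frame")
  tab
}
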