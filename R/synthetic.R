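# Validation instruments: a generator of random (but structurally valid)
# model configurations, a degenerate two-state model with a closed-form
# solution, and a patient-level microsimulation that replays the engine's
# transition structure one trajectory at a time. The microsimulation shares
# the engine's bookkeeping (cycle-start valuation, tenure clocks, age
# advance), so any disagreement isolates an implementation defect rather
# than a convention difference.

#' Generate a random valid model configuration
#'
#' Draws a complete parameter set with randomised transition probabilities,
#' costs, utilities and hazard ratios, deterministic in `seed`. `size`
#' selects the number of reachable transient states (2-5): smaller models
#' switch off recurrence pathways (size 2: alive/dead only; 3: adds
#' metastasis; 4: adds locoregional recurrence; 5: the full structure with
#' remission). Useful for property tests and engine-vs-microsimulation
#' comparisons on structures the base case does not exercise.
#'
#' @param seed integer seed
#' @param size number of reachable transient states, 2..5 (default 5)
#' @param horizon_years model horizon in years (default 10; shorter horizons
#'   keep property tests fast)
#' @return a validated `parameter_set`
#' @export
random_model <- function(seed, size = 5, horizon_years = 10) {
  if (!size %in% 2:5) stop("random_model: size must be in 2..5")
  set.seed(seed)
  ps <- base_case_parameters()
  v <- ps$values

  ru <- function(lo, hi) stats::runif(1, lo, hi)
  for (nm in grep("^tp_ef_event", names(v), value = TRUE))
    v[[nm]] <- ru(0.001, 0.04)
  v[["share_event_lrr"]] <- ru(0.1, 0.9)
  v[["share_event_met"]] <- 1 - v[["share_event_lrr"]]
  lrr_exit <- stats::runif(3)
  lrr_exit <- lrr_exit / sum(lrr_exit) * ru(0.5, 1)
  v[["tp_lrr_met"]] <- lrr_exit[1]
  v[["tp_lrr_death"]] <- lrr_exit[2]
  v[["tp_lrr_rem"]] <- lrr_exit[3]
  v[["tp_rem_met"]] <- ru(0.001, 0.05)
  v[LIFETABLE_BANDS$name] <- sort(stats::runif(8, 0.0001, 0.01))
  v[["tp_met_death"]] <- ru(0.02, 0.2)
  for (nm in grep("^hr_", names(v), value = TRUE)) {
    v[[nm]] <- ru(0.4, 1.2)
    ps$dists$ci_low[ps$dists$name == nm] <- v[[nm]] * 0.7
    ps$dists$ci_high[ps$dists$name == nm] <- v[[nm]] * 1.4
  }
  for (nm in grep("^u_", names(v), value = TRUE)) v[[nm]] <- ru(0.5, 0.95)
  for (nm in grep("^(dmc_|dnmc_)", names(v), value = TRUE))
    v[[nm]] <- v[[nm]] * exp(stats::rnorm(1, 0, 0.3))

  if (size < 5) {  # disable remission: recurrences resolve to MET or death
    tot <- v[["tp_lrr_met"]] + v[["tp_lrr_death"]] + v[["tp_lrr_rem"]]
    v[["tp_lrr_met"]] <- tot - v[["tp_lrr_death"]]
    v[["tp_lrr_rem"]] <- 0
  }
  if (size < 4) {  # disable locoregional recurrence: all events metastasise
    v[["share_event_lrr"]] <- 0
    v[["share_event_met"]] <- 1
  }
  if (size < 3) {  # alive/dead only: no disease events at all
    for (nm in grep("^tp_ef_event", names(v), value = TRUE)) v[[nm]] <- 0
  }

  ps$values <- v
  ps$dists$mean <- unname(v[ps$dists$name])
  ps$dists$se <- ifelse(ps$dists$family == "LOGNORMAL", NA_real_,
                        pmin(ps$dists$mean * 0.1,
                             ifelse(ps$dists$family == "BETA",
                                    sqrt(pmax(ps$dists$mean *
                                                (1 - ps$dists$mean), 1e-12)) * 0.5,
                                    Inf)))
  ps$dists$se[ps$dists$mean == 0] <- 0
  ps$dists$family[ps$dists$mean == 0] <- "FIXED"
  ps$dists$family[ps$dists$family == "BETA" &
                    (ps$dists$mean <= 0 | ps$dists$mean >= 1)] <- "FIXED"
  ps$settings$horizon_age_years <- ps$settings$start_age_years + horizon_years
  validate_parameter_set(ps)
  ps
}

#' Degenerate alive/dead model with a closed-form solution
#'
#' All disease transitions are switched off and every life-table band is set
#' to a single constant monthly death probability `p`, so the discounted
#' life-years equal the geometric series
#' \eqn{\sum_{t=0}^{T-1} (1-p)^t d^t / 12} with per-cycle discount factor
#' \eqn{d = (1+r)^{-1/12}}.
#'
#' @param p constant monthly death probability
#' @param horizon_years model horizon in years (default 50)
#' @return a validated `parameter_set`
#' @export
two_state_model <- function(p, horizon_years = 50) {
  ps <- base_case_parameters()
  for (nm in grep("^tp_ef_event", names(ps$values), value = TRUE))
    ps$values[[nm]] <- 0
  ps$values[["tp_rem_met"]] <- 0  # keeps unreachable rows well-formed at p = 1
  ps$values[LIFETABLE_BANDS$name] <- p
  ps$settings$horizon_age_years <- ps$settings$start_age_years + horizon_years
  validate_parameter_set(ps)
  ps
}

#' Patient-level microsimulation oracle
#'
#' Simulates `n_patients` individual monthly trajectories through the same
#' transition structure, cost clocks and valuation conventions as the cohort
#' engine, and returns mean discounted life-years, QALYs and costs with
#' Monte-Carlo standard errors. This is a test instrument: the cohort
#' engine's results should agree with the oracle within sampling error.
#'
#' @param ps a `parameter_set`
#' @param strategy strategy id
#' @param n_patients number of simulated patients
#' @param seed integer seed
#' @param perspective `"public"` or `"societal"`
#' @param keep_paths record each patient's state path (only honoured for
#'   `n_patients <= 1000`)
#' @return a `microsim_result`: list with `n`, `ly`, `qaly`, `cost` (means),
#'   `se_ly`, `se_qaly`, `se_cost`, and optionally `paths` (matrix
#'   patients x cycles of state codes, 1 = event free .. 5 = dead)
#' @export
microsim_oracle <- function(ps, strategy, n_patients, seed = 1,
                            perspective = c("public", "societal"),
                            keep_paths = FALSE) {
  perspective <- match.arg(perspective)
  strategy <- match.arg(strategy, STRATEGY_IDS)
  if (n_patients < 1) stop("microsim_oracle: n_patients must be >= 1")
  societal <- perspective == "societal"
  ei <- engine_inputs(ps, strategy)
  Tn <- ei$n_cycles; K <- ei$K
  set.seed(seed)

  n <- as.integer(n_patients)
  state <- rep.int(1L, n)      # 1 EF, 2 LRR, 3 MET, 4 REM, 5 DEAD
  tenure <- rep.int(0L, n)
  ly <- numeric(n); qaly <- numeric(n); cost <- numeric(n)
  cost <- cost + ei$neo_dmc + if (societal) ei$neo_dnmc else 0
  keep_paths <- keep_paths && n <= 1000
  paths <- if (keep_paths) matrix(NA_integer_, n, Tn + 1L) else NULL
  if (keep_paths) paths[, 1L] <- state

  lrr_cost_k <- ei$lrr_dmc_k + if (societal) ei$lrr_dnmc_k else 0
  rem_cost_k <- ei$rem_dmc_k + if (societal) ei$rem_dnmc_k else 0
  ef_cost_t <- ei$ef_dmc + if (societal) ei$ef_dnmc else 0
  met_cost <- ei$met_dmc + if (societal) ei$met_dnmc else 0

  for (t in seq_len(Tn)) {
    alive <- which(state != 5L)
    if (!length(alive)) {
      if (keep_paths) paths[, (t + 1L):(Tn + 1L)] <- 5L
      break
    }
    st <- state[alive]
    tn <- pmin(tenure[alive], K - 1L) + 1L
    d_out <- ei$disc_outc[t]; d_cost <- ei$disc_cost[t]

    # cycle-start accrual
    ly[alive] <- ly[alive] + d_out / 12
    u <- numeric(length(alive))
    u[st == 1L] <- ei$u_ef[t]
    u[st == 2L] <- ei$u_lrr
    u[st == 3L] <- ei$u_met
    u[st == 4L] <- ei$u_rem
    qaly[alive] <- qaly[alive] + u * d_out / 12
    cc <- numeric(length(alive))
    cc[st == 1L] <- ef_cost_t[t]
    cc[st == 2L] <- lrr_cost_k[tn[st == 2L]]
    cc[st == 3L] <- met_cost
    cc[st == 4L] <- rem_cost_k[tn[st == 4L]]
    cost[alive] <- cost[alive] + cc * d_cost

    # transition draws, one uniform per alive patient
    r <- stats::runif(length(alive))
    new <- st
    qt <- ei$q[t]; mt <- ei$m[t]
    i_ef <- st == 1L
    new[i_ef] <- ifelse(r[i_ef] < qt * ei$share_lrr, 2L,
                 ifelse(r[i_ef] < qt, 3L,
                 ifelse(r[i_ef] < qt + mt, 5L, 1L)))
    i_lrr <- st == 2L
    c1 <- ei$p_lrr_met; c2 <- c1 + ei$p_lrr_death; c3 <- c2 + ei$p_lrr_rem
    new[i_lrr] <- ifelse(r[i_lrr] < c1, 3L,
                  ifelse(r[i_lrr] < c2, 5L,
                  ifelse(r[i_lrr] < c3, 4L, 2L)))
    i_met <- st == 3L
    new[i_met] <- ifelse(r[i_met] < ei$p_met_death, 5L, 3L)
    i_rem <- st == 4L
    new[i_rem] <- ifelse(r[i_rem] < ei$p_rem_met, 3L,
                  ifelse(r[i_rem] < ei$p_rem_met + mt, 5L, 4L))

    moved <- new != st
    tenure[alive][moved] <- 0L
    tenure[alive][!moved] <- tenure[alive][!moved] + 1L
    state[alive] <- new
    if (keep_paths) paths[, t + 1L] <- state
  }

  structure(list(
    n = n, strategy = strategy, perspective = perspective, seed = seed,
    ly = mean(ly), qaly = mean(qaly), cost = mean(cost),
    se_ly = stats::sd(ly) / sqrt(n),
    se_qaly = stats::sd(qaly) / sqrt(n),
    se_cost = stats::sd(cost) / sqrt(n),
    paths = paths
  ), class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf(
    "<microsim_result> %s, n=%d: LY %.3f (SE %.4f), QALY %.3f (SE %.4f), cost %.0f (SE %.0f)\n",
    x$strategy, x$n, x$ly, x$se_ly, x$qaly, x$se_qaly, x$cost, x$se_cost))
  invisible(x)
}
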