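# Deterministic cohort engine. Five states (event free, locoregional
# recurrence, metastasis, remission, dead), monthly cycles from age 50 to 100,
# tenure ("tunnel") bookkeeping for states whose costs follow a time-in-state
# clock. Transitions never depend on tenure; only cost accrual does.

STATE_EF <- 1L; STATE_LRR <- 2L; STATE_MET <- 3L; STATE_REM <- 4L; STATE_DEAD <- 5L

#' Apply a hazard ratio to a per-cycle probability
#'
#' Converts the probability to a rate, scales the rate, and converts back:
#' `1 - (1 - p)^hr`. Identity when `hr = 1`.
#'
#' @param p per-cycle probability in \[0, 1); vectorised
#' @param hr hazard ratio, > 0
#' @return scaled per-cycle probability
#' @export
hazard_scale <- function(p, hr) {
  if (any(!is.finite(hr)) || any(hr <= 0)) stop("hazard_scale: hr must be > 0")
  if (any(p < 0)) stop("hazard_scale: p must be >= 0")
  if (any(p >= 1 & hr != 1)) stop("hazard_scale: p = 1 gives an undefined rate")
  1 - (1 - p)^hr
}

#' Per-cycle probability of leaving the event-free state for an event
#'
#' Composes the strategy's baseline transition schedule with its efficacy
#' hazard ratio according to the parameter set's `efficacy_mode`:
#' \describe{
#'   \item{`hr_on_baseline`}{(default) the hazard ratio scales the strategy's
#'     own baseline schedule (the trial-derived time-dependent probabilities
#'     for S4/S5 in months 0-60, the common baseline otherwise) throughout
#'     the effect window; after the effect cap (144 months) all strategies
#'     revert to the common post-60-month baseline. This is the composition
#'     that reproduces the published base-case outcomes.}
#'   \item{`baseline_then_hr`}{strategies with trial-derived baselines
#'     (S4, S5) use them unscaled for months 0-60, then the common baseline
#'     scaled by the hazard ratio until the effect cap; S2/S3 scale the
#'     common baseline by their hazard ratio until the cap.}
#'   \item{`hr_throughout`}{the hazard ratio is applied to the comparator
#'     baseline for the whole effect window, ignoring trial baselines.}
#'   \item{`trial_only`}{printed baselines only, no hazard-ratio scaling.}
#' }
#' The returned probability is the combined event probability before the
#' locoregional/metastatic split.
#'
#' @param ps a `parameter_set`
#' @param strategy strategy id `"S1"`..`"S5"`
#' @param cycle month index (0-based); vectorised
#' @return per-cycle event probability, same length as `cycle`
#' @export
ef_event_probability <- function(ps, strategy, cycle) {
  strategy <- match.arg(strategy, STRATEGY_IDS)
  v <- ps$values
  s <- ps$settings
  dur <- s$effect_duration_months
  mode <- s$efficacy_mode
  if (any(cycle < 0)) stop("ef_event_probability: cycle must be >= 0")

  p_ref <- ifelse(cycle < 60, v[["tp_ef_event_adjT_0_60"]],
                  v[["tp_ef_event_after_60"]])
  trial <- switch(strategy,
    S4 = {
      yr <- findInterval(cycle, c(0, 12, 24, 36, 60))
      c(v[["tp_ef_event_s4_y1"]], v[["tp_ef_event_s4_y2"]],
        v[["tp_ef_event_s4_y3"]], v[["tp_ef_event_s4_y4"]],
        v[["tp_ef_event_after_60"]])[yr]
    },
    S5 = ifelse(cycle < 60, v[["tp_ef_event_s5_0_60"]],
                v[["tp_ef_event_after_60"]]),
    p_ref)

  if (strategy == "S1") return(unname(p_ref))
  hr <- v[[paste0("hr_", tolower(strategy))]]
  in_effect <- cycle < dur

  out <- switch(mode,
    trial_only = trial,
    hr_throughout = ifelse(in_effect, hazard_scale(p_ref, hr), p_ref),
    hr_on_baseline = ifelse(in_effect, hazard_scale(trial, hr), p_ref),
    baseline_then_hr = {
      scaled <- ifelse(in_effect, hazard_scale(p_ref, hr), p_ref)
      if (strategy %in% c("S4", "S5")) ifelse(cycle < 60, trial, scaled)
      else scaled
    },
    stop("unknown efficacy_mode '", mode, "'"))
  unname(out)
}

#' Background (general-population) monthly mortality
#'
#' Looks up the monthly death probability for the age band containing
#' `age_years`; ages at or beyond 85 use the open-ended 85+ band.
#'
#' @param age_years age in years (vectorised); must be at or above the first
#'   band's lower edge
#' @param lt life table as returned by [life_table()]
#' @return per-cycle death probability
#' @export
background_mortality <- function(age_years, lt) {
  idx <- findInterval(age_years, lt$age_low)
  if (any(idx == 0))
    stop("background_mortality: age below the first life-table band")
  lt$monthly_death_probability[idx]
}

#' Single-cycle transition distribution
#'
#' The reference definition of one row of the (time-inhomogeneous) transition
#' matrix: the probability of each successor state for a cohort member in
#' `state` at model month `cycle`. Background mortality competes additively
#' with disease transitions in the event-free and remission rows; the stay
#' probability absorbs the remainder and an error is raised if exits exceed 1.
#'
#' @param ps a `parameter_set`
#' @param strategy strategy id
#' @param state one of `"EVENT_FREE"`, `"LOCOREGIONAL"`, `"METASTASIS"`,
#'   `"REMISSION"`, `"DEAD"`
#' @param cycle month index (0-based)
#' @param months_in_state tenure in the state (months); transitions do not
#'   depend on it, it is accepted for interface completeness
#' @return named probability vector over the five states, summing to 1
#' @export
transition_distribution <- function(ps, strategy, state, cycle,
                                    months_in_state = 0) {
  state <- match.arg(state, HEALTH_STATES)
  v <- ps$values
  age <- ps$settings$start_age_years + cycle / 12
  m <- background_mortality(age, life_table(ps))
  out <- stats::setNames(numeric(5), HEALTH_STATES)
  rem <- function(x) {
    if (x < -1e-12)
      stop("transition_distribution: exit probabilities exceed 1 in ", state)
    max(x, 0)
  }
  switch(state,
    EVENT_FREE = {
      q <- ef_event_probability(ps, strategy, cycle)
      out["LOCOREGIONAL"] <- q * v[["share_event_lrr"]]
      out["METASTASIS"] <- q * v[["share_event_met"]]
      out["DEAD"] <- m
      out["EVENT_FREE"] <- rem(1 - q - m)
    },
    LOCOREGIONAL = {
      out["METASTASIS"] <- v[["tp_lrr_met"]]
      out["DEAD"] <- v[["tp_lrr_death"]]
      out["REMISSION"] <- v[["tp_lrr_rem"]]
      out["LOCOREGIONAL"] <-
        rem(1 - v[["tp_lrr_met"]] - v[["tp_lrr_death"]] - v[["tp_lrr_rem"]])
    },
    METASTASIS = {
      out["DEAD"] <- v[["tp_met_death"]]
      out["METASTASIS"] <- rem(1 - v[["tp_met_death"]])
    },
    REMISSION = {
      out["METASTASIS"] <- v[["tp_rem_met"]]
      out["DEAD"] <- m
      out["REMISSION"] <- rem(1 - v[["tp_rem_met"]] - m)
    },
    DEAD = {
      out["DEAD"] <- 1
    })
  out
}

# per-cycle schedules shared by the cohort engine and the microsimulation
engine_inputs <- function(ps, strategy) {
  v <- ps$values
  s <- ps$settings
  n_cycles <- as.integer((s$horizon_age_years - s$start_age_years) * 12 /
                           s$cycle_months)
  cap <- s$tunnel_cap_months
  K <- cap + 1L
  cycles <- 0:(n_cycles - 1L)
  ages <- s$start_age_years + cycles / 12
  m <- background_mortality(ages, life_table(ps))
  q <- ef_event_probability(ps, strategy, cycles)

  stay_ef <- 1 - q - m
  if (any(stay_ef < -1e-12))
    stop("run_cohort: event-free exit probabilities exceed 1")
  stay_lrr <- 1 - (v[["tp_lrr_met"]] + v[["tp_lrr_death"]] + v[["tp_lrr_rem"]])
  if (stay_lrr < -1e-9)
    stop("run_cohort: locoregional exit probabilities exceed 1")
  stay_rem <- 1 - v[["tp_rem_met"]] - m
  if (any(stay_rem < -1e-12))
    stop("run_cohort: remission exit probabilities exceed 1")
  stay_met <- 1 - v[["tp_met_death"]]
  if (stay_met < -1e-12)
    stop("run_cohort: metastasis exit probabilities exceed 1")

  # event-free cost/utility follow the model clock
  ef_piece <- findInterval(cycles, c(0, 12, 60, 120))
  ef_dmc <- c(v[[paste0("dmc_ef_y1_", tolower(strategy))]],
              v[["dmc_ef_y2_5"]], v[["dmc_ef_y6_10"]],
              v[["dmc_ef_after10"]])[ef_piece]
  ef_dnmc <- c(v[["dnmc_ef_y1"]], v[["dnmc_ef_after"]], v[["dnmc_ef_after"]],
               v[["dnmc_ef_after"]])[ef_piece]
  u_ef <- ifelse(cycles < 12, v[["u_ef_y1"]], v[["u_ef_after"]])

  # locoregional recurrence and remission follow a time-in-state clock
  tenure <- 0:cap
  lrr_dmc_k <- ifelse(tenure < 12, v[["dmc_lrr_y1"]], v[["dmc_lrr_after"]])
  lrr_dnmc_k <- rep(v[["dnmc_lrr"]], K)
  rem_piece <- findInterval(tenure, c(0, 12, 60, 120))
  rem_dmc_k <- c(v[["dmc_rem_y1"]], v[["dmc_rem_y2_5"]], v[["dmc_rem_y6_10"]],
                 v[["dmc_rem_after10"]])[rem_piece]
  rem_dnmc_k <- c(v[["dnmc_rem_y1"]], v[["dnmc_rem_after"]],
                  v[["dnmc_rem_after"]], v[["dnmc_rem_after"]])[rem_piece]

  list(
    n_cycles = n_cycles, K = K, cycles = cycles, ages = ages,
    q = q, m = m,
    stay_ef = pmax(stay_ef, 0), stay_lrr = max(stay_lrr, 0),
    stay_rem = pmax(stay_rem, 0), stay_met = max(stay_met, 0),
    share_lrr = v[["share_event_lrr"]], share_met = v[["share_event_met"]],
    p_lrr_met = v[["tp_lrr_met"]], p_lrr_death = v[["tp_lrr_death"]],
    p_lrr_rem = v[["tp_lrr_rem"]], p_rem_met = v[["tp_rem_met"]],
    p_met_death = v[["tp_met_death"]],
    ef_dmc = ef_dmc, ef_dnmc = ef_dnmc, u_ef = u_ef,
    lrr_dmc_k = lrr_dmc_k, lrr_dnmc_k = lrr_dnmc_k,
    rem_dmc_k = rem_dmc_k, rem_dnmc_k = rem_dnmc_k,
    met_dmc = v[["dmc_met"]], met_dnmc = v[["dnmc_met"]],
    u_lrr = v[["u_lrr"]], u_rem = v[["u_rem"]], u_met = v[["u_met"]],
    neo_dmc = v[[paste0("dmc_neoadj_", tolower(strategy))]],
    neo_dnmc = v[["dnmc_neoadj"]],
    disc_cost = (1 + ps$settings$discount_costs_annual)^(-cycles / 12),
    disc_outc = (1 + ps$settings$discount_outcomes_annual)^(-cycles / 12)
  )
}

# tenure shift with capped top bucket
shift_tunnel <- function(x) {
  K <- length(x)
  y <- c(0, x[-K])
  y[K] <- y[K] + x[K]
  y
}

#' Run the deterministic cohort trace for one strategy
#'
#' Propagates the full cohort (starting entirely event free with zero tenure)
#' through the monthly transition structure to the horizon (age 100),
#' recording state occupancy resolved by months-in-state (tenure buckets
#' capped at the tunnel cap, default 121).
#'
#' @param ps a `parameter_set`
#' @param strategy strategy id `"S1"`..`"S5"`
#' @return a `cohort_trace`: list with `strategy`, `occupancy` (array
#'   \[cycle 0..T, tenure bucket 0..cap, state\]), `ages` (age at each cycle
#'   start), and `n_cycles` (T)
#' @export
run_cohort <- function(ps, strategy) {
  strategy <- match.arg(strategy, STRATEGY_IDS)
  ei <- engine_inputs(ps, strategy)
  Tn <- ei$n_cycles; K <- ei$K
  A <- array(0, dim = c(Tn + 1L, K, 5L),
             dimnames = list(NULL, NULL, HEALTH_STATES))
  occ <- matrix(0, K, 5L)
  occ[1L, STATE_EF] <- 1
  A[1L, , ] <- occ
  for (t in seq_len(Tn)) {
    tot <- .colSums(occ, K, 5L)
    qt <- ei$q[t]
    mt <- ei$m[t]
    entr_lrr <- tot[STATE_EF] * qt * ei$share_lrr
    entr_met <- tot[STATE_EF] * qt * ei$share_met +
      tot[STATE_LRR] * ei$p_lrr_met + tot[STATE_REM] * ei$p_rem_met
    entr_rem <- tot[STATE_LRR] * ei$p_lrr_rem
    entr_dead <- tot[STATE_EF] * mt + tot[STATE_LRR] * ei$p_lrr_death +
      tot[STATE_REM] * mt + tot[STATE_MET] * ei$p_met_death
    occ[, STATE_EF] <- shift_tunnel(occ[, STATE_EF] * ei$stay_ef[t])
    occ[, STATE_LRR] <- shift_tunnel(occ[, STATE_LRR] * ei$stay_lrr)
    occ[, STATE_REM] <- shift_tunnel(occ[, STATE_REM] * ei$stay_rem[t])
    occ[, STATE_MET] <- shift_tunnel(occ[, STATE_MET] * ei$stay_met)
    occ[, STATE_DEAD] <- shift_tunnel(occ[, STATE_DEAD])
    occ[1L, STATE_LRR] <- occ[1L, STATE_LRR] + entr_lrr
    occ[1L, STATE_MET] <- occ[1L, STATE_MET] + entr_met
    occ[1L, STATE_REM] <- occ[1L, STATE_REM] + entr_rem
    occ[1L, STATE_DEAD] <- occ[1L, STATE_DEAD] + entr_dead
    A[t + 1L, , ] <- occ
  }
  structure(list(strategy = strategy, occupancy = A,
                 ages = c(ei$ages, ps$settings$horizon_age_years),
                 n_cycles = Tn),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  dead <- sum(x$occupancy[x$n_cycles + 1L, , STATE_DEAD])
  cat(sprintf("<cohort_trace> strategy %s, %d monthly cycles, %.1f%% dead at horizon\n",
              x$strategy, x$n_cycles, 100 * dead))
  invisible(x)
}

#' Long-form export of a cohort trace
#'
#' @param trace a `cohort_trace`
#' @param drop_zero drop zero-occupancy rows (default TRUE)
#' @return data frame with `cycle`, `age_years`, `state`, `months_in_state`,
#'   `fraction`
#' @export
trace_to_df <- function(trace, drop_zero = TRUE) {
  A <- trace$occupancy
  d <- dim(A)
  df <- data.frame(
    cycle = rep(0:(d[1] - 1L), times = d[2] * d[3]),
    age_years = rep(trace$ages, times = d[2] * d[3]),
    state = rep(HEALTH_STATES, each = d[1] * d[2]),
    months_in_state = rep(rep(0:(d[2] - 1L), each = d[1]), times = d[3]),
    fraction = as.vector(A)
  )
  if (drop_zero) df <- df[df$fraction > 0, ]
  rownames(df) <- NULL
  df
}

#' Accumulate discounted outcomes and costs from a cohort trace
#'
#' Values state membership at cycle start: each cycle contributes 1/12 of a
#' life-year per alive fraction, utility-weighted for QALYs, plus the monthly
#' state cost on the state's cost clock (event free: model time; locoregional
#' recurrence and remission: time in state; metastasis: flat). The one-time
#' neoadjuvant treatment cost is charged undiscounted at cycle 0. Costs and
#' outcomes are discounted at their annual rates with factor
#' `(1 + r)^(-t/12)`. The public perspective includes direct medical costs
#' only; the societal perspective adds direct non-medical costs.
#'
#' @param trace a `cohort_trace` from [run_cohort()]
#' @param ps the `parameter_set` used to produce the trace
#' @param perspective `"public"` or `"societal"`
#' @return an `econ_result`: list with `strategy`, `perspective`, discounted
#'   and undiscounted life-years, QALYs and costs (LKR), and
#'   `per_cycle_cost_stream` (undiscounted LKR by cycle, lump sum included at
#'   cycle 0)
#' @export
accumulate <- function(trace, ps, perspective = c("public", "societal")) {
  perspective <- match.arg(perspective)
  ei <- engine_inputs(ps, trace$strategy)
  Tn <- trace$n_cycles
  A <- trace$occupancy
  rows <- seq_len(Tn)

  ef_t <- rowSums(A[rows, , STATE_EF, drop = FALSE][, , 1L])
  lrr_m <- A[rows, , STATE_LRR, drop = FALSE][, , 1L]
  rem_m <- A[rows, , STATE_REM, drop = FALSE][, , 1L]
  met_t <- rowSums(A[rows, , STATE_MET, drop = FALSE][, , 1L])
  lrr_t <- rowSums(lrr_m)
  rem_t <- rowSums(rem_m)

  ly_t <- (ef_t + lrr_t + rem_t + met_t) / 12
  qaly_t <- (ef_t * ei$u_ef + lrr_t * ei$u_lrr + rem_t * ei$u_rem +
               met_t * ei$u_met) / 12

  cost_t <- ef_t * ei$ef_dmc + drop(lrr_m %*% ei$lrr_dmc_k) +
    drop(rem_m %*% ei$rem_dmc_k) + met_t * ei$met_dmc
  lump <- ei$neo_dmc
  if (perspective == "societal") {
    cost_t <- cost_t + ef_t * ei$ef_dnmc + drop(lrr_m %*% ei$lrr_dnmc_k) +
      drop(rem_m %*% ei$rem_dnmc_k) + met_t * ei$met_dnmc
    lump <- lump + ei$neo_dnmc
  }
  cost_t[1L] <- cost_t[1L] + lump

  new_econ_result(trace$strategy, perspective, ly_t, qaly_t, cost_t,
                  ei$disc_outc, ei$disc_cost)
}

new_econ_result <- function(strategy, perspective, ly_t, qaly_t, cost_t,
                            disc_outc, disc_cost) {
  structure(list(
    strategy = strategy,
    perspective = perspective,
    ly_discounted = sum(ly_t * disc_outc),
    qaly_discounted = sum(qaly_t * disc_outc),
    cost_discounted = sum(cost_t * disc_cost),
    ly_undiscounted = sum(ly_t),
    qaly_undiscounted = sum(qaly_t),
    cost_undiscounted = sum(cost_t),
    per_cycle_cost_stream = cost_t
  ), class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("<econ_result> %s (%s): LY %.3f, QALY %.3f, cost LKR %s (discounted)\n",
              x$strategy, x$perspective, x$ly_discounted, x$qaly_discounted,
              format(round(x$cost_discounted), big.mark = ",")))
  invisible(x)
}

# streaming evaluation (no stored trace): identical dynamics, in-loop accrual
evaluate_strategy <- function(ps, strategy, perspective = c("public", "societal")) {
  perspective <- match.arg(perspective)
  strategy <- match.arg(strategy, STRATEGY_IDS)
  ei <- engine_inputs(ps, strategy)
  Tn <- ei$n_cycles; K <- ei$K
  societal <- perspective == "societal"

  ef <- 1; met <- 0; dead <- 0
  lrr_k <- numeric(K); rem_k <- numeric(K)
  ly_t <- numeric(Tn); qaly_t <- numeric(Tn); cost_t <- numeric(Tn)

  for (t in seq_len(Tn)) {
    lrr_tot <- sum(lrr_k); rem_tot <- sum(rem_k)
    alive <- ef + lrr_tot + rem_tot + met
    ly_t[t] <- alive / 12
    qaly_t[t] <- (ef * ei$u_ef[t] + lrr_tot * ei$u_lrr + rem_tot * ei$u_rem +
                    met * ei$u_met) / 12
    ct <- ef * ei$ef_dmc[t] + sum(lrr_k * ei$lrr_dmc_k) +
      sum(rem_k * ei$rem_dmc_k) + met * ei$met_dmc
    if (societal)
      ct <- ct + ef * ei$ef_dnmc[t] + lrr_tot * ei$lrr_dnmc_k[1L] +
        sum(rem_k * ei$rem_dnmc_k) + met * ei$met_dnmc
    cost_t[t] <- ct

    qt <- ei$q[t]; mt <- ei$m[t]
    entr_lrr <- ef * qt * ei$share_lrr
    entr_met <- ef * qt * ei$share_met + lrr_tot * ei$p_lrr_met +
      rem_tot * ei$p_rem_met
    entr_rem <- lrr_tot * ei$p_lrr_rem
    dead <- dead + ef * mt + lrr_tot * ei$p_lrr_death + rem_tot * mt +
      met * ei$p_met_death
    ef <- ef * ei$stay_ef[t]
    met <- met * ei$stay_met + entr_met
    lrr_k <- shift_tunnel(lrr_k * ei$stay_lrr)
    lrr_k[1L] <- lrr_k[1L] + entr_lrr
    rem_k <- shift_tunnel(rem_k * ei$stay_rem[t])
    rem_k[1L] <- rem_k[1L] + entr_rem
  }
  cost_t[1L] <- cost_t[1L] + ei$neo_dmc + if (societal) ei$neo_dnmc else 0
  new_econ_result(strategy, perspective, ly_t, qaly_t, cost_t,
                  ei$disc_outc, ei$disc_cost)
}

#' Evaluate all five strategies
#'
#' Runs the cohort model for every strategy under one perspective.
#'
#' @param ps a `parameter_set`
#' @param perspective `"public"` or `"societal"`
#' @return named list of `econ_result`, one per strategy S1..S5
#' @export
evaluate_strategies <- function(ps, perspective = c("public", "societal")) {
  perspective <- match.arg(perspective)
  stats::setNames(
    lapply(STRATEGY_IDS, evaluate_strategy, ps = ps, perspective = perspective),
    STRATEGY_IDS)
}
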