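# Probabilistic sensitivity analysis: joint parameter sampling from the
# assigned distributions (Beta for probabilities/utilities by method of
# moments, Gamma for costs, log-normal for hazard ratios from their 95% CIs),
# Monte Carlo evaluation of all strategies per draw, cost-effectiveness
# acceptability curves and cost-effectiveness plane summaries.

draw_one <- function(d) {
  switch(d$family,
    FIXED = d$mean,
    BETA = {
      ab <- beta_from_mean_se(d$mean, d$se)
      stats::rbeta(1, ab[["alpha"]], ab[["beta"]])
    },
    GAMMA = {
      if (d$se == 0) return(d$mean)
      sh <- gamma_from_mean_se(d$mean, d$se)
      stats::rgamma(1, shape = sh[["shape"]], scale = sh[["scale"]])
    },
    LOGNORMAL = {
      ms <- lognormal_from_ci(d$mean, d$ci_low, d$ci_high)
      stats::rlnorm(1, ms[["mu"]], ms[["sigma"]])
    },
    stop("unknown distribution family: ", d$family))
}

#' Draw one joint parameter sample
#'
#' Samples every parameter from its assigned distribution, in the documented
#' order of the distribution table, using the current RNG state. Parameters
#' are drawn independently, with two structural exceptions: the metastatic
#' share of events is taken as the complement of the sampled locoregional
#' share (the two must sum to 1), and if a drawn locoregional-recurrence exit
#' row exceeds the probability simplex it is renormalised to sum to 1 (the
#' draw is recorded in the returned attribute `n_renormalised`). Settings
#' (discount rates, clock, horizon) are never sampled.
#'
#' @param ps a `parameter_set` supplying means and distribution specs
#' @param max_retries draws per parameter before giving up on an invalid
#'   joint sample
#' @return a new `parameter_set` with sampled `values` (validated), carrying
#'   attribute `n_renormalised`
#' @export
sample_parameter_set <- function(ps, max_retries = 100) {
  d <- ps$dists
  out <- ps
  renorm <- 0L
  for (attempt in seq_len(max_retries)) {
    vals <- ps$values
    for (i in seq_len(nrow(d))) {
      nm <- d$name[i]
      if (nm == "share_event_met") next  # complement of the sampled LRR share
      vals[[nm]] <- draw_one(as.list(d[i, ]))
    }
    vals[["share_event_met"]] <- 1 - vals[["share_event_lrr"]]
    lrr_sum <- vals[["tp_lrr_met"]] + vals[["tp_lrr_death"]] + vals[["tp_lrr_rem"]]
    if (lrr_sum > 1) {
      for (nm in c("tp_lrr_met", "tp_lrr_death", "tp_lrr_rem"))
        vals[[nm]] <- vals[[nm]] / lrr_sum
      renorm <- renorm + 1L
    }
    mort <- vals[LIFETABLE_BANDS$name]
    vals[LIFETABLE_BANDS$name] <- cummax(mort)  # keep life table monotone
    out$values <- vals
    ok <- tryCatch({ validate_parameter_set(out); TRUE },
                   error = function(e) FALSE)
    if (ok) {
      attr(out, "n_renormalised") <- renorm
      return(out)
    }
  }
  stop("sample_parameter_set: no valid draw after ", max_retries, " attempts")
}

#' Run the probabilistic sensitivity analysis
#'
#' Monte Carlo simulation: `n` joint parameter draws, each evaluated through
#' the cohort engine for all five strategies under one perspective.
#' Reproducible under `seed`; each iteration uses its own RNG substream
#' (derived from the root seed), so results for iteration i do not depend on
#' how many iterations run before it.
#'
#' @param ps a `parameter_set`
#' @param n number of iterations (default 1000)
#' @param seed integer root seed
#' @param perspective `"public"` or `"societal"`
#' @return a `psa_result`: list with `n`, `seed`, `perspective`, `draws`
#'   (data frame: iteration, strategy, cost, qaly, ly), `parameters` (matrix
#'   of sampled values, one row per iteration, for audit), and
#'   `n_renormalised`
#' @export
run_psa <- function(ps, n = 1000, seed = 1,
                    perspective = c("societal", "public")) {
  perspective <- match.arg(perspective)
  if (n < 1) stop("run_psa: n must be >= 1")
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n)
  k <- length(STRATEGY_IDS)

  cost <- qaly <- ly <- matrix(NA_real_, n, k,
                               dimnames = list(NULL, STRATEGY_IDS))
  par_mat <- matrix(NA_real_, n, length(ps$values),
                    dimnames = list(NULL, names(ps$values)))
  renorm <- 0L
  for (i in seq_len(n)) {
    set.seed(iter_seeds[i])
    psi <- sample_parameter_set(ps)
    renorm <- renorm + attr(psi, "n_renormalised")
    par_mat[i, ] <- psi$values
    for (s in STRATEGY_IDS) {
      r <- evaluate_strategy(psi, s, perspective)
      cost[i, s] <- r$cost_discounted
      qaly[i, s] <- r$qaly_discounted
      ly[i, s] <- r$ly_discounted
    }
  }
  draws <- data.frame(
    iteration = rep(seq_len(n), times = k),
    strategy = rep(STRATEGY_IDS, each = n),
    cost = as.vector(cost),
    qaly = as.vector(qaly),
    ly = as.vector(ly),
    stringsAsFactors = FALSE
  )
  structure(list(n = n, seed = seed, perspective = perspective,
                 draws = draws, cost = cost, qaly = qaly, ly = ly,
                 parameters = par_mat, n_renormalised = renorm),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d iterations (seed %d, %s perspective)\n",
              x$n, x$seed, x$perspective))
  invisible(x)
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay value, the probability (fraction of PSA draws)
#' that each strategy has the highest net monetary benefit. Ties within a
#' draw split the probability equally.
#'
#' @param psa a `psa_result`
#' @param wtp_grid numeric vector of willingness-to-pay values (LKR/QALY)
#' @return data frame with `wtp`, `strategy`, `probability`; at each `wtp`
#'   the probabilities sum to 1
#' @export
ceac <- function(psa, wtp_grid) {
  if (!length(wtp_grid)) stop("ceac: empty wtp grid")
  k <- ncol(psa$qaly)
  out <- lapply(wtp_grid, function(w) {
    nmb <- psa$qaly * w - psa$cost
    best <- nmb == apply(nmb, 1, max)
    p <- colSums(best / rowSums(best)) / psa$n
    data.frame(wtp = w, strategy = colnames(psa$qaly), probability = unname(p),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cost-effectiveness plane
#'
#' Per-iteration incremental cost and QALYs of each intervention strategy
#' against a reference, with counts of points per plane quadrant.
#'
#' @param psa a `psa_result`
#' @param reference reference strategy id (default `"S1"`)
#' @return list with `points` (data frame: iteration, strategy, delta_cost,
#'   delta_qaly) and `quadrants` (data frame of counts: strategy, quadrant
#'   NE/NW/SE/SW, n; boundary points count toward the east/north side)
#' @export
ce_plane <- function(psa, reference = "S1") {
  if (!reference %in% colnames(psa$cost))
    stop("ce_plane: reference not in results")
  others <- setdiff(colnames(psa$cost), reference)
  pts <- do.call(rbind, lapply(others, function(s) {
    data.frame(iteration = seq_len(psa$n), strategy = s,
               delta_cost = psa$cost[, s] - psa$cost[, reference],
               delta_qaly = psa$qaly[, s] - psa$qaly[, reference],
               stringsAsFactors = FALSE)
  }))
  quad <- ifelse(pts$delta_qaly >= 0,
                 ifelse(pts$delta_cost > 0, "NE", "SE"),
                 ifelse(pts$delta_cost > 0, "NW", "SW"))
  quadrants <- as.data.frame(table(strategy = pts$strategy, quadrant = quad),
                             stringsAsFactors = FALSE)
  names(quadrants)[3] <- "n"
  list(points = pts, quadrants = quadrants)
}
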