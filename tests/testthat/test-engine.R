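# Cohort engine: transition construction, trace propagation, accrual
# conventions, and the structural invariants of a well-formed Markov cohort.

test_that("hazard scaling agrees with the rate-transform route", {
  for (p in c(0, 0.001, 0.01015, 0.3, 0.9))
    for (hr in c(0.32, 0.54, 0.85, 1, 1.22, 2)) {
      via_rate <- 1 - exp(-hr * (-log(1 - p)))
      expect_equal(hazard_scale(p, hr), via_rate, tolerance = 1e-12)
    }
  expect_equal(hazard_scale(0.01015, 0.54), 0.005493859, tolerance = 1e-7)
  expect_identical(hazard_scale(0.37, 1), 0.37)
  expect_identical(hazard_scale(0, 0.54), 0)
  expect_error(hazard_scale(1, 0.54), "undefined")
  expect_error(hazard_scale(0.5, -1), "hr")
})

test_that("event-free event probability follows the strategy schedules", {
  ps <- base_ps()
  expect_equal(ef_event_probability(ps, "S1", 30), 0.01015)
  expect_equal(ef_event_probability(ps, "S1", 100), 0.01015)
  expect_equal(ef_event_probability(ps, "S2", 30),
               hazard_scale(0.01015, 0.54))
  expect_equal(ef_event_probability(ps, "S4", 6),
               hazard_scale(0.00118, 0.54))
  expect_equal(ef_event_probability(ps, "S5", 30),
               hazard_scale(0.00798, 0.85))
  # between month 60 and the 12-year cap the common baseline is scaled
  expect_equal(ef_event_probability(ps, "S4", 100),
               hazard_scale(0.01015, 0.54))
  # after the effect cap every strategy reverts to the common baseline
  expect_equal(ef_event_probability(ps, "S5", 200), 0.01015)
  expect_equal(ef_event_probability(ps, "S2", 143),
               hazard_scale(0.01015, 0.54))
  expect_equal(ef_event_probability(ps, "S2", 144), 0.01015)

  # alternative composition modes
  alt <- ps; alt$settings$efficacy_mode <- "baseline_then_hr"
  expect_equal(ef_event_probability(alt, "S4", 6), 0.00118)
  expect_equal(ef_event_probability(alt, "S2", 30),
               hazard_scale(0.01015, 0.54))
  alt$settings$efficacy_mode <- "trial_only"
  expect_equal(ef_event_probability(alt, "S5", 30), 0.00798)
  expect_equal(ef_event_probability(alt, "S2", 30), 0.01015)
  alt$settings$efficacy_mode <- "hr_throughout"
  expect_equal(ef_event_probability(alt, "S4", 6),
               hazard_scale(0.01015, 0.54))

  expect_error(ef_event_probability(ps, "S9", 5), "arg")
  expect_error(ef_event_probability(ps, "S1", -2), ">= 0")
})

test_that("background mortality uses age bands with an open 85+ band", {
  lt <- life_table(base_ps())
  expect_equal(background_mortality(52, lt), 0.00027)
  expect_equal(background_mortality(55, lt), 0.00041)
  expect_equal(background_mortality(84.9, lt), 0.00708)
  expect_equal(background_mortality(99, lt), 0.00708)
  expect_error(background_mortality(45, lt), "below")
})

test_that("transition rows are distributions and match the published values", {
  ps <- base_ps()
  row <- transition_distribution(ps, "S1", "EVENT_FREE", 0)
  expect_equal(unname(row["LOCOREGIONAL"]), 0.01015 * 0.25)
  expect_equal(unname(row["METASTASIS"]), 0.01015 * 0.75)
  expect_equal(unname(row["DEAD"]), 0.00027)
  expect_equal(unname(row["EVENT_FREE"]), 1 - 0.01015 - 0.00027)
  expect_equal(sum(row), 1, tolerance = 1e-12)

  # locoregional recurrence resolves completely within one cycle
  row <- transition_distribution(ps, "S1", "LOCOREGIONAL", 10)
  expect_equal(unname(row["LOCOREGIONAL"]), 0)
  expect_equal(sum(row), 1, tolerance = 1e-12)

  expect_equal(unname(transition_distribution(ps, "S1", "DEAD", 5)["DEAD"]), 1)

  # row-stochastic across states, strategies and cycles
  for (s in c("S1", "S4")) for (st in c("EVENT_FREE", "LOCOREGIONAL",
                                        "METASTASIS", "REMISSION", "DEAD"))
    for (cyc in c(0, 59, 60, 143, 144, 400)) {
      row <- transition_distribution(ps, s, st, cyc)
      expect_true(all(row >= 0))
      expect_equal(sum(row), 1, tolerance = 1e-12)
    }

  # exits above 1 are a hard error
  bad <- ps
  bad$values[["tp_rem_met"]] <- 0.9999
  bad$values[["mort_85_plus"]] <- 0.008
  expect_error(transition_distribution(bad, "S1", "REMISSION", 590), "exceed")
})

test_that("cohort trace conserves mass, starts event free and absorbs into death", {
  tr <- run_cohort(base_ps(), "S1")
  A <- tr$occupancy
  expect_equal(tr$n_cycles, 600)
  # initial condition: whole cohort event free with zero tenure
  expect_equal(unname(A[1, 1, "EVENT_FREE"]), 1)
  expect_equal(sum(A[1, , ]), 1)
  totals <- apply(A, 1, sum)
  expect_true(all(abs(totals - 1) < 1e-10))
  dead <- apply(A[, , "DEAD", drop = FALSE], 1, sum)
  expect_true(all(diff(dead) >= -1e-15))
  expect_true(all(A >= 0))
})

test_that("event-free occupancy matches the closed-form survival product", {
  ps <- base_ps()
  tr <- run_cohort(ps, "S1")
  lt <- life_table(ps)
  surv <- prod(1 - 0.01015 -
                 background_mortality(50 + (0:59) / 12, lt))
  expect_equal(sum(tr$occupancy[61, , "EVENT_FREE"]), surv, tolerance = 1e-12)
})

test_that("trace accumulation and streaming evaluation agree", {
  ps <- base_ps()
  for (s in c("S1", "S2", "S4")) for (persp in c("public", "societal")) {
    a <- accumulate(run_cohort(ps, s), ps, persp)
    b <- base_results(persp)[[s]]
    expect_equal(a$ly_discounted, b$ly_discounted, tolerance = 1e-10)
    expect_equal(a$qaly_discounted, b$qaly_discounted, tolerance = 1e-10)
    expect_equal(a$cost_discounted, b$cost_discounted, tolerance = 1e-10)
    expect_equal(a$per_cycle_cost_stream, b$per_cycle_cost_stream,
                 tolerance = 1e-10)
  }
})

test_that("outcome accounting identities hold", {
  ps <- base_ps()
  for (s in c("S1", "S3")) {
    pub <- base_results("public")[[s]]
    soc <- base_results("societal")[[s]]
    expect_lte(pub$qaly_discounted, pub$ly_discounted)
    expect_lte(pub$ly_discounted, pub$ly_undiscounted)
    expect_lte(pub$qaly_discounted, pub$qaly_undiscounted)
    expect_lte(pub$cost_discounted, pub$cost_undiscounted)
    expect_gte(soc$cost_discounted, pub$cost_discounted)
  }

  # utilities of 1 collapse QALYs onto life-years
  ones <- ps
  ones$values[grep("^u_", names(ones$values))] <- 1
  r <- evaluate_strategies(ones, "public")$S2
  expect_equal(r$qaly_discounted, r$ly_discounted, tolerance = 1e-12)

  # zero discounting collapses discounted onto undiscounted streams
  flat <- ps
  flat$settings$discount_costs_annual <- 0
  flat$settings$discount_outcomes_annual <- 0
  r <- evaluate_strategies(flat, "public")$S1
  expect_equal(r$ly_discounted, r$ly_undiscounted, tolerance = 1e-12)
  expect_equal(r$cost_discounted, r$cost_undiscounted, tolerance = 1e-12)
})

test_that("a unit hazard ratio reproduces the comparator dynamics", {
  ps <- base_ps()
  ps$values[["hr_s2"]] <- 1
  tr1 <- run_cohort(ps, "S1")
  tr2 <- run_cohort(ps, "S2")
  expect_equal(tr2$occupancy, tr1$occupancy, tolerance = 1e-14)
  r1 <- evaluate_strategy(ps, "S1", "public")
  r2 <- evaluate_strategy(ps, "S2", "public")
  expect_equal(r2$ly_discounted, r1$ly_discounted, tolerance = 1e-12)
  expect_equal(r2$qaly_discounted, r1$qaly_discounted, tolerance = 1e-12)
  # costs still differ through the neoadjuvant lump sum
  expect_gt(r2$cost_discounted, r1$cost_discounted)
})

test_that("stronger efficacy (smaller hazard ratio) never reduces life-years", {
  ps <- base_ps()
  lys <- sapply(c(0.4, 0.7, 1, 1.3), function(h) {
    ps$values[["hr_s2"]] <- h
    evaluate_strategy(ps, "S2", "public")$ly_discounted
  })
  expect_true(all(diff(lys) <= 1e-12))
})

test_that("trace exports to a tidy long table", {
  tr <- run_cohort(base_ps(), "S1")
  df <- trace_to_df(tr)
  expect_named(df, c("cycle", "age_years", "state", "months_in_state",
                     "fraction"))
  expect_equal(df$fraction[df$cycle == 0], 1)
  expect_equal(sum(df$fraction[df$cycle == 300]), 1, tolerance = 1e-10)
})
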