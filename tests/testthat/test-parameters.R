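# Parameter store: completeness of the packaged base case, distribution
# constructors, validation, and configuration round-trips.

test_that("packaged base case carries every published parameter value", {
  ps <- base_ps()
  expected <- c(
    tp_ef_event_adjT_0_60 = 0.01015, tp_ef_event_s4_y1 = 0.00118,
    tp_ef_event_s4_y2 = 0.00229, tp_ef_event_s4_y3 = 0.00220,
    tp_ef_event_s4_y4 = 0.00220, tp_ef_event_s5_0_60 = 0.00798,
    tp_ef_event_after_60 = 0.01015,
    share_event_lrr = 0.25, share_event_met = 0.75,
    tp_lrr_met = 0.02317, tp_lrr_death = 0.01064, tp_lrr_rem = 0.96619,
    tp_rem_met = 0.0076,
    mort_50_54 = 0.00027, mort_55_59 = 0.00041, mort_60_64 = 0.00067,
    mort_65_69 = 0.00120, mort_70_74 = 0.00226, mort_75_79 = 0.00379,
    mort_80_84 = 0.00708, mort_85_plus = 0.00708,
    tp_met_death = 0.04672,
    hr_s2 = 0.54, hr_s3 = 0.85, hr_s4 = 0.54, hr_s5 = 0.85,
    u_ef_y1 = 0.81, u_ef_after = 0.85, u_lrr = 0.72, u_rem = 0.82,
    u_met = 0.70,
    dmc_neoadj_s1 = 403337.46, dmc_neoadj_s2 = 2591980.99,
    dmc_neoadj_s3 = 712164.10, dmc_neoadj_s4 = 2591980.99,
    dmc_neoadj_s5 = 712164.10,
    dmc_ef_y1_s1 = 66740.23, dmc_ef_y1_s2 = 66819.49,
    dmc_ef_y1_s3 = 66740.23, dmc_ef_y1_s4 = 576956.06,
    dmc_ef_y1_s5 = 157203.06,
    dmc_ef_y2_5 = 1097.03, dmc_ef_y6_10 = 876.94, dmc_ef_after10 = 404.15,
    dmc_lrr_y1 = 307205.83, dmc_lrr_after = 263124.47,
    dmc_rem_y1 = 67429.98, dmc_rem_y2_5 = 742.72, dmc_rem_y6_10 = 1137.50,
    dmc_rem_after10 = 664.71, dmc_met = 111356.35,
    dnmc_neoadj = 61575.58, dnmc_ef_y1 = 9045.57, dnmc_ef_after = 1768.42,
    dnmc_lrr = 103098.78, dnmc_rem_y1 = 6189.48, dnmc_rem_after = 1768.42,
    dnmc_met = 9172.73
  )
  expect_setequal(names(ps$values), names(expected))
  expect_equal(ps$values[names(expected)], expected)

  # settings and epidemiology
  s <- ps$settings
  expect_equal(s$start_age_years, 50)
  expect_equal(s$horizon_age_years, 100)
  expect_equal(s$cycle_months, 1)
  expect_equal(s$discount_costs_annual, 0.03)
  expect_equal(s$discount_outcomes_annual, 0.03)
  expect_equal(s$wtp_lkr, 758680)
  expect_equal(s$lkr_per_usd, 194.78)
  expect_equal(s$effect_duration_months, 144)
  expect_equal(ps$epi$prevalent_cases_5yr, 13647)
  expect_equal(ps$epi$annual_incident_cases, 4447)
  expect_equal(ps$epi$pct_early, 0.66)
  expect_equal(ps$epi$pct_her2_positive, 0.22)

  # locoregional recurrence exits form a complete row (sum exactly 1)
  expect_identical(0.02317 + 0.01064 + 0.96619, 1)
  # spot-check published standard errors, including the utilities whose SE
  # is not 10% of the mean
  d <- ps$dists
  se_of <- function(nm) d$se[d$name == nm]
  expect_equal(se_of("u_ef_y1"), 0.0183)
  expect_equal(se_of("u_met"), 0.0266)
  expect_equal(se_of("tp_ef_event_adjT_0_60"), 0.00102)
  expect_equal(se_of("dmc_neoadj_s2"), 259198.10)
  ci_of <- function(nm) c(d$ci_low[d$name == nm], d$ci_high[d$name == nm])
  expect_equal(ci_of("hr_s2"), c(0.32, 0.91))
  expect_equal(ci_of("hr_s5"), c(0.60, 1.22))
})

test_that("typed views expose coherent strategy, life-table and cost schedules", {
  ps <- base_ps()
  s4 <- strategy_spec(ps, "S4")
  expect_equal(s4$neoadjuvant_dmc, 2591980.99)
  expect_equal(s4$ef_year1_monthly_dmc, 576956.06)
  expect_equal(s4$hr, 0.54)
  expect_true(is.na(strategy_spec(ps, "S1")$hr))

  lt <- life_table(ps)
  expect_equal(nrow(lt), 8)
  expect_equal(lt$age_low[1], 50)
  expect_true(is.infinite(lt$age_high[8]))
  expect_true(all(diff(lt$monthly_death_probability) >= 0))

  for (s in c("S1", "S4")) {
    cs <- cost_schedule_table(ps, s)
    expect_true(all(cs$monthly_dmc_lkr >= 0))
    expect_equal(cs$monthly_dmc_lkr[cs$state == "DEAD"], 0)
    # pieces contiguous per (state, clock)
    for (st in unique(cs$state)) {
      pieces <- cs[cs$state == st, ]
      expect_equal(pieces$start_month[1], 0)
      if (nrow(pieces) > 1)
        expect_equal(pieces$start_month[-1],
                     pieces$end_month[-nrow(pieces)])
      expect_true(is.infinite(pieces$end_month[nrow(pieces)]))
    }
  }
  u <- utility_set(ps)
  expect_equal(u$dead, 0)
  expect_true(all(unlist(u) >= 0 & unlist(u) <= 1))
})

test_that("beta/gamma constructors match method-of-moments oracles and round-trip", {
  ab <- beta_from_mean_se(0.5, 0.05)
  expect_equal(unname(ab), c(49.5, 49.5), tolerance = 1e-12)
  ab <- beta_from_mean_se(0.81, 0.0183)
  expect_equal(unname(ab), c(371.43, 87.13), tolerance = 1e-3)
  # round-trip: analytic mean/SD of the constructed distribution
  for (m in c(0.1, 0.5, 0.81, 0.97)) for (se in c(0.001, 0.02)) {
    ab <- beta_from_mean_se(m, se)
    a <- ab[["alpha"]]; b <- ab[["beta"]]
    expect_equal(a / (a + b), m, tolerance = 1e-9)
    expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), se, tolerance = 1e-9)
  }
  expect_error(beta_from_mean_se(0.5, 0.6), "too large")
  expect_error(beta_from_mean_se(1.2, 0.1), "mean")

  sh <- gamma_from_mean_se(403337.46, 40333.75)
  expect_equal(sh[["shape"]], 100.000018, tolerance = 1e-6)
  expect_equal(sh[["scale"]], 4033.374, tolerance = 1e-4)
  expect_equal(unname(gamma_from_mean_se(10, 1)), c(100, 0.1), tolerance = 1e-12)
  expect_equal(gamma_from_mean_se(7, 7)[["shape"]], 1)  # exponential case
  for (m in c(0.5, 100, 4e5)) for (se in c(0.01, 10)) {
    sh <- gamma_from_mean_se(m, se)
    expect_equal(sh[["shape"]] * sh[["scale"]], m, tolerance = 1e-9)
    expect_equal(sqrt(sh[["shape"]]) * sh[["scale"]], se, tolerance = 1e-9)
  }
  expect_error(gamma_from_mean_se(-1, 1), "mean")
})

test_that("lognormal constructor recovers the printed hazard-ratio CIs", {
  ms <- lognormal_from_ci(0.54, 0.32, 0.91)
  expect_equal(ms[["mu"]], -0.61619, tolerance = 1e-4)
  expect_equal(ms[["sigma"]], 0.26662, tolerance = 1e-4)
  # the implied 95% CI reproduces the printed bounds (within CI rounding)
  expect_equal(exp(ms[["mu"]] + c(-1, 1) * qnorm(0.975) * ms[["sigma"]]),
               c(0.32, 0.91), tolerance = 0.01)
  lo <- exp(log(0.54) - qnorm(0.975) * ms[["sigma"]])
  hi <- exp(log(0.54) + qnorm(0.975) * ms[["sigma"]])
  expect_equal(hi / lo, 0.91 / 0.32, tolerance = 1e-9)

  ms <- lognormal_from_ci(0.85, 0.60, 1.22)
  expect_equal(ms[["mu"]], -0.16252, tolerance = 1e-4)
  expect_equal(ms[["sigma"]], 0.18104, tolerance = 1e-4)
  expect_equal(unname(lognormal_from_ci(1, 1, 1)), c(0, 0))
  expect_error(lognormal_from_ci(0.5, -0.1, 1), "positive")
  expect_error(lognormal_from_ci(0.2, 0.3, 1), "ci_low")
})

test_that("validation names the offending key", {
  ps <- base_ps()
  bad <- ps; bad$values[["tp_lrr_met"]] <- 1.2
  expect_error(validate_parameter_set(bad), "tp_lrr_met")
  bad <- ps; bad$values[["u_met"]] <- -0.1
  expect_error(validate_parameter_set(bad), "u_met")
  bad <- ps; bad$values[["dmc_met"]] <- -5
  expect_error(validate_parameter_set(bad), "dmc_met")
  bad <- ps; bad$values[["share_event_met"]] <- 0.8
  expect_error(validate_parameter_set(bad), "share_event")
  bad <- ps; bad$values[["mort_80_84"]] <- 0.0001
  expect_error(validate_parameter_set(bad), "life_table")
  bad <- ps; bad$settings$horizon_age_years <- 40
  expect_error(validate_parameter_set(bad), "horizon")
  bad <- ps; bad$values <- ps$values[setdiff(names(ps$values), "tp_rem_met")]
  expect_error(validate_parameter_set(bad), "tp_rem_met")
})

test_that("configuration files round-trip through YAML, JSON and CSV tables", {
  ps <- base_ps()
  for (ext in c(".yaml", ".json")) {
    f <- withr::local_tempfile(fileext = ext)
    write_parameter_set(ps, f)
    ps2 <- load_parameter_set(f)
    expect_equal(ps2$values[names(ps$values)], ps$values)
    expect_equal(ps2$settings[order(names(ps2$settings))],
                 ps$settings[order(names(ps$settings))])
    expect_equal(ps2$epi[order(names(ps2$epi))],
                 ps$epi[order(names(ps$epi))])
  }

  # property: synthetic models survive the round trip too
  for (seed in 1:5) {
    m <- random_model(seed)
    f <- withr::local_tempfile(fileext = ".yaml")
    write_parameter_set(m, f)
    expect_equal(load_parameter_set(f)$values[names(m$values)], m$values,
                 tolerance = 1e-12)
  }

  # values may be outsourced to a CSV table
  dir <- withr::local_tempdir()
  write_parameter_set(ps, file.path(dir, "full.yaml"))
  doc <- yaml::read_yaml(file.path(dir, "full.yaml"))
  utils::write.csv(
    data.frame(name = names(doc$values), value = unlist(doc$values)),
    file.path(dir, "values.csv"), row.names = FALSE)
  doc$values <- NULL
  doc$values_csv <- "values.csv"
  yaml::write_yaml(doc, file.path(dir, "split.yaml"), precision = 15)
  ps3 <- load_parameter_set(file.path(dir, "split.yaml"))
  expect_equal(ps3$values[names(ps$values)], ps$values, tolerance = 1e-12)

  # out-of-range values are rejected with the offending key named
  bad <- ps; bad$values[["u_lrr"]] <- 1.2
  f <- withr::local_tempfile(fileext = ".yaml")
  expect_error(write_parameter_set(bad, f), "u_lrr")
  f3 <- withr::local_tempfile(fileext = ".yaml")
  write_parameter_set(ps, f3)
  doc3 <- yaml::read_yaml(f3)
  doc3$values$tp_met_death <- 1.2
  f4 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc3, f4, precision = 15)
  expect_error(load_parameter_set(f4), "tp_met_death")

  # a configuration without the life-table block is incomplete
  doc3$values$tp_met_death <- 0.04672
  doc3$values[grep("^mort_", names(doc3$values))] <- NULL
  doc3$dists <- Filter(function(r) !grepl("^mort_", r$name), doc3$dists)
  f5 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(doc3, f5, precision = 15)
  expect_error(load_parameter_set(f5), "life_table required")
})

test_that("packaged fixture files load to the base case", {
  for (f in c("base_case.yaml", "base_case.json")) {
    path <- system.file("extdata", f, package = "her2cea")
    expect_true(nzchar(path))
    ps <- load_parameter_set(path)
    expect_equal(ps$values[names(base_ps()$values)], base_ps()$values)
  }
})
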