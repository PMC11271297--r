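#!/usr/bin/env Rscript
# Budget impact analysis: five fiscal years, public healthcare system
# perspective, at 60% and 20% programme coverage.

suppressPackageStartupMessages(library(her2cea))
dir.create("results", showWarnings = FALSE)

ps <- base_case_parameters()

for (cov in c(0.60, 0.20)) {
  bia <- run_bia(ps, coverage = cov)
  tag <- sprintf("%.0f", 100 * cov)
  write_report_csv(bia, sprintf("results/bia_coverage%s.csv", tag), ps)
  tabs <- bia_table(bia)
  write_report_csv(tabs$incremental_lkr_millions,
                   sprintf("results/bia_incremental_lkr_m_coverage%s.csv", tag), ps)
  write_report_csv(tabs$budget_ratio,
                   sprintf("results/bia_ratio_coverage%s.csv", tag), ps)
  message(sprintf("\n== %s%% coverage: incremental budget vs S1, LKR millions ==", tag))
  print(tabs$incremental_lkr_millions, digits = 4)
}

b60 <- bia_table(run_bia(ps, coverage = 0.6))
message(sprintf(
  "\nYear-1 budget ratios vs S1 (coverage-invariant): %s",
  paste(sprintf("%s %.2f", b60$budget_ratio$strategy[-1],
                b60$budget_ratio$year1[-1]), collapse = ", ")))
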