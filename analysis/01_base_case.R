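#!/usr/bin/env Rscript
# Base-case cost-utility analysis: deterministic lifetime outcomes and costs
# for the five neoadjuvant/adjuvant HER2-targeted strategies, pairwise ICERs
# versus the comparator (S1, neoadjuvant TC + adjuvant T), and the
# ascending-cost incremental analysis, in both analysis perspectives.

suppressPackageStartupMessages(library(her2cea))
dir.create("results", showWarnings = FALSE)

ps <- base_case_parameters()
wtp <- ps$settings$wtp_lkr

for (persp in c("public", "societal")) {
  tab <- ce_table(ps, persp)
  write_report_csv(tab, sprintf("results/base_case_%s.csv", persp), ps)
  message(sprintf("\n== %s perspective (WTP LKR %s/QALY) ==",
                  persp, format(wtp, big.mark = ",")))
  print(tab[, c("strategy", "total_ly", "total_qaly", "total_cost_lkr",
                "icer_vs_comparator_lkr", "sequential_icer_lkr",
                "dominance")], digits = 4)
}

soc <- evaluate_strategies(ps, "societal")
ic3 <- icer(soc$S3, soc$S1)
message(sprintf(
  "\nLowest ICER: S3 vs S1 at LKR %s (USD %s) per QALY — %s the LKR %s threshold.",
  format(round(ic3$per_qaly), big.mark = ","),
  format(round(to_usd(ic3$per_qaly)), big.mark = ","),
  if (ic3$per_qaly <= wtp) "below" else "above",
  format(wtp, big.mark = ",")))
inc <- incremental_analysis(soc, wtp = wtp)
message(sprintf(
  "Incremental analysis: S2 vs next-least-costly (S5) at LKR %s per QALY gained.",
  format(round(inc$sequential_icer[inc$strategy == "S2"]), big.mark = ",")))
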