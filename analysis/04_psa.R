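#!/usr/bin/env Rscript
# Probabilistic sensitivity analysis: 1,000 Monte Carlo iterations, societal
# perspective. Exports the cost-effectiveness plane points (versus S1) and
# the cost-effectiveness acceptability curves over a willingness-to-pay grid.
#
# Usage: Rscript analysis/04_psa.R [--seed N] [--n N]

suppressPackageStartupMessages({library(her2cea); library(optparse)})
opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--n", type = "integer", default = 1000L))))
dir.create("results", showWarnings = FALSE)

ps <- base_case_parameters()
wtp <- ps$settings$wtp_lkr

psa <- run_psa(ps, n = opts$n, seed = opts$seed, perspective = "societal")
message(sprintf("%d iterations (seed %d); %d locoregional-exit draws renormalised",
                psa$n, psa$seed, psa$n_renormalised))

write_report_csv(psa$draws, "results/psa_draws.csv", ps, seed = opts$seed)

cp <- ce_plane(psa, reference = "S1")
write_report_csv(cp$points, "results/ce_plane.csv", ps, seed = opts$seed)
print(cp$quadrants[cp$quadrants$n > 0, ])

grid <- seq(0, 4e6, by = 5e4)
cc <- ceac(psa, grid)
write_report_csv(cc, "results/ceac.csv", ps, seed = opts$seed)

at_wtp <- cc[cc$wtp == wtp, ]
message(sprintf("\nAt the threshold (LKR %s/QALY):", format(wtp, big.mark = ",")))
for (i in seq_len(nrow(at_wtp)))
  message(sprintf("  P(%s most cost-effective) = %.1f%%",
                  at_wtp$strategy[i], 100 * at_wtp$probability[i]))
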