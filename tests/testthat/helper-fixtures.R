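# Shared fixtures, memoised so expensive model runs happen once per suite.

base_ps <- local({
  ps <- NULL
  function() {
    if (is.null(ps)) ps <<- base_case_parameters()
    ps
  }
})

base_results <- local({
  cache <- list()
  function(perspective = "public") {
    if (is.null(cache[[perspective]]))
      cache[[perspective]] <<- evaluate_strategies(base_ps(), perspective)
    cache[[perspective]]
  }
})

small_psa <- local({
  psa <- NULL
  function() {
    if (is.null(psa))
      psa <<- run_psa(base_ps(), n = 40, seed = 42, perspective = "societal")
    psa
  }
})

# hand-built econ_result stub for arithmetic tests
stub_result <- function(strategy, cost, qaly, ly = qaly / 0.8,
                        perspective = "public") {
  structure(list(strategy = strategy, perspective = perspective,
                 ly_discounted = ly, qaly_discounted = qaly,
                 cost_discounted = cost,
                 ly_undiscounted = ly, qaly_undiscounted = qaly,
                 cost_undiscounted = cost,
                 per_cycle_cost_stream = numeric(0)),
            class = "econ_result")
}
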