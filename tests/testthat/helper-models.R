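# Shared fixtures, built once per test run.

# maximum entropy model with rates (3, 3) and correlation 0.2
me33_rho02 <- fit_maxent(3, 3, 0.2)

# small explicit support used by the oracle fixtures
small_support <- function(K) {
  structure(list(max_x = as.integer(K), max_y = as.integer(K)),
            class = "truncated_support")
}

pmf_support_of <- function(p) small_support(max(nrow(p), ncol(p)) - 1L)

# quick annealing budget for tests that only need a valid (not maximally
# powerful) nuisance search
fast_anneal <- anneal_config(steps = 10L)
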