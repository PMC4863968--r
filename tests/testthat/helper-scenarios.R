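# Shared fixtures: the nine benchmark scenarios and random valid parameters.

benchmark_params <- function(name) {
  sc <- worked_scenarios()
  row <- sc[sc$name == name, ]
  list(params = model_params(row$sigma_I, row$alpha, row$beta),
       sigma_O0 = row$sigma_O0)
}

# Random interior parameter sets for property sweeps (away from the
# degenerate beta = 0 edge, which has dedicated tests).
random_params <- function(n, sigma_I = c(0.01, 0.99), rate = c(0.05, 5)) {
  lapply(seq_len(n), function(i)
    model_params(stats::runif(1, sigma_I[1], sigma_I[2]),
                 stats::runif(1, rate[1], rate[2]),
                 stats::runif(1, rate[1], rate[2])))
}
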