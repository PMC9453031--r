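# shared generator configurations for the simulation studies:
# a moderate-dispersion volume model (log-scale sd ~1.2) keeps the NIHSS
# floor/ceiling out of play so planted slopes are recoverable
recovery_volume <- function() {
  list(single = list(median = exp(2), iqr = 13.31),
       multiple = list(median = exp(2), iqr = 13.31))
}

flat_nihss <- function(a_s, a_m, b_s, b_m, sigma) {
  st <- list(alpha = c(single = a_s, multiple = a_m),
             beta = c(single = b_s, multiple = b_m), sigma = sigma)
  list(anterior = st, posterior = st, both = st)
}

recovery_config <- function(n, nihss,
                            mrs = list(alpha = c(single = -1, multiple = -1),
                                       beta = c(single = 0.8, multiple = 0.8))) {
  generator_config(n_patients = n, volume = recovery_volume(),
                   nihss = nihss, mrs = mrs,
                   missingness = list(severity = 0, wmh = 0, mrs = 0))
}

fast_spec <- function(model, seed) {
  hier_model_spec(model, chains = 2, draws = 1000, warmup = 500, seed = seed)
}
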