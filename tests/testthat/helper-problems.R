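# shared small fixtures, built in code

default_gel <- function(...) gel_params(...)

# a modest core/skin problem used across tests
small_problem <- function(G_ratio = 20, Pi_ext_over_G = 10,
                          R_in_frac = 0.7, ...) {
  drying_problem(G_ratio = G_ratio, Pi_ext_over_G = Pi_ext_over_G,
                 R_in_frac = R_in_frac, ...)
}

# random admissible local states for identity checks
random_states <- function(n, seed = 42) {
  set.seed(seed)
  data.frame(lambda_r = exp(stats::runif(n, -0.7, 0.7)),
             lambda_theta = exp(stats::runif(n, -0.7, 0.7)),
             p_liq = stats::runif(n, -2e5, 5e5))
}
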