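# shared fixtures, all built in code

# a well-conditioned LODE meal: 30 bites of 10 g, asymptote above the total
lode_case <- function(theta = 30, r = 0.15, emax = 330, n = 30, total = 300) {
  simulate_constant_bite(lode_params(theta, r, emax), n, total,
                         case_id = "lode_fix")
}

# a satiating quadratic meal whose vertex (200 g here for the defaults)
# lies above the total, so the whole ladder is invertible
quad_case <- function(a = -0.5, b = 20, c = 0, n = 25, total = 150) {
  simulate_constant_bite(quadratic_params(a, b, c), n, total,
                         case_id = "quad_fix")
}

# random valid LODE parameter sets for property-style loops
random_lode_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    lode_params(theta = exp(stats::runif(1, log(0.5), log(60))),
                r = stats::runif(1, 0.01, 1),
                emax = stats::runif(1, 100, 600)))
}

random_quadratic_params <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    quadratic_params(a = stats::runif(1, -2, -0.01),
                     b = stats::runif(1, 5, 50),
                     c = stats::runif(1, -5, 15)))
}

# small microstructure table for generator tests
small_profiles <- function(n = 60, seed = 7)
  sample_microstructure(reference_stats(), n, seed = seed)
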