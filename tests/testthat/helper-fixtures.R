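# Shared builders for the test suite. Everything is generated in code;
# seeds are fixed inside each test that draws random numbers.

default_rates <- function(sa = 0.97, gb = 0.20, g4 = 0.001,
                          rho = c(5.0, 2.3, 1.1, 1.05)) {
  vital_rates(s1 = mortality_ratio_to_survival(rho[1], sa),
              s2 = mortality_ratio_to_survival(rho[2], sa),
              s3 = mortality_ratio_to_survival(rho[3], sa),
              s4 = mortality_ratio_to_survival(rho[4], sa),
              sp = sa, sa = sa, g4 = g4, gp = gb, gb = gb)
}

random_state <- function(max_count = 200L) {
  as_sv <- function(x) do.call(stage_vector, as.list(x))
  counts <- stats::rpois(10L, lambda = stats::runif(10L, 5, max_count))
  names(counts) <- stage_names()
  as_sv(counts)
}

random_rates <- function() {
  p <- stats::runif(9L, 0.05, 0.99)
  vital_rates(s1 = p[1], s2 = p[2], s3 = p[3], s4 = p[4], sp = p[5],
              sa = p[6], g4 = p[7], gp = p[8], gb = p[9])
}

# a small fitted-model configuration used by several inference tests
small_fit_config <- function(ds, sc, n_iter = 3000L, n_burnin = 1000L,
                             thin = 5L, n_chains = 2L, seed = 1L) {
  pr <- priors_from_estimates(ds$estimates)
  ipm_config(years = sc$years, priors = pr,
             carcass = ds$carcass, surveys = ds$surveys,
             synoptic = ds$synoptic,
             n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
             thin = thin, seed = seed)
}
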