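# The joint density, the sampler machinery, convergence diagnostics,
# and posterior summaries.

make_tiny <- function(seed = 21, years = 2001:2005, N0 = 400) {
  sc <- truth_scenario(years = years, N0 = N0,
                       survey_years = years[c(length(years) - 1L,
                                              length(years))],
                       survey_sd_log = c(0.166, 0.132), seed = seed)
  simulate_dataset(sc)
}

test_that("compiled and reference joint densities agree", {
  ds <- make_tiny()
  sc <- ds$truth$scenario
  cfg <- small_fit_config(ds, sc)
  d <- manateeIPM:::build_cpp_data(cfg)
  set.seed(9)
  for (i in 1:10) {
    init <- manateeIPM:::ipm_initial_values(cfg)
    lp_cpp <- manateeIPM:::ipm_logpost_cpp(d, init$par, init$lat)
    lp_r <- ipm_log_joint(cfg, init$par, init$lat)
    expect_true(is.finite(lp_cpp))
    expect_equal(lp_cpp, lp_r, tolerance = 1e-10)
  }
})

test_that("the joint density matches a hand-assembled sum on a two-year model", {
  # smallest possible span: one transition, no data blocks except one
  # carcass year and one survey; every term written out directly
  cfg <- ipm_config(years = 2001:2002,
                    carcass = data.frame(year = 2001,
                                         stage = c("calf", "subadult", "adult"),
                                         count = c(1, 0, 2)),
                    surveys = data.frame(year = 2002, mu_log = log(300),
                                         sd_log = 0.2),
                    n_iter = 100, n_burnin = 10, thin = 1)
  d <- manateeIPM:::build_cpp_data(cfg)
  lay <- manateeIPM:::par_layout(1L)
  set.seed(15)
  init <- manateeIPM:::ipm_initial_values(cfg)
  par <- init$par; lat <- init$lat
  got <- ipm_log_joint(cfg, par, lat)

  n1 <- manateeIPM:::states_from_assignment(cfg, par, lat)[, 1]
  n2 <- manateeIPM:::states_from_assignment(cfg, par, lat)[, 2]
  sa <- plogis(par[lay$lsa]); gb <- plogis(par[lay$lgb])
  g4 <- plogis(par[lay$lg4]); rho <- exp(par[lay$lrho])
  s <- pmin(pmax(1 - rho * (1 - sa), 0), 1)
  sigma <- exp(par[lay$lsig])
  L <- lat[, 1]
  hand <- dnorm(par[lay$lsa], d$sa_mu, d$sa_sd, log = TRUE) +
    dnorm(par[lay$lgb], d$gb_mu, d$gb_sd, log = TRUE) +
    dnorm(par[lay$lg4], d$g4_mu, d$g4_sd, log = TRUE) +
    sum(dnorm(par[lay$lrho], d$rho_mu, d$rho_sd, log = TRUE)) +
    sum(dnorm(par[lay$a], 0, 2.5, log = TRUE)) +
    dnorm(par[lay$eps], 0, sigma, log = TRUE) +
    log(2) + dnorm(sigma, 0, 1.5, log = TRUE) + par[lay$lsig] +
    dnorm(par[lay$lN0], d$init_mu, d$init_sd, log = TRUE) +
    sum(d$dir_alpha * par[lay$w] - exp(par[lay$w]) - lgamma(d$dir_alpha)) +
    dbinom(L[1], n1["c"], s[1], log = TRUE) +
    dbinom(L[2], n1["f4"], s[4], log = TRUE) +
    dbinom(L[3], n1["p"], sa, log = TRUE) +
    dbinom(L[4], n1["c"], sa, log = TRUE) +
    dbinom(L[5], n1["b"], sa, log = TRUE) +
    dbinom(L[6], n1["m4"], s[4], log = TRUE) +
    dbinom(L[7], n1["ma"], sa, log = TRUE) +
    dbinom(L[8], L[2], g4, log = TRUE) +
    dbinom(L[9], L[3], gb, log = TRUE) +
    dbinom(L[10], L[5], gb, log = TRUE) +
    dbinom(L[11], L[1], 0.5, log = TRUE) +
    dbinom(L[12], n1["f2"], s[2], log = TRUE) +
    dbinom(L[13], n1["f3"], s[3], log = TRUE) +
    dbinom(L[14], n1["m2"], s[2], log = TRUE) +
    dbinom(L[15], n1["m3"], s[3], log = TRUE) +
    {
      M <- c((n1["c"] - L[1]) + (n1["f2"] - L[12]) + (n1["m2"] - L[14]),
             (n1["f3"] - L[13]) + (n1["m3"] - L[15]) +
               (n1["f4"] - L[2]) + (n1["m4"] - L[6]),
             (n1["p"] - L[3]) + (n1["c"] - L[4]) +
               (n1["b"] - L[5]) + (n1["ma"] - L[7]))
      r <- plogis(par[lay$a] + par[lay$eps])
      sum(dbinom(c(1, 0, 2), M, r, log = TRUE))
    } +
    dlnorm(sum(n2) + n2["c"], log(300), 0.2, log = TRUE)
  expect_equal(got, unname(hand), tolerance = 1e-10)
})

test_that("support violations give a log-density of -Inf", {
  ds <- make_tiny()
  sc <- ds$truth$scenario
  cfg <- small_fit_config(ds, sc)
  set.seed(9)
  init <- manateeIPM:::ipm_initial_values(cfg)
  # survivor count raised above its source stage
  lat_bad <- init$lat
  lat_bad[7, 2] <- lat_bad[7, 2] + 10000L
  expect_identical(ipm_log_joint(cfg, init$par, lat_bad), -Inf)
  d <- manateeIPM:::build_cpp_data(cfg)
  expect_identical(manateeIPM:::ipm_logpost_cpp(d, init$par, lat_bad), -Inf)
  # carcasses exceeding latent deaths in some year
  cfg2 <- cfg
  cfg2$carcass$count <- cfg2$carcass$count + 100000L
  expect_identical(ipm_log_joint(cfg2, init$par, init$lat), -Inf)
})

test_that("removing all data blocks leaves exactly the prior", {
  ds <- make_tiny()
  sc <- ds$truth$scenario
  cfg <- small_fit_config(ds, sc)
  prior_cfg <- ipm_config(years = sc$years, priors = cfg$priors,
                          n_iter = 100, n_burnin = 10, thin = 1)
  set.seed(12)
  init <- manateeIPM:::ipm_initial_values(prior_cfg)
  lay <- manateeIPM:::par_layout(length(sc$years) - 1L)
  d <- manateeIPM:::build_cpp_data(prior_cfg)
  lp <- ipm_log_joint(prior_cfg, init$par, init$lat)
  # prior + process only: subtracting the process terms leaves the prior
  n <- manateeIPM:::states_from_assignment(prior_cfg, init$par, init$lat)
  proc <- 0
  for (t in seq_len(ncol(init$lat))) {
    r <- manateeIPM:::rates_from_par(init$par, lay, t)
    Lt <- init$lat[, t]
    sizes <- c(n[5, t], n[3, t], n[4, t], n[5, t], n[6, t], n[9, t],
               n[10, t], Lt[2], Lt[3], Lt[5], Lt[1], n[1, t], n[2, t],
               n[7, t], n[8, t])
    probs <- c(r$s1, r$s4, r$sp, r$sa, r$sa, r$s4, r$sa, r$g4, r$gp,
               r$gb, 0.5, r$s2, r$s3, r$s2, r$s3)
    proc <- proc + sum(dbinom(Lt, sizes, probs, log = TRUE))
  }
  # with no data blocks the joint is the prior plus the process terms;
  # assemble the prior directly and compare
  sigma <- exp(init$par[lay$lsig])
  prior <- sum(dnorm(init$par[lay$lsa], d$sa_mu, d$sa_sd, log = TRUE)) +
    sum(dnorm(init$par[lay$lgb], d$gb_mu, d$gb_sd, log = TRUE)) +
    dnorm(init$par[lay$lg4], d$g4_mu, d$g4_sd, log = TRUE) +
    sum(dnorm(init$par[lay$lrho], d$rho_mu, d$rho_sd, log = TRUE)) +
    sum(dnorm(init$par[lay$a], d$a_mu, d$a_sd, log = TRUE)) +
    sum(dnorm(init$par[lay$eps], 0, sigma, log = TRUE)) +
    log(2) + dnorm(sigma, 0, d$sig_scale, log = TRUE) + init$par[lay$lsig] +
    dnorm(init$par[lay$lN0], d$init_mu, d$init_sd, log = TRUE) +
    sum(d$dir_alpha * init$par[lay$w] - exp(init$par[lay$w]) -
          lgamma(d$dir_alpha))
  expect_equal(lp - proc, prior, tolerance = 1e-9)
  expect_identical(d$C[1, 1], -1L)
  expect_identical(length(d$surv_idx), 0L)
})

test_that("an incomplete assignment is rejected with a helpful message", {
  ds <- make_tiny()
  cfg <- small_fit_config(ds, ds$truth$scenario)
  expect_error(ipm_log_joint(cfg, numeric(3), matrix(0L, 15, 4)),
               "lsa, lgb")
  set.seed(1)
  init <- manateeIPM:::ipm_initial_values(cfg)
  expect_error(ipm_log_joint(cfg, init$par, init$lat[, 1:2]), "15 x 4")
})

test_that("a short fit returns reproducible, support-valid draws", {
  ds <- make_tiny()
  sc <- ds$truth$scenario
  cfg <- small_fit_config(ds, sc, n_iter = 1500, n_burnin = 500,
                          thin = 2, n_chains = 2, seed = 77)
  fit1 <- ipm_fit(cfg)
  fit2 <- ipm_fit(cfg)
  expect_identical(fit1$chains, fit2$chains)
  m <- as_draw_matrix(fit1)
  expect_identical(nrow(m), 2L * 500L)
  # retained draws: probabilities in [0,1], counts integral & non-negative
  ty <- sc$years[-length(sc$years)]
  for (cn in c(paste0("sa[", ty[1], "]"), "g4", paste0("r_calf[", ty, "]"))) {
    expect_true(all(m[, cn] >= 0 & m[, cn] <= 1))
  }
  ncols <- grep("^n_", colnames(m), value = TRUE)
  expect_true(all(m[, ncols] >= 0))
  expect_true(all(m[, ncols] == round(m[, ncols])))
  # latent deaths never fall below observed carcasses
  for (s in c("calf", "subadult", "adult")) {
    for (y in ty) {
      obs <- ds$carcass$count[ds$carcass$year == y & ds$carcass$stage == s]
      expect_true(all(m[, paste0("M_", s, "[", y, "]")] >= obs))
    }
  }
})

test_that("with recovery fixed at one the deaths collapse to the carcass counts", {
  ds <- make_tiny(seed = 5)
  sc <- ds$truth$scenario
  # regenerate the observations in the noiseless limit so C = M is feasible
  obs <- generate_observations(ds$truth, noiseless = TRUE)
  cfg <- ipm_config(years = sc$years,
                    priors = priors_from_estimates(obs$estimates),
                    carcass = obs$carcass, surveys = obs$surveys,
                    n_chains = 1, n_iter = 1500, n_burnin = 500, thin = 2,
                    seed = 4, fix_recovery = 1)
  fit <- ipm_fit(cfg)
  m <- as_draw_matrix(fit)
  ty <- sc$years[-length(sc$years)]
  for (s in c("calf", "subadult", "adult")) {
    for (y in ty) {
      obs_c <- obs$carcass$count[obs$carcass$year == y &
                                   obs$carcass$stage == s]
      expect_true(all(m[, paste0("M_", s, "[", y, "]")] == obs_c))
    }
  }
})

test_that("the random-walk kernel reproduces a conjugate Beta posterior", {
  # one-binomial model: C ~ Bin(M, r), r ~ Beta(a, b); the closed form
  # posterior is Beta(a + C, b + M - C)
  M <- 50; C <- 37; a <- 2; b <- 2
  lp <- function(logit_r) {
    r <- plogis(logit_r)
    dbinom(C, M, r, log = TRUE) + dbeta(r, a, b, log = TRUE) +
      log(r) + log(1 - r)   # Jacobian of the logit transform
  }
  set.seed(101)
  draws <- plogis(rw_metropolis(lp, init = 0, scale = 0.4,
                                n_iter = 40000)[-(1:2000), 1])
  post_mean <- (a + C) / (a + b + M)
  mc_se <- sd(draws) / sqrt(length(draws) / 10)   # conservative ESS
  expect_lt(abs(mean(draws) - post_mean), 3 * mc_se)
})

test_that("Gelman-Rubin diagnostics separate mixed from unmixed chains", {
  set.seed(55)
  n <- 10000
  fake <- function(x1, x2) {
    structure(list(chains = list(cbind(theta = x1), cbind(theta = x2)),
                   years = integer(0)), class = "ipm_draws")
  }
  iid <- fake(rnorm(n), rnorm(n))
  expect_lt(check_convergence(iid)$psrf, 1.01)
  apart <- fake(rnorm(n), rnorm(n) + 10)
  expect_gt(check_convergence(apart)$psrf, 2)
  const <- fake(rep(1, n), rep(1, n))
  expect_true(is.na(check_convergence(const)$psrf))
  expect_error(check_convergence(structure(list(chains = iid$chains[1]),
                                           class = "ipm_draws")),
               "two chains")
})

test_that("posterior summaries use medians and the 95% central interval", {
  x <- cbind(q = c(1, 2, 3, 4, 5))
  s <- summarize_draws(x)
  expect_equal(s$median, 3)
  expect_equal(s$lo95, unname(quantile(1:5, 0.025)))
  expect_equal(s$hi95, unname(quantile(1:5, 0.975)))
  # invariant to chain concatenation order
  set.seed(8)
  a <- matrix(rnorm(2000), ncol = 2, dimnames = list(NULL, c("u", "v")))
  b <- a[sample(nrow(a)), ]
  expect_equal(summarize_draws(a)$median, summarize_draws(b)$median)
  # lognormal CV closed form
  y <- cbind(N = rlnorm(200000, 8.16, 0.132))
  cv <- summarize_draws(y)$cv
  expect_equal(cv, sqrt(exp(0.132^2) - 1), tolerance = 0.01)
})
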