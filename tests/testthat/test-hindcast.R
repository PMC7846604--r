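# Simulation-based hindcasts: back-projection, pooling, the lognormal
# prior fit, and the event-shifted structure.

test_that("back-projection under constant rates divides by the growth rate", {
  r <- default_rates()
  ss <- stable_stage_distribution(r)
  anchor <- ss$proportions * 3000 / (1 + ss$proportions[5])
  for (method in c("inverse", "eigen")) {
    bp <- backproject(anchor, rep(list(r), 6), method = method)
    expect_true(bp$valid)
    ratios <- bp$totals[-1] / bp$totals[-7]
    expect_true(all(abs(ratios - ss$lambda) < 1e-8))
  }
})

test_that("forward projection then exact back-projection is the identity", {
  set.seed(17)
  for (i in 1:5) {
    rates <- lapply(1:5, function(t) default_rates(
      sa = runif(1, 0.93, 0.98), gb = runif(1, 0.15, 0.35)))
    # start sex-symmetric (the two-sex expectation map collapses the
    # juvenile sex pairs, so only the pooled components are recoverable)
    h <- runif(3, 10, 100)
    x0 <- c(h[1], h[2], h[3], runif(1, 50, 300), runif(1, 50, 300),
            runif(1, 50, 300), h[1], h[2], h[3], runif(1, 200, 800))
    x <- x0
    for (t in 1:5) x <- as.vector(expectation_matrix(rates[[t]]) %*% x)
    bp <- backproject(x, rates)
    expect_true(bp$valid)
    expect_lt(max(abs(bp$states[, 1] - x0)), 1e-6)
  }
})

test_that("degenerate rates invalidate a run instead of failing", {
  r0 <- vital_rates(0, 0, 0, 0, 0, 0, 0, 0, 0)
  anchor <- rep(100, 10)
  bp <- backproject(anchor, list(r0))
  expect_false(bp$valid)
  expect_match(bp$reason, "singular")
  bp2 <- backproject(anchor, list(r0), method = "eigen")
  expect_false(bp2$valid)
})

test_that("pooled lognormal fit recovers known parameters and doubling gives the prior", {
  set.seed(29)
  runs <- rlnorm(5000, 7.38, 0.245)
  fit <- pool_and_fit_lognormal(runs)
  expect_lt(abs(fit$mu_log - 7.38), 3 * 0.245 / sqrt(5000))
  expect_lt(abs(fit$sd_log - 0.245), 3 * 0.245 / sqrt(2 * 5000))
  prior <- build_initial_abundance_prior(fit$mu_log, fit$sd_log)
  expect_equal(prior$meanlog, 7.38, tolerance = 0.02)
  expect_equal(prior$sdlog, 0.49, tolerance = 0.02)
  # order invariance and degenerate pools
  fit2 <- pool_and_fit_lognormal(rev(runs))
  expect_identical(fit$mu_log, fit2$mu_log)
  expect_error(pool_and_fit_lognormal(runs[1:50]), "too few")
  expect_error(pool_and_fit_lognormal(rep(2000, 200)), "degenerate")
})

test_that("event shifts depress the affected stages and renormalize", {
  ss <- stable_stage_distribution(default_rates())$proportions
  same <- event_shift_initial_structure(ss)
  expect_equal(unname(same), unname(ss), tolerance = 1e-12)
  shifted <- event_shift_initial_structure(
    ss, c(calf = 0.5, subadult = 0, adult = 0))
  expect_equal(sum(shifted), 1, tolerance = 1e-12)
  # second-year proportions halve before renormalization: their ratio
  # to any unaffected stage halves exactly
  expect_equal(shifted[1] / shifted[10], unname(0.5 * ss[1] / ss[10]),
               tolerance = 1e-12)
  # adult share strictly increases
  adult_ix <- c(4, 5, 6, 10)
  expect_gt(sum(shifted[adult_ix]), sum(ss[adult_ix]))
  expect_error(event_shift_initial_structure(ss, c(calf = 1, subadult = 0,
                                                   adult = 0)),
               "in \\[0, 1\\)")
})

test_that("hindcast ensembles pool into a usable initial prior", {
  sc <- truth_scenario(years = 2001:2012, N0 = 1500, seed = 31)
  ds <- simulate_dataset(sc)
  pr <- priors_from_estimates(ds$estimates)
  pr$rho <- default_mortality_ratio_priors()
  set.seed(33)
  est <- dist_spec("lognormal", meanlog = ds$surveys$mu_log[2],
                   sdlog = ds$surveys$sd_log[2])
  runs <- hindcast_ensemble(300, sc$years, est, pr)
  expect_gte(sum(runs$valid), 100)
  fit <- pool_and_fit_lognormal(runs)
  tot_true <- colSums(ds$truth$states) + ds$truth$states[5, ]
  # the pooled hindcast lognormal should place the true 2001 abundance
  # within its doubled-SD prior's central 95%
  prior <- build_initial_abundance_prior(fit$mu_log, fit$sd_log)
  q <- qlnorm(c(0.025, 0.975), prior$meanlog, prior$sdlog)
  expect_gt(tot_true[1], q[1])
  expect_lt(tot_true[1], q[2])
})

test_that("hindcasts can contradict carcass data and the check reports it", {
  # a hindcast with implausibly high juvenile survival implies fewer
  # deaths than carcasses actually recovered
  sc <- truth_scenario(years = 2001:2008, N0 = 1200, seed = 35)
  ds <- simulate_dataset(sc)
  rates <- lapply(1:7, function(t) default_rates(sa = 0.998, gb = 0.2,
                                                 rho = c(1, 1, 1, 1)))
  ss <- stable_stage_distribution(rates[[7]])$proportions
  anchor <- ss * 1200 / (1 + ss[5])
  bp <- backproject(anchor, rates, method = "eigen")
  chk <- hindcast_carcass_check(bp$states, rates, ds$carcass, sc$years)
  expect_true(any(chk$inconsistent))
  expect_true(all(c("year", "stage", "expected_deaths", "carcasses")
                  %in% names(chk)))
})
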