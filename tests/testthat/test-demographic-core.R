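# The stochastic projection process, its deterministic expectation, and
# death accounting.

test_that("no-mortality and complete-mortality projections are exact", {
  st <- stage_vector(f2 = 10, f3 = 9, f4 = 8, p = 30, c = 15, b = 40,
                     m2 = 10, m3 = 9, m4 = 8, ma = 60)
  # all survive, nobody breeds
  r1 <- vital_rates(1, 1, 1, 1, 1, 1, 0, 0, 0)
  set.seed(1)
  step <- project_one_year(st, r1)
  nxt <- step$state
  expect_identical(nxt[["c"]], 0L)
  expect_identical(nxt[["f2"]] + nxt[["m2"]], st[["c"]])
  expect_identical(nxt[["p"]], st[["f4"]] + st[["p"]])
  expect_identical(nxt[["b"]], st[["c"]] + st[["b"]])
  expect_identical(sum(deaths_by_coarse_stage(st, nxt, step$draws)), 0L)
  # nobody survives
  r0 <- vital_rates(0, 0, 0, 0, 0, 0, 0.5, 0.5, 0.5)
  step0 <- project_one_year(st, r0)
  expect_true(all(step0$state == 0L))
  d <- deaths_by_coarse_stage(st, step0$state, step0$draws)
  expect_identical(d[["calf"]], st[["c"]] + st[["f2"]] + st[["m2"]])
  expect_identical(d[["subadult"]],
                   st[["f3"]] + st[["m3"]] + st[["f4"]] + st[["m4"]])
  expect_identical(d[["adult"]],
                   st[["p"]] + st[["c"]] + st[["b"]] + st[["ma"]])
})

test_that("survival draws follow the exact binomial distribution", {
  # 10,000 replicate draws of S1 from a state with 20 mothers, s1 = 0.5,
  # compared with the closed-form binomial pmf by chi-square
  st <- stage_vector(c = 20)
  r <- vital_rates(s1 = 0.5, s2 = 1, s3 = 1, s4 = 1, sp = 1, sa = 1,
                   g4 = 0, gp = 0, gb = 0)
  set.seed(42)
  S1 <- replicate(10000, {
    step <- project_one_year(st, r)
    step$state[["f2"]] + step$state[["m2"]]  # = S1 (all survivors split)
  })
  obs <- tabulate(S1 + 1L, nbins = 21L)
  expected <- dbinom(0:20, 20, 0.5) * 10000
  keep <- expected > 5
  chisq <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_lt(chisq, qchisq(0.99, df = sum(keep) - 1L))
})

test_that("total abundance counts mothers-with-calf twice", {
  expect_identical(total_abundance(do.call(stage_vector,
                                           as.list(rep(1, 10)))), 11L)
  expect_identical(total_abundance(stage_vector()), 0L)
  set.seed(3)
  for (i in 1:20) {
    st <- random_state()
    expect_identical(total_abundance(st),
                     as.integer(sum(unclass(st)) + st[["c"]]))
  }
})

test_that("invalid rates and negative counts are rejected with the field named", {
  expect_error(vital_rates(1.2, 1, 1, 1, 1, 1, 0, 0, 0), "s1")
  expect_error(vital_rates(1, 1, 1, 1, 1, 1, 0, -0.1, 0), "gp")
  expect_error(stage_vector(f2 = -1), "f2")
})

test_that("expectation matrix matches the mean of stochastic projections", {
  r <- default_rates()
  A <- expectation_matrix(r)
  expect_true(all(dim(A) == c(10, 10)))
  st <- stage_vector(f2 = 60, f3 = 55, f4 = 50, p = 180, c = 150, b = 420,
                     m2 = 60, m3 = 55, m4 = 50, ma = 700)
  n_rep <- 50000
  set.seed(7)
  sims <- matrix(0, 10, n_rep)
  for (i in seq_len(n_rep)) sims[, i] <- project_one_year(st, r)$state
  mn <- rowMeans(sims)
  se <- apply(sims, 1, sd) / sqrt(n_rep)
  mu <- as.vector(A %*% as.numeric(st))
  expect_true(all(abs(mn - mu) <= 3 * pmax(se, 1e-9)))
})

test_that("expectation matrix limiting cases", {
  r0 <- vital_rates(0, 0, 0, 0, 0, 0, 0, 0, 0)
  expect_true(all(expectation_matrix(r0) == 0))
  # with no breeding, the column sums over survivor-receiving rows give
  # each stage's survival probability
  r <- vital_rates(0.8, 0.85, 0.9, 0.92, 0.95, 0.97, 0, 0, 0)
  A <- expectation_matrix(r)
  expect_equal(sum(A[c("f2", "m2"), "c"]) , 0.8)   # calf column via sexes
  expect_equal(sum(A[, "f2"]), 0.85)
  expect_equal(sum(A[, "f4"]), 0.92)
  expect_equal(sum(A[, "ma"]), 0.97)
})

test_that("stable stage distribution matches eigen-decomposition and long-run projection", {
  set.seed(11)
  for (i in 1:5) {
    r <- default_rates(sa = runif(1, 0.9, 0.98), gb = runif(1, 0.15, 0.4))
    ss <- stable_stage_distribution(r)
    expect_equal(sum(ss$proportions), 1, tolerance = 1e-12)
    e <- eigen(expectation_matrix(r))
    k <- which.max(abs(Re(e$values)))
    v <- abs(Re(e$vectors[, k]))
    expect_lt(max(abs(ss$proportions - v / sum(v))), 1e-10)
    expect_equal(ss$lambda, Re(e$values[k]), tolerance = 1e-10)
    # long-run projection of an arbitrary positive start vector; the
    # damping ratio of this life cycle is near 0.96, so convergence to
    # 1e-6 takes a few hundred years
    x <- runif(10, 1, 10)
    A <- expectation_matrix(r)
    for (y in 1:600) x <- as.vector(A %*% x) / sum(A %*% x)
    expect_lt(max(abs(x - ss$proportions)), 1e-6)
  }
})

test_that("deaths and survivors reconcile with the census totals", {
  # conservation: deaths = N[t] - N[t+1] + births for any simulated step
  set.seed(19)
  for (i in 1:1000) {
    st <- random_state(80L)
    r <- random_rates()
    step <- project_one_year(st, r)
    d <- deaths_by_coarse_stage(st, step$state, step$draws)
    births <- step$state[["c"]]
    expect_identical(sum(d),
                     total_abundance(st) - total_abundance(step$state) +
                       births)
  }
})

test_that("inconsistent projection triples are rejected", {
  st <- stage_vector(f2 = 5, c = 5)
  set.seed(2)
  step <- project_one_year(st, default_rates())
  bad <- step$draws
  bad[["S1"]] <- st[["c"]] + 3L   # more survivors than mothers
  expect_error(deaths_by_coarse_stage(st, step$state, bad),
               "inconsistent")
})

test_that("age-class structure sums to one and handles the bookkeeping", {
  st <- do.call(stage_vector, as.list(rep(1, 10)))
  expect_equal(age_class_structure(st),
               c(first = 1, second = 2, third = 2, fourth = 2, adult = 4) / 11)
  set.seed(5)
  for (i in 1:20) {
    p <- age_class_structure(random_state())
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  expect_error(age_class_structure(stage_vector()), "zero population")
})

test_that("stable structure under the estimated regime is adult-dominated", {
  # the adult age class (prebreeders, mothers, breeders, adult males)
  # holds well over 65% of the population at the estimated rates
  ss <- stable_stage_distribution(default_rates())
  st <- do.call(stage_vector, as.list(round(ss$proportions * 1e6)))
  expect_gt(age_class_structure(st)[["adult"]], 0.65)
})

test_that("sex symmetry and ergodic convergence of stage proportions", {
  r <- default_rates()
  A <- expectation_matrix(r)
  expect_equal(A["f2", ], A["m2", ])   # equal expected inflows by sex
  # two different positive structures converge under a shared random
  # rate sequence (weak ergodicity), measured by decreasing L1 distance
  set.seed(23)
  for (rep in 1:5) {
    rates <- lapply(1:15, function(i) default_rates(
      sa = runif(1, 0.9, 0.99), gb = runif(1, 0.1, 0.4)))
    x <- runif(10, 1, 100); y <- runif(10, 1, 100)
    d0 <- sum(abs(x / sum(x) - y / sum(y)))
    for (t in 1:15) {
      At <- expectation_matrix(rates[[t]])
      x <- as.vector(At %*% x); y <- as.vector(At %*% y)
    }
    d1 <- sum(abs(x / sum(x) - y / sum(y)))
    expect_lt(d1, d0)
  }
})
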