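# Generation of complete synthetic datasets with the statistical
# structure the integrated model assumes: a true trajectory from the
# stochastic projection process, carcass counts thinned by recovery
# probabilities, vital-rate "estimates" equal to truth plus link-scale
# noise, sparse lognormal abundance "surveys", and synoptic undercounts.

#' Define a truth scenario
#'
#' The scenario fixes the data-generating conditions: a 20-year span
#' with a population in the low thousands growing slowly (adult
#' survival near 0.97, breeding probability near 0.20, giving lambda
#' close to 1.02), abundance surveys in relative years 15 and 20 only
#' (mirroring the sparse-survey monitoring design), and optional event
#' years in which survival drops sharply, emulating an intense red tide
#' or a severe winter.
#'
#' @param years Census years (default 1997:2016).
#' @param N0 Initial total abundance (default 2500).
#' @param sa_mean,sa_sd Adult survival: mean probability and SD of the
#'   yearly logit-scale variation.
#' @param gb_mean,gb_sd Adult breeding probability, same convention.
#' @param rho True mortality ratios for stages 1-4.
#' @param g4 True fourth-year breeding probability.
#' @param alpha True recovery intercepts (logit), named by coarse stage.
#' @param sigma_r SD of the yearly recovery random effect.
#' @param event_years Integer years with depressed survival.
#' @param event_sa_drop,event_calf_drop Probability-scale drops applied
#'   in event years to adult and first/second-year survival.
#' @param survey_years Years with an abundance survey (defaults to
#'   relative years 15 and 20).
#' @param survey_sd_log Survey lognormal SDs for those years.
#' @param estimate_sd Link-scale SD of the vital-rate estimate noise
#'   (also used as the prior SD handed to the fitting step).
#' @param synoptic_availability Expected fraction of animals counted in
#'   a synoptic survey.
#' @param seed Seed for the truth simulation.
#' @return List of class `truth_scenario`.
#' @export
truth_scenario <- function(years = 1997:2016, N0 = 2500,
                           sa_mean = 0.97, sa_sd = 0.25,
                           gb_mean = 0.20, gb_sd = 0.20,
                           rho = c(5.0, 2.3, 1.1, 1.05), g4 = 0.001,
                           alpha = c(calf = stats::qlogis(0.67),
                                     subadult = stats::qlogis(0.948),
                                     adult = stats::qlogis(0.971)),
                           sigma_r = 0.7,
                           event_years = integer(0),
                           event_sa_drop = 0.08, event_calf_drop = 0.30,
                           survey_years = NULL, survey_sd_log = NULL,
                           estimate_sd = 0.15,
                           synoptic_availability = 0.5,
                           seed = 1L) {
  years <- as.integer(years)
  if (is.null(survey_years)) {
    survey_years <- years[c(min(15L, length(years)), length(years))]
  }
  if (is.null(survey_sd_log)) {
    survey_sd_log <- c(0.166, 0.132)[seq_along(survey_years)]
  }
  if (!all(event_years %in% years[-length(years)])) {
    stop("event years must fall on transition years within the span")
  }
  structure(list(years = years, N0 = N0, sa_mean = sa_mean, sa_sd = sa_sd,
                 gb_mean = gb_mean, gb_sd = gb_sd, rho = rho, g4 = g4,
                 alpha = alpha, sigma_r = sigma_r,
                 event_years = as.integer(event_years),
                 event_sa_drop = event_sa_drop,
                 event_calf_drop = event_calf_drop,
                 survey_years = as.integer(survey_years),
                 survey_sd_log = survey_sd_log,
                 estimate_sd = estimate_sd,
                 synoptic_availability = synoptic_availability,
                 seed = as.integer(seed)),
            class = "truth_scenario")
}

#' Simulate the latent truth of a scenario
#'
#' Draws the year-specific true vital rates, realizes the initial
#' census at the stable structure, and chains the stochastic projection
#' across the span, recording every census, the intermediate draws, and
#' the deaths by coarse stage. Deterministic given the scenario seed.
#'
#' @param scenario A `truth_scenario`.
#' @return List with `states` (10 x T matrix), `rates` (list per
#'   transition), `draws`, `deaths` (3 x (T-1) matrix), `eps`
#'   (recovery year effects), `recovery` (3 x (T-1) true recovery
#'   probabilities), and `scenario`.
#' @export
generate_truth <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  years <- sc$years
  T <- length(years)
  T1 <- T - 1L
  ty <- years[-T]
  sa <- stats::plogis(stats::rnorm(T1, stats::qlogis(sc$sa_mean), sc$sa_sd))
  gb <- stats::plogis(stats::rnorm(T1, stats::qlogis(sc$gb_mean), sc$gb_sd))
  ev <- ty %in% sc$event_years
  sa[ev] <- pmax(sa[ev] - sc$event_sa_drop, 0.01)
  rates <- lapply(seq_len(T1), function(t) {
    s1 <- mortality_ratio_to_survival(sc$rho[1L], sa[t])
    s2 <- mortality_ratio_to_survival(sc$rho[2L], sa[t])
    if (ev[t]) {
      s1 <- max(s1 - sc$event_calf_drop, 0.01)
      s2 <- max(s2 - sc$event_calf_drop, 0.01)
    }
    vital_rates(s1 = s1, s2 = s2,
                s3 = mortality_ratio_to_survival(sc$rho[3L], sa[t]),
                s4 = mortality_ratio_to_survival(sc$rho[4L], sa[t]),
                sp = sa[t], sa = sa[t],
                g4 = sc$g4, gp = gb[t], gb = gb[t], year = ty[t])
  })
  ss <- stable_stage_distribution(rates[[1L]])$proportions
  state <- as_stage_vector(allocate_counts(sc$N0, ss), year = years[1L])
  states <- matrix(0L, 10L, T, dimnames = list(stage_names(), years))
  states[, 1L] <- state
  draws <- vector("list", T1)
  deaths <- matrix(0L, 3L, T1, dimnames = list(COARSE_STAGES, ty))
  for (t in seq_len(T1)) {
    step <- project_one_year(state, rates[[t]])
    draws[[t]] <- step$draws
    deaths[, t] <- deaths_by_coarse_stage(state, step$state, step$draws)
    state <- step$state
    states[, t + 1L] <- state
    if (total_abundance(state) == 0L) {
      stop("population went extinct in simulated year ", years[t + 1L],
           "; scenario rejected")
    }
  }
  eps <- stats::rnorm(T1, 0, sc$sigma_r)
  recovery <- rbind(calf = stats::plogis(sc$alpha[["calf"]] + eps),
                    subadult = stats::plogis(sc$alpha[["subadult"]] + eps),
                    adult = stats::plogis(sc$alpha[["adult"]] + eps))
  colnames(recovery) <- ty
  list(states = states, rates = rates, draws = draws, deaths = deaths,
       sa = sa, gb = gb, eps = eps, recovery = recovery, scenario = sc)
}

#' Generate the observed data streams from a simulated truth
#'
#' Thins the true deaths into carcass counts, perturbs the true vital
#' rates into link-scale "estimates", produces lognormal abundance
#' surveys in the scenario's survey years, and draws synoptic
#' undercounts.
#'
#' @param truth Output of [generate_truth()].
#' @param estimate_sd Link-scale estimate noise SD (default from the
#'   scenario).
#' @param noiseless Set `TRUE` for the noise-free limit: recovery 1,
#'   estimate noise 0, surveys centred exactly on the true abundance.
#' @return List with `carcass`, `estimates`, `surveys`, `synoptic`
#'   (tidy data frames) and `truth`.
#' @export
generate_observations <- function(truth, estimate_sd = NULL,
                                  noiseless = FALSE) {
  sc <- truth$scenario
  if (is.null(estimate_sd)) estimate_sd <- sc$estimate_sd
  years <- sc$years
  T <- length(years)
  ty <- years[-T]
  T1 <- T - 1L
  tot <- colSums(truth$states) + truth$states[5L, ]

  r <- if (noiseless) matrix(1, 3L, T1) else truth$recovery
  C <- matrix(0L, 3L, T1)
  for (s in 1:3) {
    C[s, ] <- stats::rbinom(T1, truth$deaths[s, ], r[s, ])
  }
  carcass <- data.frame(year = rep(ty, each = 3L),
                        stage = rep(COARSE_STAGES, T1),
                        count = as.integer(C[cbind(rep(1:3, T1),
                                                   rep(seq_len(T1), each = 3L))]))

  noise_sd <- if (noiseless) 0 else estimate_sd
  sa_est <- stats::qlogis(truth$sa) + stats::rnorm(T1, 0, noise_sd)
  gb_est <- stats::qlogis(truth$gb) + stats::rnorm(T1, 0, noise_sd)
  estimates <- rbind(
    data.frame(year = ty, parameter = "sa", link = "logit",
               mean = sa_est, sd = max(noise_sd, 1e-6)),
    data.frame(year = ty, parameter = "gb", link = "logit",
               mean = gb_est, sd = max(noise_sd, 1e-6)))

  sy <- sc$survey_years
  sdl <- sc$survey_sd_log
  mu <- log(tot[as.character(sy)])
  if (!noiseless) mu <- mu + stats::rnorm(length(sy), 0, sdl)
  surveys <- data.frame(year = sy, mu_log = mu, sd_log = sdl)

  syn_bound <- if (noiseless) as.integer(tot) else
    stats::rbinom(T, round(tot), sc$synoptic_availability)
  synoptic <- data.frame(year = years, bound = as.integer(syn_bound))

  list(carcass = carcass, estimates = estimates, surveys = surveys,
       synoptic = synoptic, truth = truth)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: truth plus observations in the exact formats
#' [ipm_config()] consumes.
#'
#' @param scenario A `truth_scenario` (default scenario if omitted).
#' @param ... Passed to [generate_observations()].
#' @return The [generate_observations()] list.
#' @export
simulate_dataset <- function(scenario = truth_scenario(), ...) {
  generate_observations(generate_truth(scenario), ...)
}

#' Tiny five-year fixture dataset for unit tests and examples
#'
#' @param seed Seed.
#' @return A [simulate_dataset()] list over a 5-year span with a small
#'   population.
#' @export
fixture_dataset <- function(seed = 42L) {
  sc <- truth_scenario(years = 2001:2005, N0 = 400,
                       survey_years = c(2003L, 2005L),
                       survey_sd_log = c(0.166, 0.132), seed = seed)
  simulate_dataset(sc)
}
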