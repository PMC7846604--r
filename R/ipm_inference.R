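# Assembly of the joint posterior over parameters and latent stage
# trajectories, the Metropolis-within-Gibbs sampler (hot loop in C++),
# convergence diagnostics, and posterior summaries.
#
# Parameter vector layout (shared with src/ipm_sampler.cpp), T1 = T - 1
# transitions:
#   lsa[1..T1]   logit adult survival per transition year
#   lgb[1..T1]   logit adult breeding probability per transition year
#   lg4          logit fourth-year breeding probability (constant)
#   lrho[1..4]   log mortality ratios (stage : adult)
#   a[1..3]      recovery intercepts (logit), calf/subadult/adult
#   eps[1..T1]   recovery year random effects
#   lsig         log SD of the year random effects
#   lN0          log initial total abundance
#   w[1..10]     log-gamma representation of initial stage proportions
# Latent matrix: 15 x T1 integer draws per transition, rows
#   S1, Sf4, Sp, Sc, Sb, Sm4, Sma, G4, Gp, Gb, Nf2', Nf3', Nf4', Nm3', Nm4'

LATENT_ROWS <- c("S1", "Sf4", "Sp", "Sc", "Sb", "Sm4", "Sma",
                 "G4", "Gp", "Gb", "Nf2n", "Nf3n", "Nf4n", "Nm3n", "Nm4n")

#' @keywords internal
par_layout <- function(T1) {
  list(lsa = seq_len(T1),
       lgb = T1 + seq_len(T1),
       lg4 = 2L * T1 + 1L,
       lrho = 2L * T1 + 1L + 1:4,
       a = 2L * T1 + 5L + 1:3,
       eps = 2L * T1 + 8L + seq_len(T1),
       lsig = 3L * T1 + 9L,
       lN0 = 3L * T1 + 10L,
       w = 3L * T1 + 10L + 1:10,
       n_par = 3L * T1 + 20L)
}

#' Assemble a model configuration
#'
#' Bundles the year span, every prior the model uses, the data blocks,
#' and the sampler settings. Any data block may be `NULL`, in which case
#' the corresponding likelihood term is dropped (a run with all blocks
#' `NULL` samples the prior).
#'
#' @param years Integer vector of census years (contiguous); vital rates
#'   apply to the transitions between them.
#' @param priors List with elements `sa` and `gb` (data frames with
#'   columns `year`, `mean`, `sd` on the logit scale, one row per
#'   transition year), `g4` (`dist_spec`), `rho` (list of four lognormal
#'   `dist_spec`s), `alpha` (c(mean, sd) normal prior for the recovery
#'   intercepts), `sigma_r` (half-normal scale for the year-effect SD),
#'   `init_abundance` (lognormal `dist_spec`), `init_structure`
#'   (Dirichlet `dist_spec` over the ten stages). Missing elements fall
#'   back to [default_priors()].
#' @param carcass Data frame `year`, `stage`, `count`, or `NULL`.
#' @param surveys Data frame `year`, `mu_log`, `sd_log`, or `NULL`.
#' @param synoptic Data frame `year`, `bound`, or `NULL`.
#' @param n_chains,n_iter,n_burnin,thin,seed Sampler settings.
#' @param fix_recovery `NA` to estimate recovery probabilities, or a
#'   fixed probability applied to all stages and years.
#' @param use_synoptic Set `FALSE` to ignore synoptic bounds.
#' @return List of class `ipm_config`.
#' @export
ipm_config <- function(years, priors = list(), carcass = NULL,
                       surveys = NULL, synoptic = NULL,
                       n_chains = 3L, n_iter = 60000L, n_burnin = 20000L,
                       thin = 10L, seed = 1L, fix_recovery = NA,
                       use_synoptic = TRUE) {
  years <- as.integer(years)
  if (length(years) < 2L || any(diff(years) != 1L)) {
    stop("`years` must be a contiguous span of at least two census years")
  }
  if (n_iter <= n_burnin) stop("n_iter must exceed n_burnin")
  if (thin < 1L) stop("thin must be >= 1")
  def <- default_priors(years)
  for (nm in names(def)) if (is.null(priors[[nm]])) priors[[nm]] <- def[[nm]]
  cfg <- list(years = years, priors = priors,
              carcass = carcass, surveys = surveys,
              synoptic = if (use_synoptic) synoptic else NULL,
              sampler = list(n_chains = as.integer(n_chains),
                             n_iter = as.integer(n_iter),
                             n_burnin = as.integer(n_burnin),
                             thin = as.integer(thin),
                             seed = as.integer(seed)),
              fix_recovery = fix_recovery)
  class(cfg) <- "ipm_config"
  cfg
}

#' Default priors for a year span
#'
#' Weakly-to-moderately informative defaults used when a prior block is
#' not supplied: adult survival centred near 0.97 and breeding
#' probability near 0.20 on the logit scale (jointly implying long-run
#' growth close to 1.02), the packaged mortality-ratio
#' and fourth-year reproduction priors, a Normal(0, 2.5^2) prior on the
#' recovery intercepts, a half-Normal(1.5) hyperprior for the recovery
#' year-effect SD, the doubled-SD lognormal initial-abundance prior, and
#' a variance-inflated Dirichlet around the stable stage structure.
#'
#' @param years Census years of the model span.
#' @return Named list of prior blocks (see [ipm_config()]).
#' @export
default_priors <- function(years) {
  ty <- years[-length(years)]
  sa <- data.frame(year = ty, mean = stats::qlogis(0.97), sd = 0.15)
  gb <- data.frame(year = ty, mean = stats::qlogis(0.20), sd = 0.15)
  rho <- default_mortality_ratio_priors()
  rates <- vital_rates(s1 = mortality_ratio_to_survival(5.0, 0.97),
                       s2 = mortality_ratio_to_survival(2.3, 0.97),
                       s3 = mortality_ratio_to_survival(1.1, 0.97),
                       s4 = mortality_ratio_to_survival(1.05, 0.97),
                       sp = 0.97, sa = 0.97,
                       g4 = 0.001, gp = 0.20, gb = 0.20)
  ss <- stable_stage_distribution(rates)$proportions
  base_alpha <- ss * 100
  list(sa = sa, gb = gb, g4 = default_g4_prior(), rho = rho,
       alpha = c(mean = 0, sd = 2.5), sigma_r = 1.5,
       init_abundance = build_initial_abundance_prior(7.38, 0.245),
       init_structure = dist_spec(
         "dirichlet", alpha = inflate_dirichlet_variance(base_alpha, 4)))
}

#' @keywords internal
build_cpp_data <- function(config) {
  years <- config$years
  T <- length(years)
  T1 <- T - 1L
  ty <- years[-T]
  pr <- config$priors
  get_prior_df <- function(df, what) {
    idx <- match(ty, df$year)
    if (anyNA(idx)) {
      stop("missing `", what, "` prior for year(s): ",
           paste(ty[is.na(idx)], collapse = ", "))
    }
    df[idx, , drop = FALSE]
  }
  sa <- get_prior_df(pr$sa, "sa")
  gb <- get_prior_df(pr$gb, "gb")
  C <- matrix(-1L, 3L, T1)
  if (!is.null(config$carcass)) {
    cc <- config$carcass
    for (i in seq_len(nrow(cc))) {
      t <- match(cc$year[i], ty)
      s <- match(cc$stage[i], COARSE_STAGES)
      if (is.na(t) || is.na(s)) next
      if (C[1L, t] < 0L) C[, t] <- 0L
      C[s, t] <- as.integer(cc$count[i])
    }
  }
  surv_idx <- integer(0); surv_mu <- numeric(0); surv_sd <- numeric(0)
  if (!is.null(config$surveys)) {
    sv <- config$surveys
    keep <- sv$year %in% years
    surv_idx <- match(sv$year[keep], years) - 1L
    surv_mu <- sv$mu_log[keep]
    surv_sd <- sv$sd_log[keep]
  }
  syn <- numeric(T)
  if (!is.null(config$synoptic)) {
    sy <- config$synoptic
    idx <- match(sy$year, years)
    ok <- !is.na(idx)
    syn[idx[ok]] <- sy$bound[ok]
  }
  rho_mu <- vapply(pr$rho, function(s) s$meanlog, 0.0)
  rho_sd <- vapply(pr$rho, function(s) s$sdlog, 0.0)
  list(T = T,
       sa_mu = sa$mean, sa_sd = sa$sd,
       gb_mu = gb$mean, gb_sd = gb$sd,
       g4_mu = pr$g4$mean, g4_sd = pr$g4$sd,
       rho_mu = unname(rho_mu), rho_sd = unname(rho_sd),
       a_mu = unname(pr$alpha[["mean"]]), a_sd = unname(pr$alpha[["sd"]]),
       sig_scale = pr$sigma_r,
       init_mu = pr$init_abundance$meanlog,
       init_sd = pr$init_abundance$sdlog,
       dir_alpha = unname(pr$init_structure$alpha),
       C = C,
       surv_idx = as.integer(surv_idx), surv_mu = surv_mu, surv_sd = surv_sd,
       syn_bound = syn,
       r_fixed = if (is.na(config$fix_recovery)) -1.0
                 else as.numeric(config$fix_recovery))
}

#' Rebuild the census trajectory implied by a parameter/latent state
#' @keywords internal
states_from_assignment <- function(config, par, lat) {
  T <- length(config$years)
  T1 <- T - 1L
  lay <- par_layout(T1)
  g <- exp(par[lay$w])
  p <- g / sum(g)
  n <- matrix(0L, 10L, T, dimnames = list(stage_names(), config$years))
  n[, 1L] <- allocate_counts(exp(par[lay$lN0]), p)
  for (t in seq_len(T1)) {
    Lt <- lat[, t]
    n[, t + 1L] <- c(Lt[11L], Lt[12L], Lt[13L],
                     (Lt[2L] - Lt[8L]) + (Lt[3L] - Lt[9L]),
                     Lt[8L] + Lt[9L] + Lt[10L],
                     Lt[4L] + (Lt[5L] - Lt[10L]),
                     Lt[1L] - Lt[11L],
                     Lt[14L], Lt[15L],
                     Lt[6L] + Lt[7L])
  }
  n
}

#' @keywords internal
rates_from_par <- function(par, lay, t) {
  sa <- stats::plogis(par[lay$lsa[t]])
  rho <- exp(par[lay$lrho])
  gb <- stats::plogis(par[lay$lgb[t]])
  list(s1 = mortality_ratio_to_survival(rho[1L], sa),
       s2 = mortality_ratio_to_survival(rho[2L], sa),
       s3 = mortality_ratio_to_survival(rho[3L], sa),
       s4 = mortality_ratio_to_survival(rho[4L], sa),
       sp = sa, sa = sa,
       g4 = stats::plogis(par[lay$lg4]), gp = gb, gb = gb)
}

#' Joint log-density of the integrated model
#'
#' Reference implementation in plain R of the full joint density the
#' sampler targets: prior terms, the binomial projection process at
#' every transition, and the carcass, abundance-survey, and synoptic
#' likelihoods. Returns `-Inf` for any support violation (a survivor
#' count exceeding its source stage, more carcasses than deaths, or an
#' abundance below a synoptic bound).
#'
#' @param config An `ipm_config`.
#' @param par Parameter vector in the documented layout.
#' @param lat 15 x (T-1) integer matrix of latent binomial outcomes.
#' @return Scalar log-density.
#' @export
ipm_log_joint <- function(config, par, lat) {
  d <- build_cpp_data(config)
  T <- d$T; T1 <- T - 1L
  lay <- par_layout(T1)
  if (length(par) != lay$n_par) {
    stop("parameter vector has length ", length(par),
         "; the model needs the blocks lsa, lgb, lg4, lrho, a, eps, ",
         "lsig, lN0, w (", lay$n_par, " values for this span)")
  }
  if (!is.matrix(lat) || nrow(lat) != 15L || ncol(lat) != T1) {
    stop("latent matrix must be 15 x ", T1)
  }
  n <- states_from_assignment(config, par, lat)
  if (any(n < 0)) return(-Inf)

  # priors
  lp <- sum(stats::dnorm(par[lay$lsa], d$sa_mu, d$sa_sd, log = TRUE)) +
    sum(stats::dnorm(par[lay$lgb], d$gb_mu, d$gb_sd, log = TRUE)) +
    stats::dnorm(par[lay$lg4], d$g4_mu, d$g4_sd, log = TRUE) +
    sum(stats::dnorm(par[lay$lrho], d$rho_mu, d$rho_sd, log = TRUE)) +
    sum(stats::dnorm(par[lay$a], d$a_mu, d$a_sd, log = TRUE))
  sigma <- exp(par[lay$lsig])
  lp <- lp + sum(stats::dnorm(par[lay$eps], 0, sigma, log = TRUE)) +
    log(2) + stats::dnorm(sigma, 0, d$sig_scale, log = TRUE) + par[lay$lsig] +
    stats::dnorm(par[lay$lN0], d$init_mu, d$init_sd, log = TRUE) +
    sum(d$dir_alpha * par[lay$w] - exp(par[lay$w]) - lgamma(d$dir_alpha))

  # process + data, year by year
  for (t in seq_len(T1)) {
    r <- rates_from_par(par, lay, t)
    Lt <- lat[, t]
    sizes <- c(n[5L, t], n[3L, t], n[4L, t], n[5L, t], n[6L, t],
               n[9L, t], n[10L, t], Lt[2L], Lt[3L], Lt[5L],
               Lt[1L], n[1L, t], n[2L, t], n[7L, t], n[8L, t])
    probs <- c(r$s1, r$s4, r$sp, r$sa, r$sa, r$s4, r$sa,
               r$g4, r$gp, r$gb, 0.5, r$s2, r$s3, r$s2, r$s3)
    lp <- lp + sum(lbinom_safe(as.numeric(Lt), as.numeric(sizes), probs))
    if (d$C[1L, t] >= 0L) {
      M <- c(calf = (n[5L, t] - Lt[1L]) + (n[1L, t] - Lt[12L]) +
               (n[7L, t] - Lt[14L]),
             subadult = (n[2L, t] - Lt[13L]) + (n[8L, t] - Lt[15L]) +
               (n[3L, t] - Lt[2L]) + (n[9L, t] - Lt[6L]),
             adult = (n[4L, t] - Lt[3L]) + (n[5L, t] - Lt[4L]) +
               (n[6L, t] - Lt[5L]) + (n[10L, t] - Lt[7L]))
      rr <- if (d$r_fixed >= 0) rep(d$r_fixed, 3L) else
        stats::plogis(par[lay$a] + par[lay$eps[t]])
      lp <- lp + sum(lbinom_safe(as.numeric(d$C[, t]), as.numeric(M), rr))
    }
  }
  tot <- colSums(n) + n[5L, ]
  for (j in seq_along(d$surv_idx)) {
    y <- d$surv_idx[j] + 1L
    lp <- lp + if (tot[y] > 0) {
      stats::dlnorm(tot[y], d$surv_mu[j], d$surv_sd[j], log = TRUE)
    } else -Inf
  }
  if (any(d$syn_bound > 0 & tot < d$syn_bound)) lp <- -Inf
  unname(lp)
}

#' Support-valid initial values for one chain
#'
#' Draws parameters from their priors, forward-simulates the latent
#' trajectory, and repairs any year in which recovered carcasses exceed
#' implied deaths by minimally lowering the implicated survivor counts.
#' If a deficit cannot be repaired the initial abundance is inflated and
#' the simulation retried.
#'
#' @param config An `ipm_config`.
#' @return List with `par` and `lat` in the sampler layout.
#' @keywords internal
ipm_initial_values <- function(config) {
  d <- build_cpp_data(config)
  T <- d$T; T1 <- T - 1L
  lay <- par_layout(T1)
  inflate <- 0
  for (attempt in seq_len(25L)) {
    par <- numeric(lay$n_par)
    par[lay$lsa] <- stats::rnorm(T1, d$sa_mu, d$sa_sd)
    par[lay$lgb] <- stats::rnorm(T1, d$gb_mu, d$gb_sd)
    par[lay$lg4] <- stats::rnorm(1, d$g4_mu, min(d$g4_sd, 1))
    par[lay$lrho] <- stats::rnorm(4, d$rho_mu, d$rho_sd)
    par[lay$a] <- stats::rnorm(3, 2, 0.5)
    par[lay$eps] <- stats::rnorm(T1, 0, 0.1)
    par[lay$lsig] <- log(stats::runif(1, 0.2, 0.8))
    par[lay$lN0] <- stats::rnorm(1, d$init_mu, 0.1) + inflate
    par[lay$w] <- log(stats::rgamma(10, shape = d$dir_alpha, rate = 1) + 1e-8)
    # aim the simulated trajectory's growth at the latest survey: shift
    # all breeding logits so the asymptotic growth rate at mean rates
    # matches the growth needed to reach it from the initial level
    if (length(d$surv_idx)) {
      j <- which.max(d$surv_idx)
      span <- d$surv_idx[j]           # transitions to the survey year
      if (span >= 3L) {
        target <- exp((d$surv_mu[j] - par[lay$lN0]) / span)
        lam_at <- function(delta) {
          sa_bar <- stats::plogis(mean(d$sa_mu))
          gb_bar <- stats::plogis(mean(d$gb_mu) + delta)
          rates <- vital_rates(
            s1 = mortality_ratio_to_survival(exp(d$rho_mu[1]), sa_bar),
            s2 = mortality_ratio_to_survival(exp(d$rho_mu[2]), sa_bar),
            s3 = mortality_ratio_to_survival(exp(d$rho_mu[3]), sa_bar),
            s4 = mortality_ratio_to_survival(exp(d$rho_mu[4]), sa_bar),
            sp = sa_bar, sa = sa_bar,
            g4 = stats::plogis(d$g4_mu), gp = gb_bar, gb = gb_bar)
          stable_stage_distribution(rates)$lambda
        }
        delta <- tryCatch(
          stats::uniroot(function(x) lam_at(x) - target, c(-2, 2))$root,
          error = function(e) 0)
        par[lay$lgb] <- par[lay$lgb] + max(min(delta, 0.75), -0.75)
      }
    }
    lat <- matrix(0L, 15L, T1)
    n <- matrix(0L, 10L, T)
    g <- exp(par[lay$w]); p <- g / sum(g)
    n[, 1L] <- allocate_counts(exp(par[lay$lN0]), p)
    ok <- TRUE
    for (t in seq_len(T1)) {
      r <- rates_from_par(par, lay, t)
      Lt <- integer(15L)
      Lt[1L] <- stats::rbinom(1L, n[5L, t], r$s1)
      Lt[2L] <- stats::rbinom(1L, n[3L, t], r$s4)
      Lt[3L] <- stats::rbinom(1L, n[4L, t], r$sp)
      Lt[4L] <- stats::rbinom(1L, n[5L, t], r$sa)
      Lt[5L] <- stats::rbinom(1L, n[6L, t], r$sa)
      Lt[6L] <- stats::rbinom(1L, n[9L, t], r$s4)
      Lt[7L] <- stats::rbinom(1L, n[10L, t], r$sa)
      Lt[8L] <- stats::rbinom(1L, Lt[2L], r$g4)
      Lt[9L] <- stats::rbinom(1L, Lt[3L], r$gp)
      Lt[10L] <- stats::rbinom(1L, Lt[5L], r$gb)
      Lt[11L] <- stats::rbinom(1L, Lt[1L], 0.5)
      Lt[12L] <- stats::rbinom(1L, n[1L, t], r$s2)
      Lt[13L] <- stats::rbinom(1L, n[2L, t], r$s3)
      Lt[14L] <- stats::rbinom(1L, n[7L, t], r$s2)
      Lt[15L] <- stats::rbinom(1L, n[8L, t], r$s3)
      if (d$C[1L, t] >= 0L) {
        # lower survivor draws until deaths cover the recovered
        # carcasses; with recovery fixed at one, also raise survivors
        # until deaths equal the carcasses exactly
        lower <- function(row, deficit) {
          take <- min(deficit, Lt[row])
          Lt[row] <<- Lt[row] - take
          deficit - take
        }
        raise <- function(row, surplus, cap) {
          give <- min(surplus, cap - Lt[row])
          Lt[row] <<- Lt[row] + give
          surplus - give
        }
        exact <- identical(d$r_fixed, 1)
        def <- d$C[1L, t] - ((n[5L, t] - Lt[1L]) + (n[1L, t] - Lt[12L]) +
                               (n[7L, t] - Lt[14L]))
        if (def > 0) { def <- lower(1L, def); Lt[11L] <- min(Lt[11L], Lt[1L]) }
        if (def > 0) def <- lower(12L, def)
        if (def > 0) def <- lower(14L, def)
        if (def > 0) ok <- FALSE
        if (exact && def < 0) {
          def <- raise(1L, -def, n[5L, t])
          if (def > 0) def <- raise(12L, def, n[1L, t])
          if (def > 0) def <- raise(14L, def, n[7L, t])
          if (def > 0) ok <- FALSE
        }
        def <- d$C[2L, t] - ((n[2L, t] - Lt[13L]) + (n[8L, t] - Lt[15L]) +
                               (n[3L, t] - Lt[2L]) + (n[9L, t] - Lt[6L]))
        if (def > 0) def <- lower(13L, def)
        if (def > 0) def <- lower(15L, def)
        if (def > 0) { def <- lower(2L, def); Lt[8L] <- min(Lt[8L], Lt[2L]) }
        if (def > 0) def <- lower(6L, def)
        if (def > 0) ok <- FALSE
        if (exact && def < 0) {
          def <- raise(13L, -def, n[2L, t])
          if (def > 0) def <- raise(15L, def, n[8L, t])
          if (def > 0) def <- raise(2L, def, n[3L, t])
          if (def > 0) def <- raise(6L, def, n[9L, t])
          if (def > 0) ok <- FALSE
        }
        def <- d$C[3L, t] - ((n[4L, t] - Lt[3L]) + (n[5L, t] - Lt[4L]) +
                               (n[6L, t] - Lt[5L]) + (n[10L, t] - Lt[7L]))
        if (def > 0) { def <- lower(3L, def); Lt[9L] <- min(Lt[9L], Lt[3L]) }
        if (def > 0) def <- lower(4L, def)
        if (def > 0) { def <- lower(5L, def); Lt[10L] <- min(Lt[10L], Lt[5L]) }
        if (def > 0) def <- lower(7L, def)
        if (def > 0) ok <- FALSE
        if (exact && def < 0) {
          def <- raise(3L, -def, n[4L, t])
          if (def > 0) def <- raise(4L, def, n[5L, t])
          if (def > 0) def <- raise(5L, def, n[6L, t])
          if (def > 0) def <- raise(7L, def, n[10L, t])
          if (def > 0) ok <- FALSE
        }
      }
      if (!ok) break
      lat[, t] <- Lt
      n[, t + 1L] <- c(Lt[11L], Lt[12L], Lt[13L],
                       (Lt[2L] - Lt[8L]) + (Lt[3L] - Lt[9L]),
                       Lt[8L] + Lt[9L] + Lt[10L],
                       Lt[4L] + (Lt[5L] - Lt[10L]),
                       Lt[1L] - Lt[11L],
                       Lt[14L], Lt[15L],
                       Lt[6L] + Lt[7L])
    }
    if (ok) {
      tot <- colSums(n) + n[5L, ]
      if (any(d$syn_bound > 0 & tot < d$syn_bound)) ok <- FALSE
    }
    if (ok) return(list(par = par, lat = lat))
    inflate <- inflate + 0.15
  }
  stop("could not find support-valid initial values: the carcass counts ",
       "or synoptic bounds appear incompatible with the initial-abundance ",
       "prior")
}

#' Fit the integrated population model by MCMC
#'
#' Runs the Metropolis-within-Gibbs sampler: integer random-walk and
#' forward-resimulation proposals on the latent binomial outcomes, and
#' adaptive random-walk proposals on the link-scale continuous
#' parameters (adaptation stops at the end of burn-in). Each chain gets
#' its own seeded random stream derived from the configured seed.
#'
#' @param config An `ipm_config`.
#' @return Object of class `ipm_draws`: a list with `chains` (one
#'   matrix of monitored draws per chain), `years`, `config`, and
#'   sampler acceptance diagnostics.
#' @export
ipm_fit <- function(config) {
  d <- build_cpp_data(config)
  s <- config$sampler
  years <- config$years
  T <- d$T; T1 <- T - 1L
  ty <- years[-T]
  cn <- c(paste0("sa[", ty, "]"), paste0("gb[", ty, "]"), "g4",
          paste0("rho", 1:4),
          paste0("alpha_", COARSE_STAGES), "sigma_r",
          unlist(lapply(COARSE_STAGES, function(sg) paste0("r_", sg, "[", ty, "]"))),
          paste0("Ntot[", years, "]"),
          unlist(lapply(COARSE_STAGES, function(sg) paste0("M_", sg, "[", ty, "]"))),
          unlist(lapply(stage_names(), function(st) paste0("n_", st, "[", years, "]"))),
          "lp__")
  chains <- vector("list", s$n_chains)
  accept <- vector("list", s$n_chains)
  for (ch in seq_len(s$n_chains)) {
    set.seed(s$seed + 1000L * (ch - 1L))
    for (try in seq_len(50L)) {
      init <- ipm_initial_values(config)
      if (is.finite(ipm_logpost_cpp(d, init$par, init$lat))) break
      if (try == 50L) stop("no support-valid starting point found")
    }
    res <- ipm_mcmc_cpp(d, init$par, init$lat,
                        list(n_iter = s$n_iter, n_burnin = s$n_burnin,
                             thin = s$thin))
    m <- res$samples
    colnames(m) <- cn
    chains[[ch]] <- m
    accept[[ch]] <- c(latent = res$accept_latent, block = res$accept_block)
  }
  structure(list(chains = chains, years = years, config = config,
                 accept = accept),
            class = "ipm_draws")
}

#' Pool retained draws across chains
#' @param draws An `ipm_draws` object.
#' @return Matrix with one column per monitored quantity.
#' @export
as_draw_matrix <- function(draws) {
  do.call(rbind, draws$chains)
}

#' Gelman-Rubin convergence diagnostics
#'
#' Classic potential-scale-reduction factor per monitored scalar
#' (between/within chain variance ratio) plus a crude autocorrelation-
#' based effective sample size. A PSRF above 1.1 is flagged. Quantities
#' with zero within-chain variance (constants) are reported as `NA`,
#' not 1.
#'
#' @param draws An `ipm_draws` object with at least two chains.
#' @param params Optional character vector restricting the report.
#' @return Data frame with columns `parameter`, `psrf`, `ess`, `flagged`.
#' @export
check_convergence <- function(draws, params = NULL) {
  ch <- draws$chains
  if (length(ch) < 2L) {
    stop("convergence diagnostics require at least two chains")
  }
  cols <- colnames(ch[[1L]])
  if (!is.null(params)) cols <- intersect(cols, params)
  n <- nrow(ch[[1L]])
  m <- length(ch)
  psrf <- ess <- numeric(length(cols))
  for (i in seq_along(cols)) {
    x <- vapply(ch, function(cc) cc[, cols[i]], numeric(n))
    W <- mean(apply(x, 2L, stats::var))
    B <- n * stats::var(colMeans(x))
    if (!is.finite(W) || W <= 0) {
      psrf[i] <- NA_real_
      ess[i] <- NA_real_
      next
    }
    vplus <- (n - 1) / n * W + B / n
    psrf[i] <- sqrt(vplus / W)
    # initial-monotone cut of the pooled-chain autocorrelation
    rho_sum <- 0
    v <- as.vector(x)
    v <- v - mean(v)
    denom <- sum(v^2)
    for (k in seq_len(min(n - 2L, 200L))) {
      # lag within chains only
      r <- sum(vapply(seq_len(m), function(j) {
        xi <- x[, j] - mean(x[, j])
        sum(xi[seq_len(n - k)] * xi[(k + 1L):n])
      }, 0.0)) / denom
      if (r < 0.05) break
      rho_sum <- rho_sum + r
    }
    ess[i] <- m * n / (1 + 2 * rho_sum)
  }
  data.frame(parameter = cols, psrf = psrf, ess = ess,
             flagged = !is.na(psrf) & psrf > 1.1)
}

#' Posterior summary table
#'
#' Medians as point estimates and the 0.025/0.975 quantiles as 95%
#' credible intervals, plus mean, SD, and CV, for every monitored
#' quantity (or a subset).
#'
#' @param draws An `ipm_draws` object or a numeric matrix of draws.
#' @param params Optional character vector of quantities to keep.
#' @return Data frame with one row per quantity.
#' @export
summarize_draws <- function(draws, params = NULL) {
  m <- if (inherits(draws, "ipm_draws")) as_draw_matrix(draws) else as.matrix(draws)
  if (!is.null(params)) m <- m[, intersect(colnames(m), params), drop = FALSE]
  if (nrow(m) == 0L) stop("no draws to summarize")
  q <- t(apply(m, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
               names = FALSE, type = 7))
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  data.frame(parameter = colnames(m),
             median = q[, 1L], lo95 = q[, 2L], hi95 = q[, 3L],
             mean = mu, sd = sdv, cv = sdv / mu,
             row.names = NULL)
}

#' Generic random-walk Metropolis sampler for a scalar or vector target
#'
#' A small, dependency-free kernel used to validate sampler components
#' against conjugate closed forms (and available for ad-hoc targets).
#'
#' @param log_post Function of the parameter vector returning a log
#'   density (up to a constant).
#' @param init Numeric starting vector.
#' @param scale Proposal SD (scalar or per-coordinate).
#' @param n_iter Number of iterations.
#' @return Matrix of draws, one row per iteration.
#' @export
rw_metropolis <- function(log_post, init, scale, n_iter) {
  p <- length(init)
  scale <- rep(scale, length.out = p)
  out <- matrix(NA_real_, n_iter, p)
  cur <- init
  cur_lp <- log_post(cur)
  for (i in seq_len(n_iter)) {
    for (j in seq_len(p)) {
      prop <- cur
      prop[j] <- prop[j] + stats::rnorm(1L, 0, scale[j])
      lp <- log_post(prop)
      if (is.finite(lp) && log(stats::runif(1L)) < lp - cur_lp) {
        cur <- prop
        cur_lp <- lp
      }
    }
    out[i, ] <- cur
  }
  out
}
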