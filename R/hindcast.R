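# Simulation-based hindcast models: draw vital rates and a terminal
# abundance, back-project the expectation matrix to the first census
# year, pool runs, and fit the lognormal initial-abundance prior.

#' Deterministic back-projection of a census vector
#'
#' Iterates `n[t] = B[t]^{-1} n[t+1]` on the real-valued stage vector,
#' where `B[t]` is the deterministic expectation matrix of the
#' transition on the sex-collapsed state. The full two-sex expectation
#' matrix is always singular -- second-year females and males receive
#' identical expected inflows (half the surviving calves each) -- so the
#' inversion pools the second-year stages into one, which is invertible
#' whenever all survival probabilities are positive. Back-projected
#' states are therefore sex-symmetric in the second-year stages; anchor
#' states are symmetrized on entry. Stochasticity enters a hindcast
#' only through the parameter and anchor draws, not the back-iteration.
#'
#' @param anchor_state Real-valued stage vector (length 10, canonical
#'   order) at the anchor year.
#' @param rates_sequence List of `vital_rates`, one per transition,
#'   ordered forward in time (earliest first); the back-projection
#'   applies them in reverse.
#' @param method `"inverse"` for the exact matrix-inverse back-step
#'   (exactly reverses a deterministic forward projection, but is
#'   numerically explosive over long spans of year-varying rates
#'   because the near-zero juvenile pass-through modes of the life
#'   cycle are amplified by the inverse), or `"eigen"` for the stable
#'   dominant-eigenpair back-step used by the hindcast ensembles: the
#'   total is divided by each year's asymptotic growth rate and the
#'   structure tracked at that year's stable distribution. Both agree
#'   exactly under constant rates anchored at the stable structure.
#' @return List with `states` (10 x (length(rates_sequence)+1) matrix,
#'   earliest year first), `totals` (double-counted totals), and
#'   `valid` (with a `reason` when invalid).
#' @export
backproject <- function(anchor_state, rates_sequence,
                        method = c("inverse", "eigen")) {
  method <- match.arg(method)
  K <- length(rates_sequence)
  if (method == "eigen") {
    states <- matrix(NA_real_, 10L, K + 1L)
    rownames(states) <- stage_names()
    states[, K + 1L] <- as.numeric(anchor_state)
    tot <- sum(anchor_state) + anchor_state[5L]
    valid <- TRUE
    reason <- NULL
    for (t in rev(seq_len(K))) {
      ed <- tryCatch(stable_stage_distribution(rates_sequence[[t]]),
                     error = function(e) NULL)
      if (is.null(ed) || !is.finite(ed$lambda) || ed$lambda <= 0) {
        valid <- FALSE
        reason <- "degenerate expectation matrix"
        break
      }
      tot <- tot / ed$lambda
      states[, t] <- ed$proportions * tot / (1 + ed$proportions[5L])
    }
    totals <- colSums(states) + states[5L, ]
    return(list(states = states, totals = totals, valid = isTRUE(valid),
                reason = reason))
  }
  states <- matrix(NA_real_, 10L, K + 1L)
  rownames(states) <- stage_names()
  x10 <- as.numeric(anchor_state)
  # pool juvenile sexes: (n2, n3, n4, p, c, b, ma); the two-sex system
  # collapses pair by pair because each juvenile sex pair receives
  # identical expected inflows
  reduce <- function(v) c(v[1L] + v[7L], v[2L] + v[8L], v[3L] + v[9L],
                          v[4L], v[5L], v[6L], v[10L])
  expand <- function(v) c(v[1L] / 2, v[2L] / 2, v[3L] / 2, v[4L], v[5L],
                          v[6L], v[1L] / 2, v[2L] / 2, v[3L] / 2, v[7L])
  states[, K + 1L] <- expand(reduce(x10))
  valid <- TRUE
  reason <- NULL
  x <- reduce(x10)
  for (t in rev(seq_len(K))) {
    r <- rates_sequence[[t]]
    B <- matrix(0, 7L, 7L)
    B[1L, 5L] <- r$s1
    B[2L, 1L] <- r$s2
    B[3L, 2L] <- r$s3
    B[4L, 3L] <- r$s4 * (1 - r$g4) / 2
    B[4L, 4L] <- r$sp * (1 - r$gp)
    B[5L, 3L] <- r$s4 * r$g4 / 2
    B[5L, 4L] <- r$sp * r$gp
    B[5L, 6L] <- r$sa * r$gb
    B[6L, 5L] <- r$sa
    B[6L, 6L] <- r$sa * (1 - r$gb)
    B[7L, 3L] <- r$s4 / 2
    B[7L, 7L] <- r$sa
    x <- tryCatch(solve(B, x), error = function(e) NULL)
    if (is.null(x) || any(!is.finite(x))) {
      valid <- FALSE
      reason <- "singular expectation matrix"
      break
    }
    if (any(x < 0)) {
      valid <- FALSE
      reason <- "negative back-solved stage count"
    }
    states[, t] <- expand(x)
  }
  totals <- colSums(states) + states[5L, ]
  list(states = states, totals = totals, valid = isTRUE(valid),
       reason = reason)
}

#' Shift a stable stage structure for an event year
#'
#' Applies additional per-coarse-stage mortality to a stage-proportion
#' vector (as after a severe winter or an intense red tide) and
#' renormalizes. The mothers-with-calf stage is treated as its mother's
#' coarse stage (adult).
#'
#' @param structure Proportion vector over the ten stages (sums to 1).
#' @param event_effects Named vector `c(calf=, subadult=, adult=)` of
#'   additional mortality fractions in `[0, 1)`.
#' @return Shifted proportion vector summing to 1.
#' @export
event_shift_initial_structure <- function(structure,
                                          event_effects = c(calf = 0,
                                                            subadult = 0,
                                                            adult = 0)) {
  if (any(event_effects >= 1) || any(event_effects < 0)) {
    stop("event effects must be additional mortality fractions in [0, 1)")
  }
  cmap <- coarse_stage_map()
  mult <- 1 - event_effects[cmap]
  out <- as.numeric(structure) * as.numeric(mult)
  out / sum(out)
}

#' Run an ensemble of simulation-based hindcasts
#'
#' Each run draws a terminal abundance from the anchor-year survey
#' estimate and a full sequence of vital rates from their priors,
#' anchors the stage structure at the stable distribution under the
#' anchor-year rates (optionally event-shifted), and back-projects to
#' the first year.
#'
#' @param n_runs Number of runs.
#' @param years Census years, earliest to the anchor year.
#' @param anchor_est Lognormal `dist_spec` for abundance at the last
#'   element of `years`.
#' @param priors List with `sa`, `gb` data frames (logit mean/sd per
#'   transition year), `g4` spec, and `rho` list of four specs, as in
#'   [ipm_config()].
#' @param event_effects Optional per-coarse-stage additional mortality
#'   applied to the anchor structure (the event-shifted variant).
#' @param method Back-step method passed to [backproject()]; the
#'   stable `"eigen"` step is the ensemble default.
#' @return Data frame with one row per run: `run_id`, `anchor`,
#'   `valid`, `n_first`, `n_anchor`.
#' @export
hindcast_ensemble <- function(n_runs, years, anchor_est, priors,
                              event_effects = NULL, method = "eigen") {
  T1 <- length(years) - 1L
  ty <- years[-length(years)]
  sa_pr <- priors$sa[match(ty, priors$sa$year), ]
  gb_pr <- priors$gb[match(ty, priors$gb$year), ]
  if (anyNA(sa_pr$year) || anyNA(gb_pr$year)) {
    stop("vital-rate priors do not cover the hindcast span")
  }
  out <- data.frame(run_id = seq_len(n_runs),
                    anchor = years[length(years)],
                    valid = FALSE, n_first = NA_real_, n_anchor = NA_real_)
  for (i in seq_len(n_runs)) {
    sa <- stats::plogis(stats::rnorm(T1, sa_pr$mean, sa_pr$sd))
    gb <- stats::plogis(stats::rnorm(T1, gb_pr$mean, gb_pr$sd))
    g4 <- spec_sample(1L, priors$g4)
    rho <- vapply(priors$rho, function(s) spec_sample(1L, s), 0.0)
    rates <- lapply(seq_len(T1), function(t) {
      vital_rates(s1 = mortality_ratio_to_survival(rho[1L], sa[t]),
                  s2 = mortality_ratio_to_survival(rho[2L], sa[t]),
                  s3 = mortality_ratio_to_survival(rho[3L], sa[t]),
                  s4 = mortality_ratio_to_survival(rho[4L], sa[t]),
                  sp = sa[t], sa = sa[t],
                  g4 = g4, gp = gb[t], gb = gb[t])
    })
    N_anchor <- spec_sample(1L, anchor_est)
    struct <- stable_stage_distribution(rates[[T1]])$proportions
    if (!is.null(event_effects)) {
      struct <- event_shift_initial_structure(struct, event_effects)
    }
    anchor_state <- struct * N_anchor / (1 + struct[5L])
    bp <- backproject(anchor_state, rates, method = method)
    out$n_anchor[i] <- N_anchor
    out$valid[i] <- bp$valid
    if (bp$valid) out$n_first[i] <- bp$totals[1L]
  }
  out
}

#' Fit a lognormal to pooled hindcast first-year abundances
#'
#' @param runs Either a numeric vector of first-year abundances or the
#'   data frame from [hindcast_ensemble()] (invalid runs dropped).
#' @param min_valid Minimum number of valid runs required.
#' @return List with `mu_log`, `sd_log`, `n_valid`, `n_invalid`.
#' @export
pool_and_fit_lognormal <- function(runs, min_valid = 100L) {
  if (is.data.frame(runs)) {
    n_invalid <- sum(!runs$valid)
    x <- runs$n_first[runs$valid]
  } else {
    n_invalid <- sum(!is.finite(runs) | runs <= 0)
    x <- runs[is.finite(runs) & runs > 0]
  }
  if (length(x) < min_valid) {
    stop("too few valid hindcast runs (", length(x), " < ", min_valid, ")")
  }
  lx <- log(x)
  sd_log <- stats::sd(lx)
  if (sd_log == 0) stop("degenerate hindcast pool: all runs identical")
  list(mu_log = mean(lx), sd_log = sd_log,
       n_valid = length(x), n_invalid = n_invalid)
}

#' Initial-abundance prior from hindcast ensembles
#'
#' The full prior-construction pipeline: run a hindcast ensemble
#' anchored at each abundance survey, pool the first-year abundances,
#' fit a lognormal, and double the SD of the log.
#'
#' @param years Census years of the model span.
#' @param surveys Data frame `year`, `mu_log`, `sd_log`.
#' @param priors Vital-rate priors (`sa`, `gb`, `g4`, `rho`) as in
#'   [hindcast_ensemble()].
#' @param n_runs Runs per anchor model.
#' @return A lognormal `dist_spec` (the doubled-SD prior), with the
#'   pooled fit attached as attribute `"pooled_fit"`.
#' @export
hindcast_initial_prior <- function(years, surveys, priors, n_runs = 1000L) {
  pools <- lapply(seq_len(nrow(surveys)), function(j) {
    anchor <- surveys$year[j]
    if (!anchor %in% years[-1L]) return(NULL)
    span <- years[1L]:anchor
    est <- dist_spec("lognormal", meanlog = surveys$mu_log[j],
                     sdlog = surveys$sd_log[j])
    runs <- hindcast_ensemble(n_runs, span, est, priors)
    runs$n_first[runs$valid]
  })
  fit <- pool_and_fit_lognormal(unlist(pools))
  out <- build_initial_abundance_prior(fit$mu_log, fit$sd_log)
  attr(out, "pooled_fit") <- fit
  out
}

#' Compare hindcast death trajectories with recovered carcasses
#'
#' A hindcast, unlike the fitted model, can imply fewer deaths in a
#' year/stage than carcasses actually recovered. Given a back-projected
#' state trajectory and per-transition rates, computes the expected
#' deaths by coarse stage and flags every year/stage cell where the
#' recovered count exceeds them.
#'
#' @param states 10 x T matrix from [backproject()].
#' @param rates_sequence Per-transition `vital_rates` (length T-1).
#' @param carcass Data frame `year`, `stage`, `count`.
#' @param years Census years matching the columns of `states`.
#' @return Data frame `year`, `stage`, `expected_deaths`, `carcasses`,
#'   `inconsistent`.
#' @export
hindcast_carcass_check <- function(states, rates_sequence, carcass, years) {
  T1 <- length(rates_sequence)
  recs <- list()
  for (t in seq_len(T1)) {
    r <- rates_sequence[[t]]
    n <- unname(states[, t])
    qa <- function(s) 1 - s
    M <- c(calf = n[5L] * qa(r$s1) + n[1L] * qa(r$s2) + n[7L] * qa(r$s2),
           subadult = n[2L] * qa(r$s3) + n[8L] * qa(r$s3) +
             n[3L] * qa(r$s4) + n[9L] * qa(r$s4),
           adult = (n[4L] * qa(r$sp)) + (n[5L] + n[6L] + n[10L]) * qa(r$sa))
    for (s in COARSE_STAGES) {
      obs <- carcass$count[carcass$year == years[t] & carcass$stage == s]
      obs <- if (length(obs)) obs[1L] else NA_integer_
      recs[[length(recs) + 1L]] <- data.frame(
        year = years[t], stage = s, expected_deaths = unname(M[s]),
        carcasses = obs,
        inconsistent = !is.na(obs) && obs > M[s])
    }
  }
  do.call(rbind, recs)
}
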