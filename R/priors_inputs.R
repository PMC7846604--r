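# Construction of every prior the IPM uses from input estimate tables:
# initial abundance and stage structure, yearly adult survival and
# reproduction, juvenile:adult mortality ratios, and the reproductive
# constraints.

#' Parametric distribution specification
#'
#' A light container for the prior/estimate families the model uses.
#'
#' @param family One of `"lognormal"` (meanlog, sdlog), `"logit_normal"`
#'   (mean, sd on the logit scale), `"dirichlet"` (concentration vector),
#'   `"beta"` (shape1, shape2), `"point_mass"` (value).
#' @param ... Family-specific parameters (named).
#' @return List of class `dist_spec`.
#' @export
dist_spec <- function(family = c("lognormal", "logit_normal", "dirichlet",
                                 "beta", "point_mass"), ...) {
  family <- match.arg(family)
  pars <- list(...)
  chk <- function(cond, msg) if (!cond) stop("invalid dist_spec: ", msg)
  switch(family,
    lognormal = {
      chk(all(c("meanlog", "sdlog") %in% names(pars)), "need meanlog, sdlog")
      chk(pars$sdlog > 0, "sdlog must be > 0")
    },
    logit_normal = {
      chk(all(c("mean", "sd") %in% names(pars)), "need mean, sd")
      chk(pars$sd >= 0, "sd must be >= 0")
    },
    dirichlet = {
      chk("alpha" %in% names(pars), "need alpha")
      chk(all(pars$alpha > 0), "all concentrations must be > 0")
    },
    beta = {
      chk(all(c("shape1", "shape2") %in% names(pars)), "need shape1, shape2")
      chk(pars$shape1 > 0 && pars$shape2 > 0, "shapes must be > 0")
    },
    point_mass = chk("value" %in% names(pars), "need value")
  )
  structure(c(list(family = family), pars), class = "dist_spec")
}

#' Sample from a distribution specification
#' @param n Number of draws.
#' @param spec A `dist_spec`.
#' @return Numeric vector (or matrix for `dirichlet`, draws in rows).
#' @export
spec_sample <- function(n, spec) {
  switch(spec$family,
    lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
    logit_normal = stats::plogis(stats::rnorm(n, spec$mean, spec$sd)),
    dirichlet = rdirichlet(n, spec$alpha),
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    point_mass = rep(spec$value, n)
  )
}

#' Median of a distribution specification
#' @param spec A `dist_spec`.
#' @return Scalar median (vector of component medians for `dirichlet` is
#'   not defined; the mean vector is returned instead).
#' @export
spec_median <- function(spec) {
  switch(spec$family,
    lognormal = exp(spec$meanlog),
    logit_normal = stats::plogis(spec$mean),
    dirichlet = spec$alpha / sum(spec$alpha),
    beta = stats::qbeta(0.5, spec$shape1, spec$shape2),
    point_mass = spec$value
  )
}

#' Dirichlet sampler
#' @param n Draws. @param alpha Concentration vector.
#' @return Matrix, one draw per row.
#' @keywords internal
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

#' Convert a mortality ratio and adult survival to a stage survival
#'
#' Younger-stage survival is tied to adult survival through a mortality
#' ratio held constant across years: `1 - s = rho * (1 - sa)`, truncated
#' to `[0, 1]`. `rho = 1` recovers adult survival; larger ratios mean
#' proportionally higher mortality.
#'
#' @param rho Positive mortality ratio (stage mortality : adult
#'   mortality).
#' @param sa Adult survival probability.
#' @return Survival probability in `[0, 1]`.
#' @export
mortality_ratio_to_survival <- function(rho, sa) {
  if (any(rho <= 0)) stop("rho must be > 0")
  pmin(pmax(1 - rho * (1 - sa), 0), 1)
}

#' Initial-abundance prior from a pooled hindcast fit
#'
#' The lognormal fitted to pooled hindcast abundances understates the
#' true uncertainty about initial abundance; the prior doubles the SD of
#' the log.
#'
#' @param mu_log,sd_log Lognormal parameters of the pooled hindcast fit.
#' @return A lognormal `dist_spec` with `sdlog` doubled.
#' @export
build_initial_abundance_prior <- function(mu_log, sd_log) {
  if (sd_log <= 0) stop("sd_log must be > 0")
  dist_spec("lognormal", meanlog = mu_log, sdlog = 2 * sd_log)
}

#' Inflate the variance of a Dirichlet distribution
#'
#' Rescales the concentration vector so every component's variance is
#' multiplied by `factor` while the mean vector is unchanged. Since
#' `Var_i = p_i (1 - p_i) / (sum(alpha) + 1)`, the new concentration sum
#' satisfies `sum(alpha') + 1 = (sum(alpha) + 1) / factor`.
#'
#' @param alpha Concentration vector (all > 0).
#' @param factor Variance inflation factor (> 1 inflates; 1 is identity).
#' @return Rescaled concentration vector.
#' @export
inflate_dirichlet_variance <- function(alpha, factor = 4) {
  if (any(alpha <= 0)) stop("all concentrations must be > 0")
  if (factor < 1) stop("factor must be >= 1")
  new_sum <- (sum(alpha) + 1) / factor - 1
  if (new_sum <= 0) {
    stop("infeasible variance inflation: factor ", factor,
         " too large for concentration sum ", sum(alpha))
  }
  alpha / sum(alpha) * new_sum
}

#' Per-year vital-rate priors from an estimate table
#'
#' Converts a tidy table of link-scale estimates (columns `year`,
#' `parameter`, `link`, `mean`, `sd`) into year-indexed logit-normal
#' `dist_spec`s for adult survival (`sa`) and adult breeding probability
#' (`gb`), plus a single spec for fourth-year reproduction (`g4`), which
#' is assumed constant over time. The prebreeder breeding probability is
#' constrained equal to the breeder probability year by year.
#'
#' @param table Data frame with the columns above; `parameter` must
#'   contain `sa` and `gb` for every year of the span and one `g4` row.
#' @param years Optional integer vector of required years; defaults to
#'   the range present.
#' @return List with `sa` and `gb` (named lists of `dist_spec` keyed by
#'   year), `g4` (one `dist_spec`), and `gp_equals_gb = TRUE`.
#' @export
vital_rate_priors <- function(table, years = NULL) {
  need <- c("year", "parameter", "mean", "sd")
  if (!all(need %in% names(table))) {
    stop("estimate table must have columns: ", paste(need, collapse = ", "))
  }
  per_year <- function(par) {
    rows <- table[table$parameter == par, , drop = FALSE]
    yrs <- if (is.null(years)) sort(rows$year) else years
    missing <- setdiff(yrs, rows$year)
    if (length(missing)) {
      stop("missing `", par, "` estimate for year(s): ",
           paste(missing, collapse = ", "))
    }
    out <- lapply(yrs, function(y) {
      r <- rows[rows$year == y, ][1, ]
      if (r$sd <= 0) {
        dist_spec("point_mass", value = stats::plogis(r$mean))
      } else {
        dist_spec("logit_normal", mean = r$mean, sd = r$sd)
      }
    })
    names(out) <- yrs
    out
  }
  g4row <- table[table$parameter == "g4", , drop = FALSE]
  g4 <- if (nrow(g4row)) {
    dist_spec("logit_normal", mean = g4row$mean[1], sd = g4row$sd[1])
  } else {
    default_g4_prior()
  }
  list(sa = per_year("sa"), gb = per_year("gb"), g4 = g4,
       gp_equals_gb = TRUE)
}

#' Convert a vital-rate estimate table to model prior blocks
#'
#' Reshapes a tidy estimate table (columns `year`, `parameter`, `mean`,
#' `sd`, link scale) into the `sa`/`gb` data frames and `g4` spec
#' consumed by [ipm_config()].
#'
#' @param table Data frame as documented in [vital_rate_priors()].
#' @return List with elements `sa`, `gb` (data frames) and `g4`
#'   (`dist_spec`).
#' @export
priors_from_estimates <- function(table) {
  pick <- function(par) {
    rows <- table[table$parameter == par, c("year", "mean", "sd")]
    rows[order(rows$year), , drop = FALSE]
  }
  g4row <- table[table$parameter == "g4", , drop = FALSE]
  g4 <- if (nrow(g4row)) {
    dist_spec("logit_normal", mean = g4row$mean[1], sd = g4row$sd[1])
  } else {
    default_g4_prior()
  }
  list(sa = pick("sa"), gb = pick("gb"), g4 = g4)
}

#' Default prior for fourth-year reproductive probability
#'
#' A wide logit-normal with median 0.001 and 97.5th percentile near
#' 0.285, reflecting that fourth-year breeding is rare but poorly known.
#' @return A `dist_spec`.
#' @export
default_g4_prior <- function() {
  dist_spec("logit_normal", mean = stats::qlogis(0.001), sd = 3.05)
}

#' Default mortality-ratio priors
#'
#' Lognormal priors for the four juvenile:adult mortality ratios,
#' centred on first-year mortality about five times adult mortality,
#' second-year about twice, and third/fourth-year close to adult
#' (ratios near 1), consistent with the only direct estimates of
#' juvenile manatee survival, which found calf survival depressed but
#' subadult survival indistinguishable from adults'.
#' @return Named list of four lognormal `dist_spec`s (`rho1`..`rho4`).
#' @export
default_mortality_ratio_priors <- function() {
  list(rho1 = dist_spec("lognormal", meanlog = log(5.0), sdlog = 0.40),
       rho2 = dist_spec("lognormal", meanlog = log(2.3), sdlog = 0.40),
       rho3 = dist_spec("lognormal", meanlog = log(1.10), sdlog = 0.30),
       rho4 = dist_spec("lognormal", meanlog = log(1.05), sdlog = 0.30))
}

#' Realize an initial census from the initial-abundance and structure
#' priors
#'
#' Draws a total abundance from its lognormal prior and stage
#' proportions from the (variance-inflated) Dirichlet prior, then
#' allocates integer counts. Because the mothers-with-calf stage is
#' double counted in total abundance, the model-stage total is scaled by
#' `1 / (1 + p_c)` before allocation.
#'
#' @param abund_spec Lognormal `dist_spec` for total abundance.
#' @param struct_spec Dirichlet `dist_spec` over the ten model stages.
#' @return A `stage_vector`.
#' @export
draw_initial_state <- function(abund_spec, struct_spec) {
  N <- spec_sample(1, abund_spec)
  p <- as.vector(spec_sample(1, struct_spec))
  as_stage_vector(allocate_counts(N, p))
}

#' Deterministic largest-remainder allocation of an abundance target
#'
#' Shared by the prior realization and the MCMC initial-state
#' parametrization: given a target total abundance (with the calf stage
#' counted twice) and stage proportions over the ten model stages,
#' returns integer stage counts whose double-counted total is within
#' rounding of the target. Ties in fractional remainders break by stage
#' order.
#'
#' @param N_target Positive real target total abundance.
#' @param p Proportion vector over the ten model stages (sums to 1).
#' @return Integer vector of ten counts.
#' @export
allocate_counts <- function(N_target, p) {
  if (N_target <= 0) stop("target abundance must be positive")
  p <- p / sum(p)
  S <- N_target / (1 + p[5])          # model-stage total; stage 5 is `c`
  target <- S * p
  base <- floor(target)
  rem <- round(S) - sum(base)
  if (rem > 0) {
    frac <- target - base
    ord <- order(frac, seq_along(frac), decreasing = c(TRUE, FALSE),
                 method = "radix")
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
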