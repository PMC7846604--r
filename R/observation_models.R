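# Likelihood components linking latent states to the observed data
# streams: carcass recovery, aerial abundance surveys, synoptic count
# lower bounds, and the carcass length classifier.

COARSE_STAGES <- c("calf", "subadult", "adult")

#' Binomial log-pmf that is safe on the support boundary
#'
#' Returns `-Inf` outside the support (including `x > n`), and handles
#' `p = 0` and `p = 1` as point masses.
#' @param x,n,p Count, size, probability (vectorized).
#' @return Log-probability (vector).
#' @keywords internal
lbinom_safe <- function(x, n, p) {
  out <- rep(-Inf, length(x))
  ok <- n >= 0 & x >= 0 & x <= n & p >= 0 & p <= 1
  out[ok] <- stats::dbinom(x[ok], n[ok], p[ok], log = TRUE)
  out
}

#' Carcass-recovery log-likelihood for one year
#'
#' Observed carcass counts by coarse stage are binomial thinnings of the
#' latent death counts: `C_s ~ Bin(M_s, r_s)`. The log-likelihood is
#' `-Inf` whenever more carcasses were recovered than animals died — the
#' support property that lets the fitted model rule out trajectories
#' implying impossibly few deaths.
#'
#' @param C Named vector of observed carcass counts (`calf`, `subadult`,
#'   `adult`).
#' @param M Named vector of latent death counts for the same coarse
#'   stages.
#' @param r Recovery probabilities per coarse stage, each in `[0, 1]`.
#' @return Scalar log-likelihood.
#' @export
carcass_loglik <- function(C, M, r) {
  C <- C[COARSE_STAGES]; M <- M[COARSE_STAGES]
  r <- if (length(r) == 1L) rep(r, 3L) else r[COARSE_STAGES]
  if (anyNA(C) || anyNA(M)) stop("carcass/death counts must be named calf, subadult, adult")
  if (any(C < 0) || any(M < 0)) stop("negative carcass or death count")
  sum(lbinom_safe(as.numeric(C), as.numeric(M), as.numeric(r)))
}

#' Recovery probability from the additive logit model
#'
#' Carcass recovery probability for a coarse stage and year under the
#' settled model: additive effects of coarse stage and year on the link
#' scale, with year as a random effect shared across stages,
#' `r_s[t] = linkinv(alpha_s + eps[t])`.
#'
#' @param params List with `alpha` (named numeric: `calf`, `subadult`,
#'   `adult` link-scale intercepts) and `eps` (named or year-indexed
#'   numeric vector of year effects).
#' @param stage Coarse stage name.
#' @param year Year label or index into `eps`.
#' @param link `"logit"` (default) or `"probit"`.
#' @return Probability in (0, 1).
#' @export
recovery_probability <- function(params, stage, year, link = c("logit", "probit")) {
  link <- match.arg(link)
  if (!stage %in% COARSE_STAGES) stop("unknown coarse stage: ", stage)
  eps <- params$eps
  key <- as.character(year)
  e <- if (!is.null(names(eps))) {
    if (!key %in% names(eps)) stop("unknown year: ", year)
    eps[[key]]
  } else {
    if (year < 1L || year > length(eps)) stop("unknown year: ", year)
    eps[[year]]
  }
  eta <- params$alpha[[stage]] + e
  if (link == "logit") stats::plogis(eta) else stats::pnorm(eta)
}

#' Abundance-survey log-likelihood
#'
#' Aerial survey estimates enter the model as lognormal densities on the
#' latent total abundance, evaluated at the integer total without a
#' continuity correction (negligible at abundances in the thousands).
#'
#' @param N_tot Latent total abundance (positive).
#' @param est List or data-frame row with `mu_log` and `sd_log`.
#' @return Scalar log-likelihood; `-Inf` for `N_tot <= 0`.
#' @export
abundance_loglik <- function(N_tot, est) {
  if (est$sd_log <= 0) stop("sd_log must be positive")
  if (N_tot <= 0) return(-Inf)
  stats::dlnorm(N_tot, meanlog = est$mu_log, sdlog = est$sd_log, log = TRUE)
}

#' Synoptic count lower-bound constraint
#'
#' Uncorrected synoptic counts are treated as hard lower bounds on total
#' abundance (inclusive).
#'
#' @param N_tot Latent total abundance.
#' @param bound Synoptic count.
#' @return `TRUE` when feasible (`N_tot >= bound`).
#' @export
synoptic_constraint <- function(N_tot, bound) {
  N_tot >= bound
}

#' Classify a carcass into a coarse stage by length
#'
#' Length classes: under 151 cm is perinatal (excluded from the
#' analysis), 151-235 cm calf, 236-265 cm subadult, 266 cm or more
#' adult; carcasses of unknown length are excluded.
#'
#' @param length_cm Carcass length in centimetres, or `NA` for unknown.
#' @return Character vector with levels `perinatal_excluded`, `calf`,
#'   `subadult`, `adult`, `unknown_excluded`.
#' @export
classify_carcass <- function(length_cm) {
  out <- character(length(length_cm))
  for (i in seq_along(length_cm)) {
    L <- length_cm[i]
    if (is.na(L)) {
      out[i] <- "unknown_excluded"
    } else if (L <= 0) {
      stop("carcass length must be positive (got ", L, ")")
    } else if (L < 151) {
      out[i] <- "perinatal_excluded"
    } else if (L < 236) {
      out[i] <- "calf"
    } else if (L < 266) {
      out[i] <- "subadult"
    } else {
      out[i] <- "adult"
    }
  }
  out
}
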