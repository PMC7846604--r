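# Posterior-sample transforms reported to managers: realized growth
# rates, net change in abundance, age-class structure series, and the
# minimum abundance / potential biological removal formulas of the U.S.
# Marine Mammal Protection Act.

#' Realized population growth rates
#'
#' Year-specific realized growth `lambda[t] = N[t+1] / N[t]` and the
#' geometric mean growth rate, computed per posterior draw (never on
#' posterior medians, which would bias the telescoping identity
#' `prod(lambda) = N[T] / N[1]`).
#'
#' @param N Abundance series: numeric vector or a draws x years matrix.
#' @return List with `lambda` (matrix or vector, one column per
#'   transition) and `geometric_mean` (per draw).
#' @export
realized_growth <- function(N) {
  N <- if (is.matrix(N)) N else matrix(N, nrow = 1L)
  if (any(N <= 0)) stop("abundance must be positive to compute growth rates")
  T <- ncol(N)
  if (T < 2L) stop("need at least two years")
  lam <- N[, -1L, drop = FALSE] / N[, -T, drop = FALSE]
  gm <- (N[, T] / N[, 1L])^(1 / (T - 1L))
  if (!is.null(colnames(N))) colnames(lam) <- colnames(N)[-T]
  list(lambda = if (nrow(lam) == 1L) drop(lam) else lam,
       geometric_mean = unname(gm))
}

#' Net change in abundance
#'
#' Per-draw change `N[t+1] - N[t]` for a chosen year, or the mean over
#' all transitions for an average year.
#'
#' @param N Abundance series (vector or draws x years matrix); columns
#'   may be named by year.
#' @param year A year label / column index, or `"average"`.
#' @return Numeric vector, one value per draw.
#' @export
net_change <- function(N, year = "average") {
  N <- if (is.matrix(N)) N else matrix(N, nrow = 1L)
  T <- ncol(N)
  diffs <- N[, -1L, drop = FALSE] - N[, -T, drop = FALSE]
  if (identical(year, "average")) return(unname(rowMeans(diffs)))
  idx <- if (!is.null(colnames(N))) match(as.character(year), colnames(N)[-T])
         else as.integer(year)
  if (is.na(idx) || idx < 1L || idx > T - 1L) {
    stop("year ", year, " outside the series span")
  }
  unname(diffs[, idx])
}

#' Minimum population abundance estimate
#'
#' The 20th percentile of the abundance-estimate distribution as used in
#' the potential biological removal formula:
#' `N_min = N_hat / exp(0.842 * sqrt(log(1 + CV^2)))`.
#' For a lognormal estimate with the same CV this equals the 20th
#' percentile up to the rounding of the normal quantile 0.842.
#'
#' @param N_hat Point estimate of abundance (> 0).
#' @param CV Coefficient of variation of the estimate (>= 0).
#' @return N_min, a positive real.
#' @export
nmin <- function(N_hat, CV) {
  if (any(N_hat <= 0)) stop("N_hat must be positive")
  if (any(CV < 0)) stop("CV must be non-negative")
  N_hat / exp(0.842 * sqrt(log(1 + CV^2)))
}

#' Potential biological removal
#'
#' `PBR = N_min * R_max / 2 * F_r`: the maximum human-caused removal
#' consistent with allowing the stock to reach or remain at its optimum
#' sustainable population.
#'
#' @param N_hat Abundance point estimate.
#' @param CV Coefficient of variation of `N_hat`.
#' @param R_max Theoretical maximum rate of increase.
#' @param F_r Recovery factor in `(0, 1]` (0.5 is typical for a
#'   threatened stock).
#' @return PBR, a non-negative real.
#' @export
pbr <- function(N_hat, CV, R_max, F_r) {
  if (R_max < 0) stop("R_max must be non-negative")
  if (F_r < 0 || F_r > 1) stop("F_r must be in [0, 1]")
  nmin(N_hat, CV) * R_max / 2 * F_r
}

#' N_min and PBR from a posterior sample
#'
#' Applies the point-estimate convention of the analysis: `N_hat` is
#' the posterior median and `CV` the posterior SD over mean.
#'
#' @param draws Numeric vector of posterior abundance draws.
#' @param R_max,F_r As in [pbr()].
#' @return List with `N_hat`, `CV`, `N_min`, `PBR`.
#' @export
pbr_from_posterior <- function(draws, R_max = 0.04, F_r = 0.5) {
  N_hat <- stats::median(draws)
  CV <- stats::sd(draws) / mean(draws)
  list(N_hat = N_hat, CV = CV, N_min = nmin(N_hat, CV),
       PBR = pbr(N_hat, CV, R_max, F_r))
}

#' Per-year age-class structure summaries from posterior draws
#'
#' Applies [age_class_structure()] to every retained draw's census in
#' every reported year and summarizes the proportions. The reporting
#' window defaults to the full span but can exclude early years still
#' influenced by the initial-structure prior.
#'
#' @param draws An `ipm_draws` object (latent states monitored).
#' @param years Optional subset of census years to report.
#' @return Data frame `year`, `class`, `median`, `lo95`, `hi95`, `mean`.
#' @export
structure_series <- function(draws, years = NULL) {
  m <- as_draw_matrix(draws)
  yrs <- if (is.null(years)) draws$years else intersect(years, draws$years)
  classes <- c("first", "second", "third", "fourth", "adult")
  recs <- vector("list", length(yrs) * 5L)
  k <- 0L
  for (y in yrs) {
    n <- vapply(stage_names(), function(st) m[, paste0("n_", st, "[", y, "]")],
                numeric(nrow(m)))
    if (is.null(dim(n))) n <- matrix(n, nrow = 1L,
                                     dimnames = list(NULL, stage_names()))
    tot <- rowSums(n) + n[, "c"]
    props <- cbind(first = n[, "c"],
                   second = n[, "f2"] + n[, "m2"],
                   third = n[, "f3"] + n[, "m3"],
                   fourth = n[, "f4"] + n[, "m4"],
                   adult = n[, "p"] + n[, "c"] + n[, "b"] + n[, "ma"]) / tot
    for (cl in classes) {
      k <- k + 1L
      q <- stats::quantile(props[, cl], c(0.5, 0.025, 0.975), names = FALSE)
      recs[[k]] <- data.frame(year = y, class = cl, median = q[1L],
                              lo95 = q[2L], hi95 = q[3L],
                              mean = mean(props[, cl]))
    }
  }
  do.call(rbind, recs)
}

#' Abundance draw matrix from a fitted model
#'
#' Convenience accessor: retained draws of total abundance, one column
#' per census year, columns named by year.
#'
#' @param draws An `ipm_draws` object.
#' @return Draws x years numeric matrix.
#' @export
abundance_draws <- function(draws) {
  m <- as_draw_matrix(draws)
  cols <- paste0("Ntot[", draws$years, "]")
  out <- m[, cols, drop = FALSE]
  colnames(out) <- as.character(draws$years)
  out
}
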