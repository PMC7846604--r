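# Stochastic two-sex stage-structured projection process for the Florida
# manatee, its deterministic expectation, and death accounting.
#
# Stage order used throughout the package:
#   f2, f3, f4  - second/third/fourth-year females
#   p           - adult female prebreeders
#   c           - mothers with a dependent first-year calf
#   b           - adult female breeders (without dependent calf)
#   m2, m3, m4  - second/third/fourth-year males
#   ma          - adult males
# First-year calves are not tracked separately: each is carried inside its
# mother's `c` stage, so total abundance counts `c` twice.

#' Stage names in canonical order
#' @return Character vector of the ten stage labels.
#' @export
stage_names <- function() {
  c("f2", "f3", "f4", "p", "c", "b", "m2", "m3", "m4", "ma")
}

#' Construct a stage vector
#'
#' A `stage_vector` holds the December-census counts of the ten life-cycle
#' stages. The census is taken in December and labeled for the subsequent
#' calendar year, about half a year after the birth pulse.
#'
#' @param f2,f3,f4,p,c,b,m2,m3,m4,ma Non-negative integer counts.
#' @param year Optional census-year label (integer).
#' @return Named integer vector of class `stage_vector`.
#' @export
stage_vector <- function(f2 = 0, f3 = 0, f4 = 0, p = 0, c = 0, b = 0,
                         m2 = 0, m3 = 0, m4 = 0, ma = 0, year = NULL) {
  x <- c(f2 = f2, f3 = f3, f4 = f4, p = p, c = c, b = b,
         m2 = m2, m3 = m3, m4 = m4, ma = ma)
  validate_stage_vector(x)
  x <- structure(as.integer(round(x)), names = stage_names(),
                 class = "stage_vector")
  if (!is.null(year)) attr(x, "year") <- as.integer(year)
  x
}

#' @keywords internal
as_stage_vector <- function(x, year = NULL) {
  stopifnot(length(x) == 10L)
  if (!is.null(names(x)) && all(stage_names() %in% names(x))) {
    x <- x[stage_names()]
  }
  validate_stage_vector(x)
  x <- structure(as.integer(round(x)), names = stage_names(),
                 class = "stage_vector")
  if (!is.null(year)) attr(x, "year") <- as.integer(year)
  x
}

validate_stage_vector <- function(x) {
  if (anyNA(x)) stop("stage counts contain NA")
  bad <- which(x < 0)
  if (length(bad)) {
    stop("negative stage count in field(s): ",
         paste(stage_names()[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Construct a set of vital rates
#'
#' Survival probabilities for the first four years of life (`s1`-`s4`),
#' prebreeders (`sp`) and other adults (`sa`), and reproductive
#' probabilities for fourth-year females (`g4`), prebreeders (`gp`) and
#' breeders (`gb`). All probabilities refer to one annual time step.
#'
#' @param s1,s2,s3,s4,sp,sa Survival probabilities in `[0, 1]`.
#' @param g4,gp,gb Reproductive probabilities in `[0, 1]`.
#' @param year Optional year label for the transition the rates govern.
#' @return Named list of class `vital_rates`.
#' @export
vital_rates <- function(s1, s2, s3, s4, sp, sa, g4, gp, gb, year = NULL) {
  r <- list(s1 = s1, s2 = s2, s3 = s3, s4 = s4, sp = sp, sa = sa,
            g4 = g4, gp = gp, gb = gb)
  for (nm in names(r)) {
    v <- r[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("vital rate `", nm, "` must be a probability in [0, 1]")
    }
  }
  if (!is.null(year)) r$year <- as.integer(year)
  structure(r, class = "vital_rates")
}

#' Project the population one year forward
#'
#' One annual time step of the demographically stochastic two-sex process:
#' survival and breeding outcomes are binomial draws taken in a fixed
#' documented order from R's random stream (so trajectories are
#' reproducible given `set.seed()`), and the next census follows by
#' deterministic bookkeeping. Calves enter the model at age 1.5 from the
#' mothers-with-calf stage, splitting 50:50 between the sexes.
#'
#' @param state A `stage_vector` (census at year `t`).
#' @param rates A `vital_rates` object for the transition `t -> t+1`.
#' @return List with elements `state` (the next `stage_vector`) and
#'   `draws` (named integer vector of the intermediate binomial outcomes:
#'   survivor counts `S1`, `Sf4`, `Sp`, `Sc`, `Sb`, `Sm4`, `Sma` and
#'   breeder counts `G4`, `Gp`, `Gb`).
#' @export
project_one_year <- function(state, rates) {
  state <- as_stage_vector(state)
  if (!inherits(rates, "vital_rates")) {
    rates <- do.call(vital_rates, as.list(rates)[
      intersect(names(rates), c("s1","s2","s3","s4","sp","sa","g4","gp","gb"))])
  }
  n <- state
  # survival draws, in the order the process equations list them
  S1  <- stats::rbinom(1L, n[["c"]],  rates$s1)
  Sf4 <- stats::rbinom(1L, n[["f4"]], rates$s4)
  Sp  <- stats::rbinom(1L, n[["p"]],  rates$sp)
  Sc  <- stats::rbinom(1L, n[["c"]],  rates$sa)
  Sb  <- stats::rbinom(1L, n[["b"]],  rates$sa)
  Sm4 <- stats::rbinom(1L, n[["m4"]], rates$s4)
  Sma <- stats::rbinom(1L, n[["ma"]], rates$sa)
  # breeding draws among survivors
  G4 <- stats::rbinom(1L, Sf4, rates$g4)
  Gp <- stats::rbinom(1L, Sp,  rates$gp)
  Gb <- stats::rbinom(1L, Sb,  rates$gb)
  # next-census draws and difference equations
  nf2 <- stats::rbinom(1L, S1, 0.5)
  nf3 <- stats::rbinom(1L, n[["f2"]], rates$s2)
  nf4 <- stats::rbinom(1L, n[["f3"]], rates$s3)
  nm3 <- stats::rbinom(1L, n[["m2"]], rates$s2)
  nm4 <- stats::rbinom(1L, n[["m3"]], rates$s3)
  nxt <- c(f2 = nf2,
           f3 = nf3,
           f4 = nf4,
           p  = (Sf4 - G4) + (Sp - Gp),
           c  = G4 + Gp + Gb,
           b  = Sc + (Sb - Gb),
           m2 = S1 - nf2,
           m3 = nm3,
           m4 = nm4,
           ma = Sm4 + Sma)
  year <- attr(state, "year")
  draws <- c(S1 = S1, Sf4 = Sf4, Sp = Sp, Sc = Sc, Sb = Sb,
             Sm4 = Sm4, Sma = Sma, G4 = G4, Gp = Gp, Gb = Gb)
  list(state = as_stage_vector(nxt,
                               year = if (is.null(year)) NULL else year + 1L),
       draws = draws)
}

#' Total abundance at a census
#'
#' The mothers-with-calf stage is counted twice because each mother
#' carries an untracked first-year calf.
#'
#' @param state A `stage_vector`.
#' @return Integer total abundance.
#' @export
total_abundance <- function(state) {
  state <- as_stage_vector(state)
  as.integer(sum(state) + state[["c"]])
}

#' Deterministic expectation matrix of the projection process
#'
#' Returns the 10 x 10 matrix `A` such that `E[state(t+1) | state(t)] =
#' A %*% state(t)` under the stochastic process of [project_one_year()].
#' Rows and columns follow [stage_names()].
#'
#' @param rates A `vital_rates` object.
#' @return Numeric 10 x 10 matrix.
#' @export
expectation_matrix <- function(rates) {
  s <- rates
  A <- matrix(0, 10, 10, dimnames = list(stage_names(), stage_names()))
  A["f2", "c"]  <- 0.5 * s$s1
  A["f3", "f2"] <- s$s2
  A["f4", "f3"] <- s$s3
  A["p", "f4"]  <- s$s4 * (1 - s$g4)
  A["p", "p"]   <- s$sp * (1 - s$gp)
  A["c", "f4"]  <- s$s4 * s$g4
  A["c", "p"]   <- s$sp * s$gp
  A["c", "b"]   <- s$sa * s$gb
  A["b", "c"]   <- s$sa
  A["b", "b"]   <- s$sa * (1 - s$gb)
  A["m2", "c"]  <- 0.5 * s$s1
  A["m3", "m2"] <- s$s2
  A["m4", "m3"] <- s$s3
  A["ma", "m4"] <- s$s4
  A["ma", "ma"] <- s$sa
  A
}

#' Stable stage distribution and asymptotic growth rate
#'
#' Dominant eigenpair of the expectation matrix, computed by power
#' iteration. The proportions are the long-run census composition under
#' constant rates; the eigenvalue is the asymptotic annual growth rate of
#' the census vector.
#'
#' @param rates A `vital_rates` object.
#' @param tol Convergence tolerance on the L1 change of proportions.
#' @param max_iter Maximum number of power iterations.
#' @return List with `proportions` (length 10, sums to 1) and `lambda`.
#' @export
stable_stage_distribution <- function(rates, tol = 1e-12, max_iter = 100000L) {
  A <- expectation_matrix(rates)
  v <- rep(1 / 10, 10)
  lam <- NA_real_
  for (i in seq_len(max_iter)) {
    w <- as.vector(A %*% v)
    sw <- sum(w)
    if (!is.finite(sw) || sw <= 0) {
      stop("power iteration failed: expectation matrix drives the ",
           "population to zero or is degenerate for the supplied rates")
    }
    w <- w / sw
    if (sum(abs(w - v)) < tol) {
      v <- w
      lam <- sw
      break
    }
    v <- w
    lam <- sw
  }
  if (sum(abs(as.vector(A %*% v) / sum(A %*% v) - v)) >= tol * 10) {
    stop("power iteration did not converge in ", max_iter, " iterations")
  }
  names(v) <- stage_names()
  list(proportions = v, lambda = lam)
}

#' Decompose one projection step's deaths into coarse stages
#'
#' Coarse stages group the ten model stages for carcass classification:
#' calves are first- and second-year animals, subadults third- and
#' fourth-year, adults everything older. First-year calf deaths are the
#' calves whose mothers' draw did not carry them to age 1.5; the mother's
#' own death is counted separately as an adult death.
#'
#' @param state Census at year `t`.
#' @param next_state Census at year `t + 1` produced by the same step.
#' @param draws The `draws` element returned by [project_one_year()].
#' @return Named integer vector `c(calf, subadult, adult)`.
#' @export
deaths_by_coarse_stage <- function(state, next_state, draws) {
  n <- as_stage_vector(state)
  n2 <- as_stage_vector(next_state)
  d <- draws
  calf <- (n[["c"]] - d[["S1"]]) +
    (n[["f2"]] - n2[["f3"]]) + (n[["m2"]] - n2[["m3"]])
  subadult <- (n[["f3"]] - n2[["f4"]]) + (n[["m3"]] - n2[["m4"]]) +
    (n[["f4"]] - d[["Sf4"]]) + (n[["m4"]] - d[["Sm4"]])
  adult <- (n[["p"]] - d[["Sp"]]) + (n[["c"]] - d[["Sc"]]) +
    (n[["b"]] - d[["Sb"]]) + (n[["ma"]] - d[["Sma"]])
  out <- c(calf = calf, subadult = subadult, adult = adult)
  if (any(out < 0)) {
    stop("inconsistent (state, next_state, draws) triple: ",
         "negative death count in ",
         paste(names(out)[out < 0], collapse = ", "))
  }
  structure(as.integer(out), names = names(out))
}

#' Age-class structure of a census
#'
#' Proportions of total abundance in the five age classes: first-year,
#' second-year, third-year, fourth-year, and adult. First-year calves are
#' the untracked dependents of the mothers-with-calf stage; their mothers
#' are counted among the adults, so the class proportions sum to 1 over
#' the double-counted total.
#'
#' @param state A `stage_vector`.
#' @return Named numeric vector of five proportions summing to 1.
#' @export
age_class_structure <- function(state) {
  n <- as_stage_vector(state)
  tot <- total_abundance(n)
  if (tot <= 0) stop("age-class proportions undefined for a zero population")
  c(first  = n[["c"]],
    second = n[["f2"]] + n[["m2"]],
    third  = n[["f3"]] + n[["m3"]],
    fourth = n[["f4"]] + n[["m4"]],
    adult  = n[["p"]] + n[["c"]] + n[["b"]] + n[["ma"]]) / tot
}

#' Map model stages to coarse stages
#' @return Named character vector: coarse stage for each model stage.
#' @export
coarse_stage_map <- function() {
  c(f2 = "calf", f3 = "subadult", f4 = "subadult", p = "adult",
    c = "adult", b = "adult", m2 = "calf", m3 = "subadult",
    m4 = "subadult", ma = "adult")
}
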