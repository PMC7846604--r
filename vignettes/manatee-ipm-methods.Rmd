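---
title: "Reconstructing manatee population dynamics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing manatee population dynamics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(manateeIPM)
```

## The problem

Florida manatees (*Trichechus manatus latirostris*) are long-lived,
slow-reproducing, and hard to count. Abundance surveys that correct for
detection are expensive and sparse (in the southwest management unit,
only two in twenty years), while two other data streams accumulate every
year: recovered carcasses classified by body length, and
photo-identification estimates of adult survival and reproduction. This
package reconstructs the yearly population trajectory by fusing all of
these streams around a single demographic process model, then derives
the management quantities that depend on it: realized growth rates, the
net population change in ordinary and unusual-mortality years, age-class
structure, and the minimum abundance (N_min) and potential biological
removal (PBR) of the U.S. Marine Mammal Protection Act.

## The projection process

The population is censused each December, labeled for the subsequent
year, with ten stages: second-, third-, and fourth-year animals of each
sex, adult female prebreeders (`p`), mothers with a dependent first-year
calf (`c`), breeders without a dependent calf (`b`), and adult males
(`ma`). First-year calves are not tracked separately; each rides with
its mother in `c`, so total abundance counts `c` twice. Calves enter the
model at age 1.5, splitting 50:50 between the sexes.

One annual step is a fixed sequence of binomial draws (survival of each
stage, then breeding among surviving breeders-to-be) followed by
deterministic bookkeeping; `project_one_year()` implements it exactly,
and `expectation_matrix()` gives the 10 x 10 matrix of its conditional
expectation. Demographic stochasticity therefore enters through the
binomial draws and nothing else: there is no environmental noise term,
no density dependence, and no movement between management units.

Survival of the four pre-adult year classes is tied to adult survival
through mortality ratios held constant across years,
`1 - s_k = rho_k (1 - s_a)`, so the carcass data can inform juvenile
survival even though no direct juvenile mark-recapture estimates exist
for this population. The prebreeder stage shares the adult survival
probability: the only direct juvenile survival study found subadult and
adult survival indistinguishable, and the mark-recapture survival
estimates used as priors refer to all adults. Reproductive
probabilities: the fourth-year breeding probability is constant over
time, and prebreeders are assumed to breed with the same year-specific
probability as breeders (the prebreeder rate is otherwise
unidentifiable because no data stream separates the two).

Deaths are tallied by *coarse stage* -- calves (first and second year),
subadults (third and fourth), adults (everything else) -- matching how
carcasses are classified from body length (calf 151-235 cm, subadult
236-265 cm, adult 266 cm and longer; shorter carcasses are perinatal
and excluded, as are carcasses of unknown length). The decomposition of
one step's deaths into coarse stages follows the only bookkeeping
consistent with the process equations: second-year deaths are the
second-year animals that do not appear as third-years in the next
census.

## Data models

* **Carcasses.** Observed counts by year and coarse stage are binomial
  thinnings of the latent deaths, `C_s[t] ~ Bin(M_s[t], r_s[t])`. The
  recovery probability follows an additive model on the logit scale:
  one intercept per coarse stage plus a year random effect shared
  across stages, `r_s[t] = logit^-1(alpha_s + eps[t])`,
  `eps[t] ~ N(0, sigma_r^2)`. The logit link and the shared (rather
  than stage-specific) year effect are our choices where the additive
  structure alone was specified; a probit variant is available in
  `recovery_probability()`. The support constraint `C <= M` is what
  lets the model reject trajectories that imply impossibly few deaths.
* **Abundance surveys.** Each detection-corrected survey estimate
  enters as a lognormal density on the latent total abundance of its
  year, evaluated at the integer total without continuity correction
  (the error is negligible at abundances in the thousands).
* **Synoptic counts.** Uncorrected winter aggregation counts are hard
  lower bounds on total abundance (inclusive), switchable off.

## Priors

* Year-specific adult survival and breeding probabilities: independent
  logit-normals centred on the mark-recapture point estimates with
  their reported link-scale SDs. The upstream analyses used sin-link
  coefficients with method-of-moments random effects; the logit-normal
  is a close surrogate, and refitting those models is out of scope.
* Mortality ratios `rho_1..rho_4`: lognormal priors centred at 5.0,
  2.3, 1.1, and 1.05 (log-scale SDs 0.4, 0.4, 0.3, 0.3), encoding
  depressed calf survival and near-adult subadult survival.
* Fourth-year breeding probability: logit-normal with median 0.001 and
  97.5th percentile 0.285 -- rare but poorly known.
* Recovery intercepts: Normal(0, 2.5^2) on the logit scale;
  `sigma_r`: half-Normal(1.5).
* Initial (first-census) abundance: lognormal. The packaged default is
  the doubled-SD construction `lognormal(7.38, 0.49)`; the full
  pipeline builds it from the hindcast ensembles
  (`hindcast_initial_prior()`), again doubling the SD of the log
  because the pooled ensemble understates the real uncertainty.
* Initial stage structure: Dirichlet around the stable stage
  distribution at prior-median rates, with the variance inflated
  fourfold (`inflate_dirichlet_variance()`, which preserves the mean
  vector exactly). The concentrations sum to about 24 after inflation.
  The deposited analysis derived its concentrations from an
  event-shifted hindcast; those exact values are not in the main text,
  so the stable-structure-based default is a documented substitution.

The initial census is realized from continuous latents: a lognormal
total and Dirichlet proportions, allocated to integer counts by
largest-remainder rounding with the mothers-with-calf double count
handled in the target (`allocate_counts()`). Parametrizing the initial
state this way (rather than as ten free integer latents) makes the
prior-only marginal of initial abundance exactly the lognormal prior,
which is also how we test it.

## Posterior sampling

The joint density -- priors, every binomial of the process at every
year, and the three data likelihoods -- is `ipm_log_joint()`, with an
identical compiled implementation inside the sampler that is
cross-checked against the R reference in the tests. Sampling is
Metropolis-within-Gibbs (the compiled hot loop lives in `src/`):

* integer random-walk proposals on every latent binomial outcome;
* per-transition forward resimulation proposals (the process proposal
  cancels, leaving only the data terms);
* adaptive random-walk proposals on the link-scale continuous
  parameters, with adaptation frozen at the end of burn-in;
* three families of joint proposals that are essential for mixing at
  this data density, because the carcass likelihood pins the death
  series tightly:
  * *survivor-chain shifts*: add or remove an animal from an adult
    stage chain (`Sp`, `Sb`, or `Sma`) from year `t0` to the end of the
    span, changing the death tally in year `t0` only;
  * *windowed chain shifts*: the same between two years `t0 < t1`,
    which moves a death from one year to another without moving the
    overall level;
  * *birth pulses*: add or remove a breeding outcome and carry the new
    mother-calf pair, the breeder chain, and the male half of the
    cohort through the rest of the span -- a death-neutral move that
    lets the growth rate of the latent trajectory mix;
  * a *level move* that shifts the log initial abundance and slides all
    adult chains to match.

Latent-state initialization forward-simulates from prior draws and then
repairs any year in which recovered carcasses would exceed implied
deaths by minimally lowering the implicated survivor draws (and, when
recovery is fixed at 1, raising them where deaths exceed carcasses), so
every chain starts inside the support.

Convergence is monitored with the classic potential-scale-reduction
factor per scalar (`check_convergence()`; constants are reported as
`NA`, not 1), and summaries use posterior medians with 0.025/0.975
quantiles (`summarize_draws()`), the point-estimate convention of the
original analysis. The full-scale settings of that analysis (3 chains
of 6 million iterations, 2 million burn-in, thinning by 50) are
configurable but the package defaults are a 1:100 scaling (3 x 60,000,
20,000 burn-in, thin 10), which on the synthetic study conditions gives
usable diagnostics in minutes on one core.

## Hindcasts

The simulation-based hindcast models draw a terminal abundance from an
abundance-survey estimate and a full sequence of vital rates from their
priors, anchor the stage structure at the stable distribution of the
anchor-year rates (optionally shifted by per-coarse-stage event
mortality, `event_shift_initial_structure()`, for anchors following a
severe winter or intense red tide), and project backward to the first
year. Pooled first-year abundances are fitted with a lognormal
(`pool_and_fit_lognormal()`), and doubling the SD of the log yields the
initial-abundance prior.

Two back-projection methods are provided. The exact matrix-inverse
step reverses a deterministic forward projection to machine precision,
but two structural facts make it unusable for long hindcasts: the full
two-sex expectation matrix is always singular (each juvenile sex pair
receives identical expected inflows, so the inversion must pool the
juvenile sexes), and even the pooled system has near-zero eigenvalues
from the juvenile pass-through chain, which the inverse amplifies
explosively over many heterogeneous years. The ensembles therefore use
a stable dominant-eigenpair step -- divide the total by each year's
asymptotic growth rate, track the structure at that year's stable
distribution -- which agrees exactly with the inverse step under
constant rates anchored at the stable structure. Hindcast trajectories
carry no carcass information, and `hindcast_carcass_check()` reports
the years in which they imply fewer deaths than carcasses recovered --
the characteristic failure the integrated model is immune to.

## Derived metrics

All transforms are computed per posterior draw and summarized
afterwards; in particular the geometric mean growth rate is
`(N[T]/N[1])^(1/(T-1))` per draw, never a ratio of posterior medians.
`nmin(N_hat, CV) = N_hat / exp(0.842 sqrt(log(1 + CV^2)))` is the 20th
percentile of a lognormal abundance estimate (0.842 is the rounded
0.8th normal quantile), and `pbr()` multiplies it by `R_max/2` and the
recovery factor. From a posterior sample, `pbr_from_posterior()` takes
the median as the point estimate and SD/mean as the CV. The age-class
series (`structure_series()`) reports first- through fourth-year and
adult proportions per year; a reporting window that drops the first few
years is supported because the initial-structure prior still influences
them (the weak ergodic theorem makes it irrelevant later).

## The synthetic-data generator

`truth_scenario()` fixes the study conditions the tests run under: a
20-year span; initial abundance 2,500; adult survival near 0.97 with
yearly logit-scale variation (SD 0.25); breeding probability near 0.20
(SD 0.20), which with the default mortality ratios puts the long-run
growth rate at about 1.02; mortality ratios (5.0, 2.3, 1.1, 1.05);
average recovery probabilities 0.67 / 0.948 / 0.971 for
calves/subadults/adults with a yearly logit effect of SD 0.7; surveys
in relative years 15 and 20 with log-SDs 0.166 and 0.132 (the
sparse-survey design); synoptic undercounts with availability 0.5; and
optional event years in which adult survival drops by 0.08 and calf
survival by 0.30, emulating an intense red tide. Vital-rate "estimates"
are truth plus logit-scale noise of SD 0.15, which is also the prior SD
handed to the fitting step -- the estimate-noise magnitudes are
calibration choices inferred from published interval widths, not quoted
values.

What the generator does **not** emulate: individual photo-ID capture
histories (estimates are generated at the summary level), carcass
lengths (deaths are generated already classified), cause-of-death
structure, spatial structure, and any dependence between the data
streams -- the real streams share animals and the generator's are
conditionally independent given the trajectory. Passing the recovery
tests therefore shows the estimator is consistent under the model's own
assumptions at realistic sizes, not that those assumptions hold for the
real monitoring system.

## Numerical choices and problem sizes

Binomial log-pmfs are evaluated with explicit support checks (outside
support is `-Inf`, `p` of 0 or 1 are point masses), so support
violations propagate as vetoes rather than NaNs. Largest-remainder
allocation breaks ties by stage order. Power iteration for the stable
structure runs to an L1 tolerance of 1e-12.

The test suite runs deliberately reduced problem sizes chosen to keep
the full suite in the minutes range on one core: process-expectation
checks use 50,000 replicate projections; the prior-recovery check runs
a single prior-only chain whose ancestral-refresh move makes the
retained draws near-independent; parameter-recovery uses 8 replicate
fits of the 20-year scenario (two with an event year) at 2 pooled
chains x 21,000 iterations with the hindcast-constructed initial
prior; hindcast ensembles use hundreds to a thousand runs. Full-scale settings remain available through
`ipm_config()`.

## Known limitations

* Single management unit, no immigration/emigration, no density
  dependence, no environmental covariates on rates.
* The recovery intercepts are weakly identified at desk scale: with
  near-complete recovery of adult carcasses, the posterior is happy
  anywhere between "high recovery, deaths equal carcasses" and
  "moderate recovery, a few missed deaths per year"; the joint moves
  above traverse that ridge, but short chains still show it as
  elevated PSRF on `alpha_*` before anything else converges.
* Model selection over recovery structures (the published analysis
  used binary inclusion factors) is not reimplemented; the settled
  additive model is hard-coded.
* The sensitivity-analysis hook (alternative initial structures and
  abundances via `ipm_config()` priors) is provided, but the published
  sensitivity results are not reproduced.
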