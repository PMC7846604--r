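# manateeIPM

Bayesian integrated population modelling for the Florida manatee
(*Trichechus manatus latirostris*), built for the situation every
marine-mammal monitoring program knows: detection-corrected abundance
surveys are rare and expensive, while carcass recoveries and
photo-identification estimates of survival and reproduction accumulate
every year. `manateeIPM` reconstructs the full yearly population
trajectory — abundance, stage structure, juvenile survival, carcass
recovery rates — by fusing those streams around one demographic process
model, and derives the quantities managers actually use: realized growth
rates, the net impact of unusual-mortality years, and the minimum
abundance (N_min) and potential biological removal (PBR) of the U.S.
Marine Mammal Protection Act. It is aimed at population ecologists and
agency analysts working with stage-structured monitoring data.

## The model

A December census with ten stages: second/third/fourth-year animals of
each sex (f2–f4, m2–m4), adult female prebreeders (p), mothers with a
dependent first-year calf (c), breeders (b), and adult males (ma).
First-year calves ride with their mothers, so total abundance is

    N_tot[t] = N_f2 + N_f3 + N_f4 + N_p + 2 N_c + N_b + N_m2 + N_m3 + N_m4 + N_ma

One year of dynamics is a fixed sequence of binomial survival draws
(e.g. S_1 ~ Bin(N_c, s_1), S_b ~ Bin(N_b, s_a)), binomial breeding
draws among the survivors (G ~ Bin(S, γ)), and deterministic
bookkeeping — demographic stochasticity and nothing else. Juvenile
survival is tied to adult survival by time-constant mortality ratios,
1 − s_k = ρ_k (1 − s_a).

Three data models close the loop:

* carcass counts by coarse stage (calf/subadult/adult, classified from
  body length) are binomial thinnings of the latent deaths,
  `C_s[t] ~ Bin(M_s[t], r_s[t])`, with recovery probabilities additive
  in stage and year on the logit scale;
* sparse aerial survey estimates enter as lognormal densities on the
  latent totals;
* uncorrected synoptic counts are hard lower bounds.

Mark–recapture estimates of adult survival and breeding probability
become year-specific priors; the initial-abundance prior is built by
simulation-based hindcasts from the survey anchors
(`hindcast_initial_prior()`), with the SD of the log doubled. The
posterior over all parameters and the full latent trajectory is sampled
by a bespoke compiled Metropolis-within-Gibbs sampler whose joint
proposals (survivor-chain shifts, death-neutral birth pulses, level
moves, ancestral refreshes) are what make the tightly carcass-pinned
trajectory mix; see the methods vignette.

## Worked example

Simulate twenty years of monitoring data under the packaged scenario
(slow growth λ ≈ 1.02, two surveys, yearly carcass counts), build the
initial-abundance prior by hindcasting, fit, and summarize:

```r
library(manateeIPM)

sc  <- truth_scenario(seed = 1)          # 20 years, N0 = 2500
ds  <- simulate_dataset(sc)
pr  <- priors_from_estimates(ds$estimates)
set.seed(2)
pr$init_abundance <- hindcast_initial_prior(
  sc$years, ds$surveys,
  c(pr, list(rho = default_mortality_ratio_priors())), n_runs = 1000)

cfg <- ipm_config(years = sc$years, priors = pr,
                  carcass = ds$carcass, surveys = ds$surveys,
                  synoptic = ds$synoptic,
                  n_chains = 2, n_iter = 35000, n_burnin = 14000,
                  thin = 20, seed = 3)
fit <- ipm_fit(cfg)

summarize_draws(fit, params = c("Ntot[1997]", "Ntot[2016]", "rho1",
                                "r_calf[2005]"))
N  <- abundance_draws(fit)
rg <- realized_growth(N)
median(rg$geometric_mean)
pbr_from_posterior(N[, "2016"], R_max = 0.04, F_r = 0.5)
```

Output of this exact script (about four minutes on one core):

```
     parameter   median    lo95     hi95     mean      sd     cv
1         rho1    3.990    2.18    6.521    4.015   1.145 0.2852
2 r_calf[2005]    0.908    0.57    0.999    0.866   0.126 0.1450
3   Ntot[1997] 2697.000 2489.00 3038.000 2699.856 138.887 0.0514
4   Ntot[2016] 3875.000 3546.47 4227.525 3875.594 181.791 0.0469
geometric mean lambda: 1.0198
List of 4
 $ N_hat: num 3875
 $ CV   : num 0.0469
 $ N_min: num 3725
 $ PBR  : num 37.3
```

Reading it: the posterior total abundance estimates carry ~5% credible
intervals for every year even though only two years were surveyed — the
carcass and vital-rate streams carry the trajectory between surveys.
`rho1` is the first-year:adult mortality ratio (truth 5.0 in this
scenario) and `r_calf[2005]` the probability a 2005 calf carcass was
recovered (the generator's average calf recovery is 0.67, with large
year effects). The geometric-mean realized growth rate, 1.0198 here, is
computed per posterior draw; the PBR report gives N_min (the 20th
percentile of the terminal-year abundance estimate) and the allowable
removal under a recovery factor of 0.5.

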