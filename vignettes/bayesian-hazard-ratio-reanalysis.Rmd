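---
title: "Bayesian reanalysis of a two-arm survival endpoint: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian reanalysis of a two-arm survival endpoint: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayeshr)
```

## The model

`bayeshr` reanalyses the primary endpoint of a two-arm randomized trial —
time to a composite event (for the motivating use case, COVID-19–related
hospitalization or all-cause death within 28 days) — under a range of prior
beliefs about the treatment effect. The estimand is the hazard ratio (HR)
between the treated and control arms; all modelling happens on
$\beta = \log \mathrm{HR}$.

The likelihood is the partial likelihood of a proportional-hazards model
with a single binary covariate $x$ (treatment arm), using Breslow's
convention for tied event times. With distinct event times $t_j$, event
multiplicity $d_j$, $s_j$ treated subjects among the tied events, and risk
set $R(t_j)$ (subjects with follow-up $\ge t_j$),

$$
\ell(\beta) \;=\; \sum_{\text{strata}} \sum_j \Big[ s_j \beta
  - d_j \log \!\!\sum_{k \in R(t_j)} \!\! e^{\beta x_k} \Big]
  \;=\; \sum_{\text{strata}} \sum_j \Big[ s_j \beta
  - d_j \log\!\big( n_{0j} + n_{1j} e^{\beta} \big) \Big],
$$

where the second form uses the fact that with one binary covariate the risk
set enters only through its arm counts $n_{0j}, n_{1j}$. Censored subjects
appear in risk sets but contribute no event term — the standard partial-
likelihood convention; dropping them from risk sets entirely would make the
estimator inconsistent. The denominator is evaluated as a log-sum so large
$|\beta|$ cannot overflow.

**Stratification.** The trial being emulated randomized within strata
defined by three binary factors (care-facility residence, age $\ge 60$,
region). "Adjusting for the stratification factors" is implemented as a
*stratified* partial likelihood — separate baseline hazards, i.e. risk sets
built within each stratum — rather than as extra regression covariates.
This keeps the model a one-parameter likelihood matching the single
reported HR, and avoids placing unstated priors on nuisance coefficients.
`buildRiskSets(..., stratified = FALSE)` gives the unstratified
alternative; covariate adjustment is out of scope.

The prior on $\beta$ is a $K$-component normal mixture
$\pi(\beta) = \sum_i w_i\, \phi\big((\beta - \mu_i)/\sigma_i\big)/\sigma_i$,
and the posterior is $\pi(\beta)\, e^{\ell(\beta)}$ up to a constant.
Because the parameter is one-dimensional, every posterior quantity can be
cross-checked against deterministic grid integration; the test suite does
exactly that.

## The priors

Five reference priors express stances about the treatment effect as
single normals on $\log \mathrm{HR}$ (mean HR, SD of log HR): minimally
informative $(1, 3)$, weakly skeptical $(1, 1)$, moderately skeptical
$(1, 0.5)$, weakly pessimistic $(1.25, 1)$, weakly optimistic $(0.75, 1)$.
The minimally informative prior is *described* as putting 0.99 probability
on HR between 0.001 and 1000; we treat that as descriptive of $N(0, 3)$
(which gives $\exp(\pm 2.326 \times 3) \approx (0.00093, 1076)$) rather
than as a constraint to re-fit.

Data-driven priors are built from historical-trial summary tables. Each
trial reporting point estimate $p$ with 95% CI $(L, U)$ becomes a component
with $\mu = \ln p$ and $\sigma = (\ln U - \ln L) / (2 \times 1.959964)$ —
95% of the component's mass sits over the log of the reported CI. The exact
normal quantile is used rather than 1.96; the difference is below any
printed precision. Components are weighted by trial sample size,
$w_i = n_i / \sum n$, within the selected subset (all trials, direct-acting
antivirals only, or non-DAA trials). Risk and odds ratios are placed on the
log-HR axis unchanged: the historical tables pool hazard, risk and odds
ratios into one prior without a stated conversion, and the approximation is
acceptable for rare outcomes; `trialToComponent()` exposes a
`measure_conversion` hook but only the identity is implemented.

Mixture summaries are closed-form where possible (mean HR as a lognormal-
mixture mean; SD of log HR from the mixture variance decomposition); the
median and equal-tail intervals come from bisection on the CDF over
$[10^{-6}, 10^6]$ to $10^{-10}$ CDF tolerance. `samplePrior()` provides
both i.i.d. sampling and an MCMC path, so mixture construction can be
verified by sampling exactly as the motivating analysis did.

## The sampler

The posterior is one-dimensional, so the package uses adaptive Gaussian
random-walk Metropolis rather than gradient-based samplers: with a single
parameter, NUTS buys nothing. Settings mirror the analysis being
reproduced: 4 parallel chains, 5,000 warm-up iterations, 20,000 saved
iterations per chain, chain starts overdispersed at
$\beta \in \{-2, -0.5, 0.5, 2\}$. During warm-up the log proposal scale is
adapted by Robbins–Monro (gain $i^{-0.6}$) toward acceptance 0.44, the 1-D
optimum; the scale is frozen afterwards so saved draws come from a fixed
kernel. Reproducibility: each chain's RNG stream is seeded by
`deriveSeeds()` from one master seed.

Convergence is a contract, not an assumption: split $\widehat{R}$ and
rank-normalized bulk effective sample size (Geyer initial-monotone-sequence
truncation of the autocorrelation sum) are computed for every fit, and a
fit with $\widehat{R} \ge 1.01$ or bulk ESS $\le 1000$ is flagged;
summaries remain available but `runReanalysis()` suppresses the headline
statistic if any fit failed. At the default scale the sampler typically
achieves bulk ESS $\approx$ 17,000–19,000 of 80,000 draws.

Threshold probabilities $P(\mathrm{HR} < c)$ are the fraction of pooled
post-warm-up draws below $\ln c$; the posterior median and the equal-tail
95% credible interval are the 50th and 2.5th/97.5th percentiles of
$e^\beta$, computed with the median-unbiased quantile estimator (type 8) —
at 80,000 draws the choice of estimator is below printed precision.
Probabilities are conventionally reported to 3 decimals and medians/CrIs to
2.

## The synthetic-data generator

The subject-level data behind the motivating trial are not public; the
generator reproduces what *is* published and makes explicit choices for the
rest.

* **Conditional mode** (the acceptance configuration) fixes the margins:
  279 treated with 2 events, 283 placebo with 15 events, administrative
  censoring at day 28. Event times are unpublished, so they are drawn
  uniformly on [2, 28] days. The partial likelihood depends on times only
  through risk-set composition, and with near-equal arms fully at risk the
  likelihood is almost invariant to timing: re-drawing event times moves
  the unstratified MLE by under 0.001 on the HR scale. Times are rounded
  to whole days by default so ties genuinely occur and the Breslow
  correction is exercised.
* **Generative mode** simulates exponential event times with the treated
  hazard equal to `true_hr` times the control hazard, calibrated so the
  control arm has a given event probability by end of follow-up (default
  in the tests: 0.053, the published placebo event rate). This mode drives
  the parameter-recovery suite.
* **Strata** are assigned independently with fixed marginal probabilities
  (0.05 facility residence, 0.30 age $\ge$ 60, 0.90 US) — plausible for an
  outpatient COVID-19 trial and deliberately fixed rather than tuned.
  Independence balances strata across arms, so stratification barely moves
  the estimate *in expectation*; see limitations for the realization-level
  caveat.
* **Historical trials.** The nine real trials behind the data-driven
  priors live in unpublished supplementary material, so
  `syntheticHistoricalTable()` ships a synthetic stand-in chosen once:
  nine trials with true HRs spanning 0.14–1.11 (the published range of
  their point estimates), three DAA trials with strong effects
  (0.14–0.30) and six non-DAA trials with modest ones (0.52–1.11),
  reporting SDs of 0.2–0.5 and sample sizes of 600–2,100. The resulting
  all-trials mixture is bimodal, the DAA mixture concentrated at small
  HRs, the non-DAA mixture near the null — the qualitative structure the
  real table produces. Posterior rows for these mixture priors are
  structural stand-ins, not reproductions of the published data-driven
  rows.

The composite endpoint is simulated as a single event type (the motivating
trial observed no deaths, and components are indistinguishable in the
likelihood). No viral-load, symptom or secondary-endpoint structure is
simulated, and no covariates exist beyond the three strata.

What passing tests on these data do and do not show: they verify the
*machinery* — margins, likelihood, sampler, summaries — under the published
event structure. They cannot verify features the generator does not model:
real event-time clustering (hospitalizations concentrate early), informative
censoring, within-stratum imbalance, or the real historical-trial values.

## Numerical choices

* Log-sum-exp throughout the likelihood and mixture density; risk-set arm
  counts of zero are handled as $\log 0 = -\infty$ without special cases.
* Newton–Raphson for the frequentist cross-check: start $\beta = 0$,
  step-halving on likelihood decrease, convergence $|\Delta\beta| <
  10^{-8}$, max 50 iterations; SE from observed information; Wald 95% CI.
  When every event falls in one arm the likelihood is monotone and the fit
  is returned flagged (`monotone = TRUE`) instead of diverging.
* Datasets with zero events are rejected by `buildRiskSets()` (the
  likelihood is constant) but accepted by `samplePosterior()`, which then
  samples the prior — the correct posterior under a constant likelihood.
* Density export uses the change of variables to the HR axis (Jacobian
  $1/\mathrm{HR}$) for the analytic prior curve; posterior curves are a
  Gaussian KDE of the log-HR draws (Silverman bandwidth), cosmetic only.

## Problem sizes in the checks

The full-scale checks run the eight-prior reanalysis at the published MCMC
scale (8 × 4 × 25,000 iterations on 562 subjects), a timing-sensitivity
sweep re-drawing event times under five seeds, and a parameter-recovery
suite of 20 replicates at each true HR in {0.25, 0.5, 1, 2} with 2,000
subjects per arm; recovery replicates use 2 chains × (500 + 2,500)
iterations, ample for a median and SD.

## Known limitations

* With only 17 events, the *stratified* estimate is sensitive to which
  strata the events land in: across independent strata realizations the
  stratified MLE varies over roughly 0.125–0.141 while the unstratified
  MLE stays at 0.132–0.133. Threshold probabilities near a published value
  inherit that spread (about ±0.02 on $P(\mathrm{HR} < 0.6)$). This is a
  property of stratified small-event-count analyses, not of the sampler.
* RR/OR components enter the log-HR mixture unconverted (above).
* No leave-one-out cross-validation: the motivating analysis mentions
  LOO-CV alongside $\widehat{R}$/ESS, but those are convergence
  diagnostics, not LOO statistics; the package implements the diagnostics
  and omits LOO rather than guessing at an unstated model-comparison
  target.
* No meta-analytic-predictive priors, power priors or down-weighting of
  historical data; the mixture construction is the plain sample-size
  weighting described above.

## A worked run

```{r example, eval = FALSE}
data <- simulateTrial(trialConfig(events_treat = 2, events_ctrl = 15,
                                  seed = 1))
priors <- c(lapply(referencePriorNames(), referencePrior),
            lapply(c("all", "DAA", "nonDAA"), buildMixture,
                   trials = syntheticHistoricalTable(seed = 4)))
bundle <- runReanalysis(data, priors, seed = 20260926)
bundle
writeReport(bundle, "reanalysis-output", priors = priors)
```
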