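# bayeshr

Bayesian reanalysis of a two-arm clinical trial's time-to-event endpoint
under a spectrum of prior beliefs about the treatment effect.

Randomized trials are usually summarized by one frequentist hazard ratio
(HR) and a p-value. `bayeshr` instead treats the log hazard ratio
$\beta = \log \mathrm{HR}$ as the parameter of a Bayesian model:

$$
p(\beta \mid \text{data}) \;\propto\; \pi(\beta)\, \exp\{\ell(\beta)\},
\qquad
\ell(\beta) = \sum_{\text{strata}} \sum_j \Big[ s_j\beta - d_j \log\big(n_{0j} + n_{1j} e^{\beta}\big) \Big],
$$

where $\ell$ is the stratified Cox partial log-likelihood with Breslow's
handling of tied event times ($d_j$ events at time $t_j$, $s_j$ of them
treated, risk-set arm counts $n_{0j}, n_{1j}$), and the prior $\pi$ is a
normal mixture on $\log \mathrm{HR}$ — either one of five reference priors
(minimally informative, weakly/moderately skeptical, weakly pessimistic,
weakly optimistic) or a data-driven mixture built from historical-trial
summary tables, one component per trial with weights proportional to trial
sample size. The posterior yields direct probability statements such as
$P(\mathrm{HR} < 0.6 \mid \text{data})$ — "the probability that treatment
cuts the event rate by at least 40%" — which is the quantity clinicians
actually reason with.

The package is aimed at trial statisticians and methods researchers who
want to reanalyse (or plan) a two-arm survival endpoint under explicit
prior assumptions, and at anyone who needs a fully testable, self-contained
reference implementation of the mixture-prior + partial-likelihood + MCMC
pipeline. Because subject-level trial data are rarely shareable, a
synthetic-data module generates datasets with exactly specified event
margins (or from true exponential hazards), so every stage is reproducible
from code alone.

## Worked example

Reconstruct a trial for which only the event structure is published — 279
treated patients with 2 events, 283 controls with 15 events, 28 days of
follow-up, three binary stratification factors — then fit the model under a
moderately skeptical prior, $\beta \sim N(0, 0.5^2)$:

```r
library(bayeshr)

data <- simulateTrial(trialConfig(events_treat = 2, events_ctrl = 15, seed = 1))

coxMle(buildRiskSets(data))          # frequentist cross-check
#> <cox_mle_fit> HR 0.1359 (95% CI 0.0310-0.5947), log-HR -1.9960 (SE 0.7532)

fit <- samplePosterior(referencePrior("moderately_skeptical"), data, seed = 42)
summarizePosterior(fit)
#> <threshold_table> moderately skeptical: median HR 0.44 (95% CrI 0.21-0.90)
#>  cutoff  prob
#>     1.0 0.988
#>     0.9 0.975
#>     0.8 0.948
#>     0.7 0.897
#>     0.6 0.796
#>     0.5 0.626
#>     0.4 0.390
#>     0.3 0.143
#>     0.2 0.015
#>     0.1 0.000
```

Read: the frequentist estimate says treatment cuts the hazard by ~86%
(HR 0.14). A skeptic who started from "no effect, SD 0.5 on log-HR" should,
after seeing these data, believe there is a 98.8% chance of *any* benefit
and a 79.6% chance of at least a 40% risk reduction (HR < 0.6) — but their
posterior median effect (HR 0.44) stays much more conservative than the
raw estimate, because two events in the treated arm carry limited
information against a tight prior.

`runReanalysis()` repeats this for a whole set of priors and assembles the
prior table, the posterior table and the headline robustness statistic
(the minimum across priors of $P(\mathrm{HR} < 1)$); `writeReport()` dumps
everything as CSV/JSON, including plot-ready prior and posterior density
curves on the HR axis.

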