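---
title: "Modelling interval-censored fruit ripening times"
author: "ripetime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling interval-censored fruit ripening times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripetime)
```

## The scientific problem

Climacteric fruits such as tomato ripen through an ethylene-driven burst:
after a long mature-green phase the fruit shows its first colour change
(turning), passes through orange and light red, and ends red. Two
quantities characterise a genotype's ripening behaviour: the number of
days from anthesis (flower opening) until the first ripening sign, and the
length of the climacteric phase (turning to red). Neither is observed
directly. Fruits are scored a couple of times per week on an ordinal
colour scale, so each transition time is only known to lie between the
last visit before and the first visit after it — the data are interval
censored, with right censoring for fruits that never reach red within the
experiment.

`ripetime` estimates both quantities per genotype from such records, and
additionally carries the two laboratory quantification chains that
accompany ripening phenotyping: relative gene expression by qPCR and
ethylene emission from fruits in flow-through cuvettes.

## The bivariate interval-censored mixed model

For fruit $f$ on truss $b$ of plant $p$ with genotype $m(p)$, write
$Y_{pbf} = (Y^{(1)}_{pbf}, Y^{(2)}_{pbf})^t$ for the days from anthesis to
the turning and to the red stage. The model is additive:

$$Y_{pbf} = \mu + \alpha_{m(p)} + \beta_b + \gamma_f + Z_p + U_{pbf},$$

with all terms 2-vectors: $\mu$ the wild-type baseline, $\alpha$, $\beta$,
$\gamma$ genotype, truss and fruit-position effects in reference coding
(wild type, truss 1, position 1 fixed at zero), a plant random effect
$Z_p \sim N_2(0, \Sigma_0)$, and a fruit residual
$U_{pbf} \sim N_2(0, \Sigma)$. The plant effect is structural: late plants
delay all their fruits in both components, and some plants carry few
fruits, so pooling them without a random effect would overstate precision.
The model is strictly additive — with a handful of fruits per cell the
data cannot support interactions.

Censoring enters through the observation schedule. For each fruit the
package derives the rectangle $[L^{(1)}, R^{(1)}] \times [L^{(2)},
R^{(2)}]$: $L$ is the last visit before the event's stage threshold (or
0, anthesis, if the fruit was already past it at first sight — no fruit
ripens before anthesis), $R$ the first visit at or past it (or $+\infty$).
Orange and light-red sightings sharpen the lower bound of the red event.
The log-likelihood is

$$\sum_p \log \, \mathbb{E}_{\Sigma_0}\Big[ \prod_{b,f}
  P_\Sigma\big(U + \mu + \alpha_{m(p)} + \beta_b + \gamma_f + Z \in
  [L,R]\times[L,R]\big) \Big],$$

a sum over plants of the log expected product, over the plant's fruits, of
bivariate-normal rectangle probabilities.

### Numerical evaluation

Rectangle probabilities use inclusion–exclusion over four bivariate
normal CDF values, computed by Genz's algorithm in compiled code
(absolute accuracy about $5\times10^{-16}$; values are clipped to $[0,1]$
to absorb round-off). The expectation over $Z_p$ uses product
Gauss–Hermite quadrature, 15 nodes per dimension by default.

Node placement matters more than node count here. With several fruits per
plant the integrand — the plant's posterior kernel — is much narrower
than the $N_2(0, \Sigma_0)$ prior, and a prior-centred rule can misplace
all its resolution (we observed errors up to $4\times10^{-2}$
log-likelihood units on five-plant datasets). Each plant's nodes are
therefore centred on an analytic Gaussian proxy of its posterior, built by
treating the interval midpoints as Gaussian pseudo-observations with
covariance $\Sigma$; the exact prior is restored through importance
log-weights, so the rule remains a correct, deterministic and
parameter-smooth quadrature whatever the proxy, and the proxy only
controls accuracy. With this placement the 15-node rule agrees with a
25-node rule to below $10^{-6}$ and with a $10^5$-draw Monte-Carlo
evaluation within its standard error on every test instance. A
(near-)singular $\Sigma_0$ falls back to a prior-whitened rule on the
non-degenerate subspace, which keeps the $\Sigma_0 \to 0$ limit exact and
continuous. Doubly infinite rectangles contribute a zero pseudo-residual
so that uninformative fruits do not shrink the proxy.

Log-sum-exp over nodes of sums of per-fruit log probabilities guards
against underflow; a plant whose likelihood is exactly zero yields
$-\infty$ with a warning naming the plant.

### Estimation and inference

Maximum likelihood runs quasi-Newton (`nlminb`) on an unconstrained
parameterization: fixed effects as-is, $\Sigma$ and $\Sigma_0$ through
log-Cholesky factors, so $\Sigma$ stays positive definite while
$\Sigma_0$ may sink to the positive-semidefinite boundary (a genuine
possibility in small experiments; its log-diagonals are bounded below at
an effective zero, and the residual SD is kept in $[e^{-4.5}, e^{6}]$
days so boundary fits cannot degenerate). Starting values come from
regressing interval midpoints on the design (midpoint heuristic: half an
observation gap beyond a censored bound), with the residual covariance
split evenly between $\Sigma_0$ and $\Sigma$; optional restarts jitter
this start under a fixed seed, and the relative convergence tolerance is
$10^{-8}$ on the log-likelihood. Identical data, options and seed give an
identical fit.

Covariate selection mirrors the analysis the model was built for: the
truss and fruit-position terms are dropped in turn and tested by
likelihood-ratio tests against the full model with asymptotic $\chi^2$
reference distributions (2 df per term level); terms not significant at
$\alpha = 0.05$ are removed. Genotype and the plant random effect are
never dropped. Genotype summaries report $\mu^{(1)} + \alpha^{(1)}_g$
(days to first sign) and $(\mu^{(2)} + \alpha^{(2)}_g) - (\mu^{(1)} +
\alpha^{(1)}_g)$ (ripening length) with delta-method standard errors from
the observed information — exact for these linear transforms — and stars
from per-genotype LRTs against the wild type at 0.05/0.01/0.001. We
report standard errors of the estimates; bar-plot conventions in the
field sometimes label such uncertainties "±SD", which for a fitted
quantity is ambiguous, so the summary names the column `se` explicitly.

## The synthetic-data generator

Because the original greenhouse records are not deposited, the package
ships a generator that reproduces the experiment's statistical structure,
so that every downstream stage is testable. Its defaults are fixed study
conditions, not tuning knobs:

* four genotypes — wild type, an `acs4-1` ACC-synthase mutant, two `rin`
  alleles — with 5/5/5/2 plants, two trusses of three fruits per plant
  (so 5–6 followed fruits per plant);
* twice-weekly scoring from day 30 after anthesis. The schedule runs to
  day 65: in the glasshouse, anthesis is staggered across fruits, so
  per-fruit coverage extends well beyond four calendar weeks even when
  the visits span a month — a hard four-week window would right-censor
  the red transition of slow genotypes entirely;
* $\mu = (42, 52)$ days; genotype effects $(3, 6)$ for `acs4-1`,
  $(6, 12)$ for `rin-2` and $(0.5, 6)$ for `rin-3` on the (turning, red)
  scale, i.e. delayed onset and slower progression for `acs4-1`, strongly
  so for `rin-2`, and essentially progression-only slowing for `rin-3`;
  a small positive fruit-position effect (later positions ripen later)
  and no truss effect;
* $\Sigma_0 = [[3, 1], [1, 3]]$, $\Sigma = [[2, 0.5], [0.5, 2]]$ —
  plant-to-plant SDs of about 1.7 days and fruit residual SDs of about
  1.4 days, with positive cross-correlations.

Latent pairs are drawn from the model and discretized by the schedule;
the intermediate orange and light-red stages, which the model does not
parameterize, are assigned by splitting $[Y^{(1)}, Y^{(2)})$ into three
equal sub-intervals (only the turning and red transitions matter to the
likelihood; the sub-stages make the fixtures realistic and sharpen the
red event's lower bound exactly as real intermediate sightings would).
An unconstrained bivariate Gaussian occasionally yields
$Y^{(2)} < Y^{(1)}$; the residual is redrawn once and, failing that,
$Y^{(2)}$ is clamped to $Y^{(1)}$ and the clamp counted — the model
itself does not constrain the order, but a stage series must be coherent.

What the generator does *not* emulate: scorer disagreement or
misclassification of colour stages, fruit loss during the experiment,
per-fruit anthesis-date error, and non-Gaussian event-time tails. Tests
passing on this generator therefore certify the estimation machinery
under the model's own assumptions, not robustness to those violations.

## qPCR quantification chain

The expression module reimplements the standard relative-quantification
arithmetic:

* **Efficiency (window of linearity).** After subtracting a baseline
  (mean fluorescence of cycles 1–5), contiguous windows of 4–6 cycles of
  $\log_{10}$ fluorescence are regressed on cycle within the usable
  region (above baseline noise, below 80% of plateau). The *earliest*
  window reaching $R^2 \ge 0.995$ defines $E = 10^{\text{slope}}$. We
  deliberately take the earliest qualifying window rather than the
  best-$R^2$ one: under realistic optical noise the best-$R^2$ window
  drifts into the logistic bend below the plateau, where the local slope
  is attenuated by $1/(1 + F/P)$, biasing $E$ low by 1–3%; the earliest
  qualifying window stays in the truly exponential phase and is unbiased
  (a noise-free doubling curve returns exactly 2). Per-plate, the
  arithmetic mean efficiency of all reactions is applied to every gene.
* **Normalized relative quantities.** Technical replicates are averaged
  on the Cq scale; $RQ_{s,g} = E_g^{\overline{Cq}_g - Cq_{s,g}}$ with the
  across-sample mean Cq as calibrator (a pure display choice — NRQ ratios
  between samples are invariant to it); the normalization factor is the
  geometric mean of the five reference-gene RQs, and $NRQ = RQ/NF$.
* **geNORM.** Gene stability $M_g$ is the mean SD across samples of
  pairwise $\log_2$ ratios with the other candidates; iterative exclusion
  ranks the panel, and the pairwise variation $V_{n/n+1}$ (SD of
  $\log_2 NF_n/NF_{n+1}$) decides how many references suffice (0.15 is
  the conventional threshold).
* **Batch merging and testing.** Runs are combined by per-dataset,
  per-gene mean centring of log NRQs, and group comparisons use one-way
  ANOVA with Fisher's protected LSD on log quantities, with a greedy
  compact-letter display. The protection (no pairwise claims without a
  significant omnibus F) is enforced structurally.

## Ethylene emission

A fruit in a cuvette flushed at flow $\phi$ (L/h) raises the outflow
concentration above background $c_{bg}$ by $r\,w/\phi$ at steady state,
so the emission rate is recovered as $r = (\bar c - c_{bg})\,\phi/w$ in
nL h$^{-1}$ g$^{-1}$ when the trace is in nL/L (any volume-fraction unit
works coherently). $\bar c$ averages the final five minutes of the
10–12-minute trace — a fixed, documented summarization window in place of
a by-eye choice of "representative measurement". Mature-green fruits emit
at the noise level, so rates can come out non-positive; before the
log-scale ANOVA they are replaced by half the smallest positive rate and
counted, which keeps the protected LSD applicable without discarding
fruits. Genotypes are compared within one ripening stage only.

## Problem sizes used by the tests and the acceptance script

The simulation studies run at deliberately chosen scales: likelihood
verification on 20 random instances of at most 5 plants x 4 fruits
against a $10^5$-draw Monte-Carlo oracle; parameter recovery on 30 plants
per genotype x 6 fruits over 20 seeds (5 quadrature nodes per dimension —
the adaptive rule is converged well below the reported precision there);
LRT size on 200 replicates of a 10-plant, 4-fruit null design; and the
full pipeline on the default 17-plant design. Recovery of the NRQ fold
change is judged as the mean over 10 replicate datasets because a single
n = 4 experiment at Cq noise 0.15 has a sampling SE of the same order as
the recovery band itself.

## Known limitations

* The two event times per fruit are modelled jointly Gaussian; heavy
  tails or skew in ripening times are not accommodated.
* Asymptotic $\chi^2$ reference distributions are used at modest plant
  counts; the package's own calibration study shows the size is close to
  nominal at 10 plants, but very small experiments should interpret
  borderline p-values cautiously.
* No more than two events per fruit are modelled, and covariates are
  cell means only (no time-varying covariates, no interactions).
* The geNORM and window-of-linearity implementations follow the published
  definitions of those methods; vendor software may differ in
  implementation details such as baseline handling.

## A minimal session

```{r example, eval = FALSE}
sim <- simulate_ripening_experiment(default_design(), default_params(),
                                    seed = 1)
cens <- censor_dataset(sim$observations)
fit <- fit_ripening_model(cens, model_spec(reference = "WT",
                                           include_fruit = "categorical"))
genotype_summary(fit, cens)
```
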