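---
title: "Concurrent model fitting and comparison: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concurrent model fitting and comparison: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbifit)
```

## The inference problem

A multi-subject study yields trial-level data $x_1, \dots, x_N$ and a space of
$K$ candidate computational models. Two questions are usually asked together:
which model does each subject express, and what are the parameters of each
model at the individual and population level? These questions are coupled --
the population that should inform a model's group-level parameters consists of
exactly those subjects who express it -- so `hbifit` answers both within one
generative model.

Each subject carries a latent 1-of-$K$ indicator $z_n$ drawn from model
frequencies $m \sim \mathrm{Dir}(\alpha_0)$. Given $z_{kn} = 1$, the subject's
parameters $h_{kn} \in \mathbb{R}^{D_k}$ are drawn from
$\mathcal{N}(\mu_k, T_k^{-1})$ with diagonal precision $T_k$, and the data from
the model likelihood $p(x_n \mid h_{kn}, M_k)$. Group means and precisions
carry a conjugate Gaussian-Gamma prior
$\mathcal{N}(\mu_k \mid a_0, \mathrm{diag}(b\,\tau_k)^{-1})\,
\mathcal{G}(\tau_k \mid v, s)$.

All likelihoods are parameterized on an unconstrained real scale, so the
Gaussian population assumption is meaningful for every parameter: learning
rates are sigmoid-transformed, inverse temperatures and the Kalman observation
noise exponential-transformed, biases and perseveration weights untransformed.

## The variational algorithm

The posterior is intractable, so inference is mean-field variational Bayes
with the factorization $q(H, Z)\, q(\mu, \tau, m)$. The subject-level factor
is a mixture of Gaussians obtained by quadratic (Laplace) approximation:
$q(h_{kn} \mid z_{kn}=1) = \mathcal{N}(\theta_{kn}, A_{kn}^{-1})$, with
$\theta_{kn}$ the maximum of
$\log p(x_n \mid h, M_k) + \log \mathcal{N}(h \mid \mathbb{E}[\mu_k],
\mathbb{E}[T_k]^{-1})$, $A_{kn}$ the negative Hessian there and $f_{kn}$ the
maximum value. Each iteration performs four steps:

1. **Summary statistics.** $\bar N_k = \sum_n r_{kn}$, the
   responsibility-weighted mean $\bar\theta_k$ and second moment $\bar V_k$
   of the subject modes (including the Laplace covariances $A_{kn}^{-1}$).
2. **Group update.** Conjugate Gaussian-Gamma/Dirichlet updates: e.g.
   $a_k = (\bar N_k \bar\theta_k + b\,a_0)/(\bar N_k + b)$,
   $\beta_k = b + \bar N_k$, $\nu_k = v + \bar N_k/2$,
   $\alpha_k = \alpha_0 + \bar N_k$. The group mean is thus a
   responsibility-weighted average of subject estimates shrunk toward $a_0$
   with weight $b$: subjects only influence a model's group statistics to the
   degree that the model explains them.
3. **Subject update.** Fresh Laplace fits under the current group prior
   $\mathcal{N}(a_k, \nu_k^{-1}\mathrm{diag}(\sigma_k))$.
4. **Responsibility update.**
   $\log\rho_{kn} = \log f_{kn} + \tfrac{D_k}{2}\log 2\pi -
   \tfrac12 \log |A_{kn}| + \lambda_k + \mathbb{E}[\log m_k]$, with
   $\lambda_k = \tfrac{D_k}{2}(\psi(\nu_k) - \log\nu_k - 1/\beta_k)$ and
   $\mathbb{E}[\log m_k] = \psi(\alpha_k) - \psi(\sum_j \alpha_j)$;
   responsibilities are the per-subject softmax (log-sum-exp stabilized,
   exact ties kept as equal splits).

Iteration stops when the normalized parameter change
$\hat d = \tfrac1K \sum_k \tfrac1{D_k} \sum_i
(\hat\theta_{ki}^{j} - \hat\theta_{ki}^{j-1})^2$, with
$\hat\theta_{ki} = \bar\theta_{ki}/\sqrt{\bar V_{kii}}$, falls strictly below
0.01, or after 50 iterations (flagged distinctly in the result).

### Priors and initialization

Defaults are minimally informative: $a_0 = 0$, $b = 1$ (one effective prior
subject for the means), $v = 1/2$ (one effective prior subject for the
precisions), $s = 0.01$ so the posterior Gamma scale is dominated by data, and
$\alpha_0 = 1$ (uniform prior over model frequencies). A small $s$ also
produces the prior-reversion property: a model that takes no responsibility
ends with its subject-level estimates at $a_0$ with very small variance.

Subject posteriors are initialized by fitting each model to each subject
independently under a zero-mean Gaussian prior with variance 6.25 per
dimension -- the same wide prior non-hierarchical inference uses, chosen so
that the initial modes equal the NHI modes. (The nominal prior expectation
$\mathbb{E}[\tau] = v/s = 50$ would instead imply an initial prior variance of
0.02, which pins every initial fit at zero and starves the first summary
statistics; we deliberately do not use it.) Responsibilities start uniform at
$1/K$.

### The lower bound and the frequency null

The variational lower bound $L$ is assembled analytically: under the Laplace
approximation the expected data-plus-parameter term for one subject and model
collapses to $\log f_{kn} - D_k/2 + \lambda_k$, and combining it with the
entropy of $q(H, Z)$ and the $z$ prior gives $\sum_n \log \sum_k \rho_{kn}$;
the remaining terms are closed-form negative KL divergences of the
Gaussian-Gamma and Dirichlet posteriors from their priors. The bound is
validated two ways in the test suite: it equals an independently assembled
analytic expression on a fully conjugate single-subject toy, and it is
monotone across iterations on Gaussian toys where the Laplace step is exact.
On real (non-quadratic) likelihoods monotonicity is only approximate, which
is why convergence is monitored through $\hat d$ rather than $L$.

Protected exceedance probabilities need the same model fitted under the prior
null hypothesis that all frequencies are equal ($\alpha_0 \to \infty$). We
realize the limit by hard pinning: $\mathbb{E}[\log m_k] = -\log K$ in the
responsibility update and the Dirichlet KL term evaluated at its symmetric
limit (zero). With bounds $L$ and $L_0$ of the alternative and null runs,
$P_0 = 1/(1 + e^{L - L_0})$ and
$\tilde\phi_k = \phi_k (1 - P_0) + P_0/K$. Exceedance probabilities
$\phi_k$ are exact for $K = 2$ (regularized incomplete Beta) and Monte-Carlo
with $10^6$ Dirichlet draws otherwise.

### Group-level inference

Marginalizing the Gaussian-Gamma posterior gives a Student marginal for each
group mean: $n_k = 2\nu_k$ degrees of freedom, center $a_{ki}$ and scale
$s_{ki}/\sqrt{n_k}$ (the *hierarchical error*), where
$s_{ki}^2 = 2\sigma_{ki}/\beta_k$. Degrees of freedom therefore track the
responsibility-weighted subject count ($n_k = 1 + \bar N_k$ at the default
$v = 1/2$), not the total sample size -- the statistical cost of attributing
only part of the population to the model. `hbi_ttest()` reports the posterior
tail probability of a null value and a credible interval from this marginal.
`fit_new_subject()` uses the same marginal as a multivariate Student
predictive prior (the `b = 2v` convention holds at the defaults) and returns
the MAP estimate for an unseen subject.

## Subject-level optimization

Every procedure (HBI, NHI, HPE) shares one Laplace primitive:
quasi-Newton (BFGS) maximization of the penalized log-likelihood with
C-level finite-difference gradients, five restarts by default (the prior mean
plus prior draws) because reinforcement-learning likelihoods are multimodal.
Within HBI/HPE iterations the previous mode is used as a warm start with one
additional prior draw (HBI) or alone (HPE); the independent initial fits keep
the full restart count. Hessians come from central finite differences at the
mode, are symmetrized, and non-positive-definite curvature is repaired by
eigenvalue flooring at $10^{-6}$ with a flag. Restart draws are seeded
deterministically from the master seed, the model name, the subject id and
the iteration, so results are reproducible and independent of subject
ordering. Convergence uses a relative tolerance of $10^{-10}$ on the
objective; gradient tolerances tighter than this add cost without changing
any downstream statistic at the reported precisions.

## Baselines

**NHI** fits every subject independently under a fixed
$\mathcal{N}(0, 6.25)$ prior per dimension and scores each cell by the
Laplace evidence $\log f + \tfrac D2 \log 2\pi - \tfrac12 \log|A|$; the
$N \times K$ evidence matrix feeds random-effects Bayesian model selection
(Dirichlet-multinomial variational updates), whose own protected exceedance
probabilities compare its free energy against the uniform-frequency null
free energy $\sum_n \log \mathrm{mean}_k e^{\mathrm{logev}_{nk}}$.

**HPE** is empirical-Bayes expectation-maximization for a single model under
the fixed-effects assumption: Laplace E-steps under
$\mathcal{N}(\mu, \mathrm{diag}(V))$, closed-form moment M-steps
($\mu = \frac1N\sum\theta_n$; $V$ kept diagonal to mirror the diagonal group
precision used everywhere else), convergence at relative change $10^{-4}$.
Model comparison is fixed-effects: summed per-subject evidence under the
fitted group prior minus an iBIC-style penalty
$\tfrac12 (2 D_k) \log(\text{total trials})$ for the mean and variance
hyperparameters. The penalty form is isolated in one place
(`hpe()$group_evidence`) so a different group-complexity convention can be
swapped in.

## The model library and task generators

Built-in models (all softmax choice with inverse temperature
$\beta = e^{\text{raw}}$): constant-learning-rate delta rule; dual learning
rates for positive/negative prediction errors (the delta rule is nested at
$\alpha^+ = \alpha^-$); a Kalman filter whose gain decays over trials (free
observation noise $\omega$, initial value mean 0, prior variance 1, no
process noise -- the minimal one-extra-parameter form of a decaying learning
rate); an actor-critic with a TD critic and actor preference updates sharing
one learning rate; a non-learning "last outcome" strategy; go/no-go learners
with a Pavlovian bias $\pm b$ keyed to stimulus valence; perseveration
variants adding a previous-action bonus; and two-step task agents
(model-free SARSA with the eligibility backup fixed at $\lambda = 1$,
transition-model planner over the known 0.7/0.3 structure, and their hybrid
with weight $w$, which nests both). Action values for 0/1 outcomes are
initialized at the 0.5 midpoint; stage-1/stage-2 learning rates and inverse
temperatures are collapsed to one $\alpha$ and one $\beta$ in the two-step
models to keep the model space small.

Tasks are binarized Gaussian random walks: latent reward probabilities step
with sd 0.1 and reflect at [0.2, 0.8] by default, and outcomes are Bernoulli
draws. The go/no-go task interleaves two stimuli (appetitive/aversive) at
random with independent walks per stimulus-action pair and outcome values
independent of valence; the two-step task uses fixed 0.7/0.3 common/rare
transitions into two second-stage states.

## The synthetic-data generator and what it does (not) show

`generate_group_dataset()` draws each subject's unconstrained parameters from
the configured normal (or moment-matched skewed) distribution, transforms
them, and simulates the agent on a freshly generated task. The shipped
scenario defaults (also in `inst/extdata/scenarios.yaml`):

* Same-complexity mixture: 10 delta-rule subjects (learning rate mean 0.3 on
  the constrained scale) vs 30 Kalman-filter subjects (observation noise
  mean 1), $T = 100$.
* Nested mixture: 10 delta-rule subjects with learning-rate mean 0.1 vs 30
  dual-rate subjects with rates 0.8 / 0.4 -- the single rate deliberately
  below both dual rates, the regime in which fixed-effects pooling biases
  parameter estimates most.
* Group-inference scenario: 20 go/no-go subjects whose bias parameter has
  group variance 1 and a configurable mean (effect size), optionally drawn
  from the skewed family.

Inverse temperatures are drawn with mean 3 on the constrained scale
(log-scale sd 0.5) and unconstrained-scale sds default to 0.5 throughout:
moderate decision noise and population spread typical of bandit studies.
These are configuration values, not constants, and were fixed once when the
scenarios were defined.

The skewed family is a shifted/scaled Beta solved to match (mean, variance,
skewness, kurtosis) exactly -- the Pearson Type I region covers the target
(0, 1, -0.5, 3) -- and reduces to a Gaussian at (0, 1, 0, 3).

What passing these simulations does *not* show: real choice data contain
lapses, session effects, reaction-time structure and non-Gaussian parameter
distributions that the generator deliberately omits (only the skew study
departs from normality, and only in one parameter). Recovery on these
scenarios validates the inference machinery, not any specific empirical
claim.

## Numerical choices and degenerate inputs

* $\bar N_k < 10^{-6}$: the weighted mean/covariance are undefined; they
  revert to $a_0$ and the identity, which realizes prior reversion.
* $\bar V_k$ is symmetrized and its diagonal floored at $10^{-10}$ before
  the Gamma update (numerical asymmetry of $A_{kn}^{-1}$).
* A subject whose evidence is $-\infty$ under every model raises an error
  naming the subject.
* Empty trial sequences have log-likelihood 0, so a flat-likelihood subject
  is fit to the prior.
* Argmax ties in simulators break toward the lower action index; exact
  responsibility ties stay equal.

## Problem sizes used in the shipped checks

The test suite runs the recovery studies at 5-10 replications and the
script `scripts/acceptance.R` at 10-20 replications with 40 subjects per
group and $T = 100$, plus 2000-group t-test benchmarks; these sizes were
chosen so a complete desk run finishes in minutes while keeping Monte-Carlo
noise small relative to the effects being checked. The p-value uniformity
study runs at 40 replications as a Kolmogorov-Smirnov check; the full
2000-replication version of that study is a long-running computation that
the package exposes through the same functions (`scenario_bias()`,
`hbi_ttest()`) for anyone who wants to reproduce it at scale.

A note on the nested scenario: at its defaults (single learning rate 0.1,
dual rates 0.8/0.4, inverse temperature around 3, $T = 100$) the
log-likelihood advantage of the true dual-rate parameters over the
best-fitting single-rate model on dual-generated subjects is small (median
near zero by grid search), so per-subject attribution in this scenario
plateaus near 80% rather than approaching certainty; group-level selection of
the dual-rate model is nonetheless reliable. Separability — and with it
attribution accuracy — rises with the trial count and with lower decision
noise, both of which are scenario configuration, not algorithm settings.

## Known limitations

* Group precisions are diagonal by construction; parameter correlations at
  the population level are not modeled.
* The Laplace approximation can misrepresent strongly skewed or multimodal
  subject posteriors; restarts mitigate mode-finding, not curvature,
  limitations.
* Inference under the frequency null is realized by hard pinning rather than
  a large finite $\alpha_0$; the two differ only at order $1/\alpha_0$.
* The HBI t-test inherits the normality assumption on the unconstrained
  scale; under skewed generating distributions its false-positive rate is
  elevated at small $N$ and approaches nominal as $N$ grows (see the
  benchmark in `scripts/acceptance.R`).
* When $P_0$ is large (frequency differences attributable to chance),
  frequency-conditioned parameter estimates should not be interpreted; fit
  the models separately instead.
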