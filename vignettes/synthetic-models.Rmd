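---
title: "Synthetic-model likelihoods for stochastic gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic-model likelihoods for stochastic gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbsynlik)
```

## The inference problem

Gene expression at the single-cell level is intrinsically stochastic: the
chemical master equation (CME) describes the probability
$p(\mathbf{x} \mid \theta, t)$ of observing molecule counts $\mathbf{x}$ at
time $t$ under rate parameters $\theta$. Bayesian inference needs the
likelihood $p(\mathbf{x}_{\mathrm{obs}} \mid \theta)$ of single-cell count
data, but the CME is solvable only for very small systems: the finite state
projection (FSP) truncates the state space and solves the resulting linear
ODE exactly, yet the number of states grows exponentially with the number
of species (the toggle switch below would need on the order of $10^9$
states). Simulating the CME, in contrast, is easy: Gillespie's stochastic
simulation algorithm (SSA) draws exact trajectories at any $\theta$.

`nbsynlik` turns simulations into likelihoods through a *synthetic model*:
a tractable surrogate distribution fitted to SSA output at each $\theta$
and then evaluated at the observed data. The surrogate family is chosen to
match what gene-expression data actually look like — mixtures of negative
binomials (NB) over counts, reflecting switching between discrete promoter
activity states with overdispersed (bursty) expression within each state.

## The surrogate and its fitting

For a single observation time, the surrogate is a $K$-component NB mixture
$q_\phi(x) = \sum_k w_k \,\mathrm{NB}(x;\, r_k, p_k)$. Its parameters are
chosen to minimize the Kullback–Leibler divergence from the (inaccessible)
CME marginal; replacing the CME marginal by SSA samples makes this
equivalent to maximum likelihood on the simulated counts, computed by
expectation–maximization. The M-step profiles out $p_k = r_k/(r_k+\mu_k)$
through the weighted-mean identity and updates $r_k$ by a safeguarded
Newton iteration on the profile score (digamma terms); since the profile
score can have several roots for awkward weight configurations, a
candidate update is only accepted if it does not lower the weighted
component likelihood (a generalized-EM step), which keeps the EM and
Baum–Welch traces monotone. Because counts are
small integers, the implementation aggregates EM weights per distinct count
value, which makes each update pass cost $O(\#\text{distinct values})$
rather than $O(n)$.

For time-series data (the same cells followed over $T$ observation times)
the mixture components become hidden states of an HMM: an initial
distribution $\pi$ at the first observation time, one $K \times K$
transition matrix per consecutive-observation interval, and per-(time,
state) NB emissions, conditionally independent across observed species
given the state. Fitting is by Baum–Welch (EM for HMMs); evaluation of the
observed cells uses the scaled forward algorithm, which marginalizes over
hidden paths exactly. Integrating out the hidden state shows the marginal
at any time is again an NB mixture.

The full likelihood estimator `syntheticLoglik()` is therefore:

1. simulate `nSim` trajectories at $\theta$ on the data's observation grid
   (SSA, or Extrande thinning when a reaction is modulated by a
   time-dependent input);
2. fit the surrogate to the simulations (Baum–Welch in `"hmm"` mode;
   independent per-time mixture EM in `"independent_mnb"` mode);
3. evaluate the observed cells under the fitted surrogate.

The surrogate is refit from scratch at every $\theta$, so the estimate is
stochastic; its spread grows roughly linearly with the number of observed
datapoints and shrinks with `nSim` (`syntheticLoglikVariance()` measures
both). Inside MCMC each proposal gets a fresh simulation seed derived from
the master seed and the iteration counter, and the current state's estimate
is retained unless `refreshCurrent = TRUE` (pseudo-marginal convention; the
estimator is a fitted maximum, so it is not exactly unbiased and the
sampler targets a correspondingly perturbed posterior — both conventions
are provided).

## Choices a user should know about

* **`nSim` (default 10,000).** Enough that surrogate-fit noise does not
  dominate MCMC acceptance. In the packaged experiments 1,500–5,000 suffices
  for 25–100 cells; scale it with the number of observed datapoints.
* **`K` (default 2).** Number of mixture components / hidden states;
  natural choices follow the promoter structure (2 for a two-state gene,
  3–4 for the four-state gene). Extra components are harmless: they merge
  (means closer than a relative $10^{-6}$) or receive negligible weight
  (floored at $10^{-6}$).
* **Mode.** `"hmm"` for time-correlated data; `"independent_mnb"` for
  population snapshots, where each time point is a different group of
  cells and time correlations are meaningless. For weakly correlated time
  series the independent mode is a legitimate simplification (used here
  for the toggle switch; full HMM fits performed similarly but were more
  prone to local optima).
* **Restarts.** EM is initialized from quantile blocks of the sorted
  samples (method-of-moments per block, components aligned across times by
  sorted mean) plus randomized perturbations; the best of `nRestarts`
  (default 3) is kept.
* **Convergence.** Mixture EM stops at relative log-likelihood change
  $10^{-8}$ (500 iterations cap); Baum–Welch at $10^{-6}$ (200 cap) —
  looser by design because HMM fits run inside MCMC loops.
* **Fano-factor floor.** An NB component cannot represent underdispersed
  counts (Fano factor $\le 1$); blocks with variance below the mean are
  clamped to near-Poisson ($r = 10^4$). This is a stated limitation of the
  NB family, accepted rather than worked around.

## Ground truth and baselines

*FSP.* `fspDatasetLoglik()` is the exact reference for small networks. The
truncated generator includes one entry per geometric burst jump (tail mass
below $10^{-12}$ dropped); leaked boundary mass is the mass defect, which
bounds the truncation error and is reported alongside every propagation.
Truncation bounds start at the largest observed count plus 50% headroom
and double until the defect at the final observation time is below
$10^{-8}$ (cap $10^6$ states). Time-homogeneous propagation uses the
matrix exponential (cached per unique inter-observation gap during
filtering); time-varying generators are split as $A_0 + f(t) A_1$ and
integrated with a stiff solver (`lsoda`, rtol $10^{-9}$, atol $10^{-12}$),
rebuilding the signal factor continuously through the interpolant. For
time-correlated data the likelihood is computed by exact Bayesian
filtering: propagate, weight by the mass consistent with the observation
(gene states are latent and marginalized), condition and renormalize.
Filtering is the correct treatment for correlated rows; for independent
snapshots the marginal pmf is evaluated per (cell, time).

*GSL.* Gaussian synthetic likelihoods fit a multivariate Gaussian to the
simulated molecule numbers by maximum likelihood — jointly over the
vectorized $S \times T$ trajectory (joint mode) or per time point — with a
small diagonal shrinkage $\lambda\,\mathrm{tr}(\Sigma)/d$ ($\lambda =
10^{-6}$, escalated if singular).

*MBI.* Moment-based inference models the per-time first and second
uncentred *sample* moments as Gaussian, with means from the analytic CME
moments and covariances from the exact finite-$n$ formulas
($\mathrm{Var}(m_1) = (\mu_2 - \mu_1^2)/n$, $\mathrm{Cov}(m_1, m_2) =
(\mu_3 - \mu_1\mu_2)/n$, $\mathrm{Var}(m_2) = (\mu_4 - \mu_2^2)/n$, and
their multivariate analogues), requiring moments to order 4. Moment
equations close only for affine propensities, so protein–promoter binding
is first linearized by the linear mapping approximation (LMA): the
bimolecular propensity $\sigma\,g\,p$ becomes $\sigma \langle P \mid G=1
\rangle\, g$ with the conditional mean determined self-consistently. The
LMA was the only moment closure that consistently gave positive moments in
the original comparison study, so it is the only one implemented here.
Our implementation iterates the fixed point on the *stationary* moments of
the linearized network (a long-time integration, which respects
conservation laws where a direct linear solve is singular), yielding
time-constant effective rates. A time-dependent conditional mean would be
somewhat more faithful early in the transient; the stationary choice keeps
the linearized network an ordinary `ReactionNetwork` and is accurate to a
few percent on the packaged examples.

*ABC-SMC.* Summaries are the per-time first and second uncentred moments;
the discrepancy is the sum of squared *relative* errors (absolute-error
fallback for observed entries below $10^{-12}$). Round 1 samples the box
prior (tolerance $\infty$ by default); each later round draws from a
Gaussian fitted to the previous round's acceptances (covariance inflated
by 2, rejected against the box), with tolerance set to the median accepted
discrepancy of the previous round — standard SMC-ABC practice where the
original scheme leaves the schedule open. Importance weights are
$1/\text{proposal density}$ under the uniform prior.

## Sampling and estimation

`mhSample()` is a random-walk Metropolis–Hastings sampler with independent
Gaussian steps, default step size 2% of each prior range (the reference
experiments specify only a "fixed Gaussian kernel"), and out-of-box
proposals rejected. `mleFit()` performs multi-start Nelder–Mead (Brent in
one dimension) in logit-transformed box coordinates; for stochastic
objectives, fixing the estimator seed (`makeLoglikFn(..., crn = TRUE)`)
makes the search surface deterministic (common random numbers). Burn-in is
never applied silently: `credibleInterval()` takes it as an explicit
argument (default 20%), and `gelmanRubin()` screens multi-chain runs.

## What the synthetic data emulate — and what they do not

The fixture generator reproduces the study conditions: an autoregulatory
feedback loop (gene with bound/unbound promoter, bursty protein production
with geometric bursts of mean $b$, dilution rate 1 so all rates are in
units of protein dilution) observed as 25 cell time series at $t = 4, 8,
12, 16$; a eukaryotic toggle switch with 10 species where each gene's
nuclear protein represses the other promoter, observed as 100 cell time
series of both cytoplasmic proteins at $t = 1, \dots, 8$; and a four-state
gene driven by a kinase input signal, observed as independent mRNA
snapshots. True parameter values for these fixtures are repository
choices (labelled `source: fixture_choice`), selected to lie in the
regime the reference experiments describe: promoter switching slow
relative to protein dilution ($\sigma_b = 0.02$, $\sigma_u = 0.1$ against
a dilution rate of 1), which produces bimodal protein distributions and
makes the two production rates separately identifiable, and leak-free
repressed production ($\rho_b = 0$ exactly) — the setting where
distribution-level inference visibly outperforms moment- and
Gaussian-level inference. (With fast switching only the
occupancy-averaged production rate is identifiable from data of this
size: the exact FSP posterior itself then shows a flat
$(\rho_u, \rho_b)$ ridge, so no likelihood method could concentrate
$\rho_b$ at zero.) Initial conditions are all genes unbound with
zero molecules, flagged in every truth manifest, since the reference
experiments do not state theirs.

Synthetic data contain intrinsic noise only. Real single-cell measurements
add technical noise (capture efficiency, amplification), extrinsic
parameter variability across cells, and cell-cycle effects; none are
simulated, so passing tests demonstrate correctness of the inference
machinery under the model, not robustness to model misspecification. The
toggle-switch repressor identity (nuclear protein binds the opposing
promoter) and the four-state gene wiring (nearest-neighbour chain with a
basal-plus-kinase-driven G2→G1 rate, giving 12 free parameters) are
modelling choices where the source material leaves details open; the MAPK
transition structure is user-configurable for this reason.

## Numerical conventions

* Geometric bursts live on $k \in \{0, 1, 2, \dots\}$ with $P(k) =
  b^k/(1+b)^{k+1}$ (mean $b$); a $k = 0$ firing is a no-op. The SSA and
  the FSP share this convention exactly.
* SSA observation sampling records the state immediately *before* each
  observation time (left-limit convention at exact ties, which have
  probability zero).
* Per-cell RNG streams are derived from the master seed by a splitmix64
  mix, so datasets are bit-reproducible and cells are independent streams.
  All estimator functions take explicit seeds; R-side randomness runs
  under a save/restore wrapper and never leaks into the caller's RNG
  state.
* Extrande uses the signal's declared global upper bound for the thinning
  envelope — simple and always valid; envelope efficiency is secondary at
  the problem sizes targeted here.
* The MH proposal operates on the natural (linear) parameter scale.

## Problem sizes used in the packaged checks

The test-suite experiments are scaled to run on a single CPU: the
surrogate-fidelity comparison uses 20 prior-drawn parameter sets on the
25-cell negative-feedback fixture with `nSim = 5000`, re-evaluated under 3
seeds; the posterior-recovery run uses 5,000 MH iterations with `nSim =
1500`, one EM restart per fit; MBI calibration uses 200 replicate
datasets.
These sizes were chosen as the smallest at which the qualitative claims
(surrogate fidelity ordering, credible-interval coverage,
standard-normal calibration) are stable across seeds.

## Known limitations

* NB mixtures cannot represent Fano factors below 1 (underdispersion);
  hypergeometric-type emission families would be needed.
* The synthetic-likelihood estimate is a fitted maximum, not an unbiased
  likelihood estimator, so pseudo-marginal MH is approximate (checked in
  the tests against an exactly unbiased toy estimator).
* Random-walk MH is adequate for the low-dimensional posteriors treated
  here; the 12-parameter four-state gene model is handled by MLE plus
  predictive checks rather than full posterior sampling.
* FSP is limited by state-space size (cap $10^6$ states); the toggle
  switch is intentionally out of FSP reach and is evaluated only through
  simulation-based methods.
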