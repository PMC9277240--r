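# nbsynlik

Simulation-based Bayesian inference and uncertainty quantification for
stochastic models of gene expression.

## The problem

Single-cell gene expression is governed by the chemical master equation
(CME): a linear ODE system over all discrete molecule-count states of a
reaction network. Likelihood-based inference needs
p(x<sub>obs</sub> | θ), but the CME is solvable only for tiny networks —
the finite state projection (FSP) handles a few hundred to a few thousand
states, while realistic networks (a eukaryotic toggle switch with mRNA and
protein translocation) would need ~10⁹. Simulating the CME, by contrast,
is easy with Gillespie's stochastic simulation algorithm (SSA).

`nbsynlik` approximates the likelihood with a **synthetic model**: a
tractable surrogate fitted to SSA simulations at each parameter set θ and
evaluated at the observed counts. The surrogate is a mixture of negative
binomials — the distribution family that actually fits transcript and
protein counts, with Fano factor 1 + μ/r > 1 — and, for time-series data,
a hidden Markov model whose states carry NB emissions:

1. simulate trajectories at θ on the observation grid (SSA, or the exact
   Extrande thinning algorithm when a reaction is driven by a
   time-dependent input such as a kinase signal);
2. fit the surrogate by expectation–maximization (Baum–Welch for the HMM;
   per-time NB-mixture EM for independent population snapshots);
3. evaluate the observed cells with the forward algorithm to get
   p̂<sub>syn</sub>(x<sub>obs</sub> | θ).

The estimate plugs into random-walk Metropolis–Hastings (pseudo-marginal
style: the current state's estimate is stored and reused) or into
multi-start maximum-likelihood estimation. For small networks the package
also computes the exact FSP likelihood (including exact Bayesian filtering
for time-correlated cells), and it implements the three standard
baselines: Gaussian synthetic likelihoods (GSL), moment-based inference
(MBI, with the linear mapping approximation closing the moment equations
of networks with protein–promoter binding), and sequential ABC on moment
summaries.

Built-in models: an autoregulatory feedback loop (two promoter states,
bursty protein production), a two-gene eukaryotic toggle switch
(10 species), a four-state gene driven by a kinase input (the MAPK/STL1
setting), and immigration–death toys.

## Worked example

Simulate the negative-feedback fixture (25 cells observed at t = 4, 8, 12,
16, protein counts only; true repressed production rate `rho_b = 0`), then
compare the synthetic-model likelihood against the exact FSP value at the
true parameters:

```r
library(nbsynlik)

fx  <- generateFixture("autoreg_negfb", seed = 11)
th  <- fx$truth$params
net <- fx$network

fspDatasetLoglik(net, th, fx$data)
#> [1] -255.6331
as.numeric(syntheticLoglik(net, th, fx$data,
                           synlikConfig(nSim = 5000, K = 2), seed = 5))
#> [1] -257.3132
gslLoglik(net, th, fx$data, gslConfig(nSim = 5000), seed = 5)
#> [1] -303.9206
```

The synthetic model is within ~2 log-units of the exact
log-likelihood; the Gaussian surrogate is ~48 log-units off because the
protein distribution is bimodal (slow promoter switching), which a
Gaussian cannot represent. Posterior sampling with the synthetic
likelihood:

```r
cfg <- synlikConfig(nSim = 1500, K = 2, nRestarts = 1, maxIter = 60,
                    tol = 1e-5)
fn  <- makeLoglikFn(net, fx$data, "sm", seed = 702, cfg = cfg)
ch  <- mhSample(fn, fx$prior, theta0 = th, nIter = 5000, seed = 703,
                method = "sm")
credibleInterval(ch, "rho_b", level = 0.9)
#>         lo         hi
#> 0.01211277 0.43615389
```

The 90% interval for `rho_b` hugs zero — the method recovers leak-free
repressed expression from distribution-level information, where
moment-level methods report spurious leaky expression.

A thin command-line wrapper over these functions ships at
`inst/cli/nbsynlik-cli.R` (`fixtures`, `simulate`, `infer`, `mle`,
`predictive`, `compare-likelihoods` subcommands).

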