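---
title: "Models and methods in codiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in codiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`codiv` estimates how many divergence events are shared among several
pairs of diverged populations, and when those events happened, from
biallelic characters. This vignette describes the model, the numerical
machinery, the simulator, and the design decisions behind both — in
enough detail that the behaviour of every tunable parameter can be
anticipated.

## Data and likelihood

For each population pair, the data at one site are the allele counts
`(n1, r1), (n2, r2)`: the number of sampled gene copies per population
and how many carry the arbitrarily labelled "red" allele. Sites with
identical counts are interchangeable (gene copies are exchangeable under
the coalescent), so data are stored as weighted pattern tables. Missing
cells simply reduce the sampled count at that site; a site represented
in only one population is still informative and is handled by pooling
only the sampled population's lineages at the root.

Each site evolves on its own coalescent gene tree inside the pair's
species tree: two descendant populations with size parameters `N_d1`,
`N_d2` (each the product of effective size and mutation rate) merging at
divergence time `t` into a root population of size `N_root`. Mutation is
a two-state continuous-time Markov chain; with stationary green
frequency `pi`, the relative rates are `u = mu / (2 (1 - pi))` (red to
green) and `v = mu / (2 pi)`, normalized so the stationary substitution
flux equals `mu`. With `mu = 1` (the default) all times are in expected
substitutions per site. At `pi = 0.5` the model is the symmetric
two-state chain, which we recommend for recoded nucleotide data because
binary recoding of nucleotides is arbitrary and only the symmetric model
is invariant to it.

The pattern probability integrates over all gene trees and substitution
histories analytically. Partial likelihoods are indexed by states
`(n, r)` — `n` ancestral lineages of which `r` carry red — and evolve up
a branch by the linear ODE whose generator combines pairwise coalescence
(rate `1 / (2 N)` per lineage pair, the diploid convention: the expected
pairwise coalescence time within a population equals `2 N`) with
per-lineage mutation. A coalescence merges two same-coloured lineages
and the merged ancestor is uniform among the survivors, which gives the
level-coupling weights `r / n` and `(n - r) / n`. At the species-tree
root, the two branch tables are pooled — the within-branch split of red
alleles is hypergeometric given the pooled counts — and contracted
against a "root functional" `w(n, r)`: the probability of the observed
data given `n` entering lineages with `r` reds, integrating the
coalescent down to the most recent common ancestor, whose state is
stationary. `w` solves small tridiagonal systems level by level (it is
the left null vector of the root generator), so no numerical integration
over the infinite root branch is needed.

Two properties anchor correctness and are enforced in the test suite:
pattern probabilities sum to one over all patterns at fixed sample
sizes, and simulated pattern frequencies from the generative coalescent
process match the analytic probabilities (a cross-module check run at
one million characters).

### Constant-character corrections

When constant characters are excluded upstream, the likelihood is
conditioned on variability. The per-site correction divides each
pattern's probability by the probability of a variable character *at
that pattern's own sample sizes*, so it remains exact under missing
data. The maximum-sample-size (SNAPP-style) correction divides the whole
product by the variable probability at the maximum counts; the two
coincide exactly under complete sampling and deviate otherwise. Both are
available; the per-site form is the default.

## Priors

The divergence model — the partition of pairs into events plus the event
times — has a Dirichlet-process prior with concentration `alpha` and a
gamma base distribution on event times (exponential priors are gamma
with shape one). Under the induced Chinese restaurant process, two pairs
share an event with prior probability `1 / (1 + alpha)`; `alpha` may be
fixed or given a gamma hyperprior. Gamma distributions are specified by
shape and mean throughout, matching how such priors are usually
reported. Descendant sizes get gamma priors; the root size is
parameterized *relative* to the mean descendant size with its own gamma
prior, because prior knowledge is usually about relative ancestral size,
and the root size is the nuisance parameter most strongly correlated
with the divergence time. The state frequency `pi` is fixed (default
0.5) or beta-distributed per pair. Mutation rates are fixed at one: the
data cannot inform relative rates across unconnected pairs, so rate
uncertainty should be handled by informative priors on the time scale
instead.

## Posterior sampling

One generation of the sampler applies:

* a multiplicative scale move to each free size parameter of each pair
  (window 0.5 on the log scale) and a reflected window move to each free
  `pi`;
* a multiplicative scale move to each event time;
* a joint mixing move per event that scales the event time by `s` and
  every member pair's relative root size by `1 / s` (Jacobian
  `(1 - m) log s` for `m` scaled sizes), which traverses the
  time/root-size likelihood ridge;
* one Gibbs sweep over pair assignments using Neal's Algorithm 8 with
  two auxiliary events (a vacated singleton event re-enters as an
  auxiliary candidate, so the move is reversible); auxiliary times are
  fresh draws from the base distribution;
* an auxiliary-variable Gibbs update of `alpha` under its gamma
  hyperprior, when free.

Chains are deterministic functions of the data, configuration and seed;
multi-chain runs offset the seed by the chain index. The standard
operator validation — running the sampler with the likelihood switched
off must reproduce every prior marginal — is part of the test suite, as
is a check that the cached log-likelihood and log-prior in the trace
match fresh evaluations at sampled states.

### Numerical strategy

A likelihood evaluation needs the branch operator `exp(A t)` only at the
observed leaf states. The generator `A` is block upper-bidiagonal in the
lineage count and each diagonal block is a tridiagonal matrix whose
sub/super-diagonal products are positive, so `A` is similar to a
symmetric tridiagonal block matrix and has a real spectrum. Each
eigenvector is seeded with a diagonal-block eigenvector at its source
level and extended downward by tridiagonal back-substitution, giving a
full eigendecomposition orders of magnitude faster than a dense
nonsymmetric solve. The factorization is cached per size value, and
`exp(A t)` columns are reconstructed per proposal; degenerate spectra
(detected by a singularity guard and an `exp(A * 0) = I` check) fall
back to a dense eigensolve and, failing that, to uniformization — a
Poisson-weighted series with no cancellation. The root functional and
pooled-weight matrix are cached per root-size value with two slots, and
recently used branch columns are memoized, because Metropolis proposals
alternate between the current and proposed values. These caches change
nothing mathematically; the chain likelihood agrees with the reference
dense-exponential path to about `1e-10`.

## The simulator

`simulate_dataset()` draws the divergence model and nuisance parameters
from the same prior configuration used for inference (so matched-prior
calibration studies are exact by construction), then simulates characters
along coalescent gene trees: independent coalescents in each descendant
branch truncated at `t`, survivors coalescing in the root population,
and sites evolving down the tree from a stationary root state. All sites
of a locus share one gene tree (`locus_length = 1` gives unlinked
characters; there is no intra-locus recombination, and loci are
contiguous equal-length blocks). For unlinked characters an equivalent
`"multinomial"` mode draws pattern counts directly from the exact
pattern distribution; the two modes target the same distribution of
counts (tested against each other), and the multinomial mode makes very
large data sets cheap.

Two perturbations mimic features of reduced-representation data:
`apply_missingness()` retains every gene copy of every site
independently with probability `p_sample` (counts are rebuilt
hypergeometrically, sites empty in both populations are dropped), and
`apply_singleton_bias()` retains each singleton site — exactly one copy,
pooling both populations, differing from all others — with probability
`p_retain`. When both are requested, missingness is applied first, since
acquisition bias acts on assembled patterns. The simulator emulates
unlinked or linked biallelic characters with these two artefacts only;
it does not model read-level error, assembly, selection, migration after
divergence, or rate variation among sites, so passing calibration tests
speaks to the statistical machinery, not to robustness against every
feature of real data.

Default study conditions follow the published simulation designs: three
pairs, ten gene copies per population, `alpha = 1.414216` (prior mean of
two events for three pairs), exponential event times with mean 0.01,
descendant sizes `Gamma(shape 5, mean 0.002)`, relative root size
`Gamma(shape 100, mean 1)`, `pi = 0.5`, `mu = 1`.

## Summaries and diagnostics

`summarize_trace()` pools post-burn-in samples and reports the posterior
over the number of events, the maximum a posteriori model (ties broken
by canonical order and flagged), 95% credible sets built greedily by
descending probability, and equal-tailed credible intervals for
divergence times (chosen over highest-density intervals because
equal-tailed quantiles are unambiguous and are what coverage experiments
require). Models are identified by canonical restricted-growth partition
strings (first pair always event 0), with times marginalized. Bayes
factors for each number of events against all others are posterior-odds
to prior-odds ratios, with the prior obtained by Monte Carlo simulation
from the Dirichlet process (`dp_prior_k_probs()`, default at least 1e5
draws). Burn-in is never hard-coded; it is an argument to
summarization. Convergence diagnostics are the potential scale reduction
factor (the square-root ratio of the pooled to the within-chain
variance, requiring at least two equal-length chains) and an
autocorrelation-based effective sample size using Geyer's initial
positive sequence truncation; any standard autocorrelation-based ESS
variant would serve, and the tests pin down only the properties (iid
sequences give ESS near `n`; an AR(1) process matches its closed form).

## Problem sizes and scaled-down studies

The published calibration experiments use hundreds to tens of thousands
of replicate data sets with chains of 37,500-75,000 generations. The
package's own studies (in `tests/testthat/test-acceptance.R`) run the
same designs at 50 replicates with 1,500-generation chains (each
generation is a full operator sweep, which mixes far faster per
generation than single-proposal schedules), 100k-500k characters per
pair, and report the same statistics: credible-interval coverage, the
frequency with which the true number of events lands in the 95%
credible set, and median posterior probabilities of the true number of
events and the true model. Assertions use tolerances fixed in advance
from the binomial or bootstrap-quantile Monte Carlo error of each
statistic at 50 replicates.

## Known limitations

* No migration after divergence, no recombination within loci, no rate
  variation among sites or pairs.
* Four-or-more-state models are out of scope; nucleotides must be
  recoded (first base in each column becomes green) or polyallelic
  sites removed, and with recoded data `pi` should stay fixed at 0.5.
* Heterozygous diploid genotypes are assumed already split into two
  gene-copy rows; the package does not parse genotype likelihoods or
  VCF.
* The mixing move updates the root sizes of all pairs currently sharing
  the event; with many pairs per event and very strong ridges, longer
  chains may be needed.
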