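# codiv

Full-likelihood Bayesian inference of shared divergence times across
multiple pairs of populations, from biallelic genomic characters.

## The problem

Comparative phylogeographers often study several co-distributed pairs of
diverged populations — say, sister populations of several species split
across the same pair of islands — and ask whether the pairs diverged
together (one shared event, e.g. one episode of sea-level change) or
independently. With `N` pairs there are `Bell(N)` possible *divergence
models*: partitions of the pairs into divergence events, each event with
its own time (five models for three pairs, fifteen for four). `codiv`
estimates the posterior distribution over these models, and over the
event times, directly from genome-scale data.

## The model

For each pair, data are biallelic characters ("red"/"green" states,
including constant sites): at every site, the allele counts
`(n1, r1), (n2, r2)` record how many gene copies were sampled in each
population and how many carry the red allele. Each character evolves
along its own coalescent gene tree within the pair's species tree —
an ancestral population of effective size `N_root` splitting time `t`
ago (in expected substitutions per site) into two descendants of sizes
`N_d1`, `N_d2` — under a two-state mutation model with stationary
frequency `pi`. The probability of every allele-count pattern is
computed *exactly* by analytic integration over all gene trees and
substitution histories (a matrix exponential of the combined
coalescent-plus-mutation generator on lineage-count/allele-count
states), so no gene trees are ever sampled. When only variable
characters are available the likelihood is conditioned on variability,
either per site or at the maximum sample sizes (the SNAPP-style
correction).

Across pairs, the assignment of pairs to divergence events follows a
Dirichlet-process prior with concentration `alpha` (two pairs share an
event with prior probability `1 / (1 + alpha)`); event times are iid
gamma, descendant sizes gamma, and the root size is a gamma-distributed
multiple of the mean descendant size. The joint posterior over the
partition, event times, and per-pair nuisance parameters is sampled by
MCMC: Neal's Algorithm-8 Gibbs sweeps over the partition, multiplicative
scale moves on positive parameters, and a joint event-time/root-size
mixing move that follows the divergence-time–ancestral-size likelihood
ridge.

## A worked example

Simulate three pairs (10 gene copies per population, 50,000 characters
each) under the model, then re-estimate the divergence model with
matched priors:

```r
library(codiv)
set.seed(42)

cfg <- prior_config(tau_shape = 1, tau_mean = 0.01, alpha = 1.414216)
sim <- simulate_dataset(cfg, n_pairs = 3, n_sites = 50000)
paste(sim$truth$partition, collapse = ",")   # "0,0,0" - one shared event

trace <- run_chains(sim$collection, cfg, n_chains = 2,
                    n_generations = 2000, sample_every = 5, seed = 1)
summ <- summarize_trace(trace, burn_in = 80)
summ
#> <codiv_summary> 642 samples (2 chain(s), burn-in 80 each)
#> posterior number of divergence events:
#>  k       prob
#>  1 0.76479751
#>  2 0.21806854
#>  3 0.01713396
#> MAP model: 0,0,0 (p = 0.765)
#> 95% credible set of k: {1, 2}
#> divergence times:
#>   pair       mean     median      lower      upper
#>  pair1 0.01350843 0.01352158 0.01285588 0.01411528
#>  pair2 0.01341569 0.01347190 0.01240081 0.01401443
#>  pair3 0.01364300 0.01360623 0.01302987 0.01464115
```

The sampler recovers the generating model (all three pairs sharing one
divergence, posterior probability 0.77) and the true divergence time
(0.014 expected substitutions per site sits inside every 95% interval).
Bayes factors compare each number of events against all others, with the
prior obtained by Monte Carlo simulation from the Dirichlet process:

```r
prior_k <- dp_prior_k_probs(3, alpha = 1.414216, n_sims = 1e5, seed = 1)
bayes_factors_k(summ$p_k, prior_k)
#>       k posterior prior      bf
#> 1     1    0.765  0.242 10.2
#> 2     2    0.218  0.518  0.260
#> 3     3    0.0171 0.240  0.0552
```

`tidy()`, `glance()`, `autoplot()` and `plot_divergence_times()` give
tibble and ggplot views of chains and summaries; `psrf()` and `ess()`
provide convergence diagnostics (here PSRF ~1.00 across chains).

Real data enter through `read_comparison()` (NEXUS or FASTA plus a
sequence-to-population map; nucleotides are recoded to binary with the
first base of each column as the green state) or through plain
tab-separated pattern tables; see `inst/extdata/` for small examples.
A command-line interface mirrors the main workflows:

```sh
inst/cli/codiv simulate  --config config.yml --out sims --replicates 10
inst/cli/codiv infer     --config config.yml --out run --seed 1
inst/cli/codiv summarize --trace run/chain_1_trace.tsv --out summary
inst/cli/codiv dpprobs   --pairs 4 --alpha 0.44 --sims 100000
```

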