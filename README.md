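# ucatestbed

A simulation testbed for phylogenetic model-selection tests of **universal
common ancestry (UCA)** against **independent origins (IO)**, for people who
study the behavior of such tests rather than apply them blindly: molecular
evolutionists, phylogenetic methods developers, and anyone reviewing claims
built on cross-domain likelihood comparisons.

## The problem

Given protein sequences falling into groups (say a eukaryotic quartet *E*
and a bacterial quartet *B*), UCA says all of them are related by one
phylogeny; IO says each group has its own tree and the groups are unrelated.
IO is mathematically the limit of a single tree whose connecting branch
length tends to infinity. The classical test scores both hypotheses on one
fixed multiple alignment and reports

```
delta_AIC = AIC(B) + AIC(E) - AIC(BE),     AIC = 2K - 2 logL
```

with positive values favoring UCA. The catch: the shared alignment is a
point estimate of homology, produced by an algorithm that *optimizes* the
data toward common ancestry. This package quantifies that bias by
simulation and implements the remedy — treating the unaligned sequences as
data and coestimating alignment and branch lengths in a joint Bayesian
model (TKF91 indels + an amino-acid replacement model), comparing the
hypotheses by a Bayes factor

```
delta_BF = log P(B+E) - log P(B) - log P(E)
```

estimated from harmonic means of sampled likelihoods, with |delta_BF| > 10
as strong evidence.

## What's inside

* `substitution_model()`, `transition_probabilities()`,
  `discrete_gamma_rates()` — rtREV/LG (+Γ, +F) reversible models.
* `evolve_sequences()`, `scenario_preset()`, `generate_scenario()` — the
  synthetic-data generator and the named study designs (`fig2`,
  `fig2-scaled`, `fig3`, `fig3-scaled`).
* `log_likelihood()`, `fit_ml()`, `io_limit_gap()` — Felsenstein pruning,
  ML branch lengths/shape on fixed topologies, and the
  IO-equals-infinite-branch demonstration.
* `progressive_msa()`, `pairwise_align()`, `identity_alignment()`,
  `gap_fraction()` — a deterministic progressive aligner (k-mer UPGMA guide
  tree, profile–profile affine DP).
* `run_uca_aic_test()`, `split_alignment()` — the fixed-alignment delta-AIC
  test in aligned and unaligned modes.
* `run_mcmc()`, `run_delta_bf_test()`, `harmonic_mean_logml()`,
  `tkf91_pair_hmm()`, `pair_marginal_loglik()` — the coestimation sampler
  and the Bayes-factor test.
* `run_fig2_experiment()`, `run_fig3_experiment()`, `render_report()`,
  `autoplot()` — replicated experiments, tables and figures; results are
  tibbles, fitted objects have `tidy()`/`glance()` methods.

See `vignettes/uca-testbed-methods.Rmd` for the models, the move set, the
priors, and every numerical choice. A thin command-line wrapper lives in
`inst/cli/uca-testbed.R`.

## A worked example

Simulate one independent-origins replicate (two unrelated quartets, 1000
sites, rtREV+Γ+F) and run the delta-AIC test with and without the alignment
step:

```r
library(ucatestbed)

cfg  <- scenario_preset("fig2-scaled", seed = 1, n_replicates = 1)
rep1 <- generate_scenario(cfg)[[1]]
groups <- lapply(cfg$trees, function(t) t$tip.label)
topo <- c(cfg$trees, list(joint = join_trees(cfg$trees$E, cfg$trees$B, 1)))

un <- run_uca_aic_test(rep1$combined, groups, cfg$model,
                       mode = "unaligned", topologies = topo)
al <- run_uca_aic_test(rep1$combined, groups, cfg$model,
                       mode = "aligned", topologies = topo)
un
#> common-ancestry AIC test (unaligned mode): delta = -233.78 (-0.2338/site) -> IO
al
#> common-ancestry AIC test (aligned mode): delta = 132.42 (0.1187/site) -> UCA
gap_fraction(al$alignment)
#> [1] 0.1039427
```

The same data, simulated with **no** historical connection between the
groups, yield delta-AIC = −233.8 (correctly IO) when scored as-is and
+132.4 (spuriously UCA) after progressive alignment introduces ~10% gaps:
the alignment step alone flips the verdict. Per-group log-likelihoods are
identical in both modes (columns gapped across a whole group contribute
zero), so the flip is driven entirely by the joint hypothesis improving
under the optimized homology. `run_fig2_experiment()` repeats this over
replicates; with the shipped presets the unaligned mode favors independent
origins in every replicate, while the aligned-mode false-positive rate is
high but length-dependent (about 85–95% of replicates at the scaled
preset's 1000 sites; the bias strengthens with sequence length).

The numbers above are what the code prints under seed 1; your platform's
BLAS may change trailing digits only.

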