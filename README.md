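# cultnet

Simulation toolkit for studying how the loss of individuals affects
information flow and cultural accumulation in female mammalian social
networks. It is aimed at behavioural ecologists and conservation scientists
who want to ask, for a given social structure: *how fast does the group's
communication capacity degrade as members are removed, and what does losing
particular age classes do to social learning and innovation?*

The package has three layers:

1. **Synthetic network generator.** Multi-wave weighted association
   networks for three structural archetypes — a small dense baboon-like
   troop, a large very dense elephant-like aggregation, and a large sparse,
   modular dolphin-like society — built from a planted-partition tie model
   with Beta-distributed weights in (0, 1] and aged female individuals.
   User-supplied node/edge CSVs with the same schema drop in anywhere a
   synthetic wave is used.
2. **Removal robustness.** Weighted global efficiency
   $E = \frac{1}{n(n-1)}\sum_{i \ne j} 1/d(i,j)$, with $d$ the weighted
   shortest-path distance (edge length $1/w$, disconnected pairs
   contributing 0), tracked while nodes are removed 1% at a time up to 20%
   under random, oldest-first, degree- or betweenness-targeted strategies.
3. **Social learning on NK landscapes.** An agent-based model on a rugged
   NK fitness landscape (default $N = 12$, $K = 6$: 4096 positions) in
   which, each timestep, an age-class-dependent set of "innovators"
   explores adjacent positions with probability π while everyone else
   learns vertically — copying the best position held by a strictly older
   direct tie with probability equal to the tie weight — and only uphill
   moves are accepted. Removal scenarios (none / random 10% / oldest 10%)
   are compared against paired no-removal baselines.

## Worked example

```r
library(cultnet)

profiles <- builtin_profiles()
waves <- generate_dataset(profiles$dolphin, seed = 1)
summarize_waves(waves)$summary
#>                 metric         mean           sd
#> 1              n_nodes 131.50000000 1.603434e+01
#> 2              n_edges 780.16666667 1.892442e+02
#> 3           modularity   0.55036902 2.219464e-02
#> 4         transitivity   0.20091126 1.415216e-02
#> 5              density   0.08993344 2.438928e-03
#> 6 weighted_path_length   0.05662687 8.511665e-03
```

Six dolphin-archetype waves of ~132 females: sparse (density 0.090, the
generator's calibration target), strongly modular (Q ≈ 0.55), low
transitivity. Now attack one wave:

```r
net <- build_network(waves[[1]])
remove_and_measure(net, "betweenness")
#> <efficiency_trajectory 'betweenness'> intact E = 0.151, E at 20% removed = 0.123
remove_and_measure(net, removal_strategy("random", n_replicates = 100), seed = 1)
#> <efficiency_trajectory 'random'> intact E = 0.151, E at 20% removed = 0.143
```

Removing the 20% most central brokers costs this network 19% of its
efficiency; removing the same number at random costs 5% — the signature
vulnerability of sparse, modular societies, and the contrast is much weaker
on the dense elephant archetype.

```r
l <- nk_landscape(12, 6, seed = 2)
count_local_optima(l)
#> [1] 84
base <- run_simulation(net, l, scenario_config("all", "none", pi = 0.1,
                       timesteps = 50, n_sims = 10, seed = 3), 25)
rem  <- run_simulation(net, l, scenario_config("all", "age",  pi = 0.1,
                       timesteps = 50, n_sims = 10, seed = 3), 25)
tail(difference_from_baseline(rem, base), 3)
#>    timestep    mean_diff         q25           q75
#> 49       48 -0.006190945 -0.01241628 -0.0009814504
#> 50       49 -0.006400384 -0.01222600 -0.0016085047
#> 51       50 -0.006098687 -0.01276442 -0.0013228270
```

The moderately rugged landscape has 84 local peaks. Removing the oldest
10% before the run leaves mean group fitness ~0.006 below the paired
no-removal baseline after 50 timesteps at π = 0.1 (negative = fitness cost
of removal; the q25–q75 columns give the ribbon across replicates).

`run_pi_sweep()` crosses waves × innovation scenarios × removal types × an
innovation-rate grid, and `run_full_experiment(experiment_config(...))`
drives the whole pipeline (generation → structure summary → attack →
learning sweep) into CSV tables plus a JSON manifest that reproduces every
file byte-for-byte. See the vignette in `vignettes/` for the model details
and design decisions.

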