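# connperc

Percolation analysis of weighted structural brain networks
(connectomes), for researchers studying how white-matter topology
degrades under targeted attack and what that implies, in time reverse,
about how it grew.

A structural connectome is an undirected graph of gray-matter regions
whose edges carry two tractography weights: **tract length** (mean
streamline length, mm) and **tract density** (streamline count).
Removing edges one at a time in increasing order of either property and
tracking the giant-cluster fraction `P` against the surviving mean
degree `<k> = 2E/N` yields attack curves that — unlike random graphs,
which have a percolation critical point at `<k> = 1` — decay gradually
all the way to `<k> = 0`, shedding isolated nodes rather than
fragmenting into secondary clusters.

The package implements the one-parameter growth theory behind that
signature, **Giant Cluster Self Preference (GCSP)**: a network that is
always a single cluster, where each new edge is `alpha` times more
likely to land on an open pair inside the cluster than to branch out
and recruit a new node. Its branching probability for a cluster of `n`
nodes and `E` edges in a network of final size `N` is

    p(n -> n+1 | E -> E+1) = (n(N-n)/alpha) / ( n(n-1)/2 - E + n(N-n)/alpha ),

its finite-size behaviour is an exactly evolvable master equation for
`p(n|E)`, and its infinite-size limit is the closed form

    P(<k>) = 1 + (1 - 2/alpha)^-1 * W0( (2/alpha - 1) e^(2/alpha-1) e^(-<k>/alpha) ),

with `W0` the principal Lambert W branch. The package fits `alpha` to
empirical curves by least squares and ships the **Early Path
Dominance** generator — GCSP growth inside a growing tissue, where
early edges end up longest and densest — plus Erdős–Rényi,
preferential-attachment, small-world and spatially embedded comparison
models.

## What's in the box

| area | functions |
|---|---|
| connectome I/O | `connectome()`, `read_connectome()`, `write_connectome()`, `prune_isolates()`, `summary()` |
| attack engine | `edge_ordering()`, `targeted_attack()`, `giant_fraction()`, `secondary_cluster_census()` |
| theory | `gcsp_P()`, `random_graph_P()`, `transition_probability()`, `master_evolve()`, `ode_rhs()`, `theory_curve()` |
| fitting | `fit_alpha()`, `resample_curve()`, `rank_correlation()` |
| generators | `simulate_epd()`, `simulate_gcsp_growth()`, `erdos_renyi_gnm()`, `preferential_attachment()`, `watts_strogatz()`, `spatial_random()`, `clustering_and_pathlength()` |
| pipeline | `run_subject()`, `run_cohort()`, `run_epd_experiment()` (CLI wrapper in `inst/scripts/connperc.R`) |

## Worked example

Grow a synthetic connectome at the reference parameters (727 regions,
`alpha = 11`, final mean degree 100, inflation factors 1.0001 and
1.001), attack it both ways, and refit `alpha`:

```r
library(connperc)

sim <- simulate_epd(seed = 1)
con <- sim$connectome
summary(con)
#> $N
#> [1] 727
#> $E
#> [1] 36350
#> $mean_degree
#> [1] 100

atk <- targeted_attack(con, edge_ordering("tract_density", "increasing"))
fit_alpha(atk)
#> gcsp_fit (tract_density): alpha_hat = 10.585, sse = 0.000214 (20 points, k_max 100)

atkL <- targeted_attack(con, edge_ordering("tract_length", "increasing"))
fit_alpha(atkL)
#> gcsp_fit (tract_length): alpha_hat = 11.596, sse = 0.00116 (20 points, k_max 100)
```

The density attack removes edges in exactly reverse creation order, so
its fit recovers the generative `alpha = 11` up to finite-size bias;
the length attack replays growth only approximately (coordinate
randomness scrambles the local order), which systematically pushes its
fitted `alpha` higher — the same asymmetry seen between
tract-length and tract-density fits on real scans. Per-subject analysis
of a connectome file follows the same path through `run_subject()`,
which prunes zero-degree regions, runs both attacks, fits both alphas
and writes a JSON report with curve TSVs.

Theory curves for plotting or comparison come from
`theory_curve(seq(0, 100, 0.5), "gcsp", alpha = 11)` and
`random_graph_P()`; `master_evolve(11, 727, 36350)` gives the exact
finite-size trajectory.

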