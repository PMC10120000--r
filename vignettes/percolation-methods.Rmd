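---
title: "Percolation analysis of structural connectomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Percolation analysis of structural connectomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connperc)
```

## The scientific question

Structural brain networks — gray-matter regions linked by white-matter
tracts — are, in healthy adults, a single connected whole. How a growing
brain manages to integrate every new region into that whole, rather than
leaving behind disconnected "bridges to nowhere", is a question about
network *growth* that cannot be observed directly: no longitudinal data
set traces a single brain's full developmental trajectory of topologies.

Percolation analysis offers an indirect route. A **targeted attack**
removes edges one at a time in rank order of a physical property and
tracks the fraction `P` of nodes remaining in the giant cluster as a
function of the surviving mean degree `<k> = 2E/N`. Read right-to-left,
the curve describes a breakdown; read left-to-right, it is a candidate
growth trajectory. The two properties attacked here are the two standard
outputs of diffusion-MRI tractography:

* **tract length** — mean streamline length (mm) between two regions;
* **tract density** — streamline count between two regions.

Attacking edges from smallest to largest value of either property
produces `P(<k>)` curves that decay *gradually all the way to
`<k> = 0`*, quite unlike a random graph, which has a percolation
critical point at `<k> = 1`.

## Giant Cluster Self Preference (GCSP)

The empirical signature driving the theory is the near-total absence of
**secondary clusters** (components other than the giant one with more
than one node) at every stage of these attacks: the giant cluster sheds
isolated nodes one at a time instead of fragmenting. The theory takes
this to the extreme: a growing network is *always one cluster*, and each
growth step adds exactly one edge that either

* lands on one of the `n(n-1)/2 - E` open pairs inside the cluster, or
* branches out and recruits one new node (there are `N - n` candidates,
  each reachable through any of the `n` cluster nodes, discounted by the
  self-preference factor `1/alpha`).

This gives the branching probability (`transition_probability()`)

    p(n -> n+1 | E -> E+1) =
        (n (N-n) / alpha) / ( n(n-1)/2 - E + n (N-n) / alpha ),

a one-parameter model: `alpha` is how many times more likely a new edge
is to reinforce the interior of the cluster than to recruit. The exact
finite-`N` evolution of the cluster-size distribution `p(n|E)` is a
discrete master equation (`master_evolve()`), started from
`p(n|0) = delta_{n,1}`. In the limit `N -> infinity` at fixed
`rho = n/N` and `kappa = 2E/N` the distribution collapses onto a
deterministic trajectory `f(kappa)` obeying the characteristic equation
(`ode_rhs()`)

    f'(kappa) = (1 - f) / (2 - (2 - alpha) f),   f(0) = 0,

whose closed-form solution (`gcsp_P()`) uses the principal branch of the
Lambert W function:

    P(kappa) = 1 + (1 - 2/alpha)^-1 *
               W0( (2/alpha - 1) e^(2/alpha - 1) e^(-kappa/alpha) ).

Three properties matter in practice, and the test suite verifies each:

* `P(0) = 0` and initial slope 1/2 for *every* `alpha` (each early edge
  tends to recruit, adding one node and raising `kappa` by `2/N`);
* no critical point: `P > 0` for every `kappa > 0`, so the curve decays
  gradually under attack, as the data do;
* for `alpha = 2` the prefactor degenerates and the limit is
  `P = 1 - exp(-kappa/2)`.

The published rendering of the closed form is typographically ambiguous
in the W argument's prefactor and exponent grouping. The grouping
implemented here is the unique reading satisfying `P(0) = 0` and the
characteristic equation; rather than trusting the transcription, the
package asserts consistency with a high-accuracy `deSolve` integration
of the ODE (to 1e-6 over `kappa` in [0, 100]) in its tests. The same
tests show the formula is valid as written for every `alpha > 0`,
including `alpha < 2` (the W argument stays within the principal
branch's real domain), so no separate integration fallback is used.

The comparison baseline is the random-graph closed form
(`random_graph_P()`), `P = 1 + W0(-k e^-k)/k`, zero below `<k> = 1`,
checked against its fixed point `P = 1 - exp(-<k> P)` to 1e-10.

### Numerical notes

* **Lambert W.** The theory evaluates `W0` arbitrarily close to the
  branch point `-1/e` (as `alpha` grows and `kappa -> 0`). The package
  ships a vectorised principal-branch evaluation seeded by the
  branch-point series `W = -1 + p - p^2/3 + 11 p^3/72`,
  `p = sqrt(2(1 + e z))`, refined by Halley iteration; generic
  Newton-type iterations can stall in that corner. Accuracy is ~1e-14,
  cross-checked against `pracma::lambertWp` on interior arguments.
* **Master equation.** Dense probability vectors over `n = 1..N`
  (no truncation); total mass is checked to 1e-12 at every step.
  States that would exceed a cluster's edge capacity are unreachable
  because the branching probability is exactly 1 when the cluster is
  complete; the recursion preserves this.

## The attack engine

Ranks are frozen before the attack: property values never change during
removal, so "remove the currently smallest" is one static sort. Exact
ties (ubiquitous for tract density, where many edges have density 1)
are ordered by a seeded uniform shuffle — `tie_seed` is an explicit
parameter, so poorly resolved curves (e.g. decreasing-density attack)
can be characterised as envelopes over seeds instead of silently
depending on sort stability.

`P` is always normalised by the post-pruning node count, held fixed
across the curve. The curve itself is computed by adding edges in
*reverse* removal order while maintaining a union-find forest (size
tracking, path halving), which is equivalent to recomputing components
after every forward removal and reduces the cost from `O(E^2)` to
near-linear. The forward recomputation (igraph components after every
removal) remains the normative definition and is the oracle the tests
compare against, edge for edge, on graphs of up to 200 edges.

## Fitting alpha

`fit_alpha()` resamples a curve on `n_points = 20` equidistant mean
degrees spanning `[0, k_max]` (`k_max` = the intact network's mean
degree) with a step-function convention — each grid point takes the P
of the recorded step closest from above, never an interpolation — and
minimises the sum of squared P residuals against `gcsp_P()`. The
objective is scanned on an alpha grid of step 0.05 over `[2.05, 60]`
(cheap, and no unimodality assumption) and the best cell is refined
with `stats::optimize()`. Twenty points is a documented default, not a
value the theory prescribes; fits on smooth curves move by well under
2% when doubled to 40 (tested). The fit is deterministic given the
curve and settings. Each attack property is fitted separately; no joint
fit is defined.

## The Early Path Dominance generator

GCSP fixes the topology sequence but says nothing about lengths or
densities. The Early Path Dominance model supplies them by letting the
tissue grow under the cluster's feet:

* nodes originate uniformly inside the unit ball at the moment they are
  recruited (a fresh, uninflated draw — the one place the growth rules
  leave a choice; the alternative, inflating the newborn coordinate by
  its own birth step, changes lengths by one part in 10^4);
* after every edge addition, every existing coordinate is multiplied by
  `coord_scale = 1.0001` — early edges lengthen;
* every edge starts at density 1 and is multiplied by
  `density_scale = 1.001` per subsequent addition — early edges
  densify, so final density is exactly `1.001^(E - i)` for the i-th
  created edge;
* edge lengths are Euclidean distances between final coordinates
  (lengths track current coordinates; the attack happens at the end of
  growth). Inflation is applied lazily as one closed-form factor per
  node, tested identical to naive per-step multiplication to 1e-9.

Defaults are the reference parameter set of the study conditions:
`N = 727` regions (the Talairach parcellation count), `alpha = 11`,
growth to final mean degree 100. Internal edges are placed uniformly
over absent in-cluster pairs (rejection sampling — this is exactly the
counting behind the branching probability); branch targets attach a new
node to a uniformly chosen cluster node. Labels are assigned in
recruitment order; since coordinates are i.i.d. at recruitment, this is
distributionally identical to picking an unplaced label at random.

Because densities decrease strictly with creation order, the
increasing-density attack removes edges in exactly reverse creation
order: the attack curve *is* the time-reversed growth trajectory, point
for point (tested). The increasing-length attack replays growth only
approximately — coordinate randomness scrambles the order locally —
which is why refitting length-attack curves needs a somewhat larger
alpha (about 13) than the generative value recovered by density-attack
fits (about 11). The growth occasionally ends with a label never
recruited (the master equation puts that probability near 2% at the
reference parameters); such a region formed zero edges, is not part of
the network — mirroring the zero-edge pruning every empirical
connectome undergoes — and so every simulated network ends as a single
cluster with `P = 1`.

The growth trajectory always divides by the *final* `N`, matching the
limit construction in which `rho` and `kappa` share a denominator.

## Comparison models

All alternatives are generated through igraph and wrapped to carry the
weights the attack needs:

* `erdos_renyi_gnm()` — `G(N, M)`; at `N = 727`, `<k> = 29.9` its mean
  local clustering is `<k>/(N-1) ~ 0.04`, an order of magnitude below
  the ~0.6 of brain-like networks at the same density.
* `preferential_attachment()` — linear and nonlinear kernels
  (`degree^exponent`); its growth trajectory has slope `1/(2m)` in
  `(kappa, rho)` after burn-in.
* `watts_strogatz()` — ring lattice plus rewiring, nodes on the unit
  circle with chord-length edges; at `p_rewire = 0` its clustering is
  the lattice value `3(k-2)/(4(k-1))`, and its distance attack shows
  the abrupt lattice-percolation collapse the brain curves lack.
* `spatial_random()` — uniform-ball coordinates, uniformly random
  pairs, Euclidean lengths: brain-like edge geometry with no growth
  structure. Its distance-attack curve has a transition the
  one-parameter theory cannot track (largest fit residual above 0.06,
  versus under 0.05 for the growth model's own curves).

## What the synthetic data do and do not show

The generators reproduce the *attack-curve phenomenology* the theory
addresses: single-cluster growth, gradual no-critical-point decay,
refitted `alpha` in the empirical 10-16 range, and the
length-versus-density asymmetry. They do not emulate other features of
real connectomes — degree-distribution details, hemispheric structure,
spatially correlated parcellation geometry, measurement noise in
tractography, or the anticorrelation between tract length and density —
so green tests here validate the machinery and the theory's internal
consistency, not any claim about a particular empirical dataset.
Cohort-level covariate analysis is restricted to a generic Spearman
helper (`rank_correlation()`); assembling real cohorts is out of scope.

## Problem sizes and determinism

Simulation studies in the tests and the acceptance script use 50
independent growth runs at the reference size (727 nodes, 36,350
edges), 30 seeds per generative alpha for parameter recovery, and 20
random graphs for the clustering contrast — sizes at which the
stochastic summaries are stable (the SE of the mean fitted alpha over
50 runs is under 0.1). Every stochastic function takes an explicit
`seed` and restores the caller's RNG state; given a seed, all outputs
are bit-reproducible.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_epd(seed = 1)                      # reference parameters
atk <- targeted_attack(sim$connectome,
                       edge_ordering("tract_density", "increasing"))
fit <- fit_alpha(atk)
fit
#> gcsp_fit (tract_density): alpha_hat = 10.585, sse = 0.000214 (20 points, k_max 100)
```

## Known limitations

* `alpha` is constant over growth; real growth rates change during
  development.
* The theory carries no edge weights; it explains curve *shapes*, not
  why length and density fits differ — the generator, not the closed
  form, accounts for that gap.
* Decreasing-density attacks are dominated by density-1 ties and are
  reported as seed envelopes rather than single curves.
* The master equation is `O(N * E_max)` with dense vectors; fine to a
  few thousand nodes, not meant for much larger `N`.
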