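---
title: "Predicting paths of tumor progression with CPMs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting paths of tumor progression with CPMs: models and methods}
  %\VignetteEncoding{UTF-8}
---

`cpmpaths` evaluates whether cancer progression models (CPMs) fitted to
cross-sectional mutation data can recover the distribution of mutational
paths a tumor population actually takes, and how well they estimate
evolutionary unpredictability. This vignette is the package's account of
the models it implements, the parameters that matter, and the design
decisions taken where the design was genuinely open.

## Fitness landscapes

A landscape assigns a birth rate to each of the $2^K$ genotypes over $K$
driver genes ($K \le 14$; the package enumerates genotypes exhaustively).
Three generators are provided.

**Representable.** A random DAG of restrictions is drawn (a uniform random
topological order; each forward gene-to-gene edge included independently
with probability `density`, default 0.3), its fitness graph is built (nodes
are the genotypes satisfying the conjunctive AND restrictions, edges
connect genotypes differing by one added mutation), and birth rates are
assigned iteratively: the wild type gets rate 1 and every other node gets
$\max(\text{parent rates}) \times U(1.01, 1.19)$, an average multiplicative
fitness increase of 0.1 per driver. Genotypes violating the restrictions
get rate exactly 0 and can never enter the population. These landscapes
have a single peak at the fully mutated genotype — the world CPMs assume.

**Local maxima.** Same construction, but before rate assignment a random
selection of fitness-graph edges is removed under the constraint that every
accessible genotype stays reachable from the wild type: edges are shuffled
and removed one at a time (removals that disconnect a node are undone)
until a fraction `removal_fraction` (default 0.5) has been processed. The
procedure is repeated `n_tries = 50` times and the pruning that created the
most sinks (local maxima) is kept. Accessible genotypes are unchanged; only
paths are missing — isolating the effect of multi-peakedness.

**Rough Mount Fuji (RMF).** Log birth rate is
$-c \cdot d(g, r) + \epsilon_g$ with $r$ a reference genotype drawn
uniformly, $d$ the Hamming distance, and $\epsilon_g \sim N(0, \sigma^2)$
iid (House of Cards component); the draw is repeated until $r$ is the
unique global maximum, and rates are rescaled so the wild type has rate 1.
For a pure House of Cards ($c = 0$) the reference is instead relabelled to
the argmax, since rejection would succeed with probability $2^{-K}$. The
multiplicative (log-linear) form of the additive component was chosen so
that per-step fitness effects are scale-free, comparable to the
multiplicative $U(1.01, 1.19)$ increments of the DAG-derived kinds.
Defaults $c = 0.05$, $\sigma = 0.03$ were fixed once by calibrating against
the study conditions that the three kinds should have comparable numbers of
accessible genotypes while RMF is distinctly multi-peaked: at $K = 7$ these
values give a median of roughly 15 uphill-accessible genotypes (random
DAGs at density 0.3 give a few tens), many local maxima, and peaks of 4–5
mutations.

**Two notions of local maximum.** Landscape statistics
(`landscape_stats`) count classical local maxima: genotypes with no fitter
Hamming-1 neighbor (for DAG-derived kinds, equivalently the fitness-graph
sinks). The simulator's stopping rule instead uses *forward* maxima —
genotypes with no fitter neighbor among those adding one mutation — because
a population that cannot back-mutate can overshoot a classical peak and
would otherwise never meet the stopping condition. Every classical maximum
is a forward maximum, so the stopping rule covers all classical peaks.

## Evolutionary simulations

Evolution is a continuous-time multi-type birth–death process. Each clone
divides at its genotype's birth rate; all clones share the density-dependent
death rate $D(N) = \log(1 + N/K_c)$ with $K_c = N_0/(e-1)$, so a wild-type
population of size $N_0$ starts at demographic equilibrium and the carrying
capacity grows with fitness (tumor size grows roughly logarithmically with
the number of drivers). At each division, each unmutated gene mutates with
its per-gene rate (defaults: constant $10^{-5}$ per gene per division, or
gene-specific rates log-uniform on $[0.2, 5] \times 10^{-5}$, a max/min
ratio capped at 25); at most one new mutation per division, a negligible
approximation at these rates. Offspring whose genotype has birth rate 0 are
never added. Initial sizes of 2000, 50000 and $10^6$ cells span the regimes
from clonal sweeps to heavy clonal interference.

A run stops when a forward local maximum holds at least
`fixation_threshold` (default $\theta = 0.99$) of the population; runs
exceeding `max_time` ($10^6$ time units) or going extinct are restarted
with a fresh random stream. Two integrators sit behind one interface: an
exact Gillespie algorithm and a tau-leap (births Poisson, deaths binomial
with $p = 1 - e^{-D\tau}$, $\tau$ chosen so the per-capita event
probability per step is `leap_frac` = 0.1). The tau-leap is the default —
at $N_0 = 2000$ and $K = 7$ a run to fixation costs about 10 ms versus
roughly half a second for the exact algorithm — and the two are
cross-checked against each other on small landscapes in the test suite.

The **Line of Descent (LOD)** is obtained by tracing the clone-ancestry
links of the fixated genotype back to the wild type; each LOD step adds
exactly one mutation. When a genotype's clone goes extinct and the genotype
arises again from a different parent, the ancestry link is re-recorded, so
the LOD reflects the ancestry of the clone actually alive at fixation
(rather than the first arrival); this is the one place where reasonable LOD
definitions can differ, and the package's choice is the surviving-lineage
one. `batch_simulate` also reports whether every gene appeared in at least
one genotype ever created across the runs; callers regenerate the landscape
when that fails, mirroring the study design.

## Detection and data sets

Each simulated tumor contributes one observation. A Beta deviate —
$B(1,1)$, $B(5,3)$, $B(3,5)$ for the uniform, large and small detection
regimes — is rescaled to the $[\min, \max]$ of log population sizes pooled
across all snapshots of all runs in the batch (a per-trajectory mode is
available via `pool = "per_trajectory"`; pooled was chosen because the
target is the log-transformed distribution of observed tumor sizes), the
snapshot with the closest log size is selected (ties toward the earlier
snapshot), and the genotype of its most abundant clone is returned.
Snapshots are recorded whenever the population changes by at least 1% or
`snap_dt` = 25 time units have elapsed, with a minimum spacing of
`snap_dt`/25 so demographic noise does not flood the record. Genotype
collections become binary subject-by-feature matrices (all-zero columns
kept) and are split into pairwise-disjoint subsets per sample size, drawn
without replacement. `top_features` keeps the most frequent columns (ties
by column order), as used in feature-threshold analyses at 7/10/12.

## CPMs

**CBN.** The model is a poset of direct AND restrictions with exponential
waiting times: feature $j$ becomes mutable once its parents are mutated and
then occurs at rate $\lambda_j$; the genotype is observed at an $Exp(1)$
time (the standard identifiability convention) and each bit is flipped with
probability $\varepsilon \in [0, 0.5)$. Because the transition structure is
upper triangular, the occupancy probability of each poset-compatible
genotype at the observation time solves a forward recursion
($\rho_0 = 1/(1+\Lambda_0)$,
$\rho_g = \sum_j \rho_{g \setminus j}\lambda_j / (1+\Lambda_g)$), giving an
exact marginal likelihood in one pass over the lattice (implemented in
C++). Structure search is simulated annealing over posets (moves: add,
delete or reverse a direct relation, rejecting cycles; geometric cooling
from $T_0 = 0.5\sqrt{n}$ to 0.1) with a nested parameter fit per visited
poset: an exact EM update for $\varepsilon$ (posterior expected mismatch
rate, holding $\lambda$) alternated with a guarded quasi-Newton improvement
of $\log \lambda$ (holding $\varepsilon$); both steps are accepted only if
the observed-data log-likelihood does not decrease, so the fit is monotone.
Defaults are 2 restarts of 400 proposals with a short warm-started inner
fit during the search and a full refit of the best poset; with the exact
lattice likelihood this recovers 4-gene structures from $n = 2000$
reliably while keeping a 7-gene fit at a few seconds. Pure maximum
likelihood is the default score; a BIC penalty is available. Degenerate
features (frequency 0 or 1) are excluded from the search and re-attached as
isolated nodes with clamped rates. The fit is exercised against closed
forms (single feature: $P(\text{mutated}) = \lambda/(1+\lambda)$) and
against Monte-Carlo forward sampling in the tests.

**OT.** Pairwise weights combine joint and marginal frequencies,
$w_{ij} = 2\log p_{ij} - \log(p_i + p_j) - \log p_i - \log p_j$ (Root has
frequency 1). The weight is symmetric, so the maximum-weight branching
rooted at Root coincides with the maximum spanning tree over Root plus
features, oriented away from Root — the implementation is that spanning
tree, which is deterministic. Edge weights for path extraction are the
conditional probabilities $P(\text{child} \mid \text{parent})$. This
reconstruction recovers chains from noiseless chain data and stars from
independent features, the two contracts the path modules rely on.

## Path distributions

The paths encoded by a model are the linear extensions of its poset/tree
(equivalently the source-to-sink paths of its fitness graph), enumerated
by depth-first search with a configurable cap (default $10^6$; 10-gene
empty posets exceed it by design and raise an explicit error). CBN path
probabilities follow competing exponentials: at each step the next feature
is chosen with probability $\lambda_j / \sum_{a \in \text{available}}
\lambda_a$. For OT, edge weights are normalized proportionally over the
available events (the weights are by-observation-time transition
probabilities, so a multi-event normalization must be chosen; an
independent-Bernoulli mode is provided behind `mode = "bernoulli"`).
Uniform weighting is the fallback used for models that carry no rates.

## Performance statistics

Diversities use natural logs ($S_p$ over LODs, $S_c$ over CPM paths); JS
uses base 2 so it is scaled to $[0,1]$. When LOD lengths differ from the
CPM path length $K_C$, LOD paths are grouped by terminal length $k$; within
a group, a shorter path matching the prefix of a longer one is fully
accounted for, while the longer path carries an unmatched fraction
$(K_{\max} - K_{\min})/K_{\max}$; indistinguishable prefixes are summed
into single entries and all unmatched flow is pooled (pooling is exact for
JS because entries paired with zero contribute linearly). Group statistics
are combined with weights $w_k$. By default the conditional LOD
distribution within a group is renormalized before the per-group JS — the
reading consistent with weighting by $w_k$; the unnormalized-flow variant
is implemented behind `renormalize = FALSE` and both are exercised against
a literal straight-line reimplementation in the tests. 1-recall and
1-precision are the unmatched LOD and CPM flows; the modal-LOD recovery
statistic counts a tie as recovered if any modal path is prefix-matched.

## Reliability (JS_o,b)

`bootstrap_jsob` refits the model (structure, rates and $\varepsilon$
jointly) on case-resampled data sets of the original size and averages the
JS between the original and bootstrap path distributions. Feature
thresholding is applied once to the original data and the retained features
are reused for every replicate. Failed replicates are recorded as missing
and reported.

## Problem sizes and what the tests show

The full factorial design (1260 landscape configurations; 56700 data sets;
20000 runs per landscape; sample sizes 50/200/4000 in five disjoint splits)
is enumerated exactly by `enumerate_design("full")` but executed only at
desk scale: the package's default study uses $K = 7$, $N_0 = 2000$, the
constant mutation regime, 5 landscape replicates per kind, 1000 runs per
landscape, and sample sizes up to 1000 (five disjoint splits of 50, one of
1000) — sizes chosen so the whole suite, including the directional
reproductions, runs on a single CPU in minutes. The synthetic data emulate
the shape of real cross-sectional cancer data (small n, binary features
with skewed frequencies) but not sequencing noise beyond the symmetric
$\varepsilon$, copy-number events, back mutations, or patient covariates;
passing tests therefore show that the statistical machinery behaves as
designed under the simulation model, not that any particular real data set
satisfies that model. Observed unpredictability at full scale is also
systematically larger than at 1000 runs for the same landscape (rare LODs
keep appearing), so desk-scale $S_p$ values are mild underestimates;
comparisons across conditions, which is what the tests assert, are
unaffected in direction.

## Known limitations

- CBN restrictions are conjunctive only (no OR/XOR), matching the scope of
  the evaluation; error is a single symmetric $\varepsilon$.
- The annealing search is stochastic; structure recovery is asserted as a
  rate over seeds, not per-seed.
- $K$ is capped at 14 by the exhaustive genotype enumeration (the study
  needs 7 and 10).
- Third-party CPMs (MCCBN, CAPRI, CAPRESE) are not reimplemented; their
  output can be plugged in through `external_cpm_adapter` as a DAG plus
  optional rates.
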