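---
title: "Evolutionary games of oscillator communication: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolutionary games of oscillator communication: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscomm)
```

## The model

`oscomm` studies a population of $n$ oscillators with identical periods,
arranged on a planar integer grid and connected by a fixed topology. An
oscillator's full description is its strategy $(s, \phi)$: a communication
flag $s \in \{C, N\}$ and a phase index $\phi \in \{1, \dots, d\}$, the $d$
phases being evenly spaced around the cycle. The system is an abstraction of
oscillatory neural tissue such as the mammalian suprachiasmatic nucleus:
communication costs resources, synchronization of phases carries a benefit,
and we ask under which cost/benefit trade-offs and connection patterns
communication can invade and persist.

Payoffs depend only on the two flags and the cyclic phase distance
$k = \min(|q - r|,\, d - |q - r|)$, through linear non-increasing benefits
$B(k) = B(0)(1 - k/d)$ for communicators and
$\beta(k) = \beta(0)(1 - k/d)$ for non-communicators, with
$B(0) \ge \beta(0) \ge 0$ so a communicator never gains less than a
free-rider. A communicator additionally pays a cost $c$. The resulting
$2d \times 2d$ payoff matrix (rows: focal player) has four $d \times d$
blocks; the all-$N$ block is identically zero and the whole table is
invariant under joint rotation of the two phases, properties the test suite
asserts directly.

Reducing the flag game at equal phase to a symmetric $2 \times 2$ game with
$R = B(0) - c$, $S = \beta(0) - c$, $T = \beta(0)$, $P = 0$ classifies
benefit pairs by the signs of $R - T = B(0) - \beta(0) - c$ and
$S - P = \beta(0) - c$ into mutualism (both positive), snowdrift, coordination
and Prisoner's Dilemma regions. Two conventions here were genuinely open:

* **Which phase pair the classification refers to.** We evaluate the
  reduced game at equal phase. Any common phase gives the same signs by
  rotation invariance, and equal phase is the state a nearly-absorbed
  population actually occupies; cross-phase reductions would rescale both
  benefits by the same factor and mostly reproduce the same regions.
* **Ties.** Integer benefit grids against $c = 10$ place many pairs exactly
  on region boundaries (e.g. $\beta(0) = c$). These return the explicit
  label `"boundary"` instead of being absorbed into a neighboring region,
  and sweep summaries flag them; folding them either way would silently
  bias region-level statistics.

## Dynamics

Evolution follows a death-birth process. Each iteration one oscillator is
chosen uniformly at random to die; its replacement copies the full
(flag, phase) strategy of one of its neighbors $j$, drawn with probability
proportional to $e^{\delta \pi_j}$, where $\pi_j$ is the neighbor's expected
payoff in the current configuration and $\delta$ the selection strength.
There is no mutation, so the all-$C$ and all-$N$ states are absorbing; the
recorded communicative fraction $p$ stops changing once it hits 0 or 1 and
runs terminate there, storing the absorption iteration instead of a constant
tail.

Conventions that the definitions above do not pin down, fixed here once:

* **Payoff aggregation.** $\pi$ is the *mean* payoff over neighbors by
  default (`payoff_aggregation = "mean"`), with the summed variant exposed.
  The mean keeps selection pressure comparable across degrees — under the
  sum, an all-to-all population of 1,600 nodes multiplies every payoff
  difference by $\approx n$, making replacement effectively deterministic —
  and at full scale only the mean reproduces the reported mixed-state
  snowdrift outcomes (see below).
* **Pre-replacement payoffs.** The dying node still contributes to its
  neighbors' payoffs when the profile is computed; death and birth are a
  single atomic event.
* **Invasion setup.** A trial starts from a single communicator at the
  maximally distant phase $1 + \lfloor d/2 \rfloor$ (opposite for even $d$)
  in a resident population of non-communicators at phase 1, the least
  favorable invasion. The invader's location is uniform at random; by
  rotation invariance the resident phase is fixed at 1 without loss of
  generality.
* **Isolated nodes.** The probabilistic spatial generator can (rarely at
  $\gamma = 10$) produce degree-0 nodes; these are reported, never silently
  regenerated. A death event at such a node is a no-op — there is no
  neighbor to copy — which means an invader landing on one can persist
  indefinitely without spreading.

## Parameters

| Parameter | Meaning | Default | Rationale |
|---|---|---|---|
| $B(0)$, $\beta(0)$ | benefit intercepts (payoff units) | swept 1..40, 1..$B(0)$ | resolves several multiples of $c$ |
| $c$ | communication cost | 10 | base cost; degree-adjusted mode rescales per node |
| $d$ | phase count | 10 | matches the simulated conditions |
| $\delta$ | selection strength | 1 | strong but stochastic selection |
| iterations | death-birth budget | 50,000 | $\approx 31$ updates per node at $n = 1600$ |
| trials | per benefit pair | 20 | averages over invasion stochasticity |

For irregular topologies the degree-adjusted cost $c(i) = c\,N(i)/\mu$
(degree over mean degree) keeps the population mean cost exactly $c$, so
uniform- and adjusted-cost runs are comparable; on regular graphs the two
modes coincide. The focal node's own $c(i)$ enters every cost-bearing entry
of its payoff evaluation.

## Topologies and the edge-probability kernel

Four generators cover the spectrum from dense to sparse: all-to-all, the
8-neighbor Moore and 4-neighbor von Neumann lattices (boundary nodes simply
omit missing neighbors), and a probabilistic spatial topology connecting
grid nodes with probability $1/\big((x_2-x_1)^2 + (y_2-y_1)^2 + \gamma\big)$,
each unordered pair sampled independently once. Smaller $\gamma$ gives
denser graphs; the squared-distance decay yields mostly short links with a
tail of long-range ones.

The kernel's denominator is *squared* Euclidean distance plus $\gamma$. We
fixed this form because it is the one consistent with the simulated density
regime: at $\gamma = 10$ on the 40 × 40 grid it produces ensemble mean
degree $\approx 9.8$, the "average degree 10" network whose dynamics are
compared against the degree-8 Moore lattice. The same ensembles measure an
average clustering coefficient of $\approx 0.015$ and an average path
length of $\approx 3.55$ (100 instances; computed by the acceptance script
and test suite). A kernel decaying with *unsquared* distance is sometimes
quoted in this context; it produces a several-fold denser graph at the same
$\gamma$ and is not compatible with mean degree 10, so it is deliberately
not implemented. Published summary metrics for this construction differ
between sources; the values above are what the implemented generator
actually produces, and they are internally consistent — a mean-degree-10
graph on 1,600 nodes cannot have an average path length near 2, since two
hops reach at most $\bar{N} + \bar{N}^2 \approx 110$ of the 1,599 other
nodes.

Clustering of degree-<2 nodes counts as 0 (the common convention); path
length is averaged over connected pairs, with disconnected instances flagged
rather than dropped.

## Numerical choices

* **Log-domain fitness profiles.** Replacement probabilities are softmax
  weights $e^{\delta \pi_j}$ normalized after subtracting the maximum, so
  profiles remain finite for arbitrarily large $|\delta\pi|$ (asserted up to
  $\pi \sim 10^6$).
* **Compiled engine, reference path.** The production loop is C++ (Rcpp)
  using R's RNG, so `set.seed()` makes every run bit-reproducible. A pure-R
  step (`death_birth_step()`, `fitness_profile()`, `expected_payoff()`) is
  the reference implementation; a test pins the compiled payoff computation
  to it on random configurations, and the exact-chain oracle is built solely
  from the R path.
* **Seeds.** Sweeps derive one seed per (pair, trial) from the master seed
  by a Lehmer-style fold below $2^{31}$, so partial sweeps compose exactly
  into full ones and trials are decoupled.
* **Exact means.** Degree-adjusted costs average to the base cost to
  machine precision by construction.

## The exact oracle

In the invasion setting only two strategies exist, so on a graph with
$n \le 12$ nodes the process is a Markov chain on $2^n$ states with two
absorbing states. `build_transition_matrix()` enumerates it by averaging the
uniform death choice against the exact fitness-profile birth distribution,
and `exact_fixation_probability()` solves the absorbing-chain linear system
$(I - Q)h = r$. Because the oracle reuses the R payoff/fitness path while
Monte-Carlo trials run the compiled engine, their agreement (within three
binomial standard errors, several parameter regimes) validates the
stochastic sampling itself, not merely the shared formulas. Neutral
parameters give the known $1/n$ single-invader fixation on vertex-transitive
graphs, which the oracle reproduces to $10^{-10}$.

A consequence of the invasion geometry worth noting: the lone invader
interacts at phase distance $d/2$, so its benefits are halved, and invasions
take off only when $\beta(0)/2 > c$. On a six-node all-to-all system the
exact fixation probability rises from $\sim 10^{-7}$ at
$B(0) = \beta(0) = 15$ to $0.72$ at 30 — the "benefit above twice the cost"
threshold. This also means benefit pairs in the mutualism region with
$\beta(0) < 2c$ fix only rarely from a *single* invader, even though
established communication is strongly stable there.

## What the tests show — and what they do not

The synthetic setups emulate the study conditions: 40 × 40 grids (1,600
oscillators), $d = 10$, $\delta = 1$, cost 10, 50,000 iterations, 20 trials
per benefit pair. The full-protocol checks run at exactly that scale (the
snowdrift pair $B(0)=30, \beta(0)=25$ on the Moore lattice; 100-instance
topology ensembles); the qualitative region comparisons run scaled down —
lattices of 36–100 nodes, 10–40 trials, oracle graphs of 3–8 nodes — because
their purpose is ordering (Prisoner's Dilemma dies fast everywhere,
mutualism outperforms it, denser topologies absorb sooner), not point
estimates. Passing tests show the implemented process has these properties
under the stated conditions; they do not show that real SCN tissue follows
a death-birth process, that linear benefits are biologically accurate, or
that 50,000 replacements correspond to any particular evolutionary time
span.

## Limitations

* Edges are unweighted and undirected; interaction intensity cannot vary.
* Phases are discrete; there are no intrinsic frequencies and no
  phase-pulling dynamics — synchronization enters only through the payoff
  structure.
* No mutation, no birth-death or imitation variants, no time-varying
  topologies, no external entrainment input.
* The full $(2d)^n$ strategy chain is intractable; the oracle covers the
  two-strategy invasion restriction only.
* All-to-all simulations recompute neighborhood payoffs per event and scale
  as $O(n^2)$ per iteration; they are intended for moderate $n$.
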