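---
title: "Model and methods: the spatial prisoner's dilemma with probabilistic abstention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: the spatial prisoner's dilemma with probabilistic abstention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdpa)
```

## The game

The classic spatial prisoner's dilemma (PD) puts one agent on every site of
a square lattice; each agent is a cooperator (C, coded $s = 0$) or a
defector (D, $s = 1$) and plays a pairwise game with each of its four
orthogonal neighbours (von Neumann neighbourhood) under periodic boundary
conditions, so the lattice is a torus and every agent has degree
$\kappa = 4$. A pairwise interaction pays $R$ for mutual cooperation, $P$
for mutual defection, and $T$ (temptation) versus $S$ (sucker's payoff) when
a defector meets a cooperator. The optional prisoner's dilemma (OPD) adds
voluntary participation: an agent may abstain, in which case both parties
receive the loner's payoff $L$, regardless of what the other intended.

This package implements the hybrid of the two: the prisoner's dilemma with
*probabilistic* abstention. Abstention is not a third pure strategy but an
extra attribute: each agent carries, alongside $s$, a probability
$\alpha \in [0, 1]$ of abstaining from any single interaction. $\alpha = 0$
recovers a PD agent who always plays; $\alpha = 1$ an agent who always
abstains; intermediate values give "sporadic" cooperators and defectors.
Payoffs are fixed at $R = 1$, $P = 0$, $S = 0$, with $1 < T < 2$ and
$0 < L < 1$ so that $T > R > L > P \ge S$ and the dilemma (and the cyclic
C–D–abstain dominance structure) is preserved. `game_params()` warns outside
these bounds by default and errors in strict mode — the bounds delimit the
dilemma regime, not the domain on which the payoffs are defined, and
limiting cases such as $T = 1$ are legitimate probes.

Because imitation copies $\alpha$ between neighbours, the model discretizes
$\alpha$ to $2\kappa$ equal intervals, i.e. the $2\kappa + 1$ levels
$\{0, 1/(2\kappa), \dots, 1\}$; with $\kappa = 4$ these are
$\{0, 0.125, 0.25, \dots, 0.875, 1\}$ (`alpha_grid(4)`). Internally each
agent stores a grid *index*, not a float, so imitation copies are bit-exact
and the level set is closed under the dynamics.

The summary observable is the **effective cooperation rate**

$$\varepsilon = (1 - s)(1 - \alpha),$$

the probability that an agent both is a cooperator and actually plays. Any
defector has $\varepsilon = 0$; a cooperator who always abstains also has
$\varepsilon = 0$; a pure cooperator has $\varepsilon = 1$. The strategy
coding $0 = C$, $1 = D$ is fixed precisely so that this identity is direct
arithmetic.

## Update rules

Both dynamics draw abstention afresh for every realized interaction: an
edge between $x$ and $y$ pays $(L, L)$ if either endpoint's Bernoulli
$\alpha$ draw comes up "abstain", and the PD matrix entry otherwise.

**Synchronous best-neighbour imitation.** Each Monte Carlo (MC) step, every
undirected edge is realized exactly once (one abstention draw per endpoint)
and both endpoints accumulate their payoffs, giving each agent a utility
$u_x = \sum_y p_{xy}$ over its $\kappa$ incident edges. All agents then
update simultaneously: $x$ adopts the $(s, \alpha)$ of its best neighbour
only if that neighbour's utility strictly exceeds $u_x$ and every other
neighbour's; any tie for the neighbourhood maximum, or $x$ being weakly
best, leaves $x$ unchanged. We read "plays the game once with each
neighbour" as once per *pair* — realizing each direction independently
would stochastically double-count the shared edge. Utilities are compared
with absolute tolerance $10^{-9}$: payoffs are short sums drawn from
$\{0, L, 1, T\}$, so genuine ties are representable in floating point and
the tolerance only guards against summation-order noise.

A consequence of the literal tie rule worth knowing: a lone cooperator on
a 3×3 all-defector torus is *frozen* — its four neighbours all earn exactly
$T$, a four-way tie, so nothing changes. Invasion requires a strict,
unique utility maximum.

**Asynchronous Fermi imitation.** Each MC step performs $N$ elementary
moves, the focal agent drawn uniformly *with replacement* ("each agent is
selected once on average" is implemented as $N$ independent draws, not a
random permutation). One move: $x$ plays fresh interactions with its four
neighbours to obtain $u_x$; one uniformly chosen neighbour $y$ likewise
obtains $u_y$ from its own four interactions; if $u_y > u_x$, $x$ copies
$(s_y, \alpha_y)$ with probability

$$W = \left(1 + \exp\!\big[(u_x - u_y)/(\kappa K)\big]\right)^{-1},$$

with noise amplitude $K = 0.1$, and the change applies immediately. $W$ is
evaluated in the numerically stable sigmoid form, so extreme utility gaps
saturate at 0 or 1 without overflow. The shared $x$–$y$ edge is drawn
independently for $u_x$ and for $u_y$: the two payoff acquisitions are
described as separate events, and treating them so keeps every utility an
i.i.d. realization of the same four-edge sum. (Sharing the draw is the main
alternative reading; it would couple the two utilities on one of eight
edges and is not expected to change any qualitative result.)

## Initialization and the three games

Strategies are always initialized C/D with equal probability. Three
initialization modes select the game:

* `pd` — all agents at $\alpha = 0$: the loner payoff can never be awarded
  and the trajectory is exactly a classic spatial PD (invariant to $L$);
* `opd` — $\alpha$ is 0 or 1 with equal probability: abstention is
  effectively a pure strategy and $\alpha$ stays on $\{0, 1\}$ forever
  (imitation introduces no new levels);
* `pdpa` — $\alpha$ uniform over all nine grid levels.

These limits are enforced by construction and pinned by tests: the support
of $\alpha$ in the population can only ever shrink.

## Reproducibility conventions

One seeded R RNG stream drives everything — initialization, every
abstention draw, site and neighbour selection, and the Fermi coin — in a
documented order: sites are traversed in column-major linear order; the
synchronous accrual resolves each site's South then East edge, drawing the
owner's abstention before the neighbour's; an asynchronous move draws the
focal site, then $u_x$'s eight abstention draws (N, S, W, E edge order),
then the neighbour index, then $u_y$'s draws, then (only when $u_y > u_x$)
the Fermi coin. The compiled core consumes the same stream as R's `runif()`,
which is what lets the test suite replay a run step-for-step against naive
pure-R reference implementations and demand bit-identical results.
Ensemble run $i$ uses seed $\texttt{base\_seed} + i - 1$; in parameter
sweeps the seed block is a pure function of the $(T, \text{game},
\text{scheme})$ combination and the run index, so sweep outputs are
invariant to execution order and cells differing only in $L$ are seed-paired
(which also makes pd-mode sweep rows exactly constant across $L$).

Coordinates in the R interface are 1-based `(row, column)` pairs with
neighbour order N, S, W, E, matching R matrix indexing; only the compiled
engine uses 0-based linear indices.

## Scales, parameters and defaults

The published protocol ("paper" scale in `preset_config()`) is a
$102 \times 102$ lattice, $10^5$ MC steps of thermalization, and
100-run ensembles, with $L = 0.4$ fixed and $T$ swept; stationary
quantities are measured from each run's final state and averaged across
runs (runs are independent, so standard errors are taken across runs, not
across spatially correlated sites; no within-run time averaging is used).
The "desk" scale — $60 \times 60$, $2 \times 10^4$ steps, 20 runs — is the
package's reduced protocol for tests and exploration, chosen so the full
property suite completes in minutes while the phenomenology (stationary
coexistence, the surviving-$\alpha$-level counts, the ordering of
$\varepsilon$ in $T$) is unchanged.

Tunable parameters and defaults: $T$ (dimensionless temptation, default
1.4), $L$ (loner's payoff, default 0.4), $K$ (Fermi noise, default 0.1),
lattice side, MC steps, `record_every` (time-series sampling; the initial
and final states are always recorded). An optional `stop_when_absorbing`
flag halts a run once the observable state can no longer change —
homogeneous $(s, \alpha)$ under either scheme, or an all-abstaining
population under asynchronous updating (every pairwise utility is then
$\kappa L$, so $u_y > u_x$ never fires). It is off by default to mirror the
fixed-length protocol. Note that an all-defector population is *not*
absorbing in general: strategies are closed but $\alpha$ keeps evolving
among defectors.

## What the simulator reproduces

At stationarity the hybrid game sustains markedly more cooperation than
either classic limit, under both update rules. Two behaviours serve as the
package's convergence checks (at desk scale, asserting the *modal* outcome
over 20 runs, since individual runs vary):

* from a uniform $\alpha$ initialization, the population usually collapses
  onto **two** surviving $\alpha$ levels (occupancy $\ge 1\%$) under
  synchronous updating and **three** under asynchronous updating;
* stationary mean $\varepsilon$ is non-increasing in $T$ (checked at
  $T \in \{1.1, 1.4, 1.9\}$).

The 1% occupancy threshold behind "surviving level" is this package's
choice (exposed as `min_fraction` in `distinct_alpha_levels()`); it filters
single-agent relics without affecting genuinely occupied levels.

A third, transient behaviour: starting from mean $\alpha = 0.5$, the
ensemble-mean abstention probability under the asynchronous dynamics at
$T = 1.4$ first *rises* (to roughly 0.7 — early pure defectors make
sporadic play the refuge) and then falls back as defection stops paying and
lower-$\alpha$ cooperators take over — a bell-shaped early transient.
Under synchronous best-imitation the mean $\alpha$ instead decays
monotonically from 0.5 at every scale we examined; the bell is a property
of the noisy, immediate-update dynamics.

## What the synthetic initial conditions do and do not emulate

All inputs are generated: random initial populations on a clean torus.
Passing tests therefore demonstrate the internal correctness of the
dynamics and the robustness of the stated phenomenology under the stated
protocol — not behaviour on empirical interaction networks, which have
degree heterogeneity, clustering and community structure that a regular
lattice deliberately excludes, nor robustness to payoff noise beyond the
Fermi $K$, strategy mutation, or off-grid drift of $\alpha$ (all out of
scope by design).

## Numerical and degenerate-input choices

* Utilities compared with absolute tolerance $10^{-9}$ (synchronous rule);
  the asynchronous rule uses the plain strict comparison $u_y > u_x$.
* `side = 2` tori are allowed only in non-strict mode, with documented
  multi-edge semantics (up/down neighbours coincide and count twice); the
  smallest production-sensible torus is `side = 3`.
* `mc_steps = 0` is rejected up front; a one-step run records the initial
  and the one-step state.
* Snapshot files are plain text, one lattice row per line, `s:alpha_index`
  per cell, with a single header line carrying `side` and `kappa` so files
  round-trip without out-of-band metadata.

## A worked desk-scale example

```{r example, eval = FALSE}
cfg <- preset_config("pdpa", "synchronous", "desk", T = 1.4, seed = 1)
run <- run_simulation(cfg)
run
tail(run$time_series[, 1:5], 3)
distinct_alpha_levels(run$time_series[nrow(run$time_series), ])
```

(Not evaluated here — a desk-scale run takes a few seconds; see the README
for the printed output of exactly this example.)

## Known limitations

Single-threaded; ensembles are embarrassingly parallel but the package
keeps one RNG stream per run and leaves parallel orchestration to the
caller. The asynchronous engine's utility realizations are
paired-independent (see above); no claim is made about the shared-draw
variant. Figure rendering is out of scope: sweeps return tidy tables.
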