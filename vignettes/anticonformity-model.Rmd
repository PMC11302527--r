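---
title: "Modelling preference expression under social (anti)conformity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling preference expression under social (anti)conformity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anticonf)
```

## The decision model and its assumptions

Agents face a repeated binary choice between options A and B. Two utility
channels enter the decision. A private one: the net preference
$\Delta o_i = o_{A,i} - o_{B,i}$, in utility units, positive when the
agent intrinsically prefers A. And a social one: the agent observes only
the *choices* of its network neighbours (not their preferences or types)
and weighs the surplus of A-choosers by its conformity weight $w_i$. The
marginal utility of choosing A is

$$\Delta U_i = \Delta o_i + w_i\,(\#A_i - \#B_i),$$

and the agent resamples its choice with the Fermi (logistic) probability

$$p_i(A) = \frac{1}{1 + e^{-\beta\,\Delta U_i}}.$$

Resampling — rather than switch-only — means the draw is independent of
the agent's current choice. Updates are asynchronous: each time step one
uniformly chosen agent updates, and one *sweep* (the package's time unit)
is $N$ such steps, which makes time scales comparable across population
sizes and mimics continuous time.

The sign of $w$ defines the three behavioural types: conformists
($w > 0$) gain utility from agreeing with neighbours, anticonformists
($w < 0$) from disagreeing, and nonconformists ($w = 0$) ignore the
social channel entirely. Note that anticonformists differ from
*committed minorities*: they oppose whatever is locally prevalent rather
than championing a fixed option, which is exactly what makes them useful
in changing environments.

## Parameters, defaults, and why

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| $\beta$ | 100 | 1/utility | effectively noiseless threshold decisions; $\Delta U = 0$ still resolves by a fair coin |
| $\Delta o$ | $\pm 10$ | utility | the preference scale of the static experiments (half prefer A, half B) |
| $w$ | $+1$ / $-1$ / $0$ | utility per neighbour | with minimum degree 20 this puts $|w| k \ge 20 > |\Delta o|$, the high-conformity-pressure regime in which unanimous neighbourhoods override preferences; magnitudes are configurable per subpopulation |
| BA $m$ | 20 | — | minimum degree 20; seed graph is the complete graph on $m$ nodes so every non-seed node has degree $\ge m$ |
| ER mean degree | — | — | $p = \bar k/(n-1)$; connected draws enforced for $\bar k \ge \ln n$, giant component otherwise (isolated shells would bias alignment statistics) |
| linear schedule | $\Delta o(t) = 10 - 0.1\,t$ | utility / sweep | zero-crossing at sweep 100, a quarter of the 400-sweep horizon, leaving room to measure lags |
| sinusoidal schedule | $A_0 = 10$, $T = 200$ sweeps | | several complete cycles within a 600-sweep run; half-period 100 sweeps bounds measurable leads |
| quasi-equilibrium | 50 flip-free sweeps, horizon 2000 | sweeps | a pure flip-free criterion alone cannot terminate cycling anticonformist pairs, hence the hard horizon; equilibrium alignment averages the final 10-sweep window |
| volatility burn-in | 100 | sweeps | discards the initial relaxation transient |

Dynamic-environment experiments give *all* agents one shared,
time-varying preference (the schedule), isolating the social dynamics
from preference heterogeneity; static experiments use heterogeneous
fixed preferences.

## Placing dissenters in the network

Degree centrality of anticonformists is operationalized as the Pearson
(point-biserial) correlation between node degree and the anticonformist
indicator — the simplest measure consistent with "correlation between
degree and anticonformity". Placement starts from the extreme
configuration (anticonformists on the top-degree nodes for non-negative
targets, bottom-degree for negative ones; ties broken by node id) and
greedily swaps the attributes of random pairs, accepting a swap only if
it does not increase the distance to the target. The trace of distances
is therefore non-increasing, convergence is declared at tolerance 0.01
(up to $10^6$ proposals), and the achievable range is validated first
from the degree sequence. Swaps exchange attributes only, so the edge
set — and hence every degree — is invariant.

Assortativity is tuned by two-edge degree-ordered rewiring: two random
edges with four distinct endpoints are re-paired highest-with-highest /
lowest-with-lowest (assortative), highest-with-lowest (disassortative),
or at random (neutral), rejecting self-loops and duplicate edges so the
degree sequence is preserved exactly. Because the two directed modes
saturate at very different magnitudes of Newman's $r$ on scale-free
graphs (roughly $+0.4$ versus $-0.7$ at $n = 500$), comparative
experiments stop rewiring at a matched magnitude
(`target_r`, typically $0.15$–$0.2$) instead of running to saturation;
otherwise the comparison would confound direction with intensity.

## The mean-field companion

The well-mixed analysis replaces each agent's neighbourhood by $k$ draws
from the population: $\#A \approx kX$ for global A-fraction $X$ (the
annealed approximation), giving the self-consistency map

$$G(X) = \sum_s n_s \, \sigma\!\big(\beta(\Delta o_s + w_s k (2X-1))\big),$$

whose fixed points $G(X^\*) = X^\*$ are found by a sign-change scan (4001
grid points by default — the map is nearly a step function at
$\beta = 100$, and closely spaced stable/unstable pairs near criticality
need a fine grid) followed by bisection. Stability comes from the sign
of $G'(X^\*) - 1$ via a central difference with step $10^{-6}$; roots
within $10^{-6}$ of a boundary are classified by one-sided drift. Since
$G$ maps $[0,1]$ into itself, at least one root always exists.

The *critical anticonformist fraction* $f^\*$ is the smallest $f$ at
which the map loses its bistability (the stable-root count drops),
located by bisection in $f$; anticonformists replace a uniform share of
every subpopulation, keeping its preference, which is also how simulated
scenarios mix them in. For the half/half $\Delta o = \pm 10$, $w = 1$
composition the step-rule limit gives $f^\* \approx 1/2 - |\Delta o|/(2k)$,
about $0.37$ at the BA mean degree $k = 39.16$ — and the followed stable
branch jumps discontinuously at $f^\*$, while the networked transition is
continuous and begins earlier because cascades nucleate locally around
anticonformist clusters. The effective degree $k$ is an explicit
parameter: the mean degree is the default matching choice, but
heterogeneous networks have no single canonical $k$, and this gap is the
main reason simulated and well-mixed critical points differ.

As an exact oracle at small $N$, the dynamics on the complete graph is a
Markov chain over per-subpopulation A-counts (the focal agent is
excluded from its own neighbour counts). The package builds the exact
single-update transition matrix; when absorbing states exist (typical at
$\beta = 100$) it returns absorption probabilities and flags it,
otherwise the stationary distribution by power iteration (self-loops
make the chain aperiodic). One subtlety found with this oracle: on the
complete graph with $w = 1$ the interior fixed point at $X = 0.5$ has a
basin of width $|\Delta o|/(2k)$, narrower than finite-$N$ fluctuations,
so dense-graph runs started there legitimately land on a consensus root.

## What the generators emulate — and what they do not

The synthetic networks reproduce the degree heterogeneity (BA), Poisson
degrees (ER), tunable degree assortativity and tunable dissenter
centrality that drive the phenomena of interest. They do not attempt
community structure, spatial embedding, weighted or temporal ties,
homophily in preferences, or network–choice coevolution. Passing tests
therefore demonstrate the mechanisms — conformity traps, critical
anticonformist mass, centrality leverage, cultural lag — on clean
substrates, not calibration to any measured social network. Preferences
are piecewise-deterministic inputs; there is no feedback from choices to
the environment.

## Numerical and design choices

- Choices are encoded as spins $\sigma(A) = +1$, $\sigma(B) = -1$
  package-wide; the logistic is evaluated in its numerically stable form
  (no overflow at $|\beta \Delta U| \sim 10^6$).
- Initial choices are drawn without replacement so the realized initial
  A-count is exactly `round(x0 * N)` (globally, or per subpopulation).
- Agents with $\Delta o = 0$ have no defined preference and are excluded
  from alignment, with their count reported.
- Tipping is "first time the global B-fraction exceeds 0.5" (0.9
  available); the lag is measured from the schedule's zero-crossing.
  Lead times are measured per half-cycle as the first recorded majority
  switch of a subpopulation after it held the outgoing majority, minus
  the crossing; crossings whose window shows no outgoing majority are
  skipped rather than imputed.
- The expression threshold behind "the population expresses its
  preferences" is alignment $\ge 0.9$ (configurable; the transition is
  sharp, so phase boundaries move little for thresholds 0.8–0.95).
- Empirical critical fractions are found by bisection on the median
  ensemble alignment with common random numbers across evaluated
  fractions, making the search deterministic for a given master seed.
- One master seed derives independent substream seeds for network,
  placement, initialization and dynamics, so components can be varied
  independently with the other streams held fixed.
- The welfare decomposition (`welfare()`) is package-local bookkeeping:
  per-capita preference utility $\overline{\sigma_i \Delta o_i}/2$ plus
  per-capita social utility
  $\overline{(w_i/2)\sigma_i \sum_{j \sim i} \sigma_j}$; their sum is the
  reported total, exactly.

## Problem sizes

Shipped scenarios run at desk scale: populations of 500 (static) and 500
(dynamic) with 10–20 realizations per condition, versus 1000–2000 and
100 realizations for the full-size variants behind
`canned_scenario(..., full_size = TRUE)`. The Markov-chain oracle uses
$N = 8$–$12$; dense-graph cross-checks use $N = 400$ complete graphs.
These sizes were chosen so the whole experiment battery re-runs in
minutes while keeping median-based comparisons stable across seeds.

## Known limitations

- The decision rule is linear in the neighbour surplus; higher-order
  (nonlinear) frequency dependence and "nuanced" anticonformity are out
  of scope, as are memory, learning, identity and network coevolution.
- With the default $w = \pm 1$, $\Delta o = \pm 10$, anticonformists on
  hubs keep flipping even deep in the aligned regime (their neighbour
  surplus fluctuations exceed $|\Delta o|$), so volatility does not fall
  far beyond the transition: the volatility peak at criticality is mild
  relative to the anticonformist-rich regime, though sharp relative to
  the frozen trap.
- Moderate disassortative rewiring slows tipping relative to the neutral
  baseline in this implementation (detaching dissenter hubs from the
  conformist hubs that gate cascades), so "disassortative tips fastest"
  should not be assumed; only "assortative tips slowest" is robust here.
- The mean-field map ignores degree heterogeneity and locality; on BA
  networks it overestimates the critical anticonformist fraction by
  roughly the gap between mean-degree and typical-degree thresholds.
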