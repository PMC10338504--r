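---
title: "Methods: exact computation and classification of two-state stochastic games"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact computation and classification of two-state stochastic games}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stategames)
```

This vignette documents the model the package implements, the numerical
choices behind it, and the limits of what its computations show. Everything
here is computed by the package itself; the test suite asserts each claim.

## The model

Two players repeat a prisoner's dilemma whose benefit depends on an
environmental state. In state $s_i$ cooperation costs $c$ and delivers $b_i$
to the co-player, with $b_1 \ge b_2 > c$; the cost is the payoff unit
($c = 1$). After each round the environment moves to state $s_1$ with
probability $q^i_{a\tilde a}$, an entry of the transition vector
$\mathbf{q} = (q^1_{CC}, q^1_{CD}, q^1_{DD};\, q^2_{CC}, q^2_{CD}, q^2_{DD})$
indexed by the current state and the unordered action pair. Strategies are
memory-one: with state information, 8 cooperation probabilities (one per
state and previous action pair); without, 4. Implementation errors flip an
intended move with probability $\varepsilon$, so strategy $\mathbf p$ is
effectively $(1-\varepsilon)\mathbf p + \varepsilon(\mathbf 1 - \mathbf p)$.

A strategy pair induces a Markov chain on the eight round-outcomes
$\omega = (s_i, a, \tilde a)$. Its transition probabilities factorize into an
environmental factor and one conditional-cooperation factor per player, the
player factors conditioning on the *next* round's state and the co-player's
factor using the transposed action order (`build_transition_matrix()`). For
$\varepsilon > 0$ and $\mathbf q \ne (1,1,1;0,0,0)$ the chain has a unique
stationary distribution $v$ (`stationary_distribution()`, solved as the
linear system $v^\top(M - I + \mathbf{1}) = \mathbf 1^\top$), from which
payoff and cooperation rate are linear functionals (`payoff()`,
`cooperation_rate()`). Discounted games use
$v = (1-\delta)\,v_0 (I - \delta M)^{-1}$ (`discounted_occupancy()`).

Evolution is a pairwise comparison process with selection strength $\beta$ in
a population of size $N$, analyzed in the rare-mutation limit: resident
populations are monomorphic, a mutant fixes with the Fermi fixation
probability, and the resident sequence is a Markov chain over the
deterministic strategy set whose invariant distribution weights the self-play
statistics (`evolve_population()`). The value of state information is
$V_\beta(\mathbf q) = \hat\gamma^F - \hat\gamma^N$, the difference in evolved
cooperation between the 256-strategy and the 16-strategy population.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `b1`, `b2` | 1.8, 1.3 | benefit of cooperation in states 1, 2 (payoff units; `b1 >= b2 > c`) |
| `c` | 1 | cost of cooperation, the payoff unit |
| `epsilon` | 0.01 | probability an intended move is flipped; keeps the outcome chain ergodic |
| `delta` | 1 | continuation factor; 1 means undiscounted long-run averages |
| `N` | 100 | population size |
| `beta` | 10 | selection strength of the Fermi update; 0 is payoff-blind imitation |
| `mu` | 0.01 | per-step mutation probability (trajectory simulation only) |

These defaults are the baseline conditions used by every worked example,
preset, and acceptance computation in the package; analyses that vary a
parameter (selection scans, equilibrium thresholds in `b1`) say so explicitly.

## Numerical choices

**Rare-error limits.** Weak-selection values of information and equilibrium
payoffs are defined in the limit $\varepsilon \to 0^+$. Stationary
distributions are rational functions of $\varepsilon$, so the package
evaluates at the fixed sequence $\varepsilon \in
\{10^{-3}, 3\cdot10^{-4}, 10^{-4}, 3\cdot10^{-5}, 10^{-5}\}$ and extrapolates
polynomially to zero (Neville's scheme, `limit_stationary_distribution()` and
`weak_selection_value()`). Five points in this range keep the truncation
error below $10^{-8}$ even for transition vectors with an entry comparable to
the largest $\varepsilon$, where the rational function varies fastest;
smaller error rates would start to trade truncation error for conditioning
error, since the chain's spectral gap can shrink like $\varepsilon$ or
$\varepsilon^2$. The extrapolation is validated against the one closed form
available for this model family, $V_0(q) = -3q(1-q)/(64(1+q))$ for the
recovery family $(1,0,0;q,0,0)$, to $2\cdot10^{-9}$ over a 99-point grid. A
convergence check compares the two highest extrapolation orders; their
difference is dominated by the lower order's truncation term, so the default
tolerance ($10^{-7}$) sits an order of magnitude above it while the estimate
itself is accurate to about $10^{-11}$.

All limit-of-rare-errors statements in the package (the weak-selection
classification, the 16/16 split, equilibrium payoffs) use this extrapolated
limit rather than a small fixed $\varepsilon$; at fixed $\varepsilon = 0.01$
the weak-selection values shift by $O(\varepsilon)$ (e.g. $-0.00823$ instead
of $-0.00781$ at $q = 0.5$ in the recovery family) but no sign in the
deterministic census changes. `weak_selection_value()` accepts a single-value
`eps_seq` for fixed-error evaluation.

**Weak selection is computed at exactly $\beta = 0$.** The invariant
distribution of the embedded chain is uniform for any payoffs when
$\beta = 0$, so $V_0$ is the difference of uniform averages of self-play
cooperation rates — no finite difference in $\beta$ is involved.

**Fixation probabilities** are evaluated in the log domain: the payoff
difference $\pi_M(k) - \pi_R(k)$ is linear in $k$, its partial sums are
accumulated analytically, and the sum of exponentials is shifted by its
maximum exponent, so $N \beta \,\Delta\pi$ products of order $10^3$ cannot
overflow. At $\beta = 0$ the expression is exactly $1/N$.

**Batch computation.** The positive-selection census needs every ordered pair
of the 256 full-information strategies for each of 64 games (about $2.1
\times 10^6$ stationary solves). A small C++ kernel (RcppArmadillo) performs
one $8\times 8$ solve per unordered pair, yielding both players' payoffs and
the pair's cooperation rate at once; the R-level single-pair path is
independent code and the tests cross-check the two against each other and
against long power iteration.

**Degenerate transition vectors.** $\mathbf q = (1,1,1;0,0,0)$ makes both
states absorbing and the outcome chain reducible; `stationary_distribution()`
rejects it with a pointer to the discounted/initial-state route.
Classification handles it combinatorially: with both states absorbing,
information is neutral under any initial convention, so
`value_of_information()` returns exactly 0 there. Other absorbing vectors are
computed numerically and come out neutral to $10^{-12}$, as the lumping of
the 256 full-information strategies onto 16 behavioral classes predicts.

**Initial round for $\delta < 1$.** The occupancy formula needs a first-round
distribution. The package's convention (`initial_distribution()`): play
starts in a designated state (default $s_1$) and each player draws its first
move from its strategy entry for that state with a fictitious previous round
of mutual cooperation; both the state and the fictitious action pair are
arguments. With errors and $\delta = 1$ the stationary computation is
independent of any such convention.

**Equilibrium checks.** `is_nash()` enumerates all deterministic memory-one
deviations of the chosen setting against the resident and compares rare-error
limit payoffs; ties count as no profitable deviation. `is_subgame_perfect()`
solves the single-deviator Markov decision process on the eight
outcome-states by exact policy iteration under discounting and applies the
vanishing-discount construction: the policy optimal at the most patient
discount is Blackwell-optimal, and its average reward (gain) from every state
— recovered by extrapolating $(1-\delta)V_\delta$ over
$\delta \in \{0.99, 0.999, 0.9999\}$ with the policy held fixed, so the
extrapolated curve has no policy-switch kinks — is compared with the gain of
following the resident from that state. Comparing gains (not discounted
values, and not bias terms) matches the weak inequalities of the printed
equilibrium conditions: a deviation that merely front-loads payoffs without
changing the long-run average does not break equilibrium. On the boundary of
the timeout game this matters: at $2b_1 - b_2 = 2c$ exactly, deviating after
a timeout round earns the same average as cooperating, and the strategy
remains subgame perfect. `critical_threshold()` bisects a parameter against
either predicate (default resolution $10^{-4}$); the recovered thresholds
$b_1 = 2c$ (Nash for no-information WSLS in the timeout game) and
$2b_1 - b_2 = 2c$ (subgame perfection of the state-aware WSLS variant,
identical for both arbitrary-bit instantiations) match the algebraic
conditions to $2\cdot10^{-5}$.

**Tie-breaks.** Policy iteration prefers cooperation on exactly tied action
values (a deterministic, documented choice that cannot affect gains). In
invasion graphs, edges use strict inequalities: fixation probability above
$1/N$ is a selection-favored ("solid") invasion, strictly between $1/(10N)$
and $1/N$ almost-neutral drift ("dotted"), and exact ties at $1/N$ — every
pair at $\beta = 0$ — draw no edge.

## The trajectory simulator

`simulate_trajectory()` is deliberately a simulation of the *rare-mutation
resident chain*, not of the full $N$-agent process: each step is a mutation
event with probability `mu` (the candidate drawn uniformly from the whole
strategy set, the current resident included, matching the embedded chain's
$\rho/|\mathcal P|$ convention), followed by fixation with the exact fixation
probability. Its time averages converge to the invariant-distribution
averages, which the tests verify within Monte-Carlo error (16-strategy set,
$N = 20$, batch-mean standard errors). Whether mutants may equal the resident
is immaterial in this limit — excluding the resident rescales time, not the
invariant distribution. The simulator therefore validates the exact
computation; it does not add information beyond it, and it does not model
polymorphic populations (positive-$\mu$ co-existence of strategies is outside
the package's scope).

## What the scans do and do not show

`classify_deterministic_games()` is exhaustive over the 64 deterministic
vectors, and `scan_single_stochastic()` over the 192 one-free-entry families,
so statements about those spaces are censuses, not samples.
`scan_full_grid()` enumerates the $6^6 = 46{,}656$ vectors on the canonical
grid $\{0, 0.2, 0.4, 0.6, 0.8, 1\}$ but evaluates a seeded subsample by
default (evaluating all of them is a matter of CPU-hours, not of method); any
claim about "most" grid games from a subsample carries the usual sampling
caveat, and the recorded seed makes each subsample reproducible.

Problem sizes used by the packaged checks: the weak-selection census
evaluates self-play for all $256 + 16$ strategies per game at five error
rates (a few seconds for all 64 games); the strong-selection census
additionally evaluates all strategy pairs per game and setting at
$N = 100$, $\beta = 10$ (about half a minute for all 64 games); trajectory
validation uses $6\times10^4$ mutation events. These sizes are the package's
defaults because they make every census exact and every stochastic check
statistically decisive at three standard errors.

## Known limitations

* Strategies are memory-one and deterministic at the evolutionary level;
  stochastic strategy spaces, longer memories, more than two players, and
  more than two states are out of scope.
* Transition vectors are action-symmetric ($q_{CD} = q_{DC}$) by
  construction; asymmetric feedback cannot be represented.
* The equilibrium module evaluates deviations within memory-one strategies
  (for Nash) and arbitrary behavior strategies via the MDP (for subgame
  perfection); it does not construct equilibria, only checks them.
* The rare-error limit is an extrapolation, exact only up to the stated
  $\sim 10^{-8}$ truncation bound; neutrality calls use tolerances
  ($10^{-6}$ at $\beta = 0$, $10^{-4}$ at fixed $\varepsilon = 0.01$) chosen
  two orders below the smallest non-neutral signal observed in the censuses.
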