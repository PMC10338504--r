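# stategames

Evolution of cooperation in two-state stochastic games, with and without
information about the state of the environment.

## The problem

In many social dilemmas the environment feeds back on behavior: how a group
acts today changes the game it faces tomorrow. The simplest model of this kind
is a two-player, two-state stochastic game. In every round the players are in
one of two environmental states and play a donation-style prisoner's dilemma:
cooperating costs `c` and gives the co-player a benefit `b1` (in the more
profitable state `s1`) or `b2` (in `s2`), with `b1 >= b2 > c`. The state of
the next round is drawn according to the game's **transition vector**

```
q = (q1_CC, q1_CD, q1_DD ; q2_CC, q2_CD, q2_DD),
```

where `qi_aa` is the probability of moving to `s1` given the current state
`si` and the players' action pair (transitions depend only on the number of
cooperators).

Players use **memory-one strategies**: rules that prescribe a cooperation
probability as a function of the previous round. If players can observe the
current state (*full information*), a strategy has 8 entries
`p = (p1_CC, ..., p1_DD; p2_CC, ..., p2_DD)` and there are 2^8 = 256
deterministic strategies. If they cannot (*no information*), it has 4 entries
and there are 2^4 = 16. Intended moves are flipped with a small error
probability `eps`, so a player with strategy `p` effectively plays
`(1 - eps) p + eps (1 - p)`.

A pair of such strategies induces a Markov chain over the eight round-outcomes
`(si, a, ã)`; its stationary distribution `v` gives exact long-run payoffs

```
pi = b1 (v1_CC + v1_DC) + b2 (v2_CC + v2_DC) - c (v1_CC + v1_CD + v2_CC + v2_CD)
```

and cooperation rates `gamma = v1_CC + (v1_CD + v1_DC)/2 + v2_CC + (v2_CD + v2_DC)/2`.

Evolution follows a pairwise comparison (Fermi) process in a population of
size `N` with selection strength `beta`, studied in the rare-mutation limit:
the population is monomorphic between mutations, a mutant fixes with
probability

```
rho(pR, pM) = 1 / (1 + sum_{i=1}^{N-1} prod_{k=1}^{i} exp[-beta (pi_M(k) - pi_R(k))]),
```

and evolution reduces to a Markov chain over resident strategies whose
invariant distribution `w` yields the evolved average cooperation rate
`gamma_hat = sum_p w_p gamma(p, p)`. The package's central quantity is the
**value of state information**

```
V_beta(q) = gamma_hat(full) - gamma_hat(none):
```

positive values are a *benefit of information*, negative values a *benefit of
ignorance*. Under weak selection (`beta -> 0`) the invariant distribution is
uniform and a simple integer proxy
`X = (1[q1_CC = 1] + 1[q2_CC = 0]) - (1[q1_DD = 1] + 1[q2_DD = 0])`
predicts the sign of `V_0` for every non-neutral deterministic game. The
package also checks Nash equilibrium (by enumerating all memory-one
deviations) and subgame perfection (by an average-reward dynamic program for a
single deviator) in the rare-error limit.

## Worked example

The "timeout" game `q = (1,0,0;1,1,1)` keeps mutually cooperating players in
the profitable state and sends everyone else to a one-round timeout:

```r
library(stategames)
q <- transition_vector("(1,0,0;1,1,1)")

evolve_population("full", q)
#> <evolved population> full information, q = (1,0,0;1,1,1)
#>   N = 100, beta = 10, epsilon = 0.01
#>   average cooperation rate: 0.8112   average payoff: 0.6387
#>   most abundant strategies: (1,0,0,0;0,0,0,1) (33.5%), (1,0,0,0;1,0,0,1) (33.5%), ...

evolve_population("none", q)
#> <evolved population> none information, q = (1,0,0;1,1,1)
#>   average cooperation rate: 0.0697   average payoff: 0.0454
#>   most abundant strategies: (1,0,0,0) (47.7%), (0,0,0,0) (41.6%), ...

as.numeric(value_of_information(q))
#> [1] 0.741487
```

With state information the population cooperates 81% of the time, carried by
the state-aware win-stay lose-shift variants `(1,0,0,0;x,0,0,1)`; without it,
cooperation collapses to 7% and `V_beta = 0.74`. The reason is an equilibrium
threshold: plain WSLS `(1,0,0,1)` is only a best response to itself here when
`b1 > 2c`, and the default `b1 = 1.8` falls short —

```r
is_nash(strategy_wsls(), q)
#> strategy (1,0,0,1): is_nash FALSE, best deviation (0,0,0,1;...), payoff gap 0.0667
critical_threshold(strategy_wsls(), q, vary = "b1", bracket = c(1.3, 3), predicate = "nash")
#> [1] 1.999989
```

The weak-selection classification of all 64 deterministic games takes a couple
of seconds and reproduces the full census — 15 games neutral because a state
is absorbing, 6 more because transitions are state-independent, 11 neutral by
symmetry, and the remaining 32 split 16/16 between benefit of information and
benefit of ignorance, with `sign(V0) = sign(X)` throughout:

```r
cl <- classify_deterministic_games()
attr(cl, "summary")
#> $n_absorbing [1] 15      $n_state_independent [1] 6   $n_symmetry [1] 11
#> $n_benefit_information [1] 16   $n_benefit_ignorance [1] 16
```

Each result type has plotting and tidying helpers (`tidy()`, `glance()`,
`autoplot()`, `plot_classification()`, `plot_family_scan()`), and
`inst/cli/stategames.R` exposes the same operations as shell subcommands
(`evolve`, `classify`, `scan`, `equilibrium`, `invasion-graph`, `simulate`,
`preset`).

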