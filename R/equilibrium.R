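#' Nash-equilibrium check by deviation enumeration
#'
#' A resident memory-one strategy `p` is a Nash equilibrium (within the
#' deterministic memory-one strategies of the chosen setting) when no deviant
#' strategy earns more against the resident than the resident earns against
#' itself. Payoffs are evaluated in the rare-error limit. Ties (a deviation
#' earning exactly the resident payoff) count as no profitable deviation.
#'
#' @param p resident [memory_one_strategy()].
#' @param q a [transition_vector()].
#' @param params a [game_parameters()] object.
#' @param deviation_setting `"full"` or `"none"`: which deterministic strategy
#'   set deviations are drawn from (defaults to the resident's setting).
#' @param tol numeric slack on the payoff comparison.
#' @returns A one-row tibble (an equilibrium report): `strategy`, `setting`,
#'   `is_nash`, `best_deviation`, `payoff_gap` (the best deviation's payoff
#'   minus the resident payoff; `is_nash` is true iff the gap is at most
#'   `tol`).
#' @export
is_nash <- function(p, q, params = game_parameters(),
                    deviation_setting = NULL, tol = 1e-9) {
  setting <- deviation_setting %||% attr(p, "setting") %||%
    (if (length(p) == 8L) "full" else "none")
  p8 <- embed_no_info(p)
  v_res <- limit_stationary_distribution(p8, p8, q)
  pi_res <- payoff(v_res, params)
  P <- strategy_set(setting)
  gaps <- vapply(seq_len(nrow(P)), function(i) {
    v <- limit_stationary_distribution(P[i, ], p8, q)
    payoff(v, params) - pi_res
  }, numeric(1))
  best <- which.max(gaps)
  tibble::tibble(
    strategy = strategy_label(as.numeric(p)),
    setting = setting,
    is_nash = gaps[best] <= tol,
    best_deviation = strategy_label(P[best, ]),
    payoff_gap = gaps[best],
    resident_payoff = pi_res
  )
}

# The single-deviator Markov decision process against a memory-one resident:
# states are the 8 outcome-states (current environmental state, deviator's
# previous action, resident's previous action), actions are C/D. Returns the
# reward matrix (8 x 2) and transition tensor (8 x 2 x 8).
deviator_mdp <- function(p_resident, q, params) {
  q <- unclass(transition_vector(q))
  pt <- as.numeric(embed_no_info(p_resident))
  qidx <- c(1, 2, 2, 3)
  # enumerate MDP states: sigma = (s, a, at), index like outcome order
  # resident cooperation prob this round: pt[s, at, a] (transposed order)
  res_c <- vapply(1:8, function(w) {
    s <- (w - 1) %/% 4 + 1; ap <- (w - 1) %% 4
    a <- ap %/% 2; at <- ap %% 2
    pt[(s - 1) * 4 + at * 2 + a + 1]
  }, numeric(1))
  b_s <- ifelse(rep(1:2, each = 4) == 1, params$b1, params$b2)
  # reward(sigma, a'): resident cooperates with prob res_c
  reward <- cbind(C = b_s * res_c - params$c, D = b_s * res_c)
  # transition tensor P[sigma, a', sigma']
  Ptens <- array(0, c(8, 2, 8))
  for (w in 1:8) {
    s <- (w - 1) %/% 4 + 1
    for (ai in 1:2) {
      a2 <- ai - 1                         # deviator action: 0 = C, 1 = D
      for (ati in 1:2) {
        at2 <- ati - 1                     # resident action
        pr_at <- if (at2 == 0) res_c[w] else 1 - res_c[w]
        if (pr_at == 0) next
        apn <- a2 * 2 + at2                # next previous-action pair
        qv <- q[(s - 1) * 3 + qidx[apn + 1]]
        wn1 <- apn + 1                      # next state s1
        wn2 <- 4 + apn + 1                  # next state s2
        Ptens[w, ai, wn1] <- Ptens[w, ai, wn1] + pr_at * qv
        Ptens[w, ai, wn2] <- Ptens[w, ai, wn2] + pr_at * (1 - qv)
      }
    }
  }
  list(reward = reward, Ptens = Ptens)
}

# discounted policy evaluation in the deviator MDP: value of following a fixed
# policy (1 = C, 2 = D per state) from each of the 8 states
mdp_policy_value <- function(mdp, policy, delta) {
  Ppol <- t(vapply(1:8, function(w) mdp$Ptens[w, policy[w], ], numeric(8)))
  rpol <- mdp$reward[cbind(1:8, policy)]
  solve(diag(8) - delta * Ppol, rpol)
}

# optimal discounted value by policy iteration (exact for this 8-state,
# 2-action MDP; terminates in a handful of improvement steps)
mdp_optimal <- function(mdp, delta, max_iter = 100) {
  pol <- rep(1L, 8)
  V <- NULL
  for (it in seq_len(max_iter)) {
    V <- mdp_policy_value(mdp, pol, delta)
    Q <- vapply(1:2, function(ai) {
      mdp$reward[, ai] + delta * as.numeric(mdp$Ptens[, ai, ] %*% V)
    }, numeric(8))
    newpol <- max.col(Q, ties.method = "first")
    if (all(newpol == pol)) break
    pol <- newpol
  }
  list(V = V, Q = Q, policy = pol)
}

# resident's prescribed action (1 = C, 2 = D) at each outcome-state (s, a, at):
# its own previous action is a, the co-player's is at
resident_policy <- function(p8) {
  ifelse(vapply(1:8, function(w) {
    s <- (w - 1) %/% 4 + 1; ap <- (w - 1) %% 4
    a <- ap %/% 2; at <- ap %% 2
    p8[(s - 1) * 4 + a * 2 + at + 1]
  }, numeric(1)) >= 0.5, 1L, 2L)
}

#' Subgame-perfection check by dynamic programming
#'
#' A resident strategy is subgame perfect when, after *every* possible history
#' (summarized by the eight outcome-states), no unilateral deviator can secure
#' a higher long-run average payoff than a player who keeps following the
#' resident strategy. The deviator's best response against the memory-one
#' resident is a Markov decision process on the outcome-states, solved exactly
#' by policy iteration under discounting. The undiscounted game is handled by
#' the vanishing-discount construction: the average reward (gain) of both the
#' optimal policy and the follow-the-resident policy is recovered from each
#' state as the limit of `(1 - delta) * V_delta`, by polynomial extrapolation
#' over a sequence of discount factors approaching 1. The reported
#' `payoff_gap` is the largest gain advantage of deviating at any state; ties
#' (a deviation achieving exactly the resident's average payoff, as happens on
#' the equilibrium boundary) count as no profitable deviation, matching the
#' weak inequality in the equilibrium conditions. Transient (one-round)
#' advantages that do not change the long-run average are deliberately not
#' counted.
#'
#' @inheritParams is_nash
#' @param delta_seq discount factors approaching 1 used for the
#'   vanishing-discount extrapolation.
#' @returns A one-row tibble: `strategy`, `setting`, `is_nash` (from the
#'   enumeration check of [is_nash()]), `is_subgame_perfect`, `best_deviation`
#'   (the state with the largest gain advantage and the deviator's optimal
#'   action there) and `payoff_gap`.
#' @export
is_subgame_perfect <- function(p, q, params = game_parameters(),
                               delta_seq = c(0.99, 0.999, 0.9999), tol = 1e-6) {
  p8 <- as.numeric(embed_no_info(p))
  mdp <- deviator_mdp(p, q, params)
  res_pol <- resident_policy(p8)
  # The policy that is optimal at the most patient discount is optimal for the
  # average-reward criterion (Blackwell optimality in a finite MDP). Its gain
  # from each state is the limit of (1 - delta) * V_delta; with the policy held
  # fixed, V_delta is a rational function of delta and the extrapolation is
  # free of policy-switch kinks. The same evaluation for the
  # follow-the-resident policy gives the comparison gain.
  pol_star <- mdp_optimal(mdp, max(delta_seq))$policy
  gain_opt <- vapply(delta_seq, function(d) {
    (1 - d) * mdp_policy_value(mdp, pol_star, d)
  }, numeric(8))
  gain_res <- vapply(delta_seq, function(d) {
    (1 - d) * mdp_policy_value(mdp, res_pol, d)
  }, numeric(8))
  adv <- extrapolate_to_zero(gain_opt - gain_res, 1 - delta_seq)$estimate
  gap <- max(adv, 0)
  worst <- which.max(adv)
  dp <- mdp_optimal(mdp, max(delta_seq))
  nash <- is_nash(p, q, params)
  tibble::tibble(
    strategy = strategy_label(as.numeric(p)),
    setting = attr(p, "setting") %||% (if (length(p) == 8L) "full" else "none"),
    is_nash = nash$is_nash,
    is_subgame_perfect = gap <= tol,
    best_deviation = sprintf("%s: play %s", outcome_labels()[worst],
                             c("C", "D")[dp$policy[worst]]),
    payoff_gap = gap
  )
}

#' Locate an equilibrium threshold by bisection
#'
#' Finds the parameter value at which an equilibrium predicate switches, e.g.
#' the critical benefit `b1` above which a strategy becomes a Nash equilibrium.
#' The predicate must differ at the two bracket endpoints; a monotone switch is
#' assumed (and spot-checked at the midpoint of the initial bracket).
#'
#' @param p resident [memory_one_strategy()].
#' @param q a [transition_vector()].
#' @param params baseline [game_parameters()]; the varied parameter is
#'   overridden.
#' @param vary name of the parameter to vary (`"b1"`, `"b2"` or `"c"`).
#' @param bracket length-2 numeric bracket.
#' @param predicate `"nash"` or `"subgame_perfect"`.
#' @param deviation_setting passed to [is_nash()].
#' @param xtol bisection tolerance on the parameter.
#' @returns The critical parameter value (boundary of the `TRUE` region), with
#'   attribute `"predicate_above"` (value of the predicate at the upper
#'   endpoint).
#' @export
critical_threshold <- function(p, q, params = game_parameters(),
                               vary = "b1", bracket,
                               predicate = c("nash", "subgame_perfect"),
                               deviation_setting = NULL, xtol = 1e-4) {
  predicate <- match.arg(predicate)
  eval_at <- function(x) {
    pars <- params
    pars[[vary]] <- x
    pars <- game_parameters(b1 = pars$b1, b2 = pars$b2, c = pars$c,
                            epsilon = pars$epsilon, delta = pars$delta)
    if (predicate == "nash") {
      is_nash(p, q, pars, deviation_setting)$is_nash
    } else {
      is_subgame_perfect(p, q, pars)$is_subgame_perfect
    }
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- eval_at(lo); f_hi <- eval_at(hi)
  if (f_lo == f_hi) {
    stop("equilibrium predicate does not change across the bracket", call. = FALSE)
  }
  while (hi - lo > xtol) {
    mid <- (lo + hi) / 2
    if (eval_at(mid) == f_lo) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, predicate_above = f_hi)
}
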