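#' Transition matrix of the round-outcome Markov chain
#'
#' A pair of memory-one players in a two-state game induces a Markov chain on
#' the eight round-outcomes `(si, a, a~)`. The transition probability from
#' outcome `w` to `w'` factorizes into an environmental factor (the chance that
#' the state moves as prescribed, given the transition vector and the previous
#' action pair) and one factor per player (the chance that the player chooses
#' the prescribed next action, given its strategy entry for the *next* state
#' and the previous actions). The co-player's strategy is indexed with the
#' action order transposed, since its "own" action is the focal player's
#' "other" action.
#'
#' @param p,p_tilde focal and co-player strategies, 8-entry
#'   [memory_one_strategy()] (4-entry strategies are embedded); entries may be
#'   stochastic.
#' @param q a [transition_vector()].
#' @param epsilon implementation-error probability applied to both strategies
#'   (default 0: `p` and `p_tilde` are used as given).
#' @returns An 8x8 row-stochastic matrix in the fixed outcome order
#'   `(s1,CC), (s1,CD), (s1,DC), (s1,DD), (s2,CC), (s2,CD), (s2,DC), (s2,DD)`.
#' @export
build_transition_matrix <- function(p, p_tilde, q, epsilon = 0) {
  q <- unclass(transition_vector(q))
  p <- as.numeric(effective_strategy(embed_no_info(p), epsilon))
  pt <- as.numeric(effective_strategy(embed_no_info(p_tilde), epsilon))
  M <- cpp_transition_matrix(p, pt, q)
  dimnames(M) <- list(outcome_labels(), outcome_labels())
  M
}

#' Stationary distribution over round outcomes
#'
#' The unique left eigenvector `v` of the outcome transition matrix with
#' eigenvalue 1, normalized to sum to 1. Uniqueness requires the error rate to
#' be positive and the transition vector to differ from `(1,1,1;0,0,0)` (where
#' both environmental states are absorbing and the long run depends on the
#' initial state; see [discounted_occupancy()] for that case).
#'
#' @param M an 8x8 row-stochastic matrix from [build_transition_matrix()].
#' @returns A named numeric vector of class `outcome_distribution`
#'   (nonnegative, sums to 1).
#' @export
stationary_distribution <- function(M) {
  v <- tryCatch(solve(t(M - diag(nrow(M)) + 1), rep(1, nrow(M))),
                error = function(e) NULL)
  if (is.null(v) || any(v < -1e-8) || abs(sum(v) - 1) > 1e-8) {
    stop(paste("the outcome chain has no unique stationary distribution",
               "(reducible chain: check epsilon > 0 and q != (1,1,1;0,0,0));",
               "use discounted_occupancy() with an initial-state convention instead"),
         call. = FALSE)
  }
  v <- pmax(v, 0)
  v <- v / sum(v)
  structure(setNames(v, colnames(M) %||% outcome_labels()), class = "outcome_distribution")
}

#' Stationary outcome distribution of a strategy pair
#'
#' Convenience wrapper: builds the transition matrix for `(p, p_tilde)` at the
#' given error rate and returns its stationary distribution.
#'
#' @inheritParams build_transition_matrix
#' @returns An `outcome_distribution`.
#' @export
pair_stationary <- function(p, p_tilde, q, epsilon) {
  stationary_distribution(build_transition_matrix(p, p_tilde, q, epsilon))
}

#' Rare-error limit of the stationary outcome distribution
#'
#' Stationary distributions are rational functions of the error rate, so the
#' limit as the error rate vanishes is computed by evaluating at a decreasing
#' sequence of error rates and extrapolating polynomially to zero
#' (Richardson/Neville scheme). A diagnostic error is raised when successive
#' extrapolation orders fail to agree.
#'
#' @inheritParams build_transition_matrix
#' @param eps_seq decreasing positive error rates used for extrapolation.
#' @param tol convergence tolerance on the difference between the two highest
#'   extrapolation orders. The difference is dominated by the truncation term
#'   of the lower order (about the product of the two smallest error rates
#'   times the curvature), so the default leaves an order of magnitude of
#'   headroom; the returned estimate itself is accurate to about `1e-11`.
#' @returns An `outcome_distribution` (the limit), with attribute
#'   `"extrapolation_error"`.
#' @export
limit_stationary_distribution <- function(p, p_tilde, q,
                                          eps_seq = default_eps_sequence(),
                                          tol = 1e-7) {
  vals <- vapply(eps_seq, function(e) as.numeric(pair_stationary(p, p_tilde, q, e)),
                 numeric(8))
  ex <- extrapolate_to_zero(vals, eps_seq)
  if (max(ex$error) > tol) {
    stop(sprintf("rare-error extrapolation did not converge (max discrepancy %.2e > %.1e)",
                 max(ex$error), tol), call. = FALSE)
  }
  v <- pmax(ex$estimate, 0)
  v <- v / sum(v)
  structure(setNames(v, outcome_labels()), class = "outcome_distribution",
            extrapolation_error = max(ex$error))
}

#' Initial-round outcome distribution
#'
#' For discounted games the very first round needs a convention. Play starts in
#' a designated state, and each player chooses its first move from its strategy
#' entry for that state as if the previous round had shown the fictitious
#' action pair `previous` (mutual cooperation by default).
#'
#' @inheritParams build_transition_matrix
#' @param initial_state 1 or 2.
#' @param previous fictitious previous action pair, e.g. `c("C", "C")`
#'   (focal first).
#' @returns An `outcome_distribution` supported on the initial state.
#' @export
initial_distribution <- function(p, p_tilde, q, epsilon = 0,
                                 initial_state = 1, previous = c("C", "C")) {
  stopifnot(initial_state %in% 1:2)
  a <- match(previous[1], c("C", "D")) - 1L
  at <- match(previous[2], c("C", "D")) - 1L
  if (anyNA(c(a, at))) stop("`previous` must be two of \"C\"/\"D\"", call. = FALSE)
  p <- as.numeric(effective_strategy(embed_no_info(p), epsilon))
  pt <- as.numeric(effective_strategy(embed_no_info(p_tilde), epsilon))
  pf <- p[(initial_state - 1) * 4 + a * 2 + at + 1]
  pc <- pt[(initial_state - 1) * 4 + at * 2 + a + 1]
  block <- c(pf * pc, pf * (1 - pc), (1 - pf) * pc, (1 - pf) * (1 - pc))
  v0 <- numeric(8)
  v0[(initial_state - 1) * 4 + 1:4] <- block
  structure(setNames(v0, outcome_labels()), class = "outcome_distribution")
}

#' Discounted occupancy distribution
#'
#' With continuation probability `delta < 1`, payoffs weight round `t` by
#' `(1 - delta) * delta^t`; the corresponding weighted visit frequencies are
#' `v = (1 - delta) * v0 * (I - delta M)^(-1)`.
#'
#' @param M an 8x8 transition matrix from [build_transition_matrix()].
#' @param v0 initial-round distribution (see [initial_distribution()]).
#' @param delta continuation factor in `(0, 1)`; use
#'   [stationary_distribution()] for `delta = 1`.
#' @returns An `outcome_distribution`.
#' @export
discounted_occupancy <- function(M, v0, delta) {
  if (delta <= 0 || delta >= 1) {
    stop("`delta` must be in (0, 1); use stationary_distribution() for delta = 1",
         call. = FALSE)
  }
  v <- (1 - delta) * solve(t(diag(nrow(M)) - delta * M), as.numeric(v0))
  structure(setNames(as.numeric(v), outcome_labels()), class = "outcome_distribution")
}

#' Payoff and cooperation-rate functionals of an outcome distribution
#'
#' The focal player's long-run payoff collects the benefit `b_i` whenever the
#' co-player cooperated and pays the cost whenever the focal player cooperated,
#' weighted by the outcome distribution:
#' \deqn{\pi = b_1 (v^1_{CC} + v^1_{DC}) + b_2 (v^2_{CC} + v^2_{DC})
#'   - c (v^1_{CC} + v^1_{CD} + v^2_{CC} + v^2_{CD}).}
#' `coplayer_payoff()` is the same functional with the action indices
#' transposed. The average cooperation rate counts a full point for mutual
#' cooperation and half a point for each unilateral cooperation:
#' \deqn{\gamma = v^1_{CC} + (v^1_{CD} + v^1_{DC})/2
#'   + v^2_{CC} + (v^2_{CD} + v^2_{DC})/2.}
#'
#' @param v an `outcome_distribution`.
#' @param params a [game_parameters()] object.
#' @returns A numeric scalar.
#' @export
payoff <- function(v, params) {
  v <- as.numeric(v)
  params$b1 * (v[1] + v[3]) + params$b2 * (v[5] + v[7]) -
    params$c * (v[1] + v[2] + v[5] + v[6])
}

#' @rdname payoff
#' @export
coplayer_payoff <- function(v, params) {
  v <- as.numeric(v)
  params$b1 * (v[1] + v[2]) + params$b2 * (v[5] + v[6]) -
    params$c * (v[1] + v[3] + v[5] + v[7])
}

#' @rdname payoff
#' @export
cooperation_rate <- function(v) {
  v <- as.numeric(v)
  (v[1] + (v[2] + v[3]) / 2) + (v[5] + (v[6] + v[7]) / 2)
}

#' Payoffs and cooperation rate of a strategy pair
#'
#' One-call evaluation of a match between two memory-one strategies: stationary
#' outcome distribution (or discounted occupancy when `params$delta < 1`, or
#' the rare-error limit when `limit = TRUE`), both players' payoffs and the
#' average cooperation rate.
#'
#' @inheritParams build_transition_matrix
#' @param params a [game_parameters()] object; its `epsilon` and `delta` are
#'   used.
#' @param limit take the rare-error limit instead of using `params$epsilon`.
#' @returns A one-row tibble with columns `payoff_focal`, `payoff_coplayer`,
#'   `cooperation` and the outcome weights `s1_CC` ... `s2_DD`.
#' @export
play_game <- function(p, p_tilde, q, params = game_parameters(), limit = FALSE) {
  v <- if (limit) {
    limit_stationary_distribution(p, p_tilde, q)
  } else if (params$delta < 1) {
    M <- build_transition_matrix(p, p_tilde, q, params$epsilon)
    v0 <- initial_distribution(p, p_tilde, q, params$epsilon)
    discounted_occupancy(M, v0, params$delta)
  } else {
    pair_stationary(p, p_tilde, q, params$epsilon)
  }
  out <- tibble::tibble(payoff_focal = payoff(v, params),
                        payoff_coplayer = coplayer_payoff(v, params),
                        cooperation = cooperation_rate(v))
  dplyr::bind_cols(out, tibble::as_tibble(as.list(as.numeric(v) |> setNames(outcome_labels()))))
}

#' @export
print.outcome_distribution <- function(x, ...) {
  cat("<outcome distribution>\n")
  print(round(unclass(x), 6))
  invisible(x)
}
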