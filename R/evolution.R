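#' Payoffs in a two-strategy mixed population
#'
#' In a well-mixed population of size `N` with `k` mutants and `N - k`
#' residents, every player interacts with all others (excluding itself), so
#' expected payoffs are hypergeometric-free linear mixtures of the four
#' pairwise payoffs:
#' \deqn{\pi_R(k) = \frac{N-k-1}{N-1}\pi(p_R,p_R) + \frac{k}{N-1}\pi(p_R,p_M),}
#' \deqn{\pi_M(k) = \frac{N-k}{N-1}\pi(p_M,p_R) + \frac{k-1}{N-1}\pi(p_M,p_M).}
#'
#' @param pR,pM resident and mutant [memory_one_strategy()] objects.
#' @param k number of mutants, `1 <= k <= N - 1`.
#' @param q a [transition_vector()].
#' @param params a [game_parameters()] object.
#' @param popparams a [population_parameters()] object (only `N` is used).
#' @returns A named numeric vector `c(pi_R, pi_M)`.
#' @export
mixed_population_payoffs <- function(pR, pM, k, q, params = game_parameters(),
                                     popparams = population_parameters()) {
  N <- popparams$N
  if (k < 1 || k > N - 1) stop("`k` must satisfy 1 <= k <= N - 1", call. = FALSE)
  pRR <- play_game(pR, pR, q, params)$payoff_focal
  g <- play_game(pR, pM, q, params)
  pRM <- g$payoff_focal
  pMR <- g$payoff_coplayer
  pMM <- play_game(pM, pM, q, params)$payoff_focal
  c(pi_R = ((N - k - 1) * pRR + k * pRM) / (N - 1),
    pi_M = ((N - k) * pMR + (k - 1) * pMM) / (N - 1))
}

# fixation probability from the four pairwise payoffs, log-domain safe.
# The payoff difference pi_M(k) - pi_R(k) is linear in k, so its partial sums
# are quadratic; the sum over exp terms is shifted by its maximum exponent.
fixation_from_payoffs <- function(pRR, pRM, pMR, pMM, N, beta) {
  k <- seq_len(N - 1)
  d <- ((N - k) * pMR + (k - 1) * pMM - (N - k - 1) * pRR - k * pRM) / (N - 1)
  S <- cumsum(d)
  L <- -beta * S                      # log of each product term
  m <- max(L, 0)
  exp(-m) / (exp(-m) + sum(exp(L - m)))
}

#' Fixation probability under the pairwise comparison process
#'
#' Probability that a single mutant with strategy `pM` takes over a resident
#' population playing `pR`, under imitation with Fermi update of selection
#' strength `beta`:
#' \deqn{\rho(p_R, p_M) = \Big(1 + \sum_{i=1}^{N-1}\prod_{k=1}^{i}
#'   e^{-\beta(\pi_M(k) - \pi_R(k))}\Big)^{-1}.}
#' Evaluation accumulates the exponents and shifts by their maximum, so large
#' `N * beta * payoff` products cannot overflow. At `beta = 0` the result is
#' exactly `1/N`.
#'
#' @inheritParams mixed_population_payoffs
#' @returns A probability in `(0, 1)`.
#' @export
fixation_probability <- function(pR, pM, q, params = game_parameters(),
                                 popparams = population_parameters()) {
  pRR <- play_game(pR, pR, q, params)$payoff_focal
  g <- play_game(pR, pM, q, params)
  pMM <- play_game(pM, pM, q, params)$payoff_focal
  fixation_from_payoffs(pRR, g$payoff_focal, g$payoff_coplayer, pMM,
                        popparams$N, popparams$beta)
}

# All ordered-pair fixation probabilities from a payoff matrix PI, where
# PI[i, j] = pi(p_i, p_j). Vectorized over pairs; rho[i, j] is the probability
# that a j-mutant fixes in an i-resident population. Diagonal set to NA.
fixation_matrix <- function(PI, N, beta) {
  n <- nrow(PI)
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  pRR <- PI[cbind(i, i)]; pRM <- PI[cbind(i, j)]
  pMR <- PI[cbind(j, i)]; pMM <- PI[cbind(j, j)]
  # pi_M(k) - pi_R(k) = a + b * k
  a <- (N * pMR - pMM - (N - 1) * pRR) / (N - 1)
  b <- (pMM + pRR - pMR - pRM) / (N - 1)
  kk <- seq_len(N - 1)
  # partial sums S_i = a*i + b*i(i+1)/2; logs L = -beta * S (pairs x (N-1))
  L <- -beta * (outer(a, kk) + outer(b, kk * (kk + 1) / 2))
  m <- pmax(apply(L, 1, max), 0)
  rho <- exp(-m) / (exp(-m) + rowSums(exp(L - m)))
  out <- matrix(rho, n, n)
  diag(out) <- NA_real_
  out
}

#' Pairwise payoff and cooperation matrices for a deterministic strategy set
#'
#' Evaluates every ordered pair of the 256 (full-information) or 16
#' (no-information) deterministic strategies: `pi[i, j]` is the payoff of
#' strategy `i` against strategy `j` and `gamma[i, j]` the pair's average
#' cooperation rate, at error rate `params$epsilon`. One stationary solve per
#' unordered pair (the same outcome distribution yields both players' payoffs).
#'
#' @param setting `"full"` or `"none"`, or a strategy matrix from
#'   [strategy_set()].
#' @inheritParams mixed_population_payoffs
#' @param epsilon error rate; defaults to `params$epsilon`.
#' @returns A list with matrices `pi` and `gamma` (rows/columns in strategy-id
#'   order) and the `setting`.
#' @export
pair_matrices <- function(setting, q, params = game_parameters(),
                          epsilon = params$epsilon) {
  P <- if (is.matrix(setting)) setting else strategy_set(setting)
  if (epsilon <= 0) stop("`epsilon` must be positive for stationary evaluation", call. = FALSE)
  Peff <- (1 - epsilon) * P + epsilon * (1 - P)
  q <- unclass(transition_vector(q))
  res <- cpp_pair_matrices(Peff, q, params$b1, params$b2, params$c)
  dimnames(res$pi) <- dimnames(res$gamma) <- list(rownames(P), rownames(P))
  res$setting <- attr(P, "setting")
  res
}

#' Embedded resident-strategy Markov chain under rare mutations
#'
#' When mutations are rare the population is monomorphic almost always, and
#' evolution reduces to a Markov chain over resident strategies: from resident
#' `p`, the chain moves to `p~ != p` with probability `rho(p, p~) / |P|`
#' (a uniform mutant draw followed by fixation), and stays put with the
#' remaining probability.
#'
#' @param setting `"full"` or `"none"`, or a precomputed [pair_matrices()]
#'   result.
#' @inheritParams mixed_population_payoffs
#' @returns A list with the row-stochastic `transition` matrix, the fixation
#'   matrix `rho`, and the `pi`/`gamma` pair matrices.
#' @export
embedded_chain <- function(setting, q, params = game_parameters(),
                           popparams = population_parameters()) {
  pm <- if (is.list(setting) && !is.null(setting$pi)) setting else pair_matrices(setting, q, params)
  n <- nrow(pm$pi)
  rho <- fixation_matrix(pm$pi, popparams$N, popparams$beta)
  Tm <- rho / n
  diag(Tm) <- 0
  diag(Tm) <- 1 - rowSums(Tm)
  list(transition = Tm, rho = rho, pi = pm$pi, gamma = pm$gamma,
       setting = pm$setting)
}

#' Invariant distribution of a finite Markov chain
#'
#' Left eigenvector with eigenvalue 1 of a row-stochastic matrix, normalized to
#' sum to 1. Solved as a linear system; falls back to a dense eigensolver if
#' the system is numerically singular.
#'
#' @param Tm a row-stochastic matrix.
#' @returns A nonnegative numeric vector summing to 1.
#' @export
invariant_distribution <- function(Tm) {
  n <- nrow(Tm)
  w <- tryCatch(solve(t(Tm - diag(n) + 1), rep(1, n)), error = function(e) NULL)
  if (is.null(w) || any(w < -1e-10)) {
    ev <- eigen(t(Tm))
    k <- which.min(abs(ev$values - 1))
    w <- Re(ev$vectors[, k])
    w <- w / sum(w)
  }
  w <- pmax(w, 0)
  w / sum(w)
}

#' Long-run population averages in the rare-mutation limit
#'
#' Solves the embedded resident chain and averages self-play payoff and
#' cooperation rate over its invariant distribution:
#' \eqn{\hat\pi = \sum_p w_p \pi(p,p)} and
#' \eqn{\hat\gamma = \sum_p w_p \gamma(p,p)}.
#'
#' @param setting `"full"` or `"none"` (which deterministic strategy set the
#'   population draws mutants from), or a precomputed [embedded_chain()].
#' @inheritParams mixed_population_payoffs
#' @returns An object of class `evolved_population` with the invariant
#'   distribution, per-strategy self-play statistics and the averages; see
#'   [tidy.evolved_population()] and [glance.evolved_population()].
#' @export
evolve_population <- function(setting, q, params = game_parameters(),
                              popparams = population_parameters()) {
  ch <- if (is.list(setting) && !is.null(setting$transition)) setting
        else embedded_chain(setting, q, params, popparams)
  w <- invariant_distribution(ch$transition)
  pi_self <- diag(ch$pi)
  gamma_self <- diag(ch$gamma)
  structure(list(
    setting = ch$setting, q = transition_vector(q),
    params = params, popparams = popparams,
    weights = w, pi_self = pi_self, gamma_self = gamma_self,
    rho = ch$rho, pi = ch$pi, gamma = ch$gamma,
    pi_hat = sum(w * pi_self), gamma_hat = sum(w * gamma_self)
  ), class = "evolved_population")
}

#' @export
print.evolved_population <- function(x, ...) {
  cat(sprintf("<evolved population> %s information, q = %s\n",
              x$setting, format_transition_vector(x$q)))
  cat(sprintf("  N = %d, beta = %g, epsilon = %g\n",
              x$popparams$N, x$popparams$beta, x$params$epsilon))
  cat(sprintf("  average cooperation rate: %.4f   average payoff: %.4f\n",
              x$gamma_hat, x$pi_hat))
  top <- head(order(x$weights, decreasing = TRUE), 3)
  lab <- vapply(top - 1L, function(id) {
    s <- if (x$setting == "none") strategy_from_id(id, "none") else strategy_from_id(id, "full")
    strategy_label(as.numeric(s))
  }, character(1))
  cat("  most abundant strategies:",
      paste(sprintf("%s (%.1f%%)", lab, 100 * x$weights[top]), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy an evolved population
#'
#' @param x an [evolve_population()] result.
#' @param ... unused.
#' @returns `tidy()`: one row per strategy with its id, label, invariant
#'   weight and self-play statistics, sorted by weight. `glance()`: a one-row
#'   summary with the ensemble averages and parameters.
#' @export
tidy.evolved_population <- function(x, ...) {
  n <- length(x$weights)
  ids <- seq_len(n) - 1L
  labs <- vapply(ids, function(id) {
    strategy_label(as.numeric(strategy_from_id(id, x$setting)))
  }, character(1))
  tibble::tibble(strategy_id = ids, strategy = labs, weight = x$weights,
                 payoff = x$pi_self, cooperation = x$gamma_self) |>
    dplyr::arrange(dplyr::desc(.data$weight))
}

#' @rdname tidy.evolved_population
#' @export
glance.evolved_population <- function(x, ...) {
  tibble::tibble(setting = x$setting, q = format_transition_vector(x$q),
                 gamma_hat = x$gamma_hat, pi_hat = x$pi_hat,
                 n_strategies = length(x$weights),
                 N = x$popparams$N, beta = x$popparams$beta,
                 epsilon = x$params$epsilon,
                 b1 = x$params$b1, b2 = x$params$b2, c = x$params$c)
}

#' Ensemble averages under a given invariant distribution
#'
#' @param w nonnegative weights over the strategy set (summing to 1).
#' @param setting `"full"` or `"none"`.
#' @inheritParams mixed_population_payoffs
#' @returns A named vector `c(pi_hat, gamma_hat)`.
#' @export
ensemble_averages <- function(w, setting, q, params = game_parameters()) {
  pm <- pair_matrices(setting, q, params)
  stopifnot(length(w) == nrow(pm$pi))
  c(pi_hat = sum(w * diag(pm$pi)), gamma_hat = sum(w * diag(pm$gamma)))
}

#' Value of state information
#'
#' The difference in evolved average cooperation rates between a population
#' whose strategies may condition on the environmental state and one whose
#' strategies cannot: \eqn{V_\beta(q) = \hat\gamma^F - \hat\gamma^N}, both
#' computed under identical parameters. Positive values are a benefit of
#' information, negative values a benefit of ignorance.
#'
#' For the doubly-absorbing vector `(1,1,1;0,0,0)` the outcome chain is
#' reducible (which initial state the players start in is never forgotten), so
#' the stationary computation is undefined; both states are absorbing, state
#' information is neutral under any initial convention, and the function
#' returns exactly 0.
#'
#' @inheritParams mixed_population_payoffs
#' @returns A numeric scalar, with attributes `gamma_full` and `gamma_none`.
#' @export
value_of_information <- function(q, params = game_parameters(),
                                 popparams = population_parameters()) {
  qq <- unclass(transition_vector(q))
  if (all(qq[1:3] == 1) && all(qq[4:6] == 0)) {
    return(structure(0, gamma_full = NA_real_, gamma_none = NA_real_))
  }
  gF <- evolve_population("full", q, params, popparams)$gamma_hat
  gN <- evolve_population("none", q, params, popparams)$gamma_hat
  structure(gF - gN, gamma_full = gF, gamma_none = gN)
}
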