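#' Game parameters
#'
#' The stage game in state `si` is a donation-style prisoner's dilemma:
#' cooperation costs `c` and delivers a benefit `b1` (state 1) or `b2`
#' (state 2) to the co-player. State 1 is the more profitable one, so
#' `b1 >= b2 > c`; the cost is the payoff unit (`c = 1` by default).
#' `epsilon` is the probability that an intended move is flipped;
#' `delta` is the continuation (discount) factor, with `delta = 1` the
#' undiscounted long-run average used throughout.
#'
#' Defaults are the baseline used in all worked examples:
#' `b1 = 1.8, b2 = 1.3, c = 1, epsilon = 0.01, delta = 1`.
#'
#' @param b1,b2 benefits of cooperation in states 1 and 2 (`b1 >= b2 > c`).
#' @param c cost of cooperation (`> 0`).
#' @param epsilon implementation-error probability in `[0, 1/2)`.
#' @param delta continuation factor in `(0, 1]`.
#' @returns A list of class `game_parameters`.
#' @export
game_parameters <- function(b1 = 1.8, b2 = 1.3, c = 1, epsilon = 0.01, delta = 1) {
  if (!(b1 >= b2 && b2 > c && c > 0)) stop("need b1 >= b2 > c > 0", call. = FALSE)
  if (epsilon < 0 || epsilon >= 0.5) stop("`epsilon` must be in [0, 1/2)", call. = FALSE)
  if (delta <= 0 || delta > 1) stop("`delta` must be in (0, 1]", call. = FALSE)
  structure(list(b1 = b1, b2 = b2, c = c, epsilon = epsilon, delta = delta),
            class = "game_parameters")
}

#' @export
print.game_parameters <- function(x, ...) {
  cat(sprintf("<game parameters> b1=%g b2=%g c=%g epsilon=%g delta=%g\n",
              x$b1, x$b2, x$c, x$epsilon, x$delta))
  invisible(x)
}

#' Population parameters for the pairwise comparison process
#'
#' @param N population size (integer, at least 2); default 100.
#' @param beta selection strength (non-negative); default 10. At `beta = 0`
#'   imitation is payoff-blind and every fixation probability equals `1/N`.
#' @param mu mutation probability in `[0, 1]`, used only by
#'   [simulate_trajectory()].
#' @returns A list of class `population_parameters`.
#' @export
population_parameters <- function(N = 100, beta = 10, mu = 0.01) {
  if (N < 2 || N != round(N)) stop("`N` must be an integer >= 2", call. = FALSE)
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  assert_probability(mu, "mu")
  structure(list(N = as.integer(N), beta = beta, mu = mu),
            class = "population_parameters")
}

#' @export
print.population_parameters <- function(x, ...) {
  cat(sprintf("<population parameters> N=%d beta=%g mu=%g\n", x$N, x$beta, x$mu))
  invisible(x)
}
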