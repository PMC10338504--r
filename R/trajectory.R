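#' Simulate the rare-mutation strategy dynamics
#'
#' Stochastic counterpart of the exact embedded-chain computation in
#' [evolve_population()]. The population starts monomorphic at always-defect.
#' At each step, with probability `popparams$mu` a mutation event occurs: a
#' candidate strategy is drawn uniformly from the deterministic set of the
#' chosen setting (the current resident included, matching the embedded
#' chain's convention) and replaces the resident with its fixation probability.
#' With probability `1 - mu` nothing happens. The recorded time series of
#' residents is therefore a simulation of the resident-level Markov chain, and
#' its time averages converge to the invariant-distribution averages.
#'
#' @param setting `"full"` or `"none"`.
#' @param q a [transition_vector()].
#' @param params a [game_parameters()] object.
#' @param popparams a [population_parameters()] object (`N`, `beta`, `mu`).
#' @param steps number of elementary steps (positive integer).
#' @param seed RNG seed; identical seeds give identical trajectories.
#' @returns A tibble with one row per step: `step`, `strategy_id`, `strategy`,
#'   `cooperation`, `payoff` (self-play values of the current resident).
#' @export
simulate_trajectory <- function(setting, q, params = game_parameters(),
                                popparams = population_parameters(),
                                steps = 1000, seed = 1) {
  if (steps <= 0) stop("`steps` must be positive", call. = FALSE)
  setting <- match.arg(setting, c("full", "none"))
  pm <- pair_matrices(setting, q, params)
  rho <- fixation_matrix(pm$pi, popparams$N, popparams$beta)
  n <- nrow(pm$pi)
  set.seed(seed)
  resident <- 1L   # id 0 = always defect, in both encodings
  res_seq <- integer(steps)
  u_mut <- runif(steps)
  cand <- sample.int(n, steps, replace = TRUE)
  u_fix <- runif(steps)
  for (t in seq_len(steps)) {
    if (u_mut[t] < popparams$mu) {
      m <- cand[t]
      if (m != resident && u_fix[t] < rho[resident, m]) resident <- m
    }
    res_seq[t] <- resident
  }
  ids <- res_seq - 1L
  labs <- vapply(seq_len(n) - 1L, function(id) {
    strategy_label(as.numeric(strategy_from_id(id, setting)))
  }, character(1))
  tibble::tibble(step = seq_len(steps), strategy_id = ids,
                 strategy = labs[res_seq],
                 cooperation = diag(pm$gamma)[res_seq],
                 payoff = diag(pm$pi)[res_seq])
}

#' Plot a simulated strategy trajectory
#'
#' Step plot of the resident population's self-play cooperation rate over the
#' course of a [simulate_trajectory()] run.
#'
#' @param object a tibble from [simulate_trajectory()].
#' @param ... unused.
#' @returns A ggplot object.
#' @export
plot_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$step, y = .data$cooperation)) +
    ggplot2::geom_step(color = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "mutation events", y = "resident self-cooperation rate") +
    ggplot2::theme_minimal()
}
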