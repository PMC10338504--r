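#' Weak-selection proxy variable
#'
#' An integer in `[-2, 2]` measuring how easily a deterministic game can be
#' locked into mutual cooperation versus mutual defection:
#' \deqn{X = (1_{q^1_{CC} = 1} + 1_{q^2_{CC} = 0})
#'        - (1_{q^1_{DD} = 1} + 1_{q^2_{DD} = 0}).}
#' For non-neutral deterministic games, state information is beneficial under
#' weak selection if and only if `X > 0`.
#'
#' @param q a [transition_vector()].
#' @returns An integer in `-2:2`.
#' @export
proxy_X <- function(q) {
  q <- unclass(transition_vector(q))
  as.integer((q[1] == 1) + (q[4] == 0)) - as.integer((q[3] == 1) + (q[6] == 0))
}

#' Neutrality class of a deterministic transition vector
#'
#' Under weak selection, half of the 64 deterministic games are neutral (state
#' information does not change the evolved cooperation rate). Three subclasses
#' are distinguished:
#' * `"absorbing"`: one environmental state can never be left (all state-1
#'   entries are 1, or all state-2 entries are 0); neutral for every selection
#'   strength.
#' * `"state-independent"`: both state blocks are identical, so the current
#'   state is inferable from the previous actions; neutral for every selection
#'   strength.
#' * `"symmetry"`: neutral at weak selection only, by symmetry arguments;
#'   membership is determined numerically (the weak-selection value of
#'   information vanishes although the game is in neither of the first two
#'   subclasses).
#' * `"non-neutral"`: everything else.
#'
#' @param q a deterministic [transition_vector()].
#' @param V0 optional precomputed weak-selection value of information; computed
#'   by [weak_selection_value()] when needed and not supplied.
#' @param tol neutrality tolerance on `V0` after the rare-error limit.
#' @returns One of `"absorbing"`, `"state-independent"`, `"symmetry"`,
#'   `"non-neutral"`. For stochastic `q` only the absorbing test applies;
#'   non-absorbing stochastic vectors are classified from `V0` alone.
#' @export
neutrality_class <- function(q, V0 = NULL, tol = 1e-6) {
  q <- transition_vector(q)
  qq <- unclass(q)
  if (has_absorbing_state(q)) return("absorbing")
  if (is_deterministic(q) && all(qq[1:3] == qq[4:6])) return("state-independent")
  if (is.null(V0)) V0 <- weak_selection_value(q)
  if (abs(V0) < tol) "symmetry" else "non-neutral"
}

#' Weak-selection value of information
#'
#' As selection vanishes, the invariant distribution of the rare-mutation
#' process is uniform over the strategy set regardless of payoffs, so the
#' evolved cooperation rate reduces to the uniform average of self-play
#' cooperation rates. The weak-selection value of information is therefore
#' computed exactly at `beta = 0` as
#' \deqn{V_0(q) = \frac{1}{256}\sum_{p \in P_F} \gamma(p, p)
#'             - \frac{1}{16}\sum_{p \in P_N} \gamma(p, p),}
#' taken in the rare-error limit (polynomial extrapolation of the averages over
#' a decreasing error-rate sequence). Set `eps_seq` to a single positive value
#' to evaluate at a fixed error rate instead.
#'
#' @param q a [transition_vector()].
#' @param params a [game_parameters()] object (payoff parameters are
#'   irrelevant at `beta = 0`; only kept for interface symmetry).
#' @param eps_seq error rates used for the rare-error limit; a single value
#'   disables extrapolation.
#' @returns The value of information at `beta = 0`, with attribute
#'   `"extrapolation_error"`. The doubly-absorbing vector `(1,1,1;0,0,0)` is
#'   neutral by the absorbing-state argument and returns exactly 0.
#' @export
weak_selection_value <- function(q, params = game_parameters(),
                                 eps_seq = default_eps_sequence()) {
  q <- transition_vector(q)
  qq <- unclass(q)
  if (all(qq[1:3] == 1) && all(qq[4:6] == 0)) {
    return(structure(0, extrapolation_error = 0))
  }
  PF <- strategy_set("full")
  PN <- strategy_set("none")
  one_eps <- function(e) {
    gF <- mean(cpp_selfplay((1 - e) * PF + e * (1 - PF), qq,
                            params$b1, params$b2, params$c)[, 2])
    gN <- mean(cpp_selfplay((1 - e) * PN + e * (1 - PN), qq,
                            params$b1, params$b2, params$c)[, 2])
    gF - gN
  }
  vals <- vapply(eps_seq, one_eps, numeric(1))
  if (length(eps_seq) == 1L) return(structure(vals, extrapolation_error = NA_real_))
  ex <- extrapolate_to_zero(vals, eps_seq)
  structure(ex$estimate, extrapolation_error = ex$error)
}

#' Classify all deterministic games
#'
#' One row per deterministic transition vector with the proxy variable `X`,
#' the neutrality class, the weak-selection value of information `V0`, the
#' symmetry-class representative, and (optionally) the value of information at
#' each requested positive selection strength.
#'
#' @param params a [game_parameters()] object.
#' @param beta_list selection strengths at which to additionally compute the
#'   full invariant-distribution value of information (columns `V_beta_<b>`);
#'   `NULL` (the default) computes the weak-selection analysis only.
#' @param popparams a [population_parameters()] object used for the
#'   `beta_list` computations.
#' @param tol neutrality tolerance on `V0`.
#' @returns A tibble with 64 rows, plus summary counts in attribute
#'   `"summary"` (neutral subclasses and the benefit-of-information /
#'   benefit-of-ignorance split).
#' @export
classify_deterministic_games <- function(params = game_parameters(),
                                         beta_list = NULL,
                                         popparams = population_parameters(),
                                         tol = 1e-6) {
  det <- enumerate_deterministic_q()
  reps <- symmetry_classes()
  n <- nrow(det)
  V0 <- numeric(n)
  X <- integer(n)
  for (i in seq_len(n)) {
    qi <- transition_vector(det$q[i])
    X[i] <- proxy_X(qi)
    V0[i] <- weak_selection_value(qi, params)
  }
  cls <- character(n)
  for (i in seq_len(n)) {
    cls[i] <- neutrality_class(transition_vector(det$q[i]), V0 = V0[i], tol = tol)
  }
  out <- det |>
    dplyr::mutate(X = X, class = cls, V0 = V0,
                  class_representative = reps$class_representative)
  if (!is.null(beta_list)) {
    for (b in beta_list) {
      pp <- population_parameters(N = popparams$N, beta = b, mu = popparams$mu)
      vb <- vapply(out$q, function(s) {
        as.numeric(value_of_information(transition_vector(s), params, pp))
      }, numeric(1))
      out[[paste0("V_beta_", b)]] <- unname(vb)
    }
  }
  summary <- list(
    n_absorbing = sum(out$class == "absorbing"),
    n_state_independent = sum(out$class == "state-independent"),
    n_symmetry = sum(out$class == "symmetry"),
    n_benefit_information = sum(out$class == "non-neutral" & out$V0 > 0),
    n_benefit_ignorance = sum(out$class == "non-neutral" & out$V0 < 0)
  )
  attr(out, "summary") <- summary
  out
}

#' Scan the single-stochastic transition-vector families
#'
#' Enumerates the 192 families (six possible positions for the one stochastic
#' entry, times 32 deterministic completions) and flags the 24 neutral ones
#' (those with an absorbing state). With `grid` supplied, evaluates the value
#' of information across the grid for each non-neutral family at each
#' requested selection strength (`beta = 0` uses the exact uniform-average
#' weak-selection computation).
#'
#' @param grid values in `(0, 1)` for the stochastic entry, or `NULL` to only
#'   enumerate and flag.
#' @param params a [game_parameters()] object.
#' @param beta_list selection strengths; 0 means weak selection.
#' @param popparams a [population_parameters()] object for positive `beta`.
#' @param families optional subset (row indices into the family table) to
#'   evaluate.
#' @returns Without `grid`: the 192-row family table. With `grid`: a long
#'   tibble with one row per (family, grid value, beta) and column `V`.
#' @export
scan_single_stochastic <- function(grid = NULL, params = game_parameters(),
                                   beta_list = 0,
                                   popparams = population_parameters(),
                                   families = NULL) {
  fam <- enumerate_single_stochastic_families()
  if (is.null(grid)) return(fam)
  assert_probability(grid, "grid", open_left = TRUE, open_right = TRUE)
  idx <- families %||% seq_len(nrow(fam))
  rows <- list()
  k <- 0L
  for (i in idx) {
    for (g in grid) {
      qi <- family_at(fam[i, ], g)
      for (b in beta_list) {
        k <- k + 1L
        V <- if (fam$absorbing[i]) {
          0
        } else if (b == 0) {
          as.numeric(weak_selection_value(qi, params))
        } else {
          pp <- population_parameters(N = popparams$N, beta = b, mu = popparams$mu)
          as.numeric(value_of_information(qi, params, pp))
        }
        rows[[k]] <- tibble::tibble(family = fam$family[i], position = fam$position[i],
                                    q_value = g, beta = b, V = V,
                                    absorbing = fam$absorbing[i])
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Scan the full grid of transition vectors
#'
#' Enumerates all transition vectors whose six entries are taken from
#' `grid_values` (the canonical grid `{0, 0.2, 0.4, 0.6, 0.8, 1}` gives
#' `6^6 = 46656` vectors). Evaluation of the value of information is expensive,
#' so by default only a random subsample of `subsample` vectors is evaluated
#' (with a recorded seed); `subsample = Inf` evaluates everything.
#'
#' @param grid_values entries allowed in each position.
#' @param params a [game_parameters()] object.
#' @param beta selection strength (0 for the weak-selection uniform average).
#' @param subsample number of vectors to evaluate (`0` = enumerate only).
#' @param seed RNG seed for the subsample, recorded in the output.
#' @param popparams a [population_parameters()] object for positive `beta`.
#' @returns A tibble of evaluated vectors with columns `q`, `V`, `absorbing`;
#'   attributes `n_total` (enumeration size) and `seed`.
#' @export
scan_full_grid <- function(grid_values = c(0, 0.2, 0.4, 0.6, 0.8, 1),
                           params = game_parameters(), beta = 0,
                           subsample = 0, seed = 1,
                           popparams = population_parameters()) {
  assert_probability(grid_values, "grid_values")
  m <- length(grid_values)
  n_total <- m^6
  out <- tibble::tibble(q = character(0), V = numeric(0), absorbing = logical(0))
  if (subsample > 0) {
    set.seed(seed)
    take <- if (is.finite(subsample) && subsample < n_total) {
      sample.int(n_total, subsample)
    } else seq_len(n_total)
    rows <- vector("list", length(take))
    for (t in seq_along(take)) {
      # mixed-radix decoding of the vector index (first entry most significant)
      k <- take[t] - 1L
      digits <- integer(6)
      for (d in 6:1) { digits[d] <- k %% m; k <- k %/% m }
      qi <- transition_vector(grid_values[digits + 1])
      V <- if (has_absorbing_state(qi)) {
        0
      } else if (beta == 0) {
        as.numeric(weak_selection_value(qi, params))
      } else {
        pp <- population_parameters(N = popparams$N, beta = beta, mu = popparams$mu)
        as.numeric(value_of_information(qi, params, pp))
      }
      rows[[t]] <- tibble::tibble(q = format_transition_vector(qi), V = V,
                                  absorbing = has_absorbing_state(qi))
    }
    out <- dplyr::bind_rows(rows)
  }
  attr(out, "n_total") <- n_total
  attr(out, "seed") <- seed
  out
}
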