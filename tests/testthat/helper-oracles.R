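# Independent oracles used across the test files. These deliberately avoid the
# package's own computational paths.

# reference R implementation of the outcome transition matrix, built from
# explicit loops over outcomes (used to cross-check the C++ kernel)
reference_transition_matrix <- function(p, pt, q) {
  qidx <- c(1, 2, 2, 3)
  M <- matrix(0, 8, 8)
  for (w in 1:8) {
    s <- if (w <= 4) 1 else 2
    ap <- (w - 1) %% 4
    a <- ap %/% 2
    at <- ap %% 2
    qv <- q[(s - 1) * 3 + qidx[ap + 1]]
    for (w2 in 1:8) {
      s2 <- if (w2 <= 4) 1 else 2
      ap2 <- (w2 - 1) %% 4
      x <- if (s2 == 1) qv else 1 - qv
      pf <- p[(s2 - 1) * 4 + a * 2 + at + 1]
      y <- if (ap2 %/% 2 == 0) pf else 1 - pf
      pc <- pt[(s2 - 1) * 4 + at * 2 + a + 1]
      yt <- if (ap2 %% 2 == 0) pc else 1 - pc
      M[w, w2] <- x * y * yt
    }
  }
  M
}

# brute-force stationary distribution by long power iteration
power_iteration_stationary <- function(M, iters = 200000) {
  v <- rep(1 / nrow(M), nrow(M))
  # squaring the matrix doubles the horizon per multiplication
  Mk <- M
  for (i in seq_len(ceiling(log2(iters)))) Mk <- Mk %*% Mk
  as.numeric(v %*% Mk)
}

# mixed-population payoffs by explicit enumeration of all agents
brute_force_mixed_payoffs <- function(pRR, pRM, pMR, pMM, N, k) {
  types <- c(rep("R", N - k), rep("M", k))
  pay <- function(a, b) {
    if (a == "R" && b == "R") pRR
    else if (a == "R" && b == "M") pRM
    else if (a == "M" && b == "R") pMR
    else pMM
  }
  agent_pay <- vapply(seq_len(N), function(i) {
    mean(vapply(setdiff(seq_len(N), i), function(j) pay(types[i], types[j]),
                numeric(1)))
  }, numeric(1))
  c(pi_R = mean(agent_pay[types == "R"]), pi_M = mean(agent_pay[types == "M"]))
}

# Monte-Carlo fixation probability of a single mutant under the pairwise
# comparison process. Simulates the embedded jump chain of the mutant count:
# conditional on a change, the count increases with the Fermi probability
# 1/(1 + exp(-beta * (pi_M(k) - pi_R(k)))) (the two Fermi factors sum to one).
mc_fixation <- function(pRR, pRM, pMR, pMM, N, beta, runs, seed) {
  set.seed(seed)
  kk <- seq_len(N - 1)
  piR <- ((N - kk - 1) * pRR + kk * pRM) / (N - 1)
  piM <- ((N - kk) * pMR + (kk - 1) * pMM) / (N - 1)
  p_up <- 1 / (1 + exp(-beta * (piM - piR)))
  fixed <- logical(runs)
  for (r in seq_len(runs)) {
    k <- 1L
    while (k > 0L && k < N) {
      k <- if (runif(1) < p_up[k]) k + 1L else k - 1L
    }
    fixed[r] <- k == N
  }
  mean(fixed)
}

# small helper fixtures
q_timeout <- function() transition_vector(1, 0, 0, 1, 1, 1)
q_conditional_return <- function() transition_vector(1, 0, 0, 1, 1, 0)
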