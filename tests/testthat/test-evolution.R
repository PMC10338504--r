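test_that("mixed-population payoffs match brute-force agent enumeration", {
  q <- q_timeout()
  params <- game_parameters()
  pop <- population_parameters(N = 5, beta = 1)
  pR <- strategy_wsls(); pM <- strategy_alld()
  gRR <- play_game(pR, pR, q, params)$payoff_focal
  g <- play_game(pR, pM, q, params)
  gMM <- play_game(pM, pM, q, params)$payoff_focal
  for (k in 1:4) {
    got <- mixed_population_payoffs(pR, pM, k, q, params, pop)
    want <- brute_force_mixed_payoffs(gRR, g$payoff_focal, g$payoff_coplayer, gMM, 5, k)
    expect_equal(got, want, tolerance = 1e-12)
  }
  # identical strategies earn identical payoffs at every mixture
  same <- mixed_population_payoffs(pR, pR, 2, q, params, pop)
  expect_equal(unname(same[1]), unname(same[2]), tolerance = 1e-12)
  expect_error(mixed_population_payoffs(pR, pM, 5, q, params, pop), "k")
})

test_that("fixation probability is 1/N at neutrality and matches the N = 2 formula", {
  q <- q_conditional_return()
  params <- game_parameters()
  pR <- strategy_wsls(); pM <- strategy_tft()
  rho0 <- fixation_probability(pR, pM, q, params, population_parameters(N = 37, beta = 0))
  expect_equal(rho0, 1 / 37, tolerance = 1e-15)
  pop2 <- population_parameters(N = 2, beta = 3)
  mp <- mixed_population_payoffs(pR, pM, 1, q, params, pop2)
  expect_equal(fixation_probability(pR, pM, q, params, pop2),
               1 / (1 + exp(-3 * (mp["pi_M"] - mp["pi_R"]))),
               tolerance = 1e-12, ignore_attr = TRUE)
  # log-domain evaluation survives extreme selection strengths
  rho_huge <- fixation_probability(strategy_alld(), strategy_allc(), q, params,
                                   population_parameters(N = 100, beta = 1e4))
  expect_true(is.finite(rho_huge) && rho_huge >= 0 && rho_huge < 1)
})

test_that("fixation probability agrees with Monte-Carlo simulation of the process", {
  q <- q_timeout()
  params <- game_parameters()
  N <- 10; beta <- 1; runs <- 20000
  pR <- strategy_wsls(); pM <- strategy_alld()
  gRR <- play_game(pR, pR, q, params)$payoff_focal
  g <- play_game(pR, pM, q, params)
  gMM <- play_game(pM, pM, q, params)$payoff_focal
  rho <- fixation_probability(pR, pM, q, params, population_parameters(N = N, beta = beta))
  est <- mc_fixation(gRR, g$payoff_focal, g$payoff_coplayer, gMM, N, beta,
                     runs = runs, seed = 11)
  se <- sqrt(rho * (1 - rho) / runs)
  expect_lt(abs(est - rho), 3 * se)
})

test_that("the batch fixation matrix reproduces the scalar computation", {
  q <- q_conditional_return()
  params <- game_parameters()
  pop <- population_parameters(N = 50, beta = 10)
  pm <- pair_matrices("none", q, params)
  rho <- stategames:::fixation_matrix(pm$pi, pop$N, pop$beta)
  for (pair in list(c(1, 10), c(10, 1), c(4, 16))) {
    i <- pair[1]; j <- pair[2]
    want <- fixation_probability(strategy_from_id(i - 1L, "none"),
                                 strategy_from_id(j - 1L, "none"),
                                 q, params, pop)
    expect_equal(rho[i, j], want, tolerance = 1e-12)
  }
  expect_true(all(is.na(diag(rho))))
})

test_that("embedded chain is row-stochastic with neutral off-diagonals at beta = 0", {
  q <- q_timeout()
  params <- game_parameters()
  ch <- embedded_chain("none", q, params, population_parameters(N = 20, beta = 0))
  expect_equal(unname(rowSums(ch$transition)), rep(1, 16), tolerance = 1e-12)
  off <- ch$transition[row(ch$transition) != col(ch$transition)]
  expect_equal(off, rep(1 / (20 * 16), length(off)), tolerance = 1e-15)
  w <- invariant_distribution(ch$transition)
  expect_equal(w, rep(1 / 16, 16), tolerance = 1e-12)
})

test_that("pair matrices are deterministic and reproducible", {
  q <- q_conditional_return()
  params <- game_parameters()
  a <- pair_matrices("none", q, params)
  b <- pair_matrices("none", q, params)
  expect_identical(a$pi, b$pi)
  expect_identical(a$gamma, b$gamma)
  expect_equal(a$gamma, t(a$gamma), tolerance = 0)  # cooperation is pair-symmetric
})

test_that("evolved populations expose tidy/glance summaries consistent with the weights", {
  q <- q_conditional_return()
  ev <- evolve_population("none", q, game_parameters(),
                          population_parameters(N = 50, beta = 10))
  expect_s3_class(ev, "evolved_population")
  expect_equal(sum(ev$weights), 1, tolerance = 1e-10)
  td <- tidy(ev)
  expect_equal(nrow(td), 16)
  expect_equal(sum(td$weight), 1, tolerance = 1e-10)
  expect_equal(ev$gamma_hat, sum(td$weight * td$cooperation), tolerance = 1e-12)
  gl <- glance(ev)
  expect_equal(gl$gamma_hat, ev$gamma_hat)
  expect_equal(gl$n_strategies, 16)
  # WSLS dominates the no-information conditional-return game
  expect_equal(td$strategy[1], "(1,0,0,1)")
  # ensemble averages recompute the same numbers from the weights
  ea <- ensemble_averages(ev$weights, "none", q, game_parameters())
  expect_equal(unname(ea["gamma_hat"]), ev$gamma_hat, tolerance = 1e-12)
})

test_that("value of information is the antisymmetric difference of the two settings", {
  q <- q_conditional_return()
  params <- game_parameters()
  pop <- population_parameters(N = 30, beta = 1)
  V <- value_of_information(q, params, pop)
  gF <- attr(V, "gamma_full"); gN <- attr(V, "gamma_none")
  expect_equal(as.numeric(V), gF - gN, tolerance = 1e-15)
  # swapping which set is called "full" flips the sign
  expect_equal(as.numeric(V), -(gN - gF), tolerance = 1e-15)
})

test_that("trajectories are reproducible, inert without mutation, and ergodic", {
  q <- q_conditional_return()
  params <- game_parameters()
  pop <- population_parameters(N = 20, beta = 1, mu = 1)
  t1 <- simulate_trajectory("none", q, params, pop, steps = 500, seed = 3)
  t2 <- simulate_trajectory("none", q, params, pop, steps = 500, seed = 3)
  expect_identical(t1, t2)
  no_mut <- simulate_trajectory("none", q, params,
                                population_parameters(N = 20, beta = 1, mu = 0),
                                steps = 200, seed = 5)
  expect_true(all(no_mut$strategy_id == 0))  # resident stays at always-defect
  # long-run time averages approach the invariant-distribution average within
  # Monte-Carlo error (batch-mean standard error over 20 batches)
  steps <- 60000
  tr <- simulate_trajectory("none", q, params, pop, steps = steps, seed = 9)
  ev <- evolve_population("none", q, params, pop)
  batches <- matrix(tr$cooperation, ncol = 20)
  bm <- colMeans(batches)
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(mean(tr$cooperation) - ev$gamma_hat), 3 * se)
})

test_that("invasion graphs label edges consistently with the stored fixation probabilities", {
  q <- q_conditional_return()
  params <- game_parameters()
  pop <- population_parameters(N = 100, beta = 10)
  ig <- invasion_graph("none", q, params, pop)
  expect_s3_class(ig, "invasion_graph")
  N <- pop$N
  ev <- evolve_population("none", q, params, pop)
  for (r in seq_len(nrow(ig$edges))) {
    e <- ig$edges[r, ]
    rho <- ev$rho[e$from + 1L, e$to + 1L]
    expect_equal(e$rho, rho, tolerance = 1e-15)
    expect_equal(e$type, if (rho > 1 / N) "solid" else "dotted")
  }
  # WSLS is flagged fully self-cooperative here
  wsls_row <- ig$nodes[ig$nodes$strategy_id == 9, ]
  expect_true(wsls_row$self_cooperative)
  # at beta = 0 every fixation probability ties at 1/N: no edges at all
  ig0 <- invasion_graph("none", q, params, population_parameters(N = 100, beta = 0))
  expect_equal(nrow(ig0$edges), 0)
})
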