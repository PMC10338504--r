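test_that("transition matrix matches the reference implementation and is row-stochastic", {
  set.seed(42)
  for (rep in 1:10) {
    p <- runif(8); pt <- runif(8); q <- runif(6)
    M <- build_transition_matrix(p, pt, q)
    expect_equal(unname(M), reference_transition_matrix(p, pt, q), tolerance = 1e-14)
    expect_equal(unname(rowSums(M)), rep(1, 8), tolerance = 1e-12)
  }
})

test_that("deterministic inputs give indicator rows and the documented defection cycle", {
  alld <- embed_no_info(strategy_alld())
  M <- build_transition_matrix(alld, alld, q_timeout())
  expect_true(all(apply(M, 1, function(r) sum(r == 1) == 1 && sum(r) == 1)))
  # mutual defection shuttles between the two states
  expect_equal(M["s1_DD", "s2_DD"], 1)
  expect_equal(M["s2_DD", "s1_DD"], 1)
})

test_that("stationary distribution agrees with power iteration on random instances", {
  set.seed(7)
  for (rep in 1:8) {
    p <- runif(8); pt <- runif(8); q <- runif(6)
    M <- build_transition_matrix(p, pt, q, epsilon = 0.01)
    v <- stationary_distribution(M)
    expect_equal(sum(v), 1, tolerance = 1e-12)
    expect_true(all(v >= 0))
    expect_equal(as.numeric(v), power_iteration_stationary(M), tolerance = 1e-10)
    expect_equal(as.numeric(v %*% M), as.numeric(v), tolerance = 1e-12)
  }
})

test_that("the reducible doubly-absorbing case is rejected with guidance", {
  alld <- embed_no_info(strategy_alld())
  M <- build_transition_matrix(alld, alld, transition_vector("(1,1,1;0,0,0)"),
                               epsilon = 0.01)
  expect_error(stationary_distribution(M), "discounted_occupancy")
})

test_that("rare-error limits reproduce hand-derived absorbing outcomes", {
  wsls <- strategy_wsls()
  alld <- strategy_alld()
  # mutual WSLS in the timeout game locks into cooperation in state 1
  v <- limit_stationary_distribution(wsls, wsls, q_timeout())
  expect_equal(as.numeric(v), c(1, rep(0, 7)), tolerance = 1e-9)
  # mutual defection shuttles: half weight on each (si, D, D)
  v <- limit_stationary_distribution(alld, alld, q_timeout())
  expect_equal(as.numeric(v), c(0, 0, 0, .5, 0, 0, 0, .5), tolerance = 1e-9)
  # continuity: each limit is within O(eps) of a small-eps evaluation
  v_wsls <- limit_stationary_distribution(wsls, wsls, q_timeout())
  v_eps <- pair_stationary(wsls, wsls, q_timeout(), 1e-3)
  expect_lt(max(abs(as.numeric(v_wsls) - as.numeric(v_eps))), 5e-2)
  v_alld_eps <- pair_stationary(alld, alld, q_timeout(), 1e-3)
  expect_lt(max(abs(as.numeric(v) - as.numeric(v_alld_eps))), 5e-2)
})

test_that("discounted occupancy matches its series definition and Abel limit", {
  p <- memory_one_strategy(c(1, 0, 0, 1), "none")
  pt <- memory_one_strategy(c(1, 1, 0, 0), "none")
  q <- transition_vector("(1,0,0;0.4,0.2,0)")
  eps <- 0.01
  M <- build_transition_matrix(p, pt, q, eps)
  v0 <- initial_distribution(p, pt, q, eps)
  expect_equal(sum(v0), 1, tolerance = 1e-12)
  expect_true(all(as.numeric(v0)[5:8] == 0))  # supported on initial state 1
  # series oracle: v = (1-delta) sum_t v0 (delta M)^t
  delta <- 0.8
  v <- discounted_occupancy(M, v0, delta)
  series <- Reduce(`+`, Reduce(function(acc, t) acc %*% (delta * M),
                               seq_len(300), init = matrix(as.numeric(v0), 1),
                               accumulate = TRUE))
  expect_equal(as.numeric(v), (1 - delta) * as.numeric(series), tolerance = 1e-12)
  expect_equal(sum(v), 1, tolerance = 1e-10)
  # delta -> 0 returns the first round; delta -> 1 approaches the stationary law
  expect_equal(as.numeric(discounted_occupancy(M, v0, 1e-9)), as.numeric(v0),
               tolerance = 1e-7)
  expect_lt(max(abs(as.numeric(discounted_occupancy(M, v0, 0.999)) -
                      as.numeric(stationary_distribution(M)))), 0.05)
  expect_error(discounted_occupancy(M, v0, 1), "stationary_distribution")
})

test_that("payoff and cooperation functionals evaluate their defining formulas", {
  params <- game_parameters()
  unit <- function(i) { v <- numeric(8); v[i] <- 1; v }
  expect_equal(payoff(unit(1), params), 0.8)       # b1 - c at mutual cooperation in s1
  expect_equal(payoff(unit(8), params), 0)         # mutual defection earns nothing
  expect_equal(payoff(unit(3), params), 1.8)       # focal defects, co-player cooperates
  expect_equal(coplayer_payoff(unit(3), params), -1)
  expect_equal(cooperation_rate(unit(1)), 1)
  expect_equal(cooperation_rate(unit(8)), 0)
  expect_equal(cooperation_rate(rep(1 / 8, 8)), 0.5)
})

test_that("pair evaluation is player-symmetric and embedding-consistent", {
  q <- transition_vector("(1,0,0;0.6,0.3,0)")
  params <- game_parameters()
  p4 <- memory_one_strategy(c(1, 0, 0, 1), "none")
  pt4 <- memory_one_strategy(c(0, 0, 1, 1), "none")
  a <- play_game(p4, pt4, q, params)
  b <- play_game(pt4, p4, q, params)
  expect_equal(a$cooperation, b$cooperation, tolerance = 1e-12)
  expect_equal(a$payoff_focal, b$payoff_coplayer, tolerance = 1e-12)
  expect_equal(a$payoff_coplayer, b$payoff_focal, tolerance = 1e-12)
  # a 4-entry strategy and its 8-entry embedding are interchangeable
  c8 <- play_game(embed_no_info(p4), embed_no_info(pt4), q, params)
  expect_equal(a$payoff_focal, c8$payoff_focal, tolerance = 1e-14)
  expect_equal(a$cooperation, c8$cooperation, tolerance = 1e-14)
})

test_that("spec example: defectors against WSLS in the timeout game", {
  # the rare-error limit mixes the two deterministic cycles 4/7 : 3/7, so the
  # defector earns (4 b1 + 3 b2) / 14 against WSLS while WSLS-vs-WSLS earns
  # b1 - c; the binding deviation (0,0,0,1) earns (2 b1 - c) / 3
  params <- game_parameters()
  v <- limit_stationary_distribution(strategy_alld(), strategy_wsls(), q_timeout())
  expect_equal(payoff(v, params), (4 * 1.8 + 3 * 1.3) / 14, tolerance = 1e-9)
  v2 <- limit_stationary_distribution(memory_one_strategy(c(0, 0, 0, 1), "none"),
                                      strategy_wsls(), q_timeout())
  expect_equal(payoff(v2, params), (2 * 1.8 - 1) / 3, tolerance = 1e-9)
})
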