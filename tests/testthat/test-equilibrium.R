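test_that("WSLS is Nash in the timeout game exactly when b1 exceeds twice the cost", {
  wsls <- strategy_wsls()
  r_low <- is_nash(wsls, q_timeout(), game_parameters(b1 = 1.8))
  expect_false(r_low$is_nash)
  # the binding deviation cooperates only after mutual defection
  expect_equal(r_low$best_deviation, "(0,0,0,1;0,0,0,1)")
  expect_equal(r_low$payoff_gap, (2 * 1.8 - 1) / 3 - 0.8, tolerance = 1e-8)
  r_high <- is_nash(wsls, q_timeout(), game_parameters(b1 = 2.5))
  expect_true(r_high$is_nash)
})

test_that("always-defect is Nash against itself", {
  r <- is_nash(strategy_alld(), q_timeout())
  expect_true(r$is_nash)
  r2 <- is_nash(strategy_alld(), q_conditional_return(),
                deviation_setting = "full")
  expect_true(r2$is_nash)
})

test_that("subgame perfection of the state-aware WSLS variant holds for both arbitrary bits", {
  # resident (1,0,0,0; x,0,0,1) with x in {0, 1}: subgame perfect at the
  # defaults because 2 b1 - b2 = 2.3 >= 2c
  for (x in c(0, 1)) {
    pf <- memory_one_strategy(c(1, 0, 0, 0, x, 0, 0, 1), "full")
    r <- is_subgame_perfect(pf, q_timeout())
    expect_true(r$is_subgame_perfect)
    expect_true(r$is_nash)
    # and fails when b1 is lowered so that 2 b1 - b2 < 2c
    r_low <- is_subgame_perfect(pf, q_timeout(), game_parameters(b1 = 1.5))
    expect_false(r_low$is_subgame_perfect)
    expect_gt(r_low$payoff_gap, 0)
  }
  # plain WSLS is subgame perfect in the conditional-return game at defaults
  r_wsls <- is_subgame_perfect(embed_no_info(strategy_wsls()), q_conditional_return())
  expect_true(r_wsls$is_subgame_perfect)
})

test_that("subgame perfection implies Nash on the tested instances", {
  cases <- list(
    list(p = memory_one_strategy(c(1, 0, 0, 0, 0, 0, 0, 1), "full"), q = q_timeout()),
    list(p = embed_no_info(strategy_wsls()), q = q_conditional_return()),
    list(p = embed_no_info(strategy_alld()), q = q_timeout())
  )
  for (cs in cases) {
    r <- is_subgame_perfect(cs$p, cs$q)
    if (r$is_subgame_perfect) expect_true(r$is_nash)
  }
})

test_that("the dynamic program upper-bounds every enumerated memory-one deviation", {
  params <- game_parameters()
  for (qv in list(q_timeout(), q_conditional_return())) {
    resident <- strategy_wsls()
    mdp <- stategames:::deviator_mdp(resident, qv, params)
    pol <- stategames:::mdp_optimal(mdp, 0.9999)$policy
    gain <- max(0.0001 * stategames:::mdp_policy_value(mdp, pol, 0.9999))
    P <- strategy_set("none")
    dev_pay <- vapply(seq_len(nrow(P)), function(i) {
      payoff(limit_stationary_distribution(P[i, ], embed_no_info(resident), qv), params)
    }, numeric(1))
    expect_true(all(dev_pay <= gain + 1e-3))
  }
})

test_that("bisection recovers the printed equilibrium thresholds", {
  wsls <- strategy_wsls()
  th_nash <- critical_threshold(wsls, q_timeout(), vary = "b1",
                                bracket = c(1.3, 3), predicate = "nash")
  expect_equal(as.numeric(th_nash), 2, tolerance = 1e-3)
  for (x in c(0, 1)) {
    pf <- memory_one_strategy(c(1, 0, 0, 0, x, 0, 0, 1), "full")
    th <- critical_threshold(pf, q_timeout(), vary = "b1",
                             bracket = c(1.3, 3), predicate = "subgame_perfect")
    expect_equal(2 * as.numeric(th) - 1.3, 2, tolerance = 1e-3)
  }
  # a bracket with no predicate change is an error
  expect_error(critical_threshold(wsls, q_timeout(), vary = "b1",
                                  bracket = c(2.2, 3), predicate = "nash"),
               "does not change")
})
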