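test_that("the proxy variable evaluates its indicator formula", {
  expect_equal(proxy_X(q_timeout()), 1L)
  expect_equal(proxy_X(q_conditional_return()), 0L)
  # maximal case: cooperation locks state 1, defection locks neither
  expect_equal(proxy_X(transition_vector(1, 0, 0, 0, 0, 1)), 2L)
  expect_equal(proxy_X(transition_vector(0, 0, 1, 1, 0, 0)), -2L)
})

test_that("neutrality classes follow the documented rules", {
  expect_equal(neutrality_class(transition_vector("(1,1,1;1,1,1)")), "absorbing")
  expect_equal(neutrality_class(transition_vector("(1,0,1;0,0,0)")), "absorbing")
  expect_equal(neutrality_class(transition_vector("(1,0,0;1,0,0)")), "state-independent")
  # the conditional-return game is neutral only under weak selection
  expect_equal(neutrality_class(q_conditional_return()), "symmetry")
  expect_equal(neutrality_class(q_timeout()), "non-neutral")
})

test_that("weak-selection value matches the printed closed form for the recovery family", {
  # V0(q) = -3q(1-q) / (64(1+q)) for the family (1,0,0;q,0,0)
  for (qq in c(0.2, 0.5, 0.8)) {
    V <- weak_selection_value(family_at("(1,0,0;q,0,0)", qq))
    expect_equal(as.numeric(V), -3 * qq * (1 - qq) / (64 * (1 + qq)), tolerance = 1e-8)
  }
  # the family's deterministic endpoints are neutral
  expect_lt(abs(weak_selection_value(transition_vector("(1,0,0;0,0,0)"))), 1e-8)
  expect_lt(abs(weak_selection_value(transition_vector("(1,0,0;1,0,0)"))), 1e-8)
  # absorbing games are neutral, including the doubly-absorbing special case
  expect_lt(abs(weak_selection_value(transition_vector("(1,1,1;0,1,0)"))), 1e-8)
  expect_identical(as.numeric(weak_selection_value(transition_vector("(1,1,1;0,0,0)"))), 0)
})

test_that("a fixed-error evaluation is available and differs from the limit by O(eps)", {
  q <- family_at("(1,0,0;q,0,0)", 0.5)
  v_lim <- as.numeric(weak_selection_value(q))
  v_fix <- as.numeric(weak_selection_value(q, eps_seq = 0.01))
  expect_false(isTRUE(all.equal(v_lim, v_fix, tolerance = 1e-6)))
  expect_equal(v_lim, v_fix, tolerance = 0.2)
})

test_that("the weak-selection table is antisymmetric under the action relabeling", {
  cl <- classify_deterministic_games()
  v0 <- setNames(cl$V0, cl$q)
  nn <- cl[cl$class == "non-neutral", ]
  for (r in seq_len(nrow(nn))) {
    swapped <- format_transition_vector(action_swap(transition_vector(nn$q[r])))
    expect_lt(abs(v0[[swapped]] + nn$V0[r]), 1e-7)
  }
  # hence the multiset of values is symmetric about zero
  expect_lt(max(abs(sort(cl$V0) + rev(sort(cl$V0)))), 1e-7)
})

test_that("single-stochastic scans flag absorbing families and report V on a grid", {
  fam <- scan_single_stochastic()
  expect_equal(nrow(fam), 192)
  expect_equal(sum(fam$absorbing), 24)
  idx <- which(fam$family == "(1,0,0;q,0,0)")
  sc <- scan_single_stochastic(grid = c(0.25, 0.75), beta_list = 0, families = idx)
  expect_equal(nrow(sc), 2)
  expect_true(all(sc$V < 0))  # benefit of ignorance across the family interior
  # an absorbing family reports exactly zero without computation
  ab <- which(fam$absorbing)[1]
  sc0 <- scan_single_stochastic(grid = 0.5, beta_list = 0, families = ab)
  expect_identical(sc0$V, 0)
})

test_that("full-grid scans enumerate 6^6 vectors and subsample reproducibly", {
  g <- scan_full_grid(subsample = 0)
  expect_equal(attr(g, "n_total"), 46656)
  expect_equal(nrow(g), 0)
  s1 <- scan_full_grid(grid_values = c(0, 0.5, 1), subsample = 5, seed = 4)
  s2 <- scan_full_grid(grid_values = c(0, 0.5, 1), subsample = 5, seed = 4)
  expect_identical(s1$q, s2$q)
  expect_equal(attr(s1, "n_total"), 729)
  expect_true(all(abs(s1$V[s1$absorbing]) == 0))
})
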