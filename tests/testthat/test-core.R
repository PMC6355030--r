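test_that("history replay applies depression and recovery step by step", {
  # quiescent history is a fixed point of the recovery update
  expect_equal(release_prob_from_history(rep(0, 7), 0.7, 0.7, 0.5, 0.1), 0.7)
  # hand-traced two-step histories
  expect_equal(release_prob_from_history(c(0, 1), 0.7, 0.7, 0.5, 0.1), 0.35)
  expect_equal(release_prob_from_history(c(1, 0), 0.7, 0.7, 0.5, 0.1), 0.385)
  # empty history returns the seed
  expect_equal(release_prob_from_history(integer(0), 0.3, 0.7, 0.5, 0.1), 0.3)
  expect_error(release_prob_from_history(c(0, 2), 0.7, 0.7, 0.5, 0.1),
               "0 or 1")
})

test_that("state table matches hand-traced values and the replay oracle", {
  p <- synapse_params(alpha = 0.3, p0 = 0.7, q0 = 0.1, c_sync = 0.5,
                      d_async = 0.5, e_sync = 0.1, f_async = 0.1, L = 2)
  tab <- build_state_table(p)
  expect_equal(tab$p, c(0.7, 0.35, 0.385, 0.175))
  # defaults at the all-quiescent state
  expect_equal(tab$p[1], p$p0)
  expect_equal(tab$q[1], p$q0)
  # r is a convex combination of p and q
  expect_true(all(tab$r >= pmin(tab$p, tab$q) - 1e-15 &
                  tab$r <= pmax(tab$p, tab$q) + 1e-15))
  # vectorized recursion agrees with literal history replay for random sets
  set.seed(41)
  for (i in 1:5) {
    rp <- random_params(L = sample(1:6, 1))
    tab <- build_state_table(rp)
    expect_equal(tab$p, oracle_mode_table(rp$p0, rp$c, rp$e, rp$L),
                 tolerance = 1e-14)
    expect_equal(tab$q, oracle_mode_table(rp$q0, rp$d, rp$f, rp$L),
                 tolerance = 1e-14)
  }
})

test_that("undepressed modes leave the table at its defaults", {
  p <- synapse_params(alpha = 0.2, p0 = 0.6, q0 = 0.05, c_sync = 1,
                      d_async = 1, e_sync = 0.3, f_async = 0.02, L = 6)
  tab <- build_state_table(p)
  expect_equal(tab$p, rep(0.6, 64))
  expect_equal(tab$q, rep(0.05, 64))
})

test_that("adding a release to a history never raises release probabilities", {
  set.seed(42)
  for (i in 1:5) {
    rp <- random_params(L = 6)
    tab <- build_state_table(rp)
    for (j in seq_len(2^rp$L) - 1L) {
      for (k in seq_len(rp$L) - 1L) {
        if (bitwAnd(j %/% 2^k, 1L) == 0L) {
          j_more <- j + 2^k  # same history with one extra release
          expect_lte(tab$p[j_more + 1L], tab$p[j + 1L] + 1e-14)
          expect_lte(tab$q[j_more + 1L], tab$q[j + 1L] + 1e-14)
        }
      }
    }
  }
})

test_that("memory-size guard refuses oversized state spaces", {
  p <- example_params(L = 12)
  expect_error(build_state_table(p, max_L = 10), "max_L")
})

test_that("transition chain has the two-successor shift structure", {
  p <- example_params(L = 2)
  ch <- build_transition_chain(build_state_table(p))
  # state 3 (history 11) moves to {3, 2}
  expect_identical(ch$succ_release[4], 3L)
  expect_identical(ch$succ_quiet[4], 2L)
  for (L in c(1, 3, 5)) {
    pl <- example_params(L = L)
    ch <- build_transition_chain(build_state_table(pl))
    # release successor is odd and adjacent to the quiescent successor
    expect_true(all(ch$succ_release %% 2L == 1L))
    expect_identical(ch$succ_release, ch$succ_quiet + 1L)
    expect_true(all(ch$succ_release < 2^L))
  }
})

test_that("stationary distribution solves small chains exactly", {
  # L = 1 with distinct state release probabilities: two-state balance gives
  # pi_1 = r(0) / (1 + r(0) - r(1)); with r = (0.2, 0.1), pi_1 = 0.2 / 1.1
  ch <- structure(list(succ_release = c(1L, 1L), succ_quiet = c(0L, 0L),
                       r = c(0.2, 0.1), L = 1L), class = "mro_chain")
  st <- stationary_distribution(ch)
  expect_equal(st$pi[2], 0.2 / 1.1, tolerance = 1e-10)
  expect_equal(sum(st$pi), 1, tolerance = 1e-12)

  # without depression outcomes are i.i.d.: mass on odd states equals r
  p <- synapse_params(alpha = 0.3, p0 = 0.7, q0 = 0.1, c_sync = 1,
                      d_async = 1, e_sync = 0.1, f_async = 0.1, L = 5)
  tab <- build_state_table(p)
  st <- stationary_distribution(build_transition_chain(tab))
  r0 <- (1 - p$alpha) * p$q0 + p$alpha * p$p0
  expect_equal(sum(st$pi[seq(2, 32, by = 2)]), r0, tolerance = 1e-10)
})

test_that("power iteration matches a dense linear solve on random chains", {
  set.seed(7)
  for (i in 1:8) {
    rp <- random_params(L = sample(2:9, 1))
    tab <- build_state_table(rp)
    st <- stationary_distribution(build_transition_chain(tab))
    pi_dense <- oracle_stationary(oracle_transition_matrix(tab$r, rp$L))
    expect_equal(st$pi, pi_dense, tolerance = 1e-8)
    expect_true(all(st$pi >= 0))
    expect_equal(sum(st$pi), 1, tolerance = 1e-12)
  }
})

test_that("iteration cap is reported as an error with the residual", {
  p <- example_params(L = 8)
  ch <- build_transition_chain(build_state_table(p))
  expect_error(stationary_distribution(ch, tol = 1e-12, max_iter = 3),
               "residual")
})
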