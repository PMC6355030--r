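test_that("identical seeds reproduce traces bit for bit", {
  p <- example_params(L = 6)
  t1 <- simulate_release_site(p, 5000, seed = 99)
  t2 <- simulate_release_site(p, 5000, seed = 99)
  expect_identical(t1$X, t2$X)
  expect_identical(t1$Y, t2$Y)
  expect_identical(t1$p_t, t2$p_t)
  t3 <- simulate_release_site(p, 5000, seed = 100)
  expect_false(identical(t1$Y, t3$Y))
  df <- as.data.frame(t1)
  expect_named(df, c("t_ms", "X", "Y", "p_t", "q_t"))
  expect_equal(nrow(df), 5000)
})

test_that("without depression the empirical release rate is the i.i.d. rate", {
  p <- synapse_params(alpha = 0.3, p0 = 0.7, q0 = 0.1, c_sync = 1,
                      d_async = 1, e_sync = 0.1, f_async = 0.1, L = 4)
  n <- 2e5
  tr <- simulate_release_site(p, n, seed = 5)
  rate <- (1 - p$alpha) * p$q0 + p$alpha * p$p0
  se <- sqrt(rate * (1 - rate) / n)
  expect_lt(abs(mean(tr$Y) - rate), 3 * se)
})

test_that("simulated occupancies converge to the stationary distribution", {
  # fast-forgetting dynamics so that truncating the analytic chain at
  # L = 14 leaves a bias far below the Monte-Carlo standard error
  p <- synapse_params(alpha = 0.3, p0 = 0.6, q0 = 0.1, c_sync = 0.3,
                      d_async = 0.3, e_sync = 0.3, f_async = 0.3, L = 14)
  m <- mro(p)
  n <- 4e5
  tr <- simulate_release_site(p, n, seed = 17)
  # release rate against the odd-state stationary mass
  rel <- m$rates$release_rate_per_step
  expect_lt(abs(mean(tr$Y) - rel), 3 * sqrt(rel * (1 - rel) / n))
  # occupancies of the last 6 outcomes against the marginal of pi
  Lw <- 6L
  occ <- empirical_state_occupancy(tr, Lw)
  expect_equal(sum(occ), 1, tolerance = 1e-12)
  j <- seq_along(m$stationary$pi) - 1L
  marg <- as.numeric(rowsum(m$stationary$pi, j %% 2^Lw))
  tv <- 0.5 * sum(abs(occ - marg))
  expect_lt(tv, 0.01)
})

test_that("state encoding of traces follows the bit convention", {
  # constant-release trace occupies only the all-ones state
  occ <- empirical_state_occupancy(rep(1L, 100), L = 3)
  expect_equal(occ, c(rep(0, 7), 1))
  # a known short pattern: Y = (1,0,0,1) then window (1,0,0) -> j = 4,
  # meaning the release lies L steps in the past (bit L-1 = oldest)
  occ2 <- empirical_state_occupancy(c(1L, 0L, 0L, 1L), L = 3)
  expect_equal(occ2[5], 1)
  expect_error(empirical_state_occupancy(c(1L, 0L), L = 3), "shorter")
})

test_that("continuous-time depression model solves in closed form", {
  # no releases: stays at the default
  sol <- ode_release_probability(0.7, 250, 0.3, numeric(0),
                                 t_grid_ms = seq(0, 100, by = 10))
  expect_equal(sol$p_r, rep(0.7, 11))
  # single release at t = 0: instantaneous drop then 1/e relaxation
  tau <- 200
  sol1 <- ode_release_probability(0.7, tau, 0.4, 0, t_grid_ms = c(0, tau))
  expect_equal(sol1$p_r[1], 0.6 * 0.7)
  expect_equal(sol1$p_r[2] - 0.7, (0.6 * 0.7 - 0.7) / exp(1),
               tolerance = 1e-12)
  expect_error(ode_release_probability(0.7, 250, 0.3, c(10, 5), c(0, 1)),
               "sorted")
})

test_that("the discrete recurrence tracks the continuous model", {
  # matched conversions: c = 1 - u, e = 1 - exp(-delta/tau)
  delta <- 10; tau <- 250; u <- 0.25; p0 <- 0.7
  cc <- 1 - u
  e <- 1 - exp(-delta / tau)
  # a fixed 200 ms release pattern on the time grid (L = 20 steps)
  release_steps <- c(2, 3, 7, 11, 12, 18)   # steps at which Y = 1
  hist_bits <- as.integer(seq_len(20) %in% release_steps)
  # discrete path after each step, oldest first
  disc <- numeric(20)
  u_run <- p0
  for (k in seq_len(20)) {
    u_run <- if (hist_bits[k] == 1) cc * u_run else u_run + e * (p0 - u_run)
    disc[k] <- u_run
  }
  expect_equal(disc[20],
               release_prob_from_history(hist_bits, p0, p0, cc, e))
  # continuous path evaluated at the ends of the same steps
  sol <- ode_release_probability(p0, tau, u,
                                 release_times_ms = release_steps * delta,
                                 t_grid_ms = seq_len(20) * delta)
  dev <- abs(disc - sol$p_r)
  expect_lt(max(dev), e * p0)   # within one recovery increment
})
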