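# Independent oracles, deliberately written along different code paths than
# the package internals: explicit per-state loops, a dense transition matrix,
# and a direct linear solve instead of vectorized recursions and structured
# power iteration.

# Per-state release probability by literally replaying the history bits.
oracle_mode_table <- function(default, mult, rec, L, u0 = default) {
  n <- 2^L
  out <- numeric(n)
  for (j in seq_len(n) - 1L) {
    bits <- as.integer(intToBits(j))[seq_len(L)]  # bits[1] = most recent
    u <- u0
    for (k in rev(seq_len(L)))                    # oldest first
      u <- if (bits[k] == 1L) mult * u else u + rec * (default - u)
    out[j + 1L] <- u
  }
  out
}

# Dense 2^L x 2^L transition matrix of the history chain.
oracle_transition_matrix <- function(r, L) {
  n <- 2^L
  P <- matrix(0, n, n)
  for (j in seq_len(n) - 1L) {
    s1 <- 2L * (j %% 2^(L - 1L)) + 1L
    s0 <- 2L * (j %% 2^(L - 1L))
    P[j + 1L, s1 + 1L] <- P[j + 1L, s1 + 1L] + r[j + 1L]
    P[j + 1L, s0 + 1L] <- P[j + 1L, s0 + 1L] + 1 - r[j + 1L]
  }
  P
}

# Stationary distribution by dense linear solve: pi' P = pi', sum(pi) = 1.
oracle_stationary <- function(P) {
  n <- nrow(P)
  A <- t(P) - diag(n)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  solve(A, b)
}

oracle_entropy <- function(x)
  ifelse(x <= 0 | x >= 1, 0, -x * log2(x) - (1 - x) * log2(1 - x))

# Full small-L pipeline: exhaustive per-state summation over a dense solve.
oracle_rates <- function(params) {
  p <- oracle_mode_table(params$p0, params$c, params$e, params$L)
  q <- oracle_mode_table(params$q0, params$d, params$f, params$L)
  r <- (1 - params$alpha) * q + params$alpha * p
  pi <- oracle_stationary(oracle_transition_matrix(r, params$L))
  Rj <- oracle_entropy(r) - (1 - params$alpha) * oracle_entropy(q) -
    params$alpha * oracle_entropy(p)
  odd <- seq.int(2L, 2^params$L, by = 2L)
  R_step <- sum(Rj * pi)
  rel <- sum(pi[odd])
  list(pi = pi, R_per_step = R_step, release_rate = rel,
       R_bps = R_step * 1000 / params$delta_ms,
       R_E_bps = R_step * 1000 / params$delta_ms / rel)
}

# Random valid parameter set for property sweeps.
random_params <- function(L = sample(1:8, 1)) {
  synapse_params(alpha = runif(1, 0.05, 0.95),
                 p0 = runif(1, 0.05, 0.95),
                 q0 = runif(1, 0.001, 0.5),
                 c_sync = runif(1, 0.1, 1),
                 d_async = runif(1, 0.1, 1),
                 e_sync = runif(1, 0.01, 0.5),
                 f_async = runif(1, 0.01, 0.5),
                 L = L)
}

# Shared example parameter set used across tests.
example_params <- function(L = 10, alpha = 0.3)
  synapse_params(alpha = alpha, p0 = 0.7, q0 = 0.1, c_sync = 0.5,
                 d_async = 0.5, e_sync = 0.1, f_async = 0.1, L = L)
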