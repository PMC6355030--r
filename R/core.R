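# State-space machinery: history encoding, per-state release probabilities,
# the two-successor Markov chain, and its stationary distribution.
#
# A history state is the integer j = Y_{i-1} + 2 Y_{i-2} + ... + 2^(L-1) Y_{i-L}
# (bit 0 = most recent outcome), so odd j means a release happened at the
# immediately preceding step. Vectors over states are 1-indexed by j + 1.

#' Release probability implied by a history of outcomes
#'
#' Runs the per-step update of the depressing release site over an explicit
#' history of release outcomes, oldest first: after a release the probability
#' is multiplied by the depression factor `mult`; after a quiescent step it
#' relaxes a fraction `rec` of the way back toward `default`. A step applies
#' one or the other, never both. Called with `(u0 = p0, default = p0,
#' mult = c, rec = e)` this gives the synchronous release probability; with
#' `(u0 = q0, default = q0, mult = d, rec = f)` the asynchronous one.
#'
#' @param history Integer vector of 0/1 release outcomes, ordered oldest to
#'   newest. May be empty.
#' @param u0 Seed probability before the oldest step in the history.
#' @param default Default (resting) probability the recovery relaxes toward.
#' @param mult Depression multiplier in (0, 1].
#' @param rec Recovery coefficient in (0, 1).
#' @return The release probability after the full history, a number in
#'   \[0, 1\].
#' @examples
#' release_prob_from_history(c(0, 1), u0 = 0.7, default = 0.7,
#'                           mult = 0.5, rec = 0.1)  # 0.35
#' release_prob_from_history(c(1, 0), u0 = 0.7, default = 0.7,
#'                           mult = 0.5, rec = 0.1)  # 0.385
#' @export
release_prob_from_history <- function(history, u0, default, mult, rec) {
  stopifnot(is.numeric(u0), length(u0) == 1L, u0 >= 0, u0 <= 1,
            is.numeric(default), default >= 0, default <= 1,
            is.numeric(mult), mult >= 0, mult <= 1,
            is.numeric(rec), rec >= 0, rec <= 1)
  if (length(history) && !all(history %in% c(0, 1)))
    stop("'history' entries must be 0 or 1", call. = FALSE)
  u <- u0
  for (y in history)
    u <- if (y == 1) mult * u else u + rec * (default - u)
  u
}

# Vectorized table of release probabilities for all 2^L history states of one
# release mode. Exploits the recursion: the table for L-bit histories follows
# from the (L-1)-bit table by applying the newest outcome last.
mode_prob_table <- function(u0, default, mult, rec, L) {
  u <- u0
  for (l in seq_len(L)) {
    un <- numeric(2^l)
    idx <- seq_len(2^(l - 1))
    un[2 * idx - 1] <- u + rec * (default - u)  # newest outcome 0 (even j)
    un[2 * idx]     <- mult * u                 # newest outcome 1 (odd j)
    u <- un
  }
  u
}

#' Per-state release probabilities of the channel
#'
#' Builds the table of synchronous and asynchronous release probabilities
#' p(j), q(j) for every history state j in \[0, 2^L), together with the total
#' per-step release probability r(j) = (1 - alpha) q(j) + alpha p(j).
#'
#' @param params A [synapse_params()] object.
#' @param u0_sync,u0_async Seed probabilities of the recursion for histories
#'   older than the memory window. Default to `p0` and `q0`; other values are
#'   used to probe the effective memory length (see [effective_memory()]).
#' @param max_L Guard against accidental huge state spaces; the table has
#'   `2^L` entries per mode.
#' @return An object of class `"mro_state_table"`: list with numeric vectors
#'   `p`, `q`, `r` of length `2^L` (1-indexed by state `j + 1`), plus `L`
#'   and the originating `params`.
#' @seealso [release_prob_from_history()], [build_transition_chain()]
#' @export
build_state_table <- function(params, u0_sync = params$p0,
                              u0_async = params$q0, max_L = 24L) {
  stopifnot(inherits(params, "synapse_params"))
  if (params$L > max_L)
    stop(sprintf(paste0("L = %d would create %s states per mode; ",
                        "raise 'max_L' above %d if this is intended"),
                 params$L, format(2^params$L, big.mark = ","), max_L),
         call. = FALSE)
  p <- mode_prob_table(u0_sync,  params$p0, params$c, params$e, params$L)
  q <- mode_prob_table(u0_async, params$q0, params$d, params$f, params$L)
  structure(
    list(p = p, q = q, r = (1 - params$alpha) * q + params$alpha * p,
         L = params$L, params = params),
    class = "mro_state_table")
}

#' @export
print.mro_state_table <- function(x, ...) {
  cat("Release-probability table over", length(x$p), "history states (L =",
      x$L, ")\n")
  cat(sprintf("  p(j) in [%.4g, %.4g], q(j) in [%.4g, %.4g], r(j) in [%.4g, %.4g]\n",
              min(x$p), max(x$p), min(x$q), max(x$q), min(x$r), max(x$r)))
  invisible(x)
}

#' Two-successor transition structure of the history chain
#'
#' From state j the channel moves to `2 * (j mod 2^(L-1)) + 1` when a vesicle
#' is released (probability r(j)) and to `2 * (j mod 2^(L-1))` otherwise:
#' the history window shifts by one step and the newest outcome enters at
#' bit 0.
#'
#' @param table An `"mro_state_table"` from [build_state_table()].
#' @return An object of class `"mro_chain"`: list with integer vectors
#'   `succ_release`, `succ_quiet` (0-based state indices), the release
#'   probabilities `r`, and `L`.
#' @export
build_transition_chain <- function(table) {
  stopifnot(inherits(table, "mro_state_table"))
  L <- table$L
  j <- seq_len(2^L) - 1          # 0-based states
  base <- 2L * (j %% 2^(L - 1))
  structure(
    list(succ_release = as.integer(base + 1L), succ_quiet = as.integer(base),
         r = table$r, L = L),
    class = "mro_chain")
}

#' @export
print.mro_chain <- function(x, ...) {
  cat("History-state Markov chain:", length(x$r), "states, 2 successors each\n")
  invisible(x)
}

#' Stationary distribution of the history chain
#'
#' Computes the stationary probabilities of the 2^L history states by power
#' iteration, exploiting the chain's structure (every state has exactly two
#' predecessors, `floor(s/2)` and `floor(s/2) + 2^(L-1)`), so one iteration
#' costs O(2^L) with no matrix ever being formed. Iteration stops when the
#' max-norm change between successive iterates falls below `tol`.
#'
#' @param chain An `"mro_chain"` from [build_transition_chain()].
#' @param tol Convergence threshold on the max-norm of successive iterates.
#' @param max_iter Iteration cap; exceeding it is an error.
#' @param start Optional starting distribution (defaults to uniform).
#' @return An object of class `"mro_stationary"`: list with the probability
#'   vector `pi` (1-indexed by state `j + 1`, summing to 1), the iteration
#'   count `iterations`, and the final `residual`.
#' @export
stationary_distribution <- function(chain, tol = 1e-12, max_iter = 1e5,
                                    start = NULL) {
  stopifnot(inherits(chain, "mro_chain"), tol > 0)
  N <- length(chain$r)
  m <- N %/% 2L
  if (is.null(start)) {
    pi <- rep(1 / N, N)
  } else {
    stopifnot(length(start) == N, all(start >= 0), sum(start) > 0)
    pi <- start / sum(start)
  }
  r <- chain$r
  i_odd  <- seq.int(2L, N, by = 2L)   # states with a release at the last step
  i_even <- seq.int(1L, N, by = 2L)
  lo <- seq_len(m); hi <- m + lo
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- r * pi                       # flow along the release links
    v <- pi - w                       # flow along the quiescent links
    pin <- numeric(N)
    pin[i_odd]  <- w[lo] + w[hi]
    pin[i_even] <- v[lo] + v[hi]
    res <- max(abs(pin - pi))
    pi <- pin
    if (res < tol) break
    if (iter >= max_iter)
      stop(sprintf("power iteration did not reach tol = %g in %d iterations (residual %g)",
                   tol, max_iter, res), call. = FALSE)
  }
  pi <- pi / sum(pi)
  structure(list(pi = pi, iterations = iter, residual = res),
            class = "mro_stationary")
}

#' @export
print.mro_stationary <- function(x, ...) {
  cat("Stationary distribution over", length(x$pi), "states (",
      x$iterations, "iterations, residual", format(x$residual, digits = 3),
      ")\n")
  invisible(x)
}

# Number of releases recorded in the history encoded by state j (popcount).
history_release_count <- function(j, L) {
  n <- integer(length(j))
  for (k in seq_len(L) - 1L) n <- n + bitwAnd(j %/% 2^k, 1L)
  n
}
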