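# Monte-Carlo simulation of the release site and the reference
# differential-equation depression model, used to cross-validate the
# analytic machinery.

#' Simulate spike and release trains of a depressing release site
#'
#' Draws a Bernoulli(alpha) spike train and generates release outcomes with
#' the running synchronous/asynchronous release probabilities maintained by
#' the full (untruncated) depression-recovery recurrence: a release
#' multiplies the probabilities by the depression factors, a quiescent step
#' relaxes them toward their defaults. The first `burn_in` steps are
#' discarded so that collected statistics reflect the stationary regime.
#'
#' @param params A [synapse_params()] object (`L` only sets the default
#'   burn-in; the simulated probabilities carry unbounded memory).
#' @param n_steps Number of retained time steps (after burn-in).
#' @param seed RNG seed; identical seeds give bit-identical traces.
#' @param burn_in Steps discarded at the start (default `10 * L`).
#' @return An object of class `"mro_trace"`: list with binary vectors `X`
#'   (spikes) and `Y` (releases), numeric vectors `p_t`, `q_t` (the release
#'   probabilities in force at each retained step), and `seed`, `n_steps`,
#'   `burn_in`, `params`.
#' @seealso [empirical_state_occupancy()], [simulate.mro()]
#' @export
simulate_release_site <- function(params, n_steps, seed = NULL,
                                  burn_in = NULL) {
  stopifnot(inherits(params, "synapse_params"), n_steps >= 1)
  if (is.null(burn_in)) burn_in <- 10L * params$L
  stopifnot(burn_in >= 0)
  if (!is.null(seed)) set.seed(seed)
  n_tot <- n_steps + burn_in
  ux <- stats::runif(n_tot)
  uy <- stats::runif(n_tot)
  X <- as.integer(ux < params$alpha)
  Y <- integer(n_tot)
  p_t <- numeric(n_tot)
  q_t <- numeric(n_tot)
  up <- params$p0; uq <- params$q0
  p0 <- params$p0; q0 <- params$q0
  cc <- params$c; d <- params$d; e <- params$e; f <- params$f
  for (t in seq_len(n_tot)) {
    p_t[t] <- up; q_t[t] <- uq
    y <- uy[t] < (if (X[t] == 1L) up else uq)
    if (y) {
      Y[t] <- 1L
      up <- cc * up
      uq <- d * uq
    } else {
      up <- up + e * (p0 - up)
      uq <- uq + f * (q0 - uq)
    }
  }
  keep <- seq.int(burn_in + 1L, n_tot)
  structure(
    list(X = X[keep], Y = Y[keep], p_t = p_t[keep], q_t = q_t[keep],
         seed = seed, n_steps = as.integer(n_steps),
         burn_in = as.integer(burn_in), params = params),
    class = "mro_trace")
}

#' @export
print.mro_trace <- function(x, ...) {
  cat("Simulated release-site trace:", x$n_steps, "steps (burn-in",
      x$burn_in, "discarded)\n")
  cat(sprintf("  spike rate %.4g, release rate %.4g per step\n",
              mean(x$X), mean(x$Y)))
  invisible(x)
}

#' @export
as.data.frame.mro_trace <- function(x, ...) {
  data.frame(t_ms = (seq_along(x$X) - 1) * x$params$delta_ms,
             X = x$X, Y = x$Y, p_t = x$p_t, q_t = x$q_t)
}

#' Simulate method for release-site models
#'
#' Convenience wrapper around [simulate_release_site()] for fitted-model
#' style workflows: `simulate(m, nsim, seed)` draws `nsim` independent
#' traces from the channel described by an [mro()] object.
#'
#' @param object An `"mro"` model.
#' @param nsim Number of traces.
#' @param seed RNG seed (trace k uses `seed + k - 1`).
#' @param n_steps,burn_in Passed to [simulate_release_site()].
#' @param ... Unused.
#' @return A list of `"mro_trace"` objects (a single trace if `nsim = 1`).
#' @export
simulate.mro <- function(object, nsim = 1, seed = NULL, n_steps = 1e4,
                         burn_in = NULL, ...) {
  traces <- lapply(seq_len(nsim), function(k)
    simulate_release_site(object$params, n_steps = n_steps,
                          seed = if (is.null(seed)) NULL else seed + k - 1,
                          burn_in = burn_in))
  if (nsim == 1L) traces[[1L]] else traces
}

#' Release probability of the continuous-time depression model
#'
#' Solves the classic stochastic depression dynamics
#' \eqn{dp_r/dt = (p_0 - p_r)/\tau - u\, p_r\, \delta(t - t_r)}: between
#' releases the probability relaxes exponentially toward `p0` with time
#' constant `tau_ms`; at each release time it drops instantaneously by the
#' factor `1 - u`. The solution is evaluated piecewise in closed form. This
#' is the continuous-time reference against which the discrete
#' depression-recovery recurrence is validated (with `c = 1 - u` and
#' `e = 1 - exp(-delta_ms / tau_ms)` the recurrence is the exact one-step
#' discretization at release times aligned to the grid).
#'
#' @param p0 Default (maximum) release probability.
#' @param tau_ms Recovery time constant in ms.
#' @param u Depression fraction in (0, 1); a release scales the probability
#'   by `1 - u`.
#' @param release_times_ms Sorted release times in ms.
#' @param t_grid_ms Sorted evaluation times in ms.
#' @return A data frame with columns `t_ms` and `p_r`. At a grid time that
#'   coincides with a release, the post-release value is reported.
#' @export
ode_release_probability <- function(p0, tau_ms, u, release_times_ms,
                                    t_grid_ms) {
  stopifnot(p0 > 0, p0 <= 1, tau_ms > 0, u > 0, u < 1)
  if (is.unsorted(release_times_ms) || is.unsorted(t_grid_ms))
    stop("release times and evaluation grid must be sorted", call. = FALSE)
  events <- c(release_times_ms, Inf)
  p_r <- numeric(length(t_grid_ms))
  p_cur <- p0                    # value just after the previous event
  t_cur <- -Inf                  # at the default until the first release
  gi <- 1L
  for (ev in events) {
    # evaluate on grid points strictly before the event, then apply the drop
    while (gi <= length(t_grid_ms) && t_grid_ms[gi] < ev) {
      p_r[gi] <- p0 + (p_cur - p0) * exp(-(t_grid_ms[gi] - t_cur) / tau_ms)
      gi <- gi + 1L
    }
    if (is.infinite(ev)) break
    p_cur <- (1 - u) * (p0 + (p_cur - p0) * exp(-(ev - t_cur) / tau_ms))
    t_cur <- ev
    # grid points exactly at the event report the post-release value
    while (gi <= length(t_grid_ms) && t_grid_ms[gi] == ev) {
      p_r[gi] <- p_cur
      gi <- gi + 1L
    }
  }
  data.frame(t_ms = t_grid_ms, p_r = p_r)
}

#' Empirical state-occupancy frequencies of a simulated trace
#'
#' Slides an L-step window over the release outcomes of a trace, encodes
#' each window as a history state (bit 0 = most recent outcome) and counts
#' visits. The resulting frequencies converge to the stationary
#' distribution of the history chain as the trace grows.
#'
#' @param trace An `"mro_trace"`, or a plain 0/1 vector of release
#'   outcomes.
#' @param L Memory length of the encoding (intended for L up to ~10).
#' @return A numeric vector of length `2^L` with the visit frequencies,
#'   1-indexed by state `j + 1`; sums to 1.
#' @export
empirical_state_occupancy <- function(trace, L) {
  Y <- if (inherits(trace, "mro_trace")) trace$Y else trace
  stopifnot(all(Y %in% c(0L, 1L)), L >= 1)
  n <- length(Y)
  if (n <= L) stop("trace shorter than the memory window", call. = FALSE)
  idx <- seq.int(L + 1L, n)
  j <- numeric(length(idx))
  for (k in seq_len(L)) j <- j + 2^(k - 1) * Y[idx - k]
  tabulate(j + 1L, nbins = 2^L) / length(idx)
}
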