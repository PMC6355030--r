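#' Build the release-site channel model
#'
#' `mro()` is the main entry point of the package. It models a single
#' synaptic release site under short-term depression as a binary asymmetric
#' channel with a memory of the last `L` release outcomes: presynaptic
#' spikes arrive as a Bernoulli(alpha) process, a spike releases a vesicle
#' with the state-dependent synchronous probability p(j), a quiescent step
#' releases one with the asynchronous probability q(j), and each release
#' multiplies the probabilities by depression factors (`c_sync`, `d_async`)
#' while quiescent steps relax them back toward their defaults (`e_sync`,
#' `f_async`).
#'
#' The constructor builds the per-state release-probability table, the
#' 2^L-state Markov chain over release histories, its stationary
#' distribution (power iteration), and the exact information rates of the
#' channel: the mutual information rate under depression, the
#' energy-normalized rate (bits per unit energy at one energy unit per
#' release), and the closed-form no-depression baselines.
#'
#' @param params A [synapse_params()] object. Alternatively, pass the
#'   individual parameters through `...` (they are forwarded to
#'   [synapse_params()]).
#' @param ... Parameters forwarded to [synapse_params()] when `params` is
#'   missing.
#' @param tol,max_iter Convergence control for [stationary_distribution()].
#' @param max_L State-space guard forwarded to [build_state_table()].
#' @return An object of class `"mro"`: list with components `params`,
#'   `table` (state table), `chain`, `stationary`, `rates` (depressed,
#'   an `"mro_rates"`), and `rates0` (no-depression baseline).
#' @seealso [synapse_params()], [classify_synapse()], [sweep_alpha()],
#'   [simulate.mro()], [case_study_preset()]
#' @examples
#' # hippocampal autapse at 5 Hz (10 ms time unit)
#' m <- mro(alpha = 0.05, p0 = 0.4, q0 = 0.04, c_sync = 0.75, d_async = 1,
#'          e_sync = 0.039, f_async = 0.1, L = 12)
#' m
#' coef(m)
#' @export
mro <- function(params, ..., tol = 1e-12, max_iter = 1e5, max_L = 24L) {
  if (missing(params)) params <- synapse_params(...)
  stopifnot(inherits(params, "synapse_params"))
  table <- build_state_table(params, max_L = max_L)
  chain <- build_transition_chain(table)
  st <- stationary_distribution(chain, tol = tol, max_iter = max_iter)
  structure(
    list(params = params, table = table, chain = chain, stationary = st,
         rates = mutual_information_rate(table, st),
         rates0 = rates_without_depression(params)),
    class = "mro")
}

#' @export
print.mro <- function(x, digits = 4, ...) {
  cat("Release-site channel with a memory of", x$params$L,
      "release outcomes (", length(x$table$p), "states )\n")
  print(x$params)
  cat(sprintf("  R_D = %.*g bps, R_D^(E) = %.*g bps/E  (with depression)\n",
              digits, x$rates$R_bps, digits, x$rates$R_E_bps))
  cat(sprintf("  R_0 = %.*g bps, R_0^(E) = %.*g bps/E  (without depression)\n",
              digits, x$rates0$R_bps, digits, x$rates0$R_E_bps))
  invisible(x)
}

#' @export
coef.mro <- function(object, ...) {
  p <- object$params
  c(alpha = p$alpha, p0 = p$p0, q0 = p$q0, c = p$c, d = p$d, e = p$e,
    f = p$f, L = p$L, delta_ms = p$delta_ms)
}

#' Summarize a release-site channel model
#'
#' Collects the information rates (with and without depression), the
#' functional category of the synapse (does depression raise or lower the
#' information rate and the energy-normalized rate?), stationary-occupancy
#' diagnostics and power-iteration convergence information.
#'
#' @param object An `"mro"` model.
#' @param ... Unused.
#' @return An object of class `"summary.mro"`.
#' @export
summary.mro <- function(object, ...) {
  d <- state_diagnostics(object$table, object$stationary,
                         object$params$alpha)
  delta_R  <- object$rates$R_bps - object$rates0$R_bps
  delta_RE <- object$rates$R_E_bps - object$rates0$R_E_bps
  structure(
    list(params = object$params, rates = object$rates,
         rates0 = object$rates0,
         category = category_from_deltas(delta_R, delta_RE),
         delta_R = delta_R, delta_RE = delta_RE,
         release_rate = object$rates$release_rate_per_step,
         top_states = utils::head(
           d$per_state[order(-d$per_state$pi_j), ], 5L),
         iterations = object$stationary$iterations,
         residual = object$stationary$residual),
    class = "summary.mro")
}

#' @export
print.summary.mro <- function(x, digits = 4, ...) {
  print(x$params)
  cat(sprintf("  R_D = %.*g bps, R_D^(E) = %.*g bps/E\n",
              digits, x$rates$R_bps, digits, x$rates$R_E_bps))
  cat(sprintf("  R_0 = %.*g bps, R_0^(E) = %.*g bps/E\n",
              digits, x$rates0$R_bps, digits, x$rates0$R_E_bps))
  cat(sprintf("  depression changes R by %+.*g bps and R^(E) by %+.*g bps/E\n",
              digits, x$delta_R, digits, x$delta_RE))
  cat("  functional category:", x$category,
      switch(x$category,
             "1" = "(depression raises both rates)",
             "2" = "(depression raises only the energy-normalized rate)",
             "3" = "(depression lowers both rates)"), "\n")
  cat(sprintf("  stationary release rate: %.*g per step (%.*g Hz)\n",
              digits, x$release_rate,
              digits, x$release_rate * 1000 / x$params$delta_ms))
  cat("  power iteration:", x$iterations, "iterations, residual",
      format(x$residual, digits = 3), "\n")
  cat("  most occupied states:\n")
  print(x$top_states, row.names = FALSE, digits = digits)
  invisible(x)
}

#' Plot the state-space structure of a release-site model
#'
#' Scatters the stationary probability of every history state against its
#' per-state mutual information rate, colored by the number of releases in
#' the state's history window. States with the same release count cluster,
#' making the contribution of each memory pattern to the overall rate
#' visible.
#'
#' @param x An `"mro"` model.
#' @param power Exponent applied to the rate axis to spread the clusters
#'   (the identity at 1; smaller values emphasize low-rate states).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the per-state data frame that was plotted.
#' @export
plot.mro <- function(x, power = 0.15, ...) {
  d <- state_diagnostics(x$table, x$stationary, x$params$alpha)$per_state
  pal <- grDevices::hcl.colors(x$params$L + 1L, "viridis")
  graphics::plot(d$R_j^power, d$pi_j, log = "y",
                 col = pal[d$releases + 1L], pch = 16, cex = 0.6,
                 xlab = sprintf("per-state rate R_j^%.2g (bits/step)", power),
                 ylab = expression(pi[j]), ...)
  lv <- unique(round(seq(0, x$params$L, length.out = 5)))
  graphics::legend("topright", legend = lv, col = pal[lv + 1L], pch = 16,
                   title = "releases in history", cex = 0.7)
  invisible(d)
}
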