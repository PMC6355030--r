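# Parameter-sweep analyses: capacity and optimal input rate, effective
# memory length, functional categories, per-state diagnostics.

# Re-solve the chain for a new alpha, reusing the alpha-independent p/q
# tables.
rates_at_alpha <- function(p, q, alpha, delta_ms, L, tol = 1e-12,
                           max_iter = 1e5) {
  r <- (1 - alpha) * q + alpha * p
  chain <- structure(list(succ_release = NULL, succ_quiet = NULL, r = r,
                          L = L), class = "mro_chain")
  st <- stationary_distribution(chain, tol = tol, max_iter = max_iter)
  Rj <- state_rate(p, q, alpha)
  R_step <- sum(Rj * st$pi)
  odd <- seq.int(2L, length(r), by = 2L)
  rate_summary(R_step, sum(st$pi[odd]), delta_ms, depressed = TRUE)
}

#' Sweep the input spike rate
#'
#' Evaluates the four information rates (with and without depression, plain
#' and energy-normalized) over a grid of input spike rates alpha. The
#' per-state release probabilities do not depend on alpha, so only the
#' transition probabilities and the stationary distribution are recomputed
#' per grid point. The spike rates maximizing \eqn{R_D} and \eqn{R_D^{(E)}}
#' are reported at grid resolution (no interpolation).
#'
#' @param params A [synapse_params()] object (its `alpha` is ignored).
#' @param alpha_grid Strictly increasing spike probabilities in (0, 1).
#' @param tol,max_iter Convergence control for the stationary solver.
#' @return A data frame of class `"mro_sweep"` with columns `alpha`,
#'   `R_D_bps`, `R_DE_bps`, `R_0_bps`, `R_0E_bps`, and attributes
#'   `argmax_alpha_R` and `argmax_alpha_RE`.
#' @examples
#' s <- sweep_alpha(synapse_params(alpha = 0.3, p0 = 0.7, q0 = 0.1,
#'                                 c_sync = 0.5, d_async = 0.5,
#'                                 e_sync = 0.1, f_async = 0.1, L = 8),
#'                  alpha_grid = seq(0.05, 0.95, by = 0.05))
#' attr(s, "argmax_alpha_R")
#' @export
sweep_alpha <- function(params, alpha_grid = seq(0.01, 0.99, by = 0.01),
                        tol = 1e-12, max_iter = 1e5) {
  stopifnot(inherits(params, "synapse_params"))
  if (!length(alpha_grid)) stop("'alpha_grid' is empty", call. = FALSE)
  if (any(alpha_grid <= 0 | alpha_grid >= 1) || is.unsorted(alpha_grid, strictly = TRUE))
    stop("'alpha_grid' must be strictly increasing within (0, 1)", call. = FALSE)
  tab <- build_state_table(params)
  rows <- lapply(alpha_grid, function(a) {
    rd <- rates_at_alpha(tab$p, tab$q, a, params$delta_ms, params$L,
                         tol = tol, max_iter = max_iter)
    p0 <- params; p0$alpha <- a
    r0 <- rates_without_depression(p0)
    data.frame(alpha = a, R_D_bps = rd$R_bps, R_DE_bps = rd$R_E_bps,
               R_0_bps = r0$R_bps, R_0E_bps = r0$R_E_bps)
  })
  out <- do.call(rbind, rows)
  attr(out, "argmax_alpha_R") <- out$alpha[which.max(out$R_D_bps)]
  attr(out, "argmax_alpha_RE") <- out$alpha[which.max(out$R_DE_bps)]
  class(out) <- c("mro_sweep", class(out))
  out
}

#' @export
plot.mro_sweep <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$alpha, x$R_D_bps, type = "l", xlab = expression(alpha),
                 ylab = "R (bps)", ...)
  graphics::lines(x$alpha, x$R_0_bps, lty = 2)
  graphics::abline(v = attr(x, "argmax_alpha_R"), col = "grey")
  graphics::legend("topleft", c("with depression", "without"),
                   lty = c(1, 2), bty = "n", cex = 0.8)
  graphics::plot(x$alpha, x$R_DE_bps, type = "l", xlab = expression(alpha),
                 ylab = expression(R^(E) ~ "(bps/E)"), ...)
  graphics::lines(x$alpha, x$R_0E_bps, lty = 2)
  graphics::abline(v = attr(x, "argmax_alpha_RE"), col = "grey")
  invisible(x)
}

#' Effective memory length of the depressing synapse
#'
#' How long does the channel remember its initial condition? For each memory
#' length in `L_grid` the mutual information rate is recomputed with several
#' seed values substituted for the release probability that held before the
#' memory window, and the relative variation `(max - min) / max` of the rate
#' across seeds is reported. The memory length at which this variation drops
#' below a given level is the effective memory of the synapse.
#'
#' Seeds are given on the synchronous scale; the asynchronous seed is scaled
#' proportionally (`u0 * q0 / p0`) so both modes are perturbed coherently.
#'
#' @param params A [synapse_params()] object (its `L` is ignored).
#' @param L_grid Increasing vector of memory lengths to probe.
#' @param seeds Seed probabilities for the synchronous mode; default
#'   `c(0.1 * p0, p0, min(0.99, 1.9 * p0))`. At least two.
#' @param tol,max_iter Convergence control.
#' @return A data frame with columns `L`, one `R_D_bps_seed<i>` column per
#'   seed, and `rel_variation`.
#' @export
effective_memory <- function(params, L_grid = 1:16, seeds = NULL,
                             tol = 1e-12, max_iter = 1e5) {
  stopifnot(inherits(params, "synapse_params"))
  if (is.null(seeds))
    seeds <- c(0.1 * params$p0, params$p0, min(0.99, 1.9 * params$p0))
  if (length(seeds) < 2L)
    stop("need at least two seed values", call. = FALSE)
  if (any(seeds <= 0 | seeds >= 1))
    stop("seeds must lie in (0, 1)", call. = FALSE)
  if (is.unsorted(L_grid, strictly = TRUE) || any(L_grid < 1))
    stop("'L_grid' must be increasing positive integers", call. = FALSE)
  rows <- lapply(L_grid, function(L) {
    pL <- params; pL$L <- as.integer(L)
    R <- vapply(seeds, function(u0) {
      tab <- build_state_table(pL, u0_sync = u0,
                               u0_async = min(0.99, u0 * params$q0 / params$p0))
      st <- stationary_distribution(build_transition_chain(tab),
                                    tol = tol, max_iter = max_iter)
      mutual_information_rate(tab, st)$R_bps
    }, numeric(1))
    c(L = L, R, rel_variation = (max(R) - min(R)) / max(R))
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("L", paste0("R_D_bps_seed", seq_along(seeds)),
                  "rel_variation")
  out
}

category_from_deltas <- function(delta_R, delta_RE, tol = 1e-9) {
  if (delta_R > tol && delta_RE <= tol)
    stop(sprintf(paste0("impossible rate pattern: depression raises the ",
                        "information rate (%+g) without raising the ",
                        "energy-normalized rate (%+g); this indicates a bug"),
                 delta_R, delta_RE), call. = FALSE)
  if (delta_R > 0 && delta_RE > 0) 1L else if (delta_RE > 0) 2L else 3L
}

#' Functional category of a release site under depression
#'
#' Compares the information rates with and without depression and assigns
#' one of three functional categories: (1) depression raises both the
#' mutual information rate and the energy-normalized rate; (2) depression
#' raises only the energy-normalized rate; (3) depression lowers both.
#' A rise in the energy-normalized rate is a necessary condition for a rise
#' in the information rate, so the fourth sign pattern cannot occur; if it
#' appears beyond numerical tolerance an error is raised. Ties (zero
#' difference) count as "no increase".
#'
#' @param params A [synapse_params()] object.
#' @param tol,max_iter Convergence control for the chain solver.
#' @return An object of class `"mro_category"`: list with `category` (1, 2
#'   or 3), `delta_R` and `delta_RE` (bps and bps/E differences,
#'   depressed minus baseline), and the two `"mro_rates"` objects.
#' @export
classify_synapse <- function(params, tol = 1e-12, max_iter = 1e5) {
  stopifnot(inherits(params, "synapse_params"))
  tab <- build_state_table(params)
  st <- stationary_distribution(build_transition_chain(tab), tol = tol,
                                max_iter = max_iter)
  rd <- mutual_information_rate(tab, st)
  r0 <- rates_without_depression(params)
  delta_R <- rd$R_bps - r0$R_bps
  delta_RE <- rd$R_E_bps - r0$R_E_bps
  structure(
    list(category = category_from_deltas(delta_R, delta_RE),
         delta_R = delta_R, delta_RE = delta_RE, rates = rd, rates0 = r0),
    class = "mro_category")
}

#' @export
print.mro_category <- function(x, ...) {
  cat("Functional category", x$category, "\n")
  cat(sprintf("  depression changes R by %+.4g bps and R^(E) by %+.4g bps/E\n",
              x$delta_R, x$delta_RE))
  invisible(x)
}

#' Per-state diagnostics of the history chain
#'
#' Emits, for every history state, its release probabilities, per-state
#' information rate \eqn{R_j}, stationary probability \eqn{\pi_j}, the
#' product \eqn{R_j \pi_j} (the state's contribution to the overall rate),
#' and the number of releases recorded in the state's history window,
#' together with histogram summaries.
#'
#' @param table An `"mro_state_table"`.
#' @param pi An `"mro_stationary"` for the same parameter set.
#' @param alpha Spike probability used for the per-state rates.
#' @param breaks Histogram breaks (passed to [graphics::hist()]).
#' @return A list with `per_state` (data frame with columns `state`,
#'   `releases`, `p`, `q`, `r`, `R_j`, `pi_j`, `R_pi`) and histogram objects
#'   `hist_R`, `hist_log_pi`, `hist_log_Rpi`.
#' @export
state_diagnostics <- function(table, pi, alpha = table$params$alpha,
                              breaks = 30) {
  stopifnot(inherits(table, "mro_state_table"),
            inherits(pi, "mro_stationary"),
            length(pi$pi) == length(table$p))
  j <- seq_along(table$p) - 1L
  Rj <- state_rate(table$p, table$q, alpha)
  per_state <- data.frame(
    state = j, releases = history_release_count(j, table$L),
    p = table$p, q = table$q, r = table$r,
    R_j = Rj, pi_j = pi$pi, R_pi = Rj * pi$pi)
  pos <- function(x) x[x > 0]
  list(per_state = per_state,
       hist_R = graphics::hist(Rj, breaks = breaks, plot = FALSE),
       hist_log_pi = graphics::hist(log10(pos(pi$pi)), breaks = breaks,
                                    plot = FALSE),
       hist_log_Rpi = graphics::hist(log10(pos(Rj * pi$pi)), breaks = breaks,
                                     plot = FALSE))
}

#' Sweep the default release probability at a fixed sync/async ratio
#'
#' The mutual information rate depends strongly on the default synchronous
#' release probability p0, but when the asynchronous default is tied to it
#' (q0 = K p0) the energy-normalized rate and the optimal input rate become
#' nearly independent of p0. This helper runs [sweep_alpha()] for each p0 in
#' a grid with `q0 = K * p0` and reports the spread of the optimal spike
#' rates across p0.
#'
#' @param K Ratio q0 / p0; must satisfy `K * p0 < 1` over the grid.
#' @param p0_grid Default synchronous release probabilities.
#' @param params A [synapse_params()] object supplying the remaining
#'   parameters (its `p0`, `q0` are overridden per grid point).
#' @param alpha_grid Spike-rate grid forwarded to [sweep_alpha()].
#' @param tol,max_iter Convergence control.
#' @return A list of class `"mro_ratio_sweep"`: `sweeps` (named list of
#'   `"mro_sweep"` frames), `argmax` (data frame with per-p0 optimal spike
#'   rates), and `spread_RE` (max minus min of `argmax_alpha_RE`).
#' @export
critical_ratio_sweep <- function(K, p0_grid, params,
                                 alpha_grid = seq(0.01, 0.99, by = 0.01),
                                 tol = 1e-12, max_iter = 1e5) {
  stopifnot(inherits(params, "synapse_params"), K > 0,
            all(K * p0_grid < 1), all(p0_grid > 0 & p0_grid < 1))
  sweeps <- lapply(p0_grid, function(p0) {
    pp <- params; pp$p0 <- p0; pp$q0 <- K * p0
    sweep_alpha(pp, alpha_grid, tol = tol, max_iter = max_iter)
  })
  names(sweeps) <- format(p0_grid)
  argmax <- data.frame(
    p0 = p0_grid,
    argmax_alpha_R = vapply(sweeps, attr, numeric(1), "argmax_alpha_R"),
    argmax_alpha_RE = vapply(sweeps, attr, numeric(1), "argmax_alpha_RE"))
  structure(list(sweeps = sweeps, argmax = argmax,
                 spread_RE = diff(range(argmax$argmax_alpha_RE))),
            class = "mro_ratio_sweep")
}

#' @export
print.mro_ratio_sweep <- function(x, ...) {
  cat("Spike-rate sweeps at fixed q0/p0 ratio\n")
  print(x$argmax, row.names = FALSE)
  cat("spread of argmax alpha for R^(E):", x$spread_RE, "\n")
  invisible(x)
}
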