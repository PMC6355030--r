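# Alternative one-step-state channel: the state is the pair of current
# release probabilities (plus the implied last outcome), quantized to a
# finite grid of levels so the chain stays finite.

snap_to_levels <- function(x, levels) {
  if (length(levels) == 1L) return(rep(levels, length(x)))
  levels[pmin(length(levels),
              pmax(1L, round(stats::approx(levels, seq_along(levels),
                                           xout = pmin(max(levels),
                                                       pmax(min(levels), x)))$y)))]
}

#' Quantized-probability channel for the release site
#'
#' Builds the alternative formulation in which the channel's state is the
#' current pair of release probabilities rather than the explicit history of
#' outcomes: after a release both probabilities are multiplied by their
#' depression factors, after a quiescent step both relax toward their
#' defaults, and each updated value is snapped to the nearest level of a
#' finite uniform grid on \[0, default\] (one grid per mode, `n_levels`
#' points, always containing the default). The reachable closure of the
#' level pairs under the two updates, starting from the defaults, forms a
#' finite Markov chain.
#'
#' The exact quantization used in the original supplementary treatment is
#' not reproduced here; this grid-with-snapping construction is a
#' reconstruction whose validity is checked by agreement with the
#' history-based channel as the grid is refined.
#'
#' @param params A [synapse_params()] object (`L` is ignored).
#' @param n_levels Number of grid levels per release mode (at least 2).
#' @param state_cap Guard on the size of the reachable state space.
#' @return An object of class `"mro_quantized_chain"`: list with the level
#'   grids `levels_p`, `levels_q`, the per-state data frame `states`
#'   (columns `p`, `q`, `r`), integer successor indices `succ_release`,
#'   `succ_quiet`, and `params`.
#' @seealso [quantized_information_rate()]
#' @export
build_quantized_chain <- function(params, n_levels = 64L, state_cap = 2e5) {
  stopifnot(inherits(params, "synapse_params"), n_levels >= 2)
  levels_p <- if (params$c == 1) params$p0 else
    seq(0, params$p0, length.out = n_levels)
  levels_q <- if (params$d == 1 || params$q0 == 0) params$q0 else
    seq(0, params$q0, length.out = n_levels)
  key <- function(ip, iq) paste(ip, iq)
  upd_release <- function(p, q)
    c(snap_to_levels(params$c * p, levels_p),
      snap_to_levels(params$d * q, levels_q))
  upd_quiet <- function(p, q)
    c(snap_to_levels(p + params$e * (params$p0 - p), levels_p),
      snap_to_levels(q + params$f * (params$q0 - q), levels_q))

  start <- c(params$p0, params$q0)
  states <- list(start)
  index <- new.env(parent = emptyenv())
  assign(key(start[1], start[2]), 1L, envir = index)
  succ_release <- integer(0)
  succ_quiet <- integer(0)
  head <- 1L
  while (head <= length(states)) {
    if (length(states) > state_cap)
      stop("reachable quantized state space exceeds 'state_cap'", call. = FALSE)
    s <- states[[head]]
    for (mode in 1:2) {
      nxt <- if (mode == 1) upd_release(s[1], s[2]) else upd_quiet(s[1], s[2])
      k <- key(nxt[1], nxt[2])
      id <- get0(k, envir = index)
      if (is.null(id)) {
        states[[length(states) + 1L]] <- nxt
        id <- length(states)
        assign(k, id, envir = index)
      }
      if (mode == 1) succ_release[head] <- id else succ_quiet[head] <- id
    }
    head <- head + 1L
  }
  p <- vapply(states, `[`, numeric(1), 1L)
  q <- vapply(states, `[`, numeric(1), 2L)
  structure(
    list(levels_p = levels_p, levels_q = levels_q,
         states = data.frame(p = p, q = q,
                             r = (1 - params$alpha) * q + params$alpha * p),
         succ_release = succ_release, succ_quiet = succ_quiet,
         params = params),
    class = "mro_quantized_chain")
}

#' @export
print.mro_quantized_chain <- function(x, ...) {
  cat("Quantized release-probability chain:", nrow(x$states), "states (",
      length(x$levels_p), "x", length(x$levels_q), "levels )\n")
  invisible(x)
}

#' Information rates of the quantized-probability channel
#'
#' Computes the stationary distribution of a quantized chain (power
#' iteration on its sparse transition matrix), evaluates the per-state
#' binary-asymmetric-channel rate at each level pair, and returns the
#' stationary-averaged information rates in the same summary format as
#' [mutual_information_rate()]. The expected number of releases per step is
#' \eqn{\sum_j \pi_j r_j}.
#'
#' @param chain An `"mro_quantized_chain"` from [build_quantized_chain()].
#' @param tol,max_iter Convergence control for the power iteration.
#' @return An `"mro_rates"` object.
#' @export
quantized_information_rate <- function(chain, tol = 1e-12, max_iter = 1e5) {
  stopifnot(inherits(chain, "mro_quantized_chain"))
  n <- nrow(chain$states)
  r <- chain$states$r
  # transpose of the transition matrix, two entries per column
  Pt <- Matrix::sparseMatrix(
    i = c(chain$succ_release, chain$succ_quiet),
    j = c(seq_len(n), seq_len(n)),
    x = c(r, 1 - r), dims = c(n, n))
  pi <- rep(1 / n, n)
  for (iter in seq_len(max_iter)) {
    pin <- as.numeric(Pt %*% pi)
    res <- max(abs(pin - pi))
    pi <- pin
    if (res < tol) break
    if (iter == max_iter)
      stop(sprintf("power iteration did not converge (residual %g)", res),
           call. = FALSE)
  }
  pi <- pi / sum(pi)
  Rj <- state_rate(chain$states$p, chain$states$q, chain$params$alpha)
  rate_summary(sum(Rj * pi), sum(pi * r), chain$params$delta_ms,
               depressed = TRUE)
}
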