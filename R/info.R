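# Closed-form information measures of the channel.

#' Binary entropy function
#'
#' \eqn{h(x) = -x \log_2 x - (1-x)\log_2(1-x)}, in bits, with
#' \eqn{h(0) = h(1) = 0} by continuity. Vectorized.
#'
#' @param x Probabilities in \[0, 1\].
#' @return Entropy values in bits.
#' @export
binary_entropy <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
    stop("'x' must be probabilities in [0, 1]", call. = FALSE)
  h <- numeric(length(x))
  inner <- x > 0 & x < 1
  xi <- x[inner]
  h[inner] <- -xi * log2(xi) - (1 - xi) * log2(1 - xi)
  h
}

#' Per-state mutual information rate of the binary asymmetric channel
#'
#' The mutual information (bits per time step) between the spike indicator
#' and the release outcome for a channel with synchronous release probability
#' `p`, asynchronous release probability `q` and spike probability `alpha`:
#' \deqn{R = h(\bar\alpha q + \alpha p) - \bar\alpha h(q) - \alpha h(p).}
#' Tiny negative floating-point residue is clamped to 0 (mutual information
#' is non-negative). Vectorized over `p` and `q`.
#'
#' @param p,q Release probabilities in \[0, 1\].
#' @param alpha Spike probability in \[0, 1\].
#' @return Mutual information in bits per time step.
#' @export
state_rate <- function(p, q, alpha) {
  stopifnot(length(alpha) == 1L, alpha >= 0, alpha <= 1)
  val <- binary_entropy((1 - alpha) * q + alpha * p) -
    (1 - alpha) * binary_entropy(q) - alpha * binary_entropy(p)
  pmax(val, 0)
}

# Assemble the unit conversions shared by all rate computations.
rate_summary <- function(R_per_step, release_rate_per_step, delta_ms,
                         depressed) {
  if (release_rate_per_step <= 0)
    stop("expected release rate per step is zero; energy normalization undefined",
         call. = FALSE)
  R_bps <- R_per_step * 1000 / delta_ms
  structure(
    list(R_per_step = R_per_step,
         R_bps = R_bps,
         release_rate_per_step = release_rate_per_step,
         R_E_per_release = R_per_step / release_rate_per_step,
         R_E_bps = R_bps / release_rate_per_step,
         delta_ms = delta_ms,
         depressed = depressed),
    class = "mro_rates")
}

#' @export
print.mro_rates <- function(x, ...) {
  cat(if (x$depressed) "Information rate under depression\n"
      else "Information rate without depression\n")
  cat(sprintf("  R     = %.6g bits/step  = %.6g bps\n", x$R_per_step, x$R_bps))
  cat(sprintf("  R^(E) = %.6g bits/release = %.6g bps/E\n",
              x$R_E_per_release, x$R_E_bps))
  cat(sprintf("  expected releases per step: %.6g\n", x$release_rate_per_step))
  invisible(x)
}

#' @export
as.data.frame.mro_rates <- function(x, ...) {
  data.frame(bits_per_step = x$R_per_step, bps = x$R_bps,
             bits_per_release = x$R_E_per_release,
             bps_per_E = x$R_E_bps,
             release_rate_per_step = x$release_rate_per_step,
             depressed = x$depressed)
}

#' Mutual information rate of the depressing release site
#'
#' The exact mutual information rate of the channel with memory: the
#' stationary average of the per-state rates,
#' \eqn{R_D = \sum_j R_j \pi_j}, where \eqn{R_j} is [state_rate()] evaluated
#' at state j's release probabilities and \eqn{\pi} is the stationary
#' distribution of the history chain.
#'
#' Two unit conventions are reported for the energy-normalized rate (one
#' unit of energy per vesicle release): bits per release
#' (\eqn{R_D / \sum_{odd\,j} \pi_j} per step), and the "bps/E" convention in
#' which the bits-per-second rate is divided by the expected number of
#' releases per time step.
#'
#' @param table An `"mro_state_table"` from [build_state_table()].
#' @param pi An `"mro_stationary"` from [stationary_distribution()], built
#'   from the same parameter set.
#' @return An object of class `"mro_rates"`: list with `R_per_step`, `R_bps`,
#'   `release_rate_per_step`, `R_E_per_release`, `R_E_bps`, `delta_ms`,
#'   `depressed`.
#' @seealso [energy_normalized_rate()], [rates_without_depression()], [mro()]
#' @export
mutual_information_rate <- function(table, pi) {
  stopifnot(inherits(table, "mro_state_table"),
            inherits(pi, "mro_stationary"))
  if (length(pi$pi) != length(table$p))
    stop("state table and stationary distribution have different state counts",
         call. = FALSE)
  Rj <- state_rate(table$p, table$q, table$params$alpha)
  R_step <- sum(Rj * pi$pi)
  odd <- seq.int(2L, length(pi$pi), by = 2L)  # states with a release last step
  rate_summary(R_step, sum(pi$pi[odd]), table$params$delta_ms,
               depressed = TRUE)
}

#' Energy-normalized information rate of the depressing release site
#'
#' Assuming one unit of energy per vesicle release, the information per unit
#' energy is the mutual information rate divided by the stationary release
#' rate, \eqn{R_D^{(E)} = \sum_j R_j \pi_j / \sum_{odd\,j} \pi_j}. Returns
#' the same `"mro_rates"` summary as [mutual_information_rate()] (both
#' conventions are always filled in); this wrapper exists so the
#' energy-normalized quantity can be requested by name.
#'
#' @inheritParams mutual_information_rate
#' @return An `"mro_rates"` object.
#' @export
energy_normalized_rate <- function(table, pi) {
  mutual_information_rate(table, pi)
}

#' Information rates of the release site without depression
#'
#' Closed-form baseline: with depression switched off the channel is
#' memoryless, \eqn{R_0 = h(\bar\alpha q_0 + \alpha p_0) - \bar\alpha h(q_0)
#' - \alpha h(p_0)} and \eqn{R_0^{(E)} = R_0 / (\bar\alpha q_0 + \alpha
#' p_0)}. No chain is constructed; `c`, `d`, `e`, `f` and `L` are ignored.
#'
#' @param params A [synapse_params()] object.
#' @return An `"mro_rates"` object with `depressed = FALSE`.
#' @export
rates_without_depression <- function(params) {
  stopifnot(inherits(params, "synapse_params"))
  R0 <- state_rate(params$p0, params$q0, params$alpha)
  rel0 <- (1 - params$alpha) * params$q0 + params$alpha * params$p0
  rate_summary(R0, rel0, params$delta_ms, depressed = FALSE)
}
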