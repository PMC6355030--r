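#' Parameter set for a single release site
#'
#' Bundles the full parameterization of a depressing release site: the
#' normalized input spike rate, the default synchronous (spike-evoked) and
#' asynchronous release probabilities, the multiplicative depression factors
#' applied after each release, the per-step fractional recovery coefficients
#' during quiescence, the memory length of the channel, and the time unit.
#'
#' All probabilities and coefficients live on a per-time-step scale: with a
#' time unit of `delta_ms` milliseconds, a presynaptic Poisson rate of
#' \eqn{\nu} Hz corresponds to `alpha` \eqn{= \nu \cdot} `delta_ms` / 1000,
#' and a recovery time constant of \eqn{\tau} ms corresponds to a recovery
#' coefficient \eqn{1 - e^{-\Delta/\tau}} (see [recovery_coefficient()]).
#' `rate_hz`, `tau_sync_ms` and `tau_async_ms` can be given instead of
#' `alpha`, `e` and `f` and are converted accordingly.
#'
#' The depression multipliers `c_sync` and `d_async` may be exactly 1
#' (undepressed release mode, used by the hippocampal and corticostriatal
#' presets); `q0` may be 0 or arbitrarily small (a synapse without
#' asynchronous release). All other parameters must lie strictly inside
#' (0, 1).
#'
#' @param alpha Probability of a presynaptic spike per time step (normalized
#'   input spike rate), in (0, 1).
#' @param p0 Default (maximum) synchronous release probability, in (0, 1).
#' @param q0 Default asynchronous release probability, in \[0, 1).
#' @param c_sync Depression multiplier for synchronous release, in (0, 1].
#' @param d_async Depression multiplier for asynchronous release, in (0, 1].
#' @param e_sync Recovery coefficient for synchronous release, in (0, 1).
#' @param f_async Recovery coefficient for asynchronous release, in (0, 1).
#' @param L Memory length: number of past release outcomes that determine
#'   the current state. Positive integer.
#' @param delta_ms Time unit of the model in milliseconds.
#' @param rate_hz Optional input spike rate in Hz, converted to `alpha`.
#' @param tau_sync_ms,tau_async_ms Optional recovery time constants in ms,
#'   converted to `e_sync` / `f_async`.
#'
#' @return An object of class `"synapse_params"`: a named list with elements
#'   `alpha`, `p0`, `q0`, `c`, `d`, `e`, `f`, `L`, `delta_ms`.
#' @seealso [mro()], [recovery_coefficient()], [read_synapse_params()]
#' @examples
#' synapse_params(alpha = 0.05, p0 = 0.4, q0 = 0.04,
#'                c_sync = 0.75, d_async = 1, e_sync = 0.039, f_async = 0.1,
#'                L = 20)
#' # equivalent, using physical units:
#' synapse_params(rate_hz = 5, p0 = 0.4, q0 = 0.04,
#'                c_sync = 0.75, d_async = 1, tau_sync_ms = 250,
#'                f_async = 0.1, L = 20)
#' @export
synapse_params <- function(alpha, p0, q0, c_sync, d_async, e_sync, f_async,
                           L = 20L, delta_ms = 10,
                           rate_hz = NULL, tau_sync_ms = NULL,
                           tau_async_ms = NULL) {
  if (!is.numeric(delta_ms) || length(delta_ms) != 1L || delta_ms <= 0)
    stop("'delta_ms' must be a single positive number", call. = FALSE)
  if (!is.null(rate_hz)) {
    if (!missing(alpha))
      stop("give either 'alpha' or 'rate_hz', not both", call. = FALSE)
    alpha <- rate_hz * delta_ms / 1000
  }
  if (!is.null(tau_sync_ms)) {
    if (!missing(e_sync))
      stop("give either 'e_sync' or 'tau_sync_ms', not both", call. = FALSE)
    e_sync <- recovery_coefficient(tau_sync_ms, delta_ms)
  }
  if (!is.null(tau_async_ms)) {
    if (!missing(f_async))
      stop("give either 'f_async' or 'tau_async_ms', not both", call. = FALSE)
    f_async <- recovery_coefficient(tau_async_ms, delta_ms)
  }
  chk01 <- function(x, nm, lo_open = TRUE, hi_closed = FALSE, lo_closed = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      stop(sprintf("'%s' must be a single number", nm), call. = FALSE)
    lo_ok <- if (lo_closed) x >= 0 else x > 0
    hi_ok <- if (hi_closed) x <= 1 else x < 1
    if (!lo_ok || !hi_ok)
      stop(sprintf("'%s' = %g is outside its admissible range", nm, x),
           call. = FALSE)
    as.numeric(x)
  }
  alpha   <- chk01(alpha, "alpha")
  p0      <- chk01(p0, "p0")
  q0      <- chk01(q0, "q0", lo_closed = TRUE)
  c_sync  <- chk01(c_sync, "c_sync", hi_closed = TRUE)
  d_async <- chk01(d_async, "d_async", hi_closed = TRUE)
  e_sync  <- chk01(e_sync, "e_sync")
  f_async <- chk01(f_async, "f_async")
  if (!is.numeric(L) || length(L) != 1L || L < 1 || L != round(L))
    stop("'L' must be a positive integer", call. = FALSE)
  structure(
    list(alpha = alpha, p0 = p0, q0 = q0, c = c_sync, d = d_async,
         e = e_sync, f = f_async, L = as.integer(L),
         delta_ms = as.numeric(delta_ms)),
    class = "synapse_params")
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("Release-site parameters (time unit ", x$delta_ms, " ms, memory L = ",
      x$L, ")\n", sep = "")
  cat(sprintf("  input spike rate     alpha = %-8.4g (%g Hz)\n",
              x$alpha, x$alpha * 1000 / x$delta_ms))
  cat(sprintf("  synchronous release  p0 = %-6.4g c = %-6.4g e = %-.4g\n",
              x$p0, x$c, x$e))
  cat(sprintf("  asynchronous release q0 = %-6.4g d = %-6.4g f = %-.4g\n",
              x$q0, x$d, x$f))
  invisible(x)
}

#' Recovery coefficient from a recovery time constant
#'
#' Converts an exponential recovery time constant \eqn{\tau} (in ms) into the
#' per-step recovery coefficient used by the discrete model,
#' \eqn{1 - e^{-\Delta/\tau}}. With this coefficient, one step of the
#' quiescent update `u + coef * (default - u)` is the exact one-step solution
#' of the relaxation ODE \eqn{du/dt = (u_0 - u)/\tau}.
#'
#' @param tau_ms Recovery time constant in milliseconds (positive).
#' @param delta_ms Time step in milliseconds (positive).
#' @return The recovery coefficient, a number in (0, 1).
#' @examples
#' recovery_coefficient(250, 10)   # ~0.039
#' recovery_coefficient(406, 10)   # ~0.024
#' recovery_coefficient(4200, 10)  # ~0.0024
#' @export
recovery_coefficient <- function(tau_ms, delta_ms = 10) {
  stopifnot(is.numeric(tau_ms), all(tau_ms > 0),
            is.numeric(delta_ms), all(delta_ms > 0))
  1 - exp(-delta_ms / tau_ms)
}

#' Read and write release-site parameters as flat YAML or JSON
#'
#' `write_synapse_params()` serializes a [synapse_params()] object to a flat
#' key-value file; `read_synapse_params()` reads one back. The format is
#' chosen from the file extension (`.yaml`/`.yml` or `.json`). On reading,
#' the alternative keys `rate_hz`, `tau_sync_ms` and `tau_async_ms` are
#' accepted in place of `alpha`, `e` and `f`.
#'
#' @param params A `synapse_params` object.
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @return `read_synapse_params()` returns a `synapse_params` object;
#'   `write_synapse_params()` returns `path` invisibly.
#' @export
write_synapse_params <- function(params, path) {
  stopifnot(inherits(params, "synapse_params"))
  x <- unclass(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("unrecognized config extension: ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_synapse_params
#' @export
read_synapse_params <- function(path) {
  x <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unrecognized config extension: ", path, call. = FALSE)
  args <- list()
  take <- function(key, to = key) {
    if (!is.null(x[[key]])) args[[to]] <<- x[[key]]
  }
  take("alpha"); take("rate_hz")
  take("p0"); take("q0")
  take("c", "c_sync"); take("d", "d_async")
  take("e", "e_sync"); take("f", "f_async")
  take("tau_sync_ms"); take("tau_async_ms")
  take("L"); take("delta_ms")
  do.call(synapse_params, args)
}
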