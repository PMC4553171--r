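#' Mackey-Glass system parameters
#'
#' Bundles the parameters of the Mackey-Glass delay-differential equation
#' \deqn{dx/dt = -\beta x(t) + \alpha x(t-\tau) / (1 + x(t-\tau)^{10})}
#' together with the integration settings used by [mackey_glass()].  The
#' defaults are the standard chaotic benchmark configuration: alpha = 0.2,
#' beta = 0.1, tau = 17 s, x(0) = 1.2, zero pre-history, a 2000 s horizon
#' sampled every second.
#'
#' @param alpha Production coefficient (> 0).
#' @param beta Decay-rate magnitude (> 0).  The decay term enters with a
#'   negative sign; see `literal_sign`.
#' @param tau Feedback delay in seconds (> 0); chaotic for `tau >= 17` at the
#'   default alpha/beta.
#' @param hill_exponent Exponent of the nonlinearity denominator (fixed at 10
#'   for the standard benchmark).
#' @param x0 Initial value x(0).
#' @param x_history Constant pre-history value on `[-tau, 0)` (default 0,
#'   the benchmark convention).
#' @param t_horizon Total simulated time in seconds.
#' @param sample_dt Output sampling interval in seconds; must be an integer
#'   multiple of `internal_dt`.
#' @param internal_dt Internal Runge-Kutta step in seconds; `tau` must be an
#'   integer multiple of it.
#' @param literal_sign If `TRUE`, use `+beta*x(t)` (growth) instead of the
#'   decay sign.  This form diverges for the default parameters and exists
#'   only for auditing the sign convention.
#' @return An object of class `"mg_params"` (a list of the above).
#' @export
#' @examples
#' p <- mg_params(t_horizon = 100)
#' ts <- mackey_glass(p)
#' head(ts)
mg_params <- function(alpha = 0.2, beta = 0.1, tau = 17, hill_exponent = 10,
                      x0 = 1.2, x_history = 0, t_horizon = 2000,
                      sample_dt = 1, internal_dt = 0.1,
                      literal_sign = FALSE) {
  stopifnot(is.finite(alpha), is.finite(beta), is.finite(tau),
            alpha >= 0, beta > 0, tau > 0, internal_dt > 0,
            t_horizon > 0, sample_dt > 0, hill_exponent > 0)
  if (!is_multiple(sample_dt, internal_dt))
    stop("'sample_dt' must be an integer multiple of 'internal_dt'")
  if (!is_multiple(tau, internal_dt))
    stop("'tau' must be an integer multiple of 'internal_dt'")
  structure(list(alpha = alpha, beta = beta, tau = tau,
                 hill_exponent = hill_exponent, x0 = x0,
                 x_history = x_history,
                 t_horizon = t_horizon, sample_dt = sample_dt,
                 internal_dt = internal_dt, literal_sign = literal_sign),
            class = "mg_params")
}

# integer-multiple check robust to floating-point spacing
is_multiple <- function(a, b, tol = 1e-8) {
  r <- a / b
  abs(r - round(r)) < tol
}

#' Mackey-Glass right-hand side
#'
#' Evaluates the time derivative of the Mackey-Glass equation given the
#' current and delayed state values.
#'
#' @param x_now Current value x(t).
#' @param x_delayed Delayed value x(t - tau).
#' @param params An [mg_params()] object.
#' @return The derivative dx/dt (may be vectorized over its first two
#'   arguments).
#' @export
mg_derivative <- function(x_now, x_delayed, params = mg_params()) {
  if (any(!is.finite(x_now)) || any(!is.finite(x_delayed)))
    stop("non-finite state passed to mg_derivative()")
  decay <- if (isTRUE(params$literal_sign)) params$beta else -params$beta
  decay * x_now +
    params$alpha * x_delayed / (1 + x_delayed^params$hill_exponent)
}

# derivative of the delayed-feedback nonlinearity g(u) = u / (1 + u^m),
# used by the variational (tangent) integrator in lyapunov_mg()
mg_feedback_deriv <- function(u, m = 10) {
  um <- u^m
  (1 - (m - 1) * um) / (1 + um)^2
}

#' Integrate the Mackey-Glass delay-differential equation
#'
#' Classical fourth-order Runge-Kutta integration on the internal grid with a
#' delay-history buffer.  Delayed values falling between grid points (the
#' half-step stages) are interpolated with a cubic Hermite polynomial on the
#' stored values and derivatives, keeping the interpolation error at the
#' same order as the integrator.  The pre-history is identically zero on
#' `[-tau, 0)` with `x(0) = x0`, and no transient is discarded unless
#' `burn_in > 0`.
#'
#' @param params An [mg_params()] object.
#' @param burn_in Time (seconds) to integrate and discard before `t = 0` of
#'   the returned series.  Default 0 (the benchmark convention).
#' @param guard Divergence guard: integration aborts with an error once
#'   `|x|` exceeds this value (fires, e.g., under `literal_sign = TRUE`).
#' @return A data frame of class `"mg_series"` with columns `t` (seconds,
#'   uniform) and `x`, of length `t_horizon / sample_dt + 1`.
#' @export
#' @examples
#' ts <- mackey_glass(mg_params(t_horizon = 200))
#' range(ts$x)
mackey_glass <- function(params = mg_params(), burn_in = 0, guard = 1e6) {
  h <- params$internal_dt
  n_tau <- as.integer(round(params$tau / h))
  n_steps <- as.integer(round((params$t_horizon + burn_in) / h))
  # full grid including pre-history slots [-tau, 0); index offset n_tau + 1 is t = 0
  x <- numeric(n_tau + n_steps + 1L)
  off <- n_tau + 1L
  hist0 <- if (is.null(params$x_history)) 0 else params$x_history
  x[seq_len(n_tau)] <- hist0      # pre-history on [-tau, 0)
  x[off] <- params$x0

  a <- params$alpha
  m <- params$hill_exponent
  bsign <- if (isTRUE(params$literal_sign)) params$beta else -params$beta
  f <- function(xn, xd) bsign * xn + a * xd / (1 + xd^m)

  # stored derivatives for Hermite interpolation; constant pre-history has
  # derivative zero
  dx <- numeric(length(x))

  for (i in seq_len(n_steps)) {
    j <- off + i - 1L            # index of x(t)
    k0 <- j - n_tau
    xd0 <- x[k0]                 # x(t - tau)
    xd1 <- x[k0 + 1L]            # x(t + h - tau)
    dxr <- dx[k0 + 1L]
    if (k0 + 1L == off) {
      # the delayed interval ends exactly at t = 0, where the solution jumps
      # from the pre-history to x0; stages inside this step must see the
      # left limit or the jump costs an O(h) error that chaos then amplifies
      xd1 <- hist0; dxr <- 0
    }
    xn <- x[j]
    k1 <- f(xn, xd0)
    dx[j] <- k1                  # derivative record (before xdh, for tau = h)
    # x(t + h/2 - tau): cubic Hermite at the interval midpoint
    xdh <- 0.5 * (xd0 + xd1) + 0.125 * h * (dx[k0] - dxr)
    k2 <- f(xn + 0.5 * h * k1, xdh)
    k3 <- f(xn + 0.5 * h * k2, xdh)
    k4 <- f(xn + h * k3, xd1)
    xi <- xn + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(xi) || abs(xi) > guard)
      stop("Mackey-Glass integration diverged (|x| > ", guard,
           " at t = ", (i * h) - burn_in, "); unstable parameterization")
    x[j + 1L] <- xi
  }

  keep_every <- as.integer(round(params$sample_dt / h))
  i0 <- off + as.integer(round(burn_in / h))
  idx <- seq.int(i0, length(x), by = keep_every)
  out <- data.frame(t = (idx - i0) * h, x = x[idx])
  class(out) <- c("mg_series", "data.frame")
  out
}

#' Decimate a uniformly sampled series
#'
#' Keeps every k-th point so that the output spacing equals `every`; original
#' time stamps are preserved.
#'
#' @param ts A data frame with columns `t` and `x`, uniformly sampled.
#' @param every Desired output spacing in seconds; must be an integer
#'   multiple of the native spacing.
#' @return The decimated series (same class as the input).
#' @export
sample_series <- function(ts, every) {
  dt <- series_spacing(ts)
  if (!is_multiple(every, dt))
    stop("'every' (", every, ") is not an integer multiple of the native spacing (",
         dt, ")")
  k <- as.integer(round(every / dt))
  ts[seq.int(1L, nrow(ts), by = k), , drop = FALSE]
}

# uniform spacing of a t,x series, with validation
series_spacing <- function(ts) {
  stopifnot(is.data.frame(ts), all(c("t", "x") %in% names(ts)), nrow(ts) >= 2)
  d <- diff(ts$t)
  if (any(d <= 0) || max(abs(d - d[1])) > 1e-8 * max(1, abs(d[1])))
    stop("series time stamps must be strictly increasing and uniformly spaced")
  d[1]
}

#' Read or write a series as two-column delimited text
#'
#' The on-disk format is CSV with header `t,x` at full float precision.
#'
#' @param ts A data frame with columns `t` and `x`.
#' @param path File path.
#' @return `read_series` returns the series; `write_series` returns `path`
#'   invisibly.
#' @export
write_series <- function(ts, path) {
  stopifnot(all(c("t", "x") %in% names(ts)))
  utils::write.csv(ts[, c("t", "x")], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  out <- utils::read.csv(path)
  if (!all(c("t", "x") %in% names(out)))
    stop("expected columns 't' and 'x' in ", path)
  if (any(!is.finite(out$x))) stop("non-finite values in ", path)
  series_spacing(out)  # validates uniform spacing
  class(out) <- c("mg_series", "data.frame")
  out
}
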