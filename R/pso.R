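#' Particle swarm optimizer settings
#'
#' Tuning constants of the inertia-weight PSO used for network training.
#' Defaults are the benchmark configuration: 50 particles, 1500 iterations,
#' cognitive and social constants 1.494, inertia weight decreasing linearly
#' from 0.7 to 0.5, velocity clamp 12, stopping error 1e-3.
#'
#' @param n_particles Swarm size (>= 2).
#' @param k_max Maximum number of iterations.
#' @param c1,c2 Cognitive and social acceleration constants.
#' @param omega_max,omega_min Initial and final inertia weights of the
#'   linear schedule.
#' @param v_max Component-wise velocity clamp (> 0).
#' @param min_error Stop early once the global-best fitness falls below this.
#' @return An object of class `"pso_control"`.
#' @export
pso_control <- function(n_particles = 50, k_max = 1500, c1 = 1.494,
                        c2 = 1.494, omega_max = 0.7, omega_min = 0.5,
                        v_max = 12, min_error = 1e-3) {
  stopifnot(n_particles >= 2, k_max >= 1, omega_max >= omega_min, v_max > 0,
            c1 >= 0, c2 >= 0, min_error >= 0)
  structure(list(n_particles = as.integer(n_particles),
                 k_max = as.integer(k_max), c1 = c1, c2 = c2,
                 omega_max = omega_max, omega_min = omega_min,
                 v_max = v_max, min_error = min_error),
            class = "pso_control")
}

#' Linearly decreasing inertia weight
#'
#' `omega(k) = omega_max - (omega_max - omega_min) * k / (k_max - 1)` for
#' iteration index `k` in `0 .. k_max - 1`, so the schedule starts at
#' `omega_max` and ends at `omega_min`.
#'
#' @param k Zero-based iteration index.
#' @param control A [pso_control()].
#' @export
inertia_at <- function(k, control) {
  if (any(k < 0) || any(k >= control$k_max))
    stop("iteration index out of range [0, k_max)")
  if (control$k_max == 1L) return(rep(control$omega_max, length(k)))
  control$omega_max -
    (control$omega_max - control$omega_min) * k / (control$k_max - 1)
}

#' Minimize a function by inertia-weight particle swarm optimization
#'
#' The standard synchronous PSO: velocities are updated with per-dimension
#' uniform random factors toward each particle's personal best and the
#' swarm's global best, clamped to `[-v_max, v_max]`; positions are clamped
#' into the search box.  Personal bests update on strict improvement and the
#' global best is chosen synchronously after all fitness evaluations (ties
#' broken by lowest particle index), so the global-best fitness is
#' monotonically non-increasing.
#'
#' @param fn Objective.  Either a function of one position vector, or (with
#'   `vectorized = TRUE`) a function taking a `dim x n_particles` matrix and
#'   returning a fitness per column.
#' @param lower,upper Search-box bounds, each a scalar or a vector of
#'   length `dim`.
#' @param dim Problem dimension; defaults to the longer of the two bound
#'   vectors (so scalar bounds need an explicit `dim`).
#' @param control A [pso_control()].
#' @param seed Optional integer seed for reproducibility.
#' @param vectorized Whether `fn` consumes all particle positions at once.
#' @param init_lower,init_upper Box for the initial particle positions;
#'   defaults to the full search box.  A narrower initial box keeps the
#'   search bounds as clamps while starting the swarm in a responsive region
#'   of the objective.
#' @param v_init Half-width of the uniform initial velocity draw
#'   (default `v_max`).
#' @return A list: `par` (global-best position), `value` (its fitness),
#'   `history` (global-best fitness after each iteration), `iter_best`
#'   (best fitness among particles at each iteration), `iterations`,
#'   `converged` (`TRUE` if `min_error` was reached).
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' fit <- pso_optimize(sphere, lower = -5, upper = 5,
#'                     control = pso_control(n_particles = 20, k_max = 200),
#'                     seed = 1)
#' fit$value
pso_optimize <- function(fn, lower, upper, control = pso_control(),
                         seed = NULL, vectorized = FALSE,
                         dim = max(length(lower), length(upper)),
                         init_lower = lower, init_upper = upper,
                         v_init = control$v_max) {
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  d <- dim
  lower <- rep_len(lower, d); upper <- rep_len(upper, d)
  init_lower <- pmax(rep_len(init_lower, d), lower)
  init_upper <- pmin(rep_len(init_upper, d), upper)
  stopifnot(all(upper > lower), all(init_upper >= init_lower), v_init >= 0)
  np <- control$n_particles
  vmax <- control$v_max

  evaluate <- if (vectorized) function(S) as.numeric(fn(S))
              else function(S) apply(S, 2L, fn)

  # positions: d x np, uniform in the initial box; velocities uniform draws
  S <- matrix(stats::runif(d * np, init_lower, init_upper), d, np)
  V <- matrix(stats::runif(d * np, -v_init, v_init), d, np)
  fit <- evaluate(S)
  P <- S; pfit <- fit                       # personal bests
  g <- which.min(pfit)                      # ties: which.min takes lowest index
  gbest <- P[, g]; gfit <- pfit[g]

  history <- numeric(control$k_max)
  iter_best <- numeric(control$k_max)
  k_run <- 0L
  for (k in seq_len(control$k_max)) {
    w <- inertia_at(k - 1L, control)
    R1 <- matrix(stats::runif(d * np), d, np)
    R2 <- matrix(stats::runif(d * np), d, np)
    V <- w * V + control$c1 * R1 * (P - S) + control$c2 * R2 * (gbest - S)
    V[V > vmax] <- vmax; V[V < -vmax] <- -vmax
    # flush vanishing velocities: once the swarm has collapsed they only
    # feed subnormal arithmetic, which is both meaningless and very slow
    V[abs(V) < 1e-12 * vmax] <- 0
    S <- S + V
    S[] <- pmin(pmax(S, lower), upper)      # hard clip to the box
    fit <- evaluate(S)
    improved <- fit < pfit
    P[, improved] <- S[, improved]
    pfit[improved] <- fit[improved]
    g <- which.min(pfit)
    if (pfit[g] < gfit) { gbest <- P[, g]; gfit <- pfit[g] }
    iter_best[k] <- min(fit)
    history[k] <- gfit
    k_run <- k
    if (gfit < control$min_error) break
  }
  list(par = gbest, value = gfit, history = history[seq_len(k_run)],
       iter_best = iter_best[seq_len(k_run)], iterations = k_run,
       converged = gfit < control$min_error)
}

#' Root-mean-square prediction error
#'
#' `sqrt(mean((predicted - observed)^2))`, the swarm's fitness function.
#' With `sigma` supplied, residuals are standardized first and the result is
#' the noise-weighted error `sqrt(mean(residual^2 / sigma^2))`; for constant
#' `sigma` this equals `rmse / sigma`.  Setting `literal = TRUE` omits the
#' radical over the mean, returning the mean of squared standardized
#' residuals instead (the weighted form written without an explicit root).
#'
#' @param predicted,observed Numeric vectors of equal length (raw scale).
#' @param sigma Optional per-element noise level(s), all > 0.
#' @param literal See above; only meaningful with `sigma`.
#' @export
rmse <- function(predicted, observed, sigma = NULL, literal = FALSE) {
  if (length(predicted) != length(observed) || length(observed) == 0L)
    stop("'predicted' and 'observed' must be non-empty and of equal length")
  r2 <- (predicted - observed)^2
  if (is.null(sigma)) return(sqrt(mean(r2)))
  if (any(sigma <= 0)) stop("all 'sigma' values must be > 0")
  w <- mean(r2 / sigma^2)
  if (literal) w else sqrt(w)
}
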