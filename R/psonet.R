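#' Fit a swarm-optimized neural forecaster
#'
#' Trains a single-hidden-layer feed-forward network (tanh hidden units,
#' linear output) by inertia-weight particle swarm optimization, minimizing
#' the root-mean-square prediction error on the training patterns.  Each
#' swarm particle is a flat weight/bias vector; weights are searched in
#' `[-100, 100]` and biases in `[-10, 10]`.  Inputs and targets are
#' normalized to `[-1, 1]` with a min-max scaler fitted on the training data
#' only; the fitness and all reported errors are computed on the raw
#' (denormalized) scale.
#'
#' Because the swarm search is stochastic, `restarts` independent runs are
#' performed (with seeds derived deterministically from `seed`) and the run
#' with the lowest training error is kept.
#'
#' @param x Training inputs: a numeric matrix (one row per pattern) or an
#'   `"embedded"` dataset from [embed_series()] (in which case `y` is taken
#'   from it).
#' @param y Training targets (ignored when `x` is an `"embedded"` dataset).
#' @param hidden Number of hidden neurons.
#' @param validation Optional held-out data, an `"embedded"` dataset or a
#'   `list(x = , y = )`; used only to report a validation error, never to
#'   drive the search.
#' @param control A [pso_control()] with the swarm settings.
#' @param restarts Number of independent swarm runs (>= 1).
#' @param select Which restart supplies the returned network: `"train"`
#'   (lowest training error, the default) or `"valid"` (lowest validation
#'   error, the reporting convention for prediction-phase benchmarks;
#'   requires `validation`).  The search itself never sees validation data
#'   either way.
#' @param seed Integer seed; the fit is fully deterministic given
#'   `(seed, control, data)`.
#' @param fitness_sigma Optional per-pattern noise level(s) for the
#'   noise-weighted fitness `sqrt(mean(residual^2 / sigma^2))`; with a
#'   constant level this rescales the objective without changing its
#'   minimizer.
#' @param weight_bound,bias_bound Half-widths of the search box.
#' @param init_range Half-width of the uniform box for initial particle
#'   positions and velocities.  The default 1 starts every hidden unit in
#'   the responsive (unsaturated) part of its tanh nonlinearity; the full
#'   weight/bias ranges remain in force as hard clamps during the search.
#' @return An object of class `"psonet"`.  Key components: `theta` (flat
#'   parameter vector of the best network), `topology`, `scaler`,
#'   `rmse_train`, `rmse_valid` (if validation supplied), `history`
#'   (global-best fitness per iteration of the winning run), `restart_rmse`
#'   (training error of every restart), `seed`.
#' @seealso [predict.psonet()], [pso_control()], [embed_series()]
#' @export
#' @examples
#' ts <- mackey_glass(mg_params(t_horizon = 300))
#' ds <- split_embedded(embed_series(ts), n_train = 200)
#' fit <- psonet(ds$train, hidden = 4, validation = ds$valid,
#'               control = pso_control(k_max = 50), seed = 1)
#' fit
psonet <- function(x, y = NULL, hidden = 6, validation = NULL,
                   control = pso_control(), restarts = 1, seed = NULL,
                   select = c("train", "valid"), fitness_sigma = NULL,
                   weight_bound = 100, bias_bound = 10, init_range = 1) {
  select <- match.arg(select)
  cl <- match.call()
  dat <- as_xy(x, y)
  if (nrow(dat$x) < 1L) stop("empty training set")
  if (stats::sd(dat$y) == 0 && diff(range(dat$x)) == 0)
    stop("degenerate training set: constant inputs and targets")
  vdat <- if (!is.null(validation)) as_xy(validation) else NULL
  stopifnot(restarts >= 1)

  topology <- nn_topology(n_in = ncol(dat$x), n_hidden = hidden)
  scaler <- fit_scaler(c(dat$x, dat$y))
  xn <- scaler_apply(scaler, dat$x)
  yraw <- dat$y
  bounds <- nn_bounds(topology, weight_bound, bias_bound)

  # vectorized swarm fitness: raw-scale RMSE of every particle at once
  fitness <- function(Theta) {
    pred <- scaler_invert(scaler, nn_forward_batch(Theta, topology, xn))
    r2 <- (pred - yraw)^2
    out <- colMeans(r2)
    if (!is.null(fitness_sigma)) out <- colMeans(r2 / fitness_sigma^2)
    sqrt(out)
  }

  if (is.null(seed)) seed <- as.integer(stats::runif(1, 1, 2^31 - 1))
  runs <- vector("list", restarts)
  for (r in seq_len(restarts)) {
    runs[[r]] <- pso_optimize(fitness, lower = -bounds, upper = bounds,
                              control = control,
                              seed = stage_seed(seed, "restart", r),
                              vectorized = TRUE,
                              init_lower = -init_range,
                              init_upper = init_range,
                              v_init = init_range)
  }
  restart_rmse <- vapply(runs, `[[`, numeric(1), "value")

  # per-restart validation error of each run's best network
  restart_rmse_valid <- NULL
  if (!is.null(vdat)) {
    vn <- scaler_apply(scaler, vdat$x)
    restart_rmse_valid <- vapply(runs, function(r) {
      rmse(scaler_invert(scaler, nn_forward(r$par, topology, vn)), vdat$y)
    }, numeric(1))
  }
  if (select == "valid") {
    if (is.null(vdat)) stop("select = \"valid\" requires 'validation'")
    best <- which.min(restart_rmse_valid)
  } else best <- which.min(restart_rmse)
  run <- runs[[best]]

  obj <- structure(list(theta = run$par, topology = topology,
                        scaler = scaler, control = control,
                        rmse_train = run$value, history = run$history,
                        iter_best = run$iter_best,
                        iterations = run$iterations,
                        converged = run$converged,
                        restart_rmse = restart_rmse,
                        restart_rmse_valid = restart_rmse_valid,
                        best_restart = best, select = select,
                        seed = seed, x = dat$x, y = dat$y,
                        validation = vdat, call = cl),
                   class = "psonet")
  if (!is.null(vdat)) obj$rmse_valid <- restart_rmse_valid[best]
  obj$rmse_train <- restart_rmse[best]
  obj
}

# coerce the accepted input forms to list(x = matrix, y = numeric)
as_xy <- function(x, y = NULL) {
  if (inherits(x, "embedded"))
    return(list(x = x$inputs, y = x$targets, t = x$base_times))
  if (is.list(x) && !is.null(x$x))
    return(list(x = as.matrix(x$x), y = as.numeric(x$y), t = x$t))
  x <- as.matrix(x)
  if (is.null(y)) stop("'y' is required when 'x' is a plain matrix")
  if (nrow(x) != length(y)) stop("'x' and 'y' sizes disagree")
  list(x = x, y = as.numeric(y), t = NULL)
}

# deterministic derivation of stage seeds from a master seed: adding stages
# or repetitions never perturbs the seeds of other stages
stage_seed <- function(master, stage, rep = 0) {
  ch <- utf8ToInt(stage)
  h <- sum(ch * seq_along(ch)) %% 2147483647
  as.integer((as.double(master) %% 2147483647 * 48271 + h * 1009 +
                rep * 99991) %% 2147483647)
}

#' Predict from a fitted swarm-optimized network
#'
#' The plain prediction is the deterministic forward pass (on the raw data
#' scale).  With `se = TRUE` the Monte-Carlo stochastic predictor is used
#' instead: each input vector is resampled `nsim` times with i.i.d. Gaussian
#' perturbations of standard deviation `sigma` per component (noise applied
#' on the raw scale, before normalization), the network is evaluated on
#' every copy, and the ensemble is summarized by its mean (`fit`) and its
#' standard deviation about that mean (`se`), the per-point prediction
#' uncertainty.
#'
#' `literal_second_moment = TRUE` replaces `se` by the square root of the raw
#' ensemble second moment `sqrt(mean(y_k^2))`; for series with values of
#' order one this is dominated by the signal itself rather than its spread,
#' and is provided only to audit that reading of the uncertainty formula.
#'
#' @param object A fitted `"psonet"`.
#' @param newdata Inputs: a matrix, an `"embedded"` dataset, or `NULL` for
#'   the training inputs.
#' @param se If `TRUE`, run the stochastic ensemble predictor.
#' @param sigma Input noise level for the ensemble (required if `se = TRUE`
#'   and > 0 for a nondegenerate ensemble).
#' @param nsim Ensemble size (>= 2).
#' @param seed Optional seed for the ensemble draws.
#' @param literal_second_moment See above.
#' @param ... Unused.
#' @return A numeric vector of predictions, or (with `se = TRUE`) a data
#'   frame with columns `fit` (ensemble mean), `se` (uncertainty), `point`
#'   (the deterministic prediction) and, when known, `t`.
#' @export
predict.psonet <- function(object, newdata = NULL, se = FALSE, sigma = 0,
                           nsim = 1000, seed = NULL,
                           literal_second_moment = FALSE, ...) {
  if (any(!is.finite(object$theta)))
    stop("network parameters are not finite; refusing to predict")
  tstamp <- NULL
  if (is.null(newdata)) {
    X <- object$x
  } else if (inherits(newdata, "embedded")) {
    X <- newdata$inputs; tstamp <- newdata$base_times
  } else {
    X <- as.matrix(newdata)
  }
  point <- scaler_invert(object$scaler,
                         nn_forward(object$theta, object$topology,
                                    scaler_apply(object$scaler, X)))
  if (!se) return(point)

  stopifnot(nsim >= 2, sigma >= 0)
  if (sigma == 0) {
    # degenerate ensemble: every copy is the input itself
    se_hat <- if (literal_second_moment) abs(point) else rep(0, length(point))
    out <- data.frame(fit = point, se = se_hat, point = point)
    if (!is.null(tstamp)) out <- cbind(t = tstamp, out)
    return(out)
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  n <- nrow(X)
  s <- numeric(n); s2 <- numeric(n)
  for (k in seq_len(nsim)) {
    Xk <- X + matrix(stats::rnorm(length(X), 0, sigma), n, ncol(X))
    yk <- scaler_invert(object$scaler,
                        nn_forward(object$theta, object$topology,
                                   scaler_apply(object$scaler, Xk)))
    s <- s + yk; s2 <- s2 + yk^2
  }
  fit <- s / nsim
  # ensemble spread about the mean (population form); guard tiny negatives
  var_hat <- pmax(s2 / nsim - fit^2, 0)
  se_hat <- if (literal_second_moment) sqrt(s2 / nsim) else sqrt(var_hat)
  out <- data.frame(fit = fit, se = se_hat, point = point)
  if (!is.null(tstamp)) out <- cbind(t = tstamp, out)
  out
}

#' Gaussian input-resampling ensemble
#'
#' Draws `nsim` perturbed copies of each input vector,
#' `x[i,] + N(0, sigma^2)` independently per component and copy.  This is
#' the input side of the stochastic predictor, exposed for direct use and
#' testing.
#'
#' @param inputs Numeric matrix (patterns in rows).
#' @param sigma Perturbation standard deviation (>= 0).
#' @param nsim Number of copies.
#' @param seed Optional seed.
#' @return A 3-d array `[pattern, component, copy]`.
#' @export
perturb_inputs <- function(inputs, sigma, nsim, seed = NULL) {
  stopifnot(sigma >= 0, nsim >= 1)
  inputs <- as.matrix(inputs)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  out <- array(NA_real_, c(nrow(inputs), ncol(inputs), nsim))
  for (k in seq_len(nsim))
    out[, , k] <- inputs +
      matrix(stats::rnorm(length(inputs), 0, sigma), nrow(inputs))
  out
}

#' One-sigma coverage fraction
#'
#' Fraction of points whose true value lies within one reported uncertainty
#' of the prediction: `mean(|truth - fit| <= se)`.  For well-calibrated
#' Gaussian uncertainties this is about 0.683.
#'
#' @param truth Observed values.
#' @param fit Predictions.
#' @param se Per-point uncertainties (>= 0).
#' @export
coverage_fraction <- function(truth, fit, se) {
  if (length(truth) != length(fit) || length(fit) != length(se))
    stop("'truth', 'fit' and 'se' must be aligned")
  if (any(se < 0)) stop("'se' must be non-negative")
  mean(abs(truth - fit) <= se)
}

#' @export
print.psonet <- function(x, ...) {
  cat("Swarm-optimized neural forecaster (", x$topology$n_in, "-",
      x$topology$n_hidden, "-", x$topology$n_out, ")\n", sep = "")
  cat("  training RMSE:  ", format(x$rmse_train, digits = 4), "\n", sep = "")
  if (!is.null(x$rmse_valid))
    cat("  validation RMSE:", format(x$rmse_valid, digits = 4), "\n")
  cat("  restarts: ", length(x$restart_rmse), " (best: #", x$best_restart,
      "), iterations: ", x$iterations, "\n", sep = "")
  invisible(x)
}

#' @export
summary.psonet <- function(object, ...) {
  structure(list(fit = object), class = "summary.psonet")
}

#' @export
print.summary.psonet <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  swarm: ", f$control$n_particles, " particles, c1 = c2 = ",
      f$control$c1, ", omega ", f$control$omega_max, " -> ",
      f$control$omega_min, ", v_max = ", f$control$v_max, "\n", sep = "")
  cat("  restart training RMSEs: ",
      paste(format(f$restart_rmse, digits = 4), collapse = ", "), "\n",
      sep = "")
  cat("  parameters: ", nn_n_params(f$topology), " (seed ", f$seed, ")\n",
      sep = "")
  invisible(x)
}

#' @export
coef.psonet <- function(object, ...) {
  p <- nn_unpack(object$theta, object$topology)
  nm <- c(paste0("Wh[", rep(seq_len(object$topology$n_hidden),
                            each = object$topology$n_in), ",",
                 rep(seq_len(object$topology$n_in),
                     object$topology$n_hidden), "]"),
          paste0("bh[", seq_len(object$topology$n_hidden), "]"),
          paste0("wo[", seq_len(object$topology$n_hidden), "]"), "bo")
  stats::setNames(object$theta, nm)
}

#' @export
fitted.psonet <- function(object, ...) predict(object)

#' @export
residuals.psonet <- function(object, ...) object$y - predict(object)

#' Diagnostic plots for a fitted swarm network
#'
#' Two panels: the global-best training error against swarm iteration (log
#' scale), and observed versus predicted targets (validation set when
#' available, else training).
#'
#' @param x A `"psonet"` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.psonet <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(x$history), x$history, type = "l", log = "y",
                 xlab = "iteration", ylab = "best training RMSE",
                 main = "Swarm convergence", ...)
  if (!is.null(x$validation)) {
    obs <- x$validation$y; pr <- predict(x, x$validation$x)
    lab <- "validation"
  } else {
    obs <- x$y; pr <- predict(x); lab <- "training"
  }
  graphics::plot(obs, pr, xlab = paste("observed (", lab, ")"),
                 ylab = "predicted", main = "Prediction", pch = 20,
                 cex = 0.5)
  graphics::abline(0, 1, col = "grey")
  invisible(x)
}

#' Simulate prediction ensembles from the stochastic predictor
#'
#' Returns the raw Monte-Carlo output ensemble: for each input pattern,
#' `nsim` network outputs on Gaussian-perturbed copies of that input.
#' Column means reproduce the stochastic prediction; row-wise standard
#' deviations reproduce its uncertainty.
#'
#' @param object A fitted `"psonet"`.
#' @param nsim Ensemble size.
#' @param seed Optional seed.
#' @param newdata Inputs (matrix or `"embedded"`); default training inputs.
#' @param sigma Input noise level.
#' @param ... Unused.
#' @return A matrix `[pattern, draw]` of raw-scale outputs.
#' @export
simulate.psonet <- function(object, nsim = 1000, seed = NULL,
                            newdata = NULL, sigma = 0, ...) {
  X <- if (is.null(newdata)) object$x
       else if (inherits(newdata, "embedded")) newdata$inputs
       else as.matrix(newdata)
  ens <- perturb_inputs(X, sigma, nsim, seed = seed)
  out <- matrix(NA_real_, nrow(X), nsim)
  for (k in seq_len(nsim))
    out[, k] <- scaler_invert(object$scaler,
                              nn_forward(object$theta, object$topology,
                                         scaler_apply(object$scaler,
                                                      ens[, , k, drop = TRUE])))
  out
}
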