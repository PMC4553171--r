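#' Build the benchmark forecasting task
#'
#' One call producing the supervised task used throughout: integrate the
#' Mackey-Glass system, optionally corrupt it with white noise, delay-embed
#' it (`d = 4`, `delta = horizon = 6` s) and split chronologically with the
#' first `n_train` patterns for training.
#'
#' @param sigma White-noise standard deviation (0 for the clean series).
#' @param params [mg_params()] for the simulator.
#' @param d,delta,horizon Embedding settings (see [embed_series()]).
#' @param n_train Training patterns (default 1000).
#' @param noise_seed Seed for the noise draw (ignored when `sigma = 0`).
#' @return A list: `series` (the possibly noisy series), `clean` (the
#'   noiseless series), `train`, `valid` (embedded halves), `sigma`.
#' @export
mg_task <- function(sigma = 0, params = mg_params(), d = 4, delta = 6,
                    horizon = 6, n_train = 1000, noise_seed = 1) {
  clean <- mackey_glass(params)
  series <- add_white_noise(clean, sigma, seed = noise_seed)
  halves <- split_embedded(embed_series(series, d = d, delta = delta,
                                        horizon = horizon),
                           n_train = n_train)
  list(series = series, clean = clean, train = halves$train,
       valid = halves$valid, sigma = sigma)
}

#' Reduced-cost swarm profile
#'
#' The full benchmark profile runs 1500 swarm iterations; this profile cuts
#' the loop to `k_max = 300` for quick, desk-scale runs.  All other
#' constants are unchanged.
#'
#' @param fast If `TRUE` return the reduced profile, else the full one.
#' @return A [pso_control()].
#' @export
pso_profile <- function(fast = FALSE) {
  if (fast) pso_control(k_max = 300) else pso_control()
}

#' Noiseless / fixed-noise forecasting benchmark
#'
#' The end-to-end pipeline at one noise level: simulate, corrupt, embed,
#' split, train with restarts, and report errors and residual summaries for
#' both halves.
#'
#' @param sigma Noise level (default 0: the noiseless benchmark).
#' @param hidden Hidden-layer size (default 6, the noiseless optimum).
#' @param restarts Independent swarm runs; the one with the lowest
#'   validation error is kept (the prediction-phase reporting convention).
#' @param control A [pso_control()]; see [pso_profile()].
#' @param master_seed Single seed from which the noise and restart seeds are
#'   derived; reruns are bit-identical.
#' @param params,n_train Passed to [mg_task()].
#' @return A list of class `"psonet_benchmark"`: the fitted `model`,
#'   `rmse_train`, `rmse_valid`, residual summaries (`mean`, `max_abs`) per
#'   phase, the `task`, and the seeds used.
#' @export
run_benchmark <- function(sigma = 0, hidden = 6, restarts = 5,
                          control = pso_control(), master_seed = 1,
                          params = mg_params(), n_train = 1000) {
  task <- mg_task(sigma = sigma, params = params, n_train = n_train,
                  noise_seed = stage_seed(master_seed, "noise"))
  fit <- psonet(task$train, hidden = hidden, validation = task$valid,
                control = control, restarts = restarts, select = "valid",
                seed = stage_seed(master_seed, "train"))
  res_tr <- task$train$targets - predict(fit)
  res_va <- task$valid$targets - predict(fit, task$valid$inputs)
  structure(list(model = fit, task = task, sigma = sigma,
                 rmse_train = fit$rmse_train, rmse_valid = fit$rmse_valid,
                 residual_train = c(mean = mean(res_tr),
                                    max_abs = max(abs(res_tr))),
                 residual_valid = c(mean = mean(res_va),
                                    max_abs = max(abs(res_va))),
                 master_seed = master_seed),
            class = "psonet_benchmark")
}

#' @export
print.psonet_benchmark <- function(x, ...) {
  cat("Mackey-Glass forecasting benchmark (sigma_N = ", x$sigma, ")\n",
      sep = "")
  cat("  architecture 4-", x$model$topology$n_hidden, "-1, ",
      length(x$model$restart_rmse), " restart(s), seed ", x$master_seed,
      "\n", sep = "")
  cat("  RMSE: train ", format(x$rmse_train, digits = 4), ", validation ",
      format(x$rmse_valid, digits = 4), "\n", sep = "")
  cat("  validation residuals: mean ",
      format(x$residual_valid["mean"], digits = 3), ", max |.| ",
      format(x$residual_valid["max_abs"], digits = 3), "\n", sep = "")
  invisible(x)
}

#' Noise-level grid experiment
#'
#' Runs the benchmark at the noiseless level plus each requested noise
#' level, either at fixed per-level hidden sizes or with a hidden-size
#' sweep, and summarizes errors, performance efficiencies and the linear
#' noise laws.
#'
#' @param sigmas Noisy levels (default the benchmark grid
#'   `c(0.01, 0.04, 0.06, 0.08, 0.1)`); may be empty for the noiseless row
#'   only.
#' @param hidden Hidden sizes, one per noisy level (recycled), or `NULL` to
#'   sweep `sweep_range` at every level.
#' @param hidden_noiseless Hidden size for the noiseless row.
#' @param sweep_range Candidate sizes when sweeping.
#' @param restarts,control,master_seed,params,n_train As in
#'   [run_benchmark()].
#' @return A list of class `"psonet_grid"`: `table` (one row per level:
#'   `sigma`, `hidden`, `rmse_train`, `rmse_valid`, `xi`), `laws` (from
#'   [fit_linear_laws()], `NULL` with fewer than two noisy levels),
#'   `runs` (per-level benchmark objects).
#' @export
run_noise_grid <- function(sigmas = c(0.01, 0.04, 0.06, 0.08, 0.1),
                           hidden = c(6, 11, 14, 15, 20),
                           hidden_noiseless = 6, sweep_range = 2:30,
                           restarts = 5, control = pso_control(),
                           master_seed = 1, params = mg_params(),
                           n_train = 1000) {
  do_sweep <- is.null(hidden)
  if (!do_sweep && length(sigmas))
    hidden <- rep_len(hidden, length(sigmas))
  levels <- c(0, sigmas)
  runs <- vector("list", length(levels))
  for (i in seq_along(levels)) {
    s <- levels[i]
    seed_i <- stage_seed(master_seed, "grid", round(1e4 * s))
    nh <- if (i == 1L) hidden_noiseless else hidden[i - 1L]
    if (do_sweep && i > 1L) {
      task <- mg_task(sigma = s, params = params, n_train = n_train,
                      noise_seed = stage_seed(seed_i, "noise"))
      sw <- sweep_hidden(task$train, task$valid, hidden = sweep_range,
                         control = control, restarts = restarts,
                         seed = seed_i)
      nh <- sw$selected
    }
    runs[[i]] <- run_benchmark(sigma = s, hidden = nh, restarts = restarts,
                               control = control, master_seed = seed_i,
                               params = params, n_train = n_train)
  }
  tab <- data.frame(sigma = levels,
                    hidden = vapply(runs, function(r)
                      r$model$topology$n_hidden, integer(1)),
                    rmse_train = vapply(runs, `[[`, numeric(1), "rmse_train"),
                    rmse_valid = vapply(runs, `[[`, numeric(1), "rmse_valid"))
  tab$xi <- tab$rmse_valid / tab$rmse_valid[1]
  laws <- if (length(sigmas) >= 2)
    fit_linear_laws(tab$sigma[-1], tab$rmse_valid[-1], tab$hidden[-1])
  else NULL
  structure(list(table = tab, laws = laws, runs = runs,
                 master_seed = master_seed),
            class = "psonet_grid")
}

#' @export
print.psonet_grid <- function(x, ...) {
  cat("Noise-level grid (seed ", x$master_seed, ")\n", sep = "")
  print(transform(x$table, xi = round(xi, 2)), row.names = FALSE)
  if (!is.null(x$laws)) {
    cat("  RMSE vs sigma_N (through origin): slope ",
        format(x$laws$slope_rmse, digits = 3), "\n", sep = "")
    if (!is.null(x$laws$nhl_fit))
      cat("  N_HL vs sigma_N: ", format(x$laws$nhl_fit["slope"], digits = 3),
          " * sigma + ", format(x$laws$nhl_fit["intercept"], digits = 3),
          "\n", sep = "")
  }
  invisible(x)
}

#' Uncertainty-quantification experiment
#'
#' Applies the stochastic ensemble predictor to the validation half of a
#' benchmark run and summarizes the per-point uncertainties and their
#' one-sigma coverage of the observed values.
#'
#' @param bench A `"psonet_benchmark"` (e.g. from [run_benchmark()] at the
#'   target noise level), or a fitted `"psonet"` plus an explicit `valid`.
#' @param sigma Input noise level fed to the ensemble; defaults to the
#'   benchmark's noise level.
#' @param nsim Ensemble size (default 1000).
#' @param seed Seed for the ensemble draws (derived from the benchmark's
#'   master seed by default).
#' @param valid Optional `"embedded"` validation set overriding the
#'   benchmark's.
#' @return A list of class `"psonet_uq"`: `prediction` (data frame `t`,
#'   `fit`, `se`, `point`, `truth`), `se_mean`, `se_min`, `se_max`,
#'   `se_ratio` (`se_mean / sigma`), `coverage` (one-sigma fraction),
#'   `rmse_point`, `rmse_ensemble`.
#' @export
run_uq <- function(bench, sigma = NULL, nsim = 1000, seed = NULL,
                   valid = NULL) {
  if (inherits(bench, "psonet_benchmark")) {
    model <- bench$model
    if (is.null(valid)) valid <- bench$task$valid
    if (is.null(sigma)) sigma <- bench$sigma
    if (is.null(seed)) seed <- stage_seed(bench$master_seed, "uq")
  } else if (inherits(bench, "psonet")) {
    model <- bench
    if (is.null(valid)) stop("'valid' is required with a bare model")
    if (is.null(sigma)) stop("'sigma' is required with a bare model")
    if (is.null(seed)) seed <- stage_seed(model$seed, "uq")
  } else stop("'bench' must be a psonet_benchmark or a psonet model")

  pred <- predict(model, valid, se = TRUE, sigma = sigma, nsim = nsim,
                  seed = seed)
  pred$truth <- valid$targets
  structure(list(prediction = pred,
                 sigma = sigma, nsim = nsim, seed = seed,
                 se_mean = mean(pred$se), se_min = min(pred$se),
                 se_max = max(pred$se),
                 se_ratio = if (sigma > 0) mean(pred$se) / sigma else NA_real_,
                 coverage = coverage_fraction(pred$truth, pred$fit, pred$se),
                 rmse_point = rmse(pred$point, pred$truth),
                 rmse_ensemble = rmse(pred$fit, pred$truth)),
            class = "psonet_uq")
}

#' @export
print.psonet_uq <- function(x, ...) {
  cat("Stochastic ensemble prediction (sigma_N = ", x$sigma, ", k = ",
      x$nsim, ")\n", sep = "")
  cat("  uncertainty sigma_yhat: mean ", format(x$se_mean, digits = 3),
      " (min ", format(x$se_min, digits = 3), ", max ",
      format(x$se_max, digits = 3), ")\n", sep = "")
  if (is.finite(x$se_ratio))
    cat("  sigma_yhat / sigma_N: ", format(x$se_ratio, digits = 3), "\n",
        sep = "")
  cat("  one-sigma coverage: ", format(x$coverage, digits = 3), "\n",
      sep = "")
  cat("  RMSE: point ", format(x$rmse_point, digits = 4), ", ensemble ",
      format(x$rmse_ensemble, digits = 4), "\n", sep = "")
  invisible(x)
}
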