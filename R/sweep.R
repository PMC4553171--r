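#' Hidden-layer-size sweep
#'
#' Trains the network at each candidate hidden size (with restarts) and
#' records the best training and validation errors.  The selected size is
#' the one minimizing the validation error, ties broken toward the smaller
#' network.
#'
#' @param train,valid Training and validation `"embedded"` datasets (or
#'   `list(x =, y =)`).
#' @param hidden Integer vector of hidden sizes to try (default 2:30).
#' @param control A [pso_control()].
#' @param restarts Restarts per hidden size.
#' @param seed Master seed; per-cell seeds are derived deterministically, so
#'   results do not depend on evaluation order.
#' @return A list of class `"psonet_sweep"`: `table` (data frame with
#'   columns `hidden`, `rmse_train`, `rmse_valid`), `selected` (hidden size
#'   at the validation minimum), `models` (the fitted `"psonet"` per size).
#' @export
sweep_hidden <- function(train, valid, hidden = 2:30,
                         control = pso_control(), restarts = 3, seed = 1) {
  stopifnot(length(hidden) >= 1, all(hidden >= 1))
  models <- lapply(hidden, function(nh) {
    psonet(train, hidden = nh, validation = valid, control = control,
           restarts = restarts, select = "valid",
           seed = stage_seed(seed, "sweep", nh))
  })
  tab <- data.frame(hidden = hidden,
                    rmse_train = vapply(models, `[[`, numeric(1), "rmse_train"),
                    rmse_valid = vapply(models, `[[`, numeric(1), "rmse_valid"))
  sel <- tab$hidden[which.min(tab$rmse_valid)]  # which.min: lowest index tie-break
  structure(list(table = tab, selected = sel, models = models),
            class = "psonet_sweep")
}

#' @export
print.psonet_sweep <- function(x, ...) {
  cat("Hidden-layer sweep over", nrow(x$table), "sizes; selected N_HL =",
      x$selected, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Performance efficiency under noise
#'
#' The ratio `xi = RMSE_noisy / RMSE_noiseless`, quantifying how much the
#' prediction error degrades relative to the clean-series benchmark
#' (`xi = 1` means no degradation).
#'
#' @param rmse_noisy,rmse_noiseless Scalar errors; the denominator must be
#'   positive.
#' @export
performance_efficiency <- function(rmse_noisy, rmse_noiseless) {
  if (rmse_noiseless <= 0) stop("'rmse_noiseless' must be > 0")
  rmse_noisy / rmse_noiseless
}

#' Linear noise laws from a noise-level grid
#'
#' Fits the two empirical laws relating error, architecture and noise level:
#' a zero-intercept least-squares line `RMSE = m * sigma` over the noisy
#' levels only (the noiseless point is excluded), and an ordinary
#' least-squares line with intercept `N_HL = a * sigma + b` for the selected
#' hidden size.
#'
#' @param sigma Noise levels of the noisy runs (> 0), length >= 2.
#' @param rmse_valid Validation errors at those levels.
#' @param hidden Optional selected hidden sizes at those levels (for the
#'   architecture law).
#' @return A list: `slope_rmse` (the zero-intercept slope `m`), and, when
#'   `hidden` is given, `nhl_fit` (named coefficients `intercept`, `slope`).
#' @export
fit_linear_laws <- function(sigma, rmse_valid, hidden = NULL) {
  stopifnot(length(sigma) >= 2, length(sigma) == length(rmse_valid),
            all(sigma > 0))
  slope <- sum(rmse_valid * sigma) / sum(sigma^2)  # LS through the origin
  out <- list(slope_rmse = slope)
  if (!is.null(hidden)) {
    stopifnot(length(hidden) == length(sigma))
    co <- stats::coef(stats::lm(hidden ~ sigma))
    out$nhl_fit <- c(intercept = unname(co[1]), slope = unname(co[2]))
  }
  out
}
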