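#' Corrupt a series with Gaussian white noise
#'
#' Adds i.i.d. Gaussian noise of standard deviation `sigma` to every element,
#' emulating white observational noise: `x_i <- x_i + eta_i` with
#' `eta_i ~ N(0, sigma^2)`.  Time stamps are untouched.
#'
#' @param ts A data frame with columns `t` and `x`.
#' @param sigma Noise standard deviation (>= 0, same units as `x`).
#' @param seed Optional integer seed; with a seed the output is
#'   deterministic.
#' @return The corrupted series (same shape and class).
#' @export
add_white_noise <- function(ts, sigma, seed = NULL) {
  stopifnot(is.numeric(sigma), length(sigma) == 1, sigma >= 0)
  if (sigma == 0) return(ts)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  ts$x <- ts$x + stats::rnorm(nrow(ts), 0, sigma)
  ts
}

# save/restore .Random.seed so seeded helpers do not disturb the caller's RNG
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' Delay-coordinate supervised embedding
#'
#' Builds the supervised dataset for short-term prediction: for each anchor
#' time t the input vector is the `d` lagged taps
#' `[x(t-(d-1)*delta), ..., x(t-delta), x(t)]` and the target is `x(t+T)`.
#' With the benchmark defaults (`d = 4`, `delta = T = 6` s) this is the
#' standard four-tap embedding predicting six seconds ahead.
#'
#' @param ts A uniformly sampled data frame with columns `t` and `x`.
#' @param d Number of taps (>= 1).
#' @param delta Tap spacing in seconds (a multiple of the sampling interval).
#' @param horizon Prediction horizon T in seconds (a multiple of the
#'   sampling interval).
#' @return An object of class `"embedded"`: a list with `inputs` (matrix,
#'   one row per pattern, most recent tap in the last column), `targets`
#'   (numeric), `base_times` (anchor time of each pattern), and the
#'   embedding settings.
#' @export
#' @examples
#' ts <- data.frame(t = 0:40, x = sin(0:40 / 5))
#' ds <- embed_series(ts, d = 4, delta = 6, horizon = 6)
#' nrow(ds$inputs)
embed_series <- function(ts, d = 4, delta = 6, horizon = 6) {
  stopifnot(d >= 1, delta > 0, horizon > 0)
  dt <- series_spacing(ts)
  if (!is_multiple(delta, dt) || !is_multiple(horizon, dt))
    stop("'delta' and 'horizon' must be integer multiples of the sampling interval")
  ld <- as.integer(round(delta / dt))   # lag in samples
  lh <- as.integer(round(horizon / dt)) # horizon in samples
  n <- nrow(ts)
  first <- (d - 1L) * ld + 1L           # first valid anchor index (1-based)
  last <- n - lh                        # last valid anchor index
  if (first > last)
    stop("series too short for this embedding: need at least ",
         (d - 1L) * ld + lh + 1L, " points, have ", n)
  anchors <- seq.int(first, last)
  inputs <- vapply(seq_len(d) - 1L, function(k) {
    ts$x[anchors - ((d - 1L) - k) * ld]
  }, numeric(length(anchors)))
  if (length(anchors) == 1L) inputs <- matrix(inputs, nrow = 1L)
  colnames(inputs) <- paste0("x", seq_len(d))
  structure(list(inputs = inputs,
                 targets = ts$x[anchors + lh],
                 base_times = ts$t[anchors],
                 d = d, delta = delta, horizon = horizon),
            class = "embedded")
}

#' Chronological train/validation split
#'
#' The first `n_train` patterns (in time order) form the training set; the
#' remainder is the validation set.
#'
#' @param ds An `"embedded"` dataset from [embed_series()].
#' @param n_train Number of leading patterns for training
#'   (`0 < n_train <` pattern count).
#' @return A list with elements `train` and `valid`, each an `"embedded"`
#'   dataset.
#' @export
split_embedded <- function(ds, n_train = 1000) {
  n <- length(ds$targets)
  if (n_train <= 0 || n_train >= n)
    stop("'n_train' must be strictly between 0 and ", n)
  take <- function(idx) {
    out <- ds
    out$inputs <- ds$inputs[idx, , drop = FALSE]
    out$targets <- ds$targets[idx]
    out$base_times <- ds$base_times[idx]
    out
  }
  list(train = take(seq_len(n_train)),
       valid = take(seq.int(n_train + 1L, n)))
}

#' Affine min-max scaler to [-1, 1]
#'
#' Fits the affine map sending the training minimum to -1 and maximum to +1.
#' The scaler is fitted on the training inputs and targets only (no
#' validation leakage), so validation values may map outside [-1, 1].
#'
#' @param train An `"embedded"` training set, or a numeric vector.
#' @return An object of class `"mm_scaler"` with fields `in_min`, `in_max`,
#'   `out_min = -1`, `out_max = 1`.
#' @export
fit_scaler <- function(train) {
  vals <- if (inherits(train, "embedded")) c(train$inputs, train$targets)
          else as.numeric(train)
  lo <- min(vals); hi <- max(vals)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("cannot fit scaler: data range is degenerate")
  structure(list(in_min = lo, in_max = hi, out_min = -1, out_max = 1),
            class = "mm_scaler")
}

#' @rdname fit_scaler
#' @param scaler An `"mm_scaler"`.
#' @param x Numeric values (vector or matrix) to map.
#' @export
scaler_apply <- function(scaler, x) {
  scaler$out_min + (x - scaler$in_min) *
    (scaler$out_max - scaler$out_min) / (scaler$in_max - scaler$in_min)
}

#' @rdname fit_scaler
#' @export
scaler_invert <- function(scaler, x) {
  scaler$in_min + (x - scaler$out_min) *
    (scaler$in_max - scaler$in_min) / (scaler$out_max - scaler$out_min)
}

#' Persist an embedded dataset as delimited text
#'
#' Columns are `t`, one column per tap, and `target`.
#'
#' @param ds An `"embedded"` dataset.
#' @param path File path.
#' @export
write_embedded <- function(ds, path) {
  df <- data.frame(t = ds$base_times, ds$inputs, target = ds$targets)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
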