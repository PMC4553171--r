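#' Delay-coordinate reconstruction
#'
#' Maps a scalar series to points `[x(t), x(t-lag), ..., x(t-(dim-1)*lag)]`
#' for attractor reconstruction and tangent-map estimation.
#'
#' @param ts A uniformly sampled data frame with columns `t` and `x`.
#' @param lag Delay in seconds (multiple of the sampling interval).
#' @param dim Embedding dimension (>= 1).
#' @return A matrix with `dim` columns (most recent coordinate first) and
#'   attribute `"t"` holding the anchor times.
#' @export
delay_coordinates <- function(ts, lag, dim) {
  stopifnot(dim >= 1)
  dt <- series_spacing(ts)
  if (!is_multiple(lag, dt))
    stop("'lag' must be an integer multiple of the sampling interval")
  l <- as.integer(round(lag / dt))
  n <- nrow(ts)
  first <- (dim - 1L) * l + 1L
  if (first > n) stop("series too short for this reconstruction")
  anchors <- seq.int(first, n)
  out <- vapply(seq_len(dim) - 1L, function(k) ts$x[anchors - k * l],
                numeric(length(anchors)))
  if (length(anchors) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- paste0("x_lag", (seq_len(dim) - 1L))
  attr(out, "t") <- ts$t[anchors]
  out
}

#' Lyapunov spectrum of the Mackey-Glass system (variational route)
#'
#' Ground-truth exponents from the delay-differential equation itself: the
#' nonlinear system and `n_exponents` copies of its linearization
#' \deqn{d\delta/dt = -\beta\,\delta(t) + \alpha\,g'(x(t-\tau))\,\delta(t-\tau)}
#' (with `g(u) = u/(1+u^10)`) are integrated together by the same RK4 /
#' history-buffer scheme as [mackey_glass()].  The tangent states -- the
#' discretized history segments -- are re-orthonormalized every
#' `renorm_every` seconds by QR decomposition and the exponents are the
#' time-averaged logarithmic growth rates of the R diagonal, in units of
#' 1/second.
#'
#' @param params An [mg_params()]; `t_horizon` here is the averaging time
#'   (after the transient), longer is more accurate.
#' @param n_exponents Number of leading exponents (>= 1).
#' @param transient Time (s) integrated and discarded before averaging
#'   begins, letting the trajectory settle onto the attractor.
#' @param tangent_warmup Time (s) after the transient during which the
#'   tangent vectors evolve and are re-orthonormalized without contributing
#'   to the averages, so the random initial directions relax onto the
#'   leading subspaces first.
#' @param renorm_every Re-orthonormalization interval (s).
#' @param seed Seed for the random initial tangent directions.
#' @param guard Divergence guard on the nonlinear trajectory.
#' @return An object of class `"lyapunov"`: list with `exponents` (sorted
#'   descending, 1/s), `method`, `t_averaged`.
#' @export
#' @examples
#' sp <- lyapunov_mg(mg_params(t_horizon = 500), n_exponents = 2,
#'                   transient = 100)
#' sp$exponents
lyapunov_mg <- function(params = mg_params(t_horizon = 5000),
                        n_exponents = 4, transient = 200,
                        tangent_warmup = 50, renorm_every = 1,
                        seed = 1, guard = 1e6) {
  stopifnot(n_exponents >= 1, transient >= 0, tangent_warmup >= 0,
            renorm_every > 0)
  h <- params$internal_dt
  n_tau <- as.integer(round(params$tau / h))
  nbuf <- n_tau + 1L                     # discretized history segment length
  m <- n_exponents
  if (m > nbuf) stop("cannot estimate more exponents than history samples")
  steps_total <- as.integer(round((transient + tangent_warmup +
                                     params$t_horizon) / h))
  steps_trans <- as.integer(round(transient / h))
  steps_warm <- as.integer(round(tangent_warmup / h))
  steps_renorm <- as.integer(round(renorm_every / h))

  a <- params$alpha; b <- params$beta; hm <- params$hill_exponent
  f <- function(xn, xd) -b * xn + a * xd / (1 + xd^hm)
  flin <- function(dn, dd, gp) -b * dn + a * gp * dd

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)

  # nonlinear trajectory buffer (x at the last nbuf grid points) and the
  # tangent buffers D: nbuf x m, columns are perturbation history segments
  x <- c(rep(0, n_tau), params$x0)
  D <- qr.Q(qr(matrix(stats::rnorm(nbuf * m), nbuf, m)))
  logsum <- numeric(m)
  t_accum <- 0

  for (i in seq_len(steps_total)) {
    xd0 <- x[1L]; xd1 <- x[2L]; xdh <- 0.5 * (xd0 + xd1)
    xn <- x[nbuf]
    k1 <- f(xn, xd0)
    k2 <- f(xn + 0.5 * h * k1, xdh)
    k3 <- f(xn + 0.5 * h * k2, xdh)
    k4 <- f(xn + h * k3, xd1)
    xnew <- xn + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (!is.finite(xnew) || abs(xnew) > guard)
      stop("variational integration diverged")

    if (i > steps_trans) {
      gp0 <- mg_feedback_deriv(xd0, hm)
      gp1 <- mg_feedback_deriv(xd1, hm)
      gph <- mg_feedback_deriv(xdh, hm)
      dn <- D[nbuf, ]; dd0 <- D[1L, ]; dd1 <- D[2L, ]
      ddh <- 0.5 * (dd0 + dd1)
      l1 <- flin(dn, dd0, gp0)
      l2 <- flin(dn + 0.5 * h * l1, ddh, gph)
      l3 <- flin(dn + 0.5 * h * l2, ddh, gph)
      l4 <- flin(dn + h * l3, dd1, gp1)
      dnew <- dn + h / 6 * (l1 + 2 * l2 + 2 * l3 + l4)
      D <- rbind(D[-1L, , drop = FALSE], dnew)

      if ((i - steps_trans) %% steps_renorm == 0L) {
        qrd <- qr(D)
        r <- diag(qr.R(qrd))
        Q <- qr.Q(qrd)
        # fix signs so Q columns keep positive diagonal R
        Q <- sweep(Q, 2L, sign(r + (r == 0)), `*`)
        if (i - steps_trans > steps_warm) {
          logsum <- logsum + log(abs(r) + .Machine$double.xmin)
          t_accum <- t_accum + steps_renorm * h
        }
        D <- Q
      }
    }
    x <- c(x[-1L], xnew)
  }
  if (t_accum <= 0) stop("averaging window too short")
  ex <- sort(logsum / t_accum, decreasing = TRUE)
  structure(list(exponents = ex, method = "variational-dde",
                 t_averaged = t_accum), class = "lyapunov")
}

#' Lyapunov spectrum from an observed series (tangent-map route)
#'
#' Data-driven spectrum estimate in the style of Sano and Sawada: the series
#' is delay-embedded, a local linear map (Jacobian estimate) is fitted by
#' least squares from each reference point's nearest neighbours and their
#' images `evolve` steps later, and the Jacobian product is accumulated with
#' QR re-orthonormalization.  Exponents are per unit time.
#'
#' @param ts A uniformly sampled data frame with columns `t` and `x`,
#'   approximately noise-free and long enough for neighbour statistics.
#' @param dim Embedding dimension; also the number of exponents returned.
#' @param lag Embedding delay in seconds.
#' @param evolve Evolution time between Jacobian fits, in samples.
#' @param n_neighbors Neighbours used for each local fit (> dim).
#' @param n_ref Number of reference points along the trajectory.
#' @param seed Seed for the initial orthonormal frame.
#' @return An object of class `"lyapunov"` (exponents sorted descending,
#'   1/s).
#' @export
lyapunov_series <- function(ts, dim = 4, lag = 6, evolve = 3,
                            n_neighbors = 30, n_ref = 1000,
                            seed = 1) {
  stopifnot(dim >= 1, n_neighbors > dim)
  dt <- series_spacing(ts)
  Y <- delay_coordinates(ts, lag = lag, dim = dim)
  n <- nrow(Y)
  if (n < n_neighbors + evolve + 10L)
    stop("series too short: not enough embedded points for neighbour fits")
  usable <- n - evolve
  refs <- unique(round(seq(1L, usable, length.out = min(n_ref, usable))))

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  Q <- qr.Q(qr(matrix(stats::rnorm(dim * dim), dim, dim)))
  logsum <- numeric(dim)
  t_accum <- 0

  for (i in refs) {
    # nearest neighbours of Y[i,] among usable points (excluding temporal
    # neighbours within one delay window to avoid trivially correlated pairs)
    d2 <- colSums((t(Y[seq_len(usable), , drop = FALSE]) - Y[i, ])^2)
    excl <- abs(seq_len(usable) - i) <= (dim - 1L) * lag / dt
    d2[excl] <- Inf
    nb <- order(d2)[seq_len(n_neighbors)]
    Z <- Y[nb, , drop = FALSE] - matrix(Y[i, ], n_neighbors, dim,
                                        byrow = TRUE)
    Zp <- Y[nb + evolve, , drop = FALSE] - matrix(Y[i + evolve, ],
                                                  n_neighbors, dim,
                                                  byrow = TRUE)
    # least-squares local map A: Zp ~ Z %*% t(A); relative ridge for
    # near-singular neighbourhoods
    G <- crossprod(Z)
    G <- G + diag(1e-10 * (sum(diag(G)) / dim + .Machine$double.xmin), dim)
    A <- t(solve(G, crossprod(Z, Zp)))
    W <- A %*% Q
    qrd <- qr(W)
    r <- diag(qr.R(qrd))
    Q <- sweep(qr.Q(qrd), 2L, sign(r + (r == 0)), `*`)
    logsum <- logsum + log(abs(r) + .Machine$double.xmin)
    t_accum <- t_accum + evolve * dt
  }
  ex <- sort(logsum / t_accum, decreasing = TRUE)
  structure(list(exponents = ex, method = "tangent-map",
                 t_averaged = t_accum), class = "lyapunov")
}

#' @export
print.lyapunov <- function(x, ...) {
  cat("Lyapunov spectrum (", x$method, ", averaged over ",
      format(x$t_averaged, digits = 4), " s)\n", sep = "")
  for (i in seq_along(x$exponents))
    cat(sprintf("  lambda_%d = % .5f  (1/s)\n", i, x$exponents[i]))
  dky <- tryCatch(kaplan_yorke(x$exponents), error = function(e) NA_real_)
  if (is.finite(dky)) cat("  Kaplan-Yorke dimension:", format(dky, digits = 4), "\n")
  invisible(x)
}

#' Kaplan-Yorke (Lyapunov) dimension
#'
#' `D_KY = j + (lambda_1 + ... + lambda_j) / |lambda_(j+1)|` where `j` is the
#' largest index for which the partial sum of the descending-ordered
#' exponents is still non-negative.  Conjectured equal to the information
#' dimension of the attractor.  Returns 0 when even the leading exponent is
#' negative (everywhere-contracting dynamics); errors if every partial sum
#' is non-negative, since the spectrum is then too short to locate the
#' crossing.
#'
#' @param exponents Numeric vector of Lyapunov exponents, sorted
#'   descending, or a `"lyapunov"` object.
#' @return The dimension (dimensionless).
#' @export
#' @examples
#' kaplan_yorke(c(0.1, -0.2))  # 1.5
kaplan_yorke <- function(exponents) {
  if (inherits(exponents, "lyapunov")) exponents <- exponents$exponents
  stopifnot(is.numeric(exponents), length(exponents) >= 1)
  if (any(diff(exponents) > 1e-12))
    stop("'exponents' must be sorted in descending order")
  if (exponents[1] < 0) return(0)
  cs <- cumsum(exponents)
  j <- max(which(cs >= 0))
  if (j >= length(exponents))
    stop("all partial sums are non-negative; spectrum too short for D_KY")
  j + cs[j] / abs(exponents[j + 1])
}
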