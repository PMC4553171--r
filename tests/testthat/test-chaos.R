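test_that("delay coordinates enumerate lagged points", {
  ts <- data.frame(t = 0:20, x = 0:20)
  one <- delay_coordinates(ts, lag = 1, dim = 1)
  expect_equal(unname(one[, 1]), 0:20)              # dim 1: the series itself
  two <- delay_coordinates(ts, lag = 1, dim = 2)
  expect_equal(unname(two[1, ]), c(1, 0))           # ramp: (t, t-1)
  expect_identical(nrow(two), 20L)                  # n - (dim-1)*lag points
  d4 <- delay_coordinates(ts, lag = 3, dim = 4)
  expect_identical(nrow(d4), 21L - 9L)
  expect_error(delay_coordinates(ts[1:3, ], lag = 3, dim = 4), "short")
})

test_that("Kaplan-Yorke dimension follows the partial-sum formula", {
  expect_equal(kaplan_yorke(c(0.1, -0.2)), 1.5)
  expect_equal(kaplan_yorke(c(-0.1, -0.2)), 0)      # contracting everywhere
  # published benchmark spectrum for the delayed-feedback system: direct
  # formula evaluation as the independent oracle
  lam <- c(0.00860, 0.00100, -0.03950, -0.05050)
  j <- max(which(cumsum(lam) >= 0))
  oracle <- j + sum(lam[1:j]) / abs(lam[j + 1])
  expect_equal(kaplan_yorke(lam), oracle)
  expect_equal(oracle, 2.2430, tolerance = 1e-4)    # not the printed 2.10
  expect_true(kaplan_yorke(lam) >= 2.0 && kaplan_yorke(lam) <= 2.35)
  expect_error(kaplan_yorke(c(0.2, 0.1)), "non-negative")
  expect_error(kaplan_yorke(c(0.1, 0.3)), "descending")
})

test_that("Kaplan-Yorke dimension is invariant to time-unit rescaling", {
  lam <- c(0.012, 0.0005, -0.03, -0.06)
  expect_equal(kaplan_yorke(lam), kaplan_yorke(60 * lam))
})

test_that("variational route recovers the pure-decay exponent exactly", {
  sp <- lyapunov_mg(mg_params(alpha = 0, t_horizon = 200, x0 = 1),
                    n_exponents = 1, transient = 10)
  expect_equal(sp$exponents, -0.1, tolerance = 1e-6)
})

test_that("variational spectrum of the chaotic regime has the known shape", {
  sp <- lyapunov_mg(mg_params(t_horizon = 2000), n_exponents = 4,
                    transient = 200, seed = 1)
  ex <- sp$exponents
  expect_gt(ex[1], 0)                       # chaotic: positive leading
  expect_lt(ex[1], 0.05)                    # order 1e-2
  expect_lt(abs(ex[2]), 0.005)              # neutral direction ~ 0
  expect_lt(ex[3], -0.01)                   # contracting pair
  expect_lt(ex[4], ex[3] + 1e-6)
  expect_lt(sum(ex), 0)                     # dissipative
  dky <- kaplan_yorke(sp)
  expect_gt(dky, 1.5); expect_lt(dky, 3)
})

test_that("tangent-map route matches log-eigenvalues of a linear map", {
  # damped rotation observed through one coordinate: the local fits recover
  # the companion matrix exactly, whose eigenvalues share modulus rho, so
  # both exponents equal log(rho)
  rho <- 0.95; th <- 0.7; n <- 240
  s <- numeric(n); s[1] <- 1; s[2] <- 0.6
  for (i in 3:n)
    s[i] <- 2 * rho * cos(th) * s[i - 1] - rho^2 * s[i - 2]
  ts <- data.frame(t = seq_len(n) - 1, x = s)
  sp <- lyapunov_series(ts, dim = 2, lag = 1, evolve = 1, n_neighbors = 8,
                        n_ref = 150)
  expect_lt(max(abs(sp$exponents - log(rho))), 0.01)
  # the per-step exponent sum telescopes to log|det| of the map exactly
  expect_equal(sum(sp$exponents), 2 * log(rho), tolerance = 1e-8)
})

test_that("series and variational routes agree on the leading exponent scale", {
  ts <- mackey_glass(mg_params(t_horizon = 4000))
  sp_data <- lyapunov_series(ts, dim = 4, lag = 6, n_ref = 800, seed = 2)
  sp_true <- lyapunov_mg(mg_params(t_horizon = 1500), n_exponents = 2,
                         transient = 200, seed = 2)
  expect_gt(sp_data$exponents[1], 0)
  expect_gt(sp_true$exponents[1], 0)
  # same order of magnitude (estimator tolerance: within a factor of four)
  expect_lt(abs(log(sp_data$exponents[1] / sp_true$exponents[1])), log(4))
  # estimates are reproducible per seed
  again <- lyapunov_series(ts, dim = 4, lag = 6, n_ref = 800, seed = 2)
  expect_identical(again$exponents, sp_data$exponents)
})
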