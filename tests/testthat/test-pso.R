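test_that("the inertia schedule is linear from omega_max to omega_min", {
  ctrl <- pso_control()
  expect_equal(inertia_at(0, ctrl), 0.7)
  expect_equal(inertia_at(ctrl$k_max - 1, ctrl), 0.5)
  expect_equal(inertia_at((ctrl$k_max - 1) / 2, ctrl), 0.6)
  expect_error(inertia_at(ctrl$k_max, ctrl), "range")
  expect_error(inertia_at(-1, ctrl), "range")
})

test_that("rmse and its noise-weighted form follow the definitions", {
  y <- c(1, 2, 3, 4, 5)
  expect_identical(rmse(y, y), 0)
  expect_equal(rmse(rep(2, 7), rep(5, 7)), 3)       # constant offset
  set.seed(1)
  a <- rnorm(5); b <- rnorm(5)
  expect_equal(rmse(a, b), sqrt(sum((a - b)^2) / 5))   # brute-force oracle
  # weighted: residuals equal to sigma give exactly 1
  expect_equal(rmse(b + 0.3, b, sigma = 0.3), 1)
  # sigma = 1 reduces to the plain rmse
  expect_equal(rmse(a, b, sigma = 1), rmse(a, b))
  # mixed sigmas, n = 3, against direct formula evaluation
  pr <- c(1, 2, 3); ob <- c(1.1, 1.8, 3.4); sg <- c(0.1, 0.2, 0.4)
  expect_equal(rmse(pr, ob, sigma = sg),
               sqrt(mean((pr - ob)^2 / sg^2)))
  # literal (no radical) variant
  expect_equal(rmse(pr, ob, sigma = sg, literal = TRUE),
               mean((pr - ob)^2 / sg^2))
  expect_error(rmse(pr, ob, sigma = c(0.1, 0, 0.1)), "sigma")
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
})

test_that("one swarm step reproduces the update equations by hand", {
  # 2-dimensional quadratic, 2 particles, one iteration; the reference path
  # redraws the same RNG stream and applies the velocity/position equations
  # scalar by scalar
  fn <- function(s) sum((s - c(1, -2))^2)
  ctrl <- pso_control(n_particles = 2, k_max = 1, min_error = 0)
  res <- pso_optimize(fn, lower = -5, upper = 5, control = ctrl, seed = 31,
                      dim = 2)

  set.seed(31)
  d <- 2; np <- 2
  S <- matrix(runif(d * np, -5, 5), d, np)
  V <- matrix(runif(d * np, -ctrl$v_max, ctrl$v_max), d, np)
  fit <- apply(S, 2, fn)
  P <- S; pfit <- fit
  g <- which.min(pfit); gb <- P[, g]; gf <- pfit[g]
  w <- 0.7                                    # k_max = 1: schedule start
  R1 <- matrix(runif(d * np), d, np)
  R2 <- matrix(runif(d * np), d, np)
  for (j in 1:np) for (i in 1:d) {
    V[i, j] <- w * V[i, j] + 1.494 * R1[i, j] * (P[i, j] - S[i, j]) +
      1.494 * R2[i, j] * (gb[i] - S[i, j])
    V[i, j] <- min(max(V[i, j], -ctrl$v_max), ctrl$v_max)
    S[i, j] <- min(max(S[i, j] + V[i, j], -5), 5)
  }
  fit <- apply(S, 2, fn)
  imp <- fit < pfit; P[, imp] <- S[, imp]; pfit[imp] <- fit[imp]
  g <- which.min(pfit)
  if (pfit[g] < gf) { gb <- P[, g]; gf <- pfit[g] }
  expect_equal(res$par, gb, tolerance = 1e-14)
  expect_equal(res$value, gf, tolerance = 1e-14)
})

test_that("velocity and position clamps bind at the stated bounds", {
  # all mass toward a far global best forces velocities onto the clamp;
  # positions must stay inside the box
  fn <- function(s) sum(s^2)
  ctrl <- pso_control(n_particles = 5, k_max = 40, v_max = 0.5,
                      min_error = 0)
  res <- pso_optimize(fn, lower = -100, upper = 100, control = ctrl,
                      seed = 2, dim = 2)
  expect_true(all(abs(res$par) <= 100))
  # frozen swarm: v_max -> 0 means positions never change
  ctrl0 <- pso_control(n_particles = 4, k_max = 25, v_max = 1e-300,
                       min_error = 0)
  r0 <- pso_optimize(fn, lower = -3, upper = 3, control = ctrl0, seed = 5,
                     dim = 2)
  set.seed(5)
  S0 <- matrix(runif(2 * 4, -3, 3), 2, 4)
  expect_equal(r0$par, S0[, which.min(apply(S0, 2, fn))],
               tolerance = 1e-200)
})

test_that("global-best fitness is monotonically non-increasing", {
  fn <- function(s) sum((s - 0.5)^2) + 0.1 * sum(sin(5 * s)^2)
  res <- pso_optimize(fn, lower = -4, upper = 4,
                      control = pso_control(n_particles = 15, k_max = 120,
                                            min_error = 0), seed = 4)
  expect_true(all(diff(res$history) <= 0))
  expect_equal(res$value, min(res$history))
  # running minimum of the per-iteration best is non-increasing
  expect_true(all(diff(cummin(res$iter_best)) <= 0))
})

test_that("the swarm minimizes the 2-d sphere to below 1e-6", {
  fit <- pso_optimize(function(s) sum(s^2), lower = -10, upper = 10,
                      control = pso_control(n_particles = 50, k_max = 1500,
                                            min_error = 0), seed = 1,
                      dim = 2)
  expect_lt(fit$value, 1e-6)
  expect_lte(fit$iterations, 1500)
})

test_that("optimization is deterministic per seed", {
  fn <- function(s) sum(s^4 - 3 * s^2)
  a <- pso_optimize(fn, -2, 2, pso_control(n_particles = 8, k_max = 50,
                                           min_error = 0), seed = 77, dim = 3)
  b <- pso_optimize(fn, -2, 2, pso_control(n_particles = 8, k_max = 50,
                                           min_error = 0), seed = 77, dim = 3)
  expect_identical(a, b)
})
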