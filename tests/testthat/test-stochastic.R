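# builds a network that is numerically affine, y ~ a.p + c, by keeping each
# tanh argument tiny and rescaling at the output layer; linearization error
# is O(delta^2), far below Monte-Carlo noise
affine_net <- function(a, c0, delta = 1e-4) {
  d <- length(a)
  topo <- nn_topology(d, 1)
  theta <- c(delta * a, 0, 1 / delta, c0)
  scaler <- structure(list(in_min = -1, in_max = 1, out_min = -1,
                           out_max = 1), class = "mm_scaler")  # identity map
  structure(list(theta = theta, topology = topo, scaler = scaler,
                 x = matrix(0, 1, d), y = 0), class = "psonet")
}

test_that("input resampling has the right moments and determinism", {
  X <- matrix(c(0.5, -0.2, 1.1, 0.8), 2, 2)
  ens0 <- perturb_inputs(X, sigma = 0, nsim = 5, seed = 1)
  for (k in 1:5) expect_identical(ens0[, , k], X)      # degenerate ensemble
  k <- 10000
  ens <- perturb_inputs(X, sigma = 0.1, nsim = k, seed = 2)
  m <- apply(ens, c(1, 2), mean)
  expect_lt(max(abs(m - X)), 4 * 0.1 / sqrt(k))        # moment check
  expect_identical(perturb_inputs(X, 0.1, 3, seed = 9),
                   perturb_inputs(X, 0.1, 3, seed = 9))
})

test_that("zero input noise collapses the ensemble onto the point forecast", {
  task <- small_task()
  fit <- psonet(task$train, hidden = 3, control = quick_control(), seed = 1)
  pr <- predict(fit, task$valid, se = TRUE, sigma = 0, nsim = 10, seed = 3)
  expect_equal(pr$fit, pr$point, tolerance = 1e-12)
  expect_true(all(pr$se == 0))
  expect_true(all(c("t", "fit", "se", "point") %in% names(pr)))
})

test_that("uncertainty through an affine map equals sigma times the norm", {
  a <- c(0.8, -0.5, 0.3, 0.2); sigma <- 0.1
  net <- affine_net(a, c0 = 0.4)
  X <- matrix(runif(40, -0.5, 0.5), 10, 4)
  expect_equal(predict(net, X), 0.4 + as.numeric(X %*% a),
               tolerance = 1e-6)
  pr <- predict(net, X, se = TRUE, sigma = sigma, nsim = 4000, seed = 8)
  target <- sigma * sqrt(sum(a^2))
  # Monte-Carlo sd of the sd estimate ~ target / sqrt(2k) ~ 0.5%
  expect_lt(max(abs(pr$se - target)), 0.05 * target)
  expect_lt(max(abs(pr$fit - pr$point)), 4 * target / sqrt(4000))
})

test_that("uncertainty scales linearly with input noise in the small-sigma regime", {
  task <- small_task()
  fit <- psonet(task$train, hidden = 3, control = quick_control(), seed = 4)
  X <- task$valid$inputs[1:25, ]
  p1 <- predict(fit, X, se = TRUE, sigma = 0.01, nsim = 3000, seed = 5)
  p2 <- predict(fit, X, se = TRUE, sigma = 0.02, nsim = 3000, seed = 5)
  expect_equal(p2$se / p1$se, rep(2, 25), tolerance = 0.1)
})

test_that("the literal second-moment reading is dominated by the signal", {
  task <- small_task()
  fit <- psonet(task$train, hidden = 3, control = quick_control(), seed = 4)
  X <- task$valid$inputs[1:10, ]
  lit <- predict(fit, X, se = TRUE, sigma = 0.01, nsim = 200, seed = 6,
                 literal_second_moment = TRUE)
  std <- predict(fit, X, se = TRUE, sigma = 0.01, nsim = 200, seed = 6)
  expect_equal(lit$se, sqrt(std$se^2 + lit$fit^2), tolerance = 1e-8)
  expect_gt(mean(lit$se), 10 * mean(std$se))
})

test_that("coverage_fraction counts one-sigma agreement", {
  expect_equal(coverage_fraction(c(1, 2, 3), c(1.5, 2.5, 2.8),
                                 rep(Inf, 3)), 1)
  expect_equal(coverage_fraction(c(1, 2), c(1.1, 2.1), c(0, 0)), 0)
  # matched Gaussian residuals: expected 2*pnorm(1) - 1 ~ 0.6827
  set.seed(11)
  n <- 4000; s <- 0.3
  truth <- rnorm(n, 0, 1)
  fit <- truth + rnorm(n, 0, s)
  cov <- coverage_fraction(truth, fit, rep(s, n))
  p <- 2 * pnorm(1) - 1
  expect_lt(abs(cov - p), 4 * sqrt(p * (1 - p) / n))
  expect_error(coverage_fraction(1:3, 1:2, 1:3), "aligned")
})

test_that("simulate() returns the raw ensemble behind the summaries", {
  task <- small_task()
  fit <- psonet(task$train, hidden = 3, control = quick_control(), seed = 2)
  X <- task$valid$inputs[1:8, ]
  ens <- simulate(fit, nsim = 500, seed = 7, newdata = X, sigma = 0.05)
  expect_identical(dim(ens), c(8L, 500L))
  pr <- predict(fit, X, se = TRUE, sigma = 0.05, nsim = 500, seed = 7)
  expect_equal(rowMeans(ens), pr$fit, tolerance = 1e-10)
  sds <- apply(ens, 1, function(z) sqrt(mean((z - mean(z))^2)))
  expect_equal(sds, pr$se, tolerance = 1e-10)
})
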