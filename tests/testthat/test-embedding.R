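test_that("white-noise corruption has the stated moments and determinism", {
  ts <- mackey_glass()
  expect_identical(add_white_noise(ts, 0), ts)          # zero-noise identity
  n1 <- add_white_noise(ts, 0.1, seed = 7)
  n2 <- add_white_noise(ts, 0.1, seed = 7)
  expect_identical(n1, n2)                              # determinism
  eta <- n1$x - ts$x
  n <- length(eta)
  # sample sd within 3 standard errors of 0.1; mean within 4 sigma/sqrt(n)
  expect_lt(abs(sd(eta) - 0.1), 3 * 0.1 / sqrt(2 * n))
  expect_lt(abs(mean(eta)), 4 * 0.1 / sqrt(n))
  expect_equal(n1$t, ts$t)
  expect_error(add_white_noise(ts, -0.1))
})

test_that("noise injection leaves the caller's RNG stream untouched", {
  ts <- short_mg(50)
  set.seed(42); r1 <- runif(3)
  set.seed(42); invisible(add_white_noise(ts, 0.05, seed = 9)); r2 <- runif(3)
  expect_identical(r1, r2)
})

test_that("delay embedding enumerates exactly the valid patterns", {
  # 2000-point series indexed t = 0..1999: anchors run 18..1993 -> 1976
  ts <- data.frame(t = 0:1999, x = rnorm(2000))
  ds <- embed_series(ts, d = 4, delta = 6, horizon = 6)
  expect_identical(nrow(ds$inputs), 1976L)
  expect_equal(ds$base_times[1], 18)
  expect_equal(ds$base_times[length(ds$base_times)], 1993)
})

test_that("embedding lays out taps oldest-first with the target T ahead", {
  ramp <- data.frame(t = 0:40, x = 0:40)
  ds <- embed_series(ramp, d = 4, delta = 6, horizon = 6)
  expect_equal(unname(ds$inputs[1, ]), c(0, 6, 12, 18))
  expect_equal(ds$targets[1], 24)
  # d = 1, T = 1: one-step-ahead pairs, n - 1 of them
  d1 <- embed_series(ramp, d = 1, delta = 1, horizon = 1)
  expect_identical(length(d1$targets), 40L)
  expect_error(embed_series(ramp[1:20, ], d = 4, delta = 6, horizon = 6),
               "too short")
})

test_that("embedding is shift-equivariant in time", {
  ts <- short_mg(120)
  shifted <- ts; shifted$t <- shifted$t + 500
  a <- embed_series(ts); b <- embed_series(shifted)
  expect_equal(b$inputs, a$inputs)
  expect_equal(b$targets, a$targets)
  expect_equal(b$base_times, a$base_times + 500)
})

test_that("chronological split partitions the dataset in order", {
  ts <- data.frame(t = 0:1999, x = rnorm(2000))
  ds <- embed_series(ts)
  sp <- split_embedded(ds, n_train = 1000)
  expect_identical(length(sp$train$targets), 1000L)
  expect_identical(length(sp$valid$targets), 976L)
  # concatenating the halves reproduces the input exactly
  expect_equal(rbind(sp$train$inputs, sp$valid$inputs), ds$inputs)
  expect_equal(c(sp$train$targets, sp$valid$targets), ds$targets)
  # boundary: one validation pattern
  sp1 <- split_embedded(ds, n_train = length(ds$targets) - 1L)
  expect_identical(length(sp1$valid$targets), 1L)
  expect_error(split_embedded(ds, 0))
  expect_error(split_embedded(ds, length(ds$targets)))
})

test_that("the min-max scaler maps the training range onto [-1, 1]", {
  sc <- fit_scaler(c(0, 1))
  expect_equal(scaler_apply(sc, c(0, 1)), c(-1, 1))
  expect_equal(scaler_apply(sc, 0.5), 0)                # midpoint -> 0
  v <- runif(50, -3, 7)
  sc2 <- fit_scaler(v)
  expect_equal(scaler_invert(sc2, scaler_apply(sc2, v)), v,
               tolerance = 1e-12)                        # round trip
  expect_error(fit_scaler(rep(2, 5)), "degenerate")
})

test_that("the scaler is fitted on the training half only (no leakage)", {
  task <- small_task(horizon = 400, n_train = 150)
  sc <- fit_scaler(task$train)
  expect_equal(range(scaler_apply(sc, c(task$train$inputs,
                                        task$train$targets))), c(-1, 1))
  vn <- scaler_apply(sc, c(task$valid$inputs, task$valid$targets))
  # validation values are allowed beyond [-1, 1]; the training box must not
  # have been widened to cover them
  sc_all <- fit_scaler(c(task$train$inputs, task$train$targets,
                         task$valid$inputs, task$valid$targets))
  expect_true(sc_all$in_max >= sc$in_max && sc_all$in_min <= sc$in_min)
})

test_that("embedded datasets persist as delimited text", {
  ds <- embed_series(short_mg(100))
  path <- withr::local_tempfile(fileext = ".csv")
  write_embedded(ds, path)
  back <- read.csv(path)
  expect_identical(nrow(back), length(ds$targets))
  expect_equal(back$target, ds$targets, tolerance = 1e-12)
})
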