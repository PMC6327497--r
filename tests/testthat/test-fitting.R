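quad <- function(x) (x - 3)^2

test_that("threshold accepting finds a 1-D optimum and keeps a monotone record", {
  fit <- lta_optimize(quad, x0 = 9, bounds = c(0.1, 10),
                      config = lta_config(max_iter = 2000, seed = 1))
  expect_lt(abs(fit$par - 3), 0.05)
  expect_true(all(diff(fit$trace$best_z) <= 0))
})

test_that("with zero thresholds from the optimum, the best never worsens", {
  fit <- lta_optimize(quad, x0 = 3, bounds = c(0.1, 10),
                      config = lta_config(max_iter = 200, seed = 2,
                                          initial_thresholds = rep(0, 5)))
  expect_equal(fit$value, 0)
  expect_equal(fit$par, 3)
  expect_true(all(fit$trace$best_z == 0))
})

test_that("the threshold list maximum shrinks after warm-up", {
  fit <- lta_optimize(quad, x0 = 9, bounds = c(0.1, 10),
                      config = lta_config(max_iter = 500, seed = 3))
  expect_true(all(diff(fit$trace$t_max) <= 1e-12))
})

test_that("single-walker runs are bitwise reproducible", {
  f1 <- lta_optimize(quad, 9, c(0.1, 10), lta_config(max_iter = 300, seed = 7))
  f2 <- lta_optimize(quad, 9, c(0.1, 10), lta_config(max_iter = 300, seed = 7))
  expect_identical(f1$par, f2$par)
  expect_identical(f1$trace, f2$trace)
})

test_that("one walker through the multi-walker driver reduces to the plain run", {
  cfg <- lta_config(max_iter = 200, walkers = 1, seed = 5)
  expect_identical(run_walkers(quad, 9, c(0.1, 10), cfg)$par,
                   lta_optimize(quad, 9, c(0.1, 10), cfg)$par)
})

test_that("seven walkers help on average for the same per-walker budget", {
  cfg1 <- function(s) lta_config(max_iter = 150, walkers = 1, seed = s)
  cfg7 <- function(s) lta_config(max_iter = 150, walkers = 7, seed = s)
  seeds <- 1:12
  b1 <- sapply(seeds, function(s) lta_optimize(quad, 9, c(0.1, 10), cfg1(s))$value)
  b7 <- sapply(seeds, function(s) run_walkers(quad, 9, c(0.1, 10), cfg7(s))$value)
  expect_lte(mean(b7), mean(b1))
  # the walker schedule is 1 local + (W - 1) restarting nodes
  fit7 <- run_walkers(quad, 9, c(0.1, 10), cfg7(1))
  expect_setequal(unique(fit7$trace$walker), 1:7)
  expect_identical(run_walkers(quad, 9, c(0.1, 10), cfg7(4))$par,
                   run_walkers(quad, 9, c(0.1, 10), cfg7(4))$par)
})

test_that("the simulation objective is zero at truth and grows away from it", {
  m <- toy_model("TOY2")
  tb <- toy_batch_setup("TOY2")
  meas <- synth_measurements(m, tb$init, tb$config, sigma = 0)$concentrations
  obj <- make_objective(m, meas, tb$init, tb$config)
  expect_equal(obj(c(1, 1)), 0)
  # weakening the preferred substrate's coupling is identifiable
  expect_gt(obj(c(0.1, 1)), 0)
  expect_gt(obj(c(4, 4)), 0)
  # constant-offset arithmetic: shift one species by 1 on k grid points
  meas2 <- meas
  meas2$B_e[1:5] <- meas2$B_e[1:5] + 1
  obj2 <- make_objective(m, meas2, tb$init, tb$config)
  expect_equal(obj2(c(1, 1)), 5)
})
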