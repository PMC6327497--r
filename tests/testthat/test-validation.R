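test_that("mass fractions follow both definitions", {
  expect_equal(unname(mass_fractions_translation(c(1, 1), c(2, 8))),
               c(0.2, 0.8))
  expect_equal(mass_fractions_translation(5, 3), 1)
  expect_equal(unname(mass_fractions_translation(c(0, 5), c(1, 1))), c(0, 1))
  expect_equal(unname(mass_fractions_concentration(c(0.01, 0.03), c(5, 5))),
               c(0.25, 0.75))
  expect_equal(unname(mass_fractions_concentration(rep(2, 4), rep(7, 4))),
               rep(0.25, 4))
  expect_equal(unname(mass_fractions_concentration(c(2, 0), c(3, 9))), c(1, 0))
  expect_error(mass_fractions_translation(c(0, 0), c(1, 1)), "undefined")
})

test_that("mass fractions sum to one and are scale invariant", {
  withr::with_seed(2, {
    for (i in 1:20) {
      v <- runif(6); w <- runif(6, 1, 100)
      f <- mass_fractions_translation(v, w)
      expect_equal(sum(f), 1, tolerance = 1e-12)
      expect_equal(mass_fractions_translation(37.5 * v, w), f,
                   tolerance = 1e-12)
    }
  })
})

test_that("resampling aligns profiles on the smaller native interval", {
  a <- tibble::tibble(time_h = seq(0, 1, 0.1), s = seq(0, 1, 0.1))
  rs <- resample_profiles(a, a)
  expect_equal(rs$a, a)
  expect_equal(rs$dt, 0.1)
  # linear midpoint
  b <- tibble::tibble(time_h = c(0, 1), s = c(0, 10))
  rs2 <- resample_profiles(b, b, dt = 0.1)
  expect_equal(rs2$a$s[rs2$a$time_h == 0.5], 5)
  # mixed grids: 0.1 h and 0.25 h resolve to 0.1 h
  c1 <- tibble::tibble(time_h = seq(0, 1, 0.25), s = 1:5)
  rs3 <- resample_profiles(a, c1)
  expect_equal(rs3$dt, 0.1)
  expect_error(resample_profiles(a, tibble::tibble(time_h = 2:3, s = 1:2)),
               "overlap")
})

test_that("lagged cross-correlation matches its defining convention", {
  t <- seq(0, 10, 0.1)
  x <- sin(t / 3) + exp(-(t - 4)^2)     # smooth non-periodic ramp + bump
  expect_equal(lagged_crosscorr(x, x, 0, 0.1)$r, 1)
  expect_equal(lagged_crosscorr(x, -x, 0, 0.1)$r, -1)
  # agreement with the reference implementation (stats::cor on the
  # overlapping slices) to 1e-10
  withr::with_seed(4, { y <- cumsum(rnorm(101)); z <- cumsum(rnorm(101)) })
  for (k in c(-7, -1, 0, 3, 12)) {
    n <- 101
    ref <- if (k >= 0) cor(y[1:(n - k)], z[(1 + k):n])
           else cor(y[(1 - k):n], z[1:(n + k)])
    expect_equal(lagged_crosscorr(y, z, k * 0.1, 0.1)$r, ref,
                 tolerance = 1e-10)
  }
  # symmetry: corr(x, y; l) = corr(y, x; -l)
  expect_equal(lagged_crosscorr(y, z, 0.5, 0.1)$r,
               lagged_crosscorr(z, y, -0.5, 0.1)$r, tolerance = 1e-12)
  # zero variance on the overlap is undefined, not zero
  expect_true(is.na(lagged_crosscorr(rep(1, 101), y, 0, 0.1)$r))
  expect_error(lagged_crosscorr(y, z, 0.05, 0.1), "integer multiple")
})

test_that("a planted shift is recovered as the best common lag", {
  t <- seq(0, 12, 0.1)
  base <- function(tt) exp(-(tt - 5)^2 / 2) + 0.3 * sin(tt / 2)
  base2 <- function(tt) 1 / (1 + exp(-(tt - 6))) + 0.2 * cos(tt / 3)
  sim <- tibble::tibble(time_h = t, p1 = base(t), p2 = base2(t))
  lag <- 1.2
  meas <- tibble::tibble(time_h = t, p1 = base(t - lag), p2 = base2(t - lag))
  res <- best_common_lag(sim, meas, c(-1.7, 1.7), dt = 0.1)
  expect_equal(res$best_lag, 1.2)
  expect_gt(res$median_at_best, 0.999)
  # identical profiles: zero lag, perfect correlation
  res0 <- best_common_lag(sim, sim, c(-1.7, 1.7), dt = 0.1)
  expect_equal(res0$best_lag, 0)
  expect_equal(res0$median_at_best, 1)
  expect_error(best_common_lag(sim, tibble::tibble(time_h = t, q = t)),
               "shared protein")
})

test_that("lag recovery stays within one grid step at signal-to-noise 10", {
  t <- seq(0, 12, 0.1)
  base <- function(tt) exp(-(tt - 5)^2 / 2)
  lag <- 1.2
  snr_ok <- withr::with_seed(6, {
    sig <- sd(base(t))
    sapply(1:5, function(i) {
      sim <- tibble::tibble(time_h = t,
                            p1 = base(t), p2 = base(t - 1), p3 = base(t + 1))
      meas <- tibble::tibble(time_h = t,
                             p1 = base(t - lag) + rnorm(length(t), 0, sig / 10),
                             p2 = base(t - 1 - lag) + rnorm(length(t), 0, sig / 10),
                             p3 = base(t + 1 - lag) + rnorm(length(t), 0, sig / 10))
      best_common_lag(sim, meas, c(-1.7, 1.7), dt = 0.1)$best_lag
    })
  })
  expect_true(all(abs(snr_ok - lag) <= 0.1 + 1e-9))
})

test_that("the fixture round trip recovers its planted lag through the full chain", {
  m <- toy_model("TOY2")
  tb <- toy_batch_setup("TOY2")
  ms <- synth_measurements(m, tb$init, tb$config, sigma = 0, lag = 1.2)
  fr <- mass_fraction_timecourse(ms$timecourse)
  sim_log <- dplyr::bind_cols(fr["time_h"],
                              tibble::as_tibble(log2_clamp(as.matrix(fr[-1]))))
  res <- best_common_lag(sim_log, ms$expression, c(-1.7, 1.7), dt = 0.1)
  expect_equal(res$best_lag, 1.2)
  expect_gt(res$median_at_best, 0.99)
})
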