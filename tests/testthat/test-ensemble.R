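test_that("keff perturbation factors are log-uniform on the stated range", {
  m <- toy_model("TOY2")
  pert <- perturb_keff(m, "all", n = 200, seed = 11)
  expect_identical(nrow(pert), 200L)
  f <- unlist(lapply(pert$factors, function(x) x$factor))
  expect_true(all(f >= 0.1 & f <= 10))
  # degenerate range: all factors exactly 1, models identical
  p1 <- perturb_keff(m, "all", n = 3, seed = 1, range = c(1, 1))
  expect_true(all(unlist(lapply(p1$factors, `[[`, "factor")) == 1))
  expect_identical(p1$model[[1]]$complexes$keff, m$complexes$keff)
  expect_error(perturb_keff(m, tibble::tibble(complex = "E_A", rxn = "NOPE"),
                            n = 1), "unknown keff coupling")
})

test_that("the sampling law is symmetric in log space", {
  m <- toy_model("TOY1")
  pert <- perturb_keff(m, "all", n = 10000, seed = 5)
  f <- unlist(lapply(pert$factors, `[[`, "factor"))
  # log-uniform on [0.1, 10] has median 1
  expect_gt(median(f), 0.8)
  expect_lt(median(f), 1.25)
  # about half the draws below 1 (binomial test at alpha = 0.01)
  expect_gt(binom.test(sum(f < 1), length(f), 0.5)$p.value, 0.01)
})

test_that("perturbation sampling is bitwise reproducible under a seed", {
  m <- toy_model("TOY5")
  a <- perturb_keff(m, "all", n = 10, seed = 99)
  b <- perturb_keff(m, "all", n = 10, seed = 99)
  expect_identical(a$factors, b$factors)
})

test_that("score_fit is an SSE on the common grid", {
  a <- tibble::tibble(time_h = 0:5, s = c(1, 2, 3, 4, 5, 6))
  expect_equal(score_fit(a, a), 0)
  b <- a
  b$s[2:4] <- b$s[2:4] + 1
  expect_equal(score_fit(a, b), 3)
  expect_error(score_fit(a, tibble::tibble(time_h = 0:5, other = 1:6)),
               "no shared species")
})

test_that("noisy self-comparison scores near n * sigma^2", {
  m <- toy_model("TOY2")
  tb <- toy_batch_setup("TOY2")
  clean <- synth_measurements(m, tb$init, tb$config, sigma = 0)
  noisy <- synth_measurements(m, tb$init, tb$config, sigma = 0.1, seed = 8)
  sse <- score_fit(clean$concentrations, noisy$concentrations,
                   grid = "measured")
  n <- nrow(noisy$concentrations) * 2   # two species
  expect_gt(sse / n, 0.005)   # E[SSE/n] = sigma^2 = 0.01
  expect_lt(sse / n, 0.02)
})

test_that("select_ensemble filters and orders by fit error", {
  sc <- tibble::tibble(sample = 1:3, sse = c(5, 1, 9))
  sel <- select_ensemble(sc, threshold = 6)
  expect_identical(sel$sample, c(2L, 1L))
  expect_identical(nrow(select_ensemble(sc, threshold = 0.5)), 0L)
  expect_identical(nrow(select_ensemble(sc, threshold = Inf)), 3L)
  # unperturbed model scored against itself: SSE 0, always selected
  m <- toy_model("TOY1")
  tb <- toy_batch_setup("TOY1")
  tc <- simulate_batch(m, tb$init, tb$config)
  sse0 <- score_fit(tc, tc$concentrations)
  expect_equal(sse0, 0)
  expect_true(1 %in% select_ensemble(tibble::tibble(sample = 1, sse = sse0),
                                     threshold = 0)$sample)
})
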