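test_that("step_update applies the stated integration rule", {
  st <- batch_state(c = c(glc = 10), X = 0.1)
  st2 <- step_update(st, v_ex = c(glc = -0.1), mu = 1 / 110, dt = 0.1)
  expect_equal(st2$c[["glc"]], 9.999)
  expect_equal(st2$X, 0.1 * exp(0.1 / 110))
  expect_equal(st2$t, 0.1)
  # zero exchange: concentrations unchanged, biomass still grows
  st3 <- step_update(st, v_ex = c(glc = 0), mu = 0.5, dt = 0.2)
  expect_equal(st3$c[["glc"]], 10)
  expect_equal(st3$X, 0.1 * exp(0.1))
  # mu = 0, zero exchange: identity except time
  st4 <- step_update(st, v_ex = c(glc = 0), mu = 0, dt = 0.3)
  expect_equal(st4$c, st$c)
  expect_equal(st4$X, st$X)
  expect_equal(st4$t, 0.3)
})

test_that("min_time_step lands on the first zero crossing", {
  st <- batch_state(c = c(A = 0.004), X = 0.2)
  expect_equal(min_time_step(st, v_ex = c(A = -0.1), dt0 = 0.5),
               0.004 / (0.1 * 0.2))
  # protein term
  st2 <- batch_state(c = c(A = 10), X = 0.2)
  expect_equal(min_time_step(st2, v_ex = c(A = 0), dt0 = 0.5,
                             p = c(E = 0.001), delta = c(E = -0.01)),
               0.1)
  # nothing threatened: the default step stands
  expect_equal(min_time_step(st2, v_ex = c(A = -0.1), dt0 = 0.5), 0.5)
})

test_that("availability changes are detected with their diff", {
  cfg <- sim_config()
  st <- batch_state(c = c(glc = 0, ac = 0.5), X = 0.1, t = 1)
  ch <- detect_environment_change("glc", st, cfg)
  expect_true(ch$changed)
  expect_identical(ch$added, "ac")
  expect_identical(ch$removed, "glc")
  st2 <- batch_state(c = c(glc = 3.2), X = 0.1)
  expect_false(detect_environment_change("glc", st2, cfg)$changed)
  # secretion crossing the threshold makes a metabolite newly available
  st3 <- batch_state(c = c(glc = 1, ac = 1e-4), X = 0.1)
  expect_true("ac" %in% detect_environment_change("glc", st3, cfg)$added)
})

test_that("TOY1 batch needs exactly one optimization", {
  tb <- toy_batch_setup("TOY1")
  tc <- simulate_batch(toy_model("TOY1"), tb$init, tb$config)
  expect_identical(nrow(tc$events), 1L)
  expect_identical(tc$events$trigger, "initial")
  expect_true(is.null(tc$error))
})

test_that("TOY2 batch: two solves, strict substrate preference, exact landing", {
  tb <- toy_batch_setup("TOY2")
  tc <- simulate_batch(toy_model("TOY2"), tb$init, tb$config)
  expect_identical(nrow(tc$events), 2L)
  t_dep <- tc$events$t[2]
  expect_match(tc$events$trigger[2], "A_e")
  # the poor substrate is untouched while the good one lasts
  before <- tc$fluxes$time_h < t_dep - 1e-9
  expect_lt(max(abs(tc$fluxes$UPT_B[before])), 1e-5)
  # the shortened step lands the depleting substrate exactly at zero
  i_dep <- which.min(abs(tc$concentrations$time_h - t_dep))
  expect_lt(abs(tc$concentrations$A_e[i_dep]), 1e-9)
  dts <- diff(tc$concentrations$time_h)
  expect_true(any(dts < 0.1 - 1e-9))   # MinTimeStep actually fired
  # after depletion growth continues on B at its own optimum
  expect_lt(abs(tc$events$mu[2] - toy1_mu_star(keff = 2)), 1e-5)
})

test_that("carbon balance closes at O(dt) and the defect halves with dt", {
  m <- toy_model("TOY2")
  defect <- function(dt0) {
    tb <- toy_batch_setup("TOY2", dt0 = dt0)
    tc <- simulate_batch(m, tb$init, tb$config)
    X <- tc$biomass$biomass_gdw_l
    n <- length(X)
    dts <- diff(tc$biomass$time_h)
    vform <- tc$fluxes$FORM_E_A + tc$fluxes$FORM_E_B
    # row k+1 carries the solution applied on interval (t_k, t_k+1]
    enz <- sum(vform[-1] * X[-n] * dts)
    consumed <- sum(tc$concentrations[1, c("A_e", "B_e")]) -
      sum(tc$concentrations[n, c("A_e", "B_e")])
    abs(consumed - 10 * (X[n] - X[1]) - 100 * enz)
  }
  d1 <- defect(0.1); d2 <- defect(0.05)
  expect_gt(d1 / d2, 1.8)
  expect_lt(d1 / d2, 2.2)
})

test_that("no concentration goes negative under adversarial step sizes", {
  m <- toy_model("TOY2")
  for (dt0 in c(0.37, 1.3, 5)) {
    tb <- toy_batch_setup("TOY2", dt0 = dt0)
    tc <- simulate_batch(m, tb$init, tb$config)
    expect_true(all(as.matrix(tc$concentrations[-1]) >= -1e-9))
  }
})

test_that("halving dt changes nothing but integration error when no event fires", {
  m <- toy_model("TOY1")
  tb1 <- toy_batch_setup("TOY1", dt0 = 0.2, t_batch = 4)
  tb2 <- toy_batch_setup("TOY1", dt0 = 0.1, t_batch = 4)
  tc1 <- simulate_batch(m, tb1$init, tb1$config)
  tc2 <- simulate_batch(m, tb2$init, tb2$config)
  expect_identical(nrow(tc1$events), 1L)
  expect_identical(nrow(tc2$events), 1L)
  expect_equal(unique(tc1$biomass$mu_per_h), unique(tc2$biomass$mu_per_h))
  # compare at the coarse run's timepoints (grids accumulate in floating
  # point, so match by interpolation rather than exact equality)
  fine <- approx(tc2$concentrations$time_h, tc2$concentrations$A_e,
                 xout = tc1$concentrations$time_h)$y
  expect_equal(tc1$concentrations$A_e, fine, tolerance = 1e-5)
})

test_that("a feed window re-triggers optimization at its boundary", {
  m <- toy_model("TOY1")
  tb <- toy_batch_setup("TOY1", t_batch = 2)
  tb$init$c["A_e"] <- 0    # start starved; feed begins at t = 1
  cfg <- sim_config(dt0 = 0.1, t_batch = 2,
                    feed = tibble::tibble(met = "A_e", t_start = 1,
                                          t_end = 2, rate = 0.5))
  tc <- simulate_batch(m, batch_state(c = c(A_e = 0), X = 0.1), cfg)
  expect_gte(nrow(tc$events), 2L)
  expect_lt(abs(tc$events$mu[1]), 1e-6)
  expect_true(any(abs(tc$events$t - 1) < 1e-9))
  expect_gt(max(tc$biomass$mu_per_h), 0)   # growth resumes on the feed
})
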