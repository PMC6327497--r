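test_that("mu expressions evaluate their three forms correctly", {
  expect_equal(mu_eval(mu_expr("constant", 7), c(0, 1.5)), c(7, 7))
  expect_equal(mu_eval(mu_expr("linear", a = 1, b = 2), 0.25), 1.5)
  # hyperbolic a*mu/(b+mu): zero at mu = 0, saturating towards a
  h <- mu_expr("hyperbolic", a = 1, b = 1)
  expect_equal(mu_eval(h, 0), 0)
  expect_equal(mu_eval(h, 1), 0.5)
  expect_error(mu_expr("hyperbolic", a = 1, b = 0), "b > 0")
  expect_error(mu_eval(h, -0.1), "mu")
})

test_that("fixed-mu instantiation encodes coupling and bounds", {
  m <- toy_model("TOY1")
  lp <- evaluate_at_mu(m, 0.01)
  # dilution coupling -mu/keff on the enzyme row of the catalyzed reaction
  expect_equal(lp$A["E_A", "UPT_A"], -0.01 / 10)
  # formation carries +1 on the enzyme row
  expect_equal(lp$A["E_A", "FORM_E_A"], 1)
  # growth flux pinned to mu through linear bounds
  gi <- match("GROWTH", lp$vars)
  expect_equal(lp$lb[gi], 0.01)
  expect_equal(lp$ub[gi], 0.01)
  # proteome budget slack bounded by mu * e_max (u(mu) = mu * e_max form)
  bi <- match(".budget_slack", lp$vars)
  expect_equal(lp$ub[bi], 0.01 * 0.01)
  lp5 <- evaluate_at_mu(m, 0.5)
  expect_equal(lp5$ub[match(".budget_slack", lp5$vars)], 0.5 * 0.01)
  expect_error(evaluate_at_mu(m, 3), "mu_max")
  expect_error(evaluate_at_mu(m, -0.1), "mu_max")
})

test_that("instantiation is continuous in mu", {
  m <- toy_model("TOY2")
  target <- evaluate_at_mu(m, 0.02)$A
  for (eps in c(1e-3, 1e-6, 1e-9)) {
    d <- max(abs(evaluate_at_mu(m, 0.02 + eps)$A - target))
    expect_lt(d, 10 * eps)
  }
})

test_that("validate_model reports the specific broken invariant", {
  expect_no_violations(toy_model("TOY1"))
  m <- toy_model("TOY1")
  m$complexes$keff[[1]]["UPT_A"] <- 0
  d <- validate_model(m)
  expect_identical(nrow(d), 1L)
  expect_identical(d$check, "keff_positive")
  expect_match(d$object, "E_A:UPT_A")

  m2 <- toy_model("TOY1")
  m2$complexes$formation_rxn[1] <- "NOPE"
  d2 <- validate_model(m2)
  expect_true("formation" %in% d2$check)

  m3 <- toy_model("TOY1")
  m3$complexes$keff[[1]] <- numeric()
  expect_true("cat_nonempty" %in% validate_model(m3)$check)
})

test_that("model JSON round trip preserves everything exactly", {
  for (toy in c("TOY1", "TOY2", "TOY5")) {
    m <- toy_model(toy)
    path <- withr::local_tempfile(fileext = ".json")
    write_me_model(m, path)
    m2 <- read_me_model(path)
    expect_identical(m2$metabolites, m$metabolites)
    expect_identical(m2$reactions, m$reactions)
    expect_identical(m2$exchanges, m$exchanges)
    expect_identical(m2$mu_max, m$mu_max)
    expect_identical(m2$complexes$keff, m$complexes$keff)
    expect_identical(m2$budget, m$budget)
    # expression coefficients bit-identical
    for (i in seq_len(nrow(m$stoichiometry))) {
      expect_identical(m2$stoichiometry$expr[[i]], m$stoichiometry$expr[[i]])
    }
    for (i in seq_len(nrow(m$bounds))) {
      expect_identical(m2$bounds$lower[[i]], m$bounds$lower[[i]])
      expect_identical(m2$bounds$upper[[i]], m$bounds$upper[[i]])
    }
    # and the instantiated problems agree entrywise
    expect_equal(evaluate_at_mu(m2, 0.007)$A, evaluate_at_mu(m, 0.007)$A)
  }
})
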