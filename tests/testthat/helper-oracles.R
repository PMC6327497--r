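# Closed-form oracles for the toy fixtures, derived by hand from the
# budget-limited steady state (independent of the LP/bisection code path).
#
# Growing on a single substrate with yield y, rate constant k, biomass
# cost b, enzyme cost q and budget e_max, the enzyme pool is fully used
# (e = e_max) and the precursor balance y*k*e = b*mu + q*mu*e gives
#   mu* = y * k * e_max / (b + q * e_max).
toy1_mu_star <- function(keff = 10, bcost = 10, ecost = 100, emax = 0.01,
                         yield = 1) {
  yield * keff * emax / (bcost + ecost * emax)
}

# With the inertia horizon H and p0 = 0: p = delta*H, v_form = p/H + mu*p,
# same balance with p = e_max at the budget =>
#   mu*(H) = e_max * (y*k - q/H) / (b + q*e_max), clipped at 0.
toy1_mu_star_inertia <- function(H, keff = 10, bcost = 10, ecost = 100,
                                 emax = 0.01, yield = 1) {
  max(0, emax * (yield * keff - ecost / H) / (bcost + ecost * emax))
}

# Brute-force feasibility oracle: locate the growth optimum WITHOUT the
# bisection driver, by doubling until infeasible then linearly scanning a
# mu grid of width `grid`. Only uses evaluate_at_mu + solve_lp as the
# feasibility primitive.
grid_scan_mu <- function(model, grid = 2e-4, bounds_override = NULL) {
  feasible <- function(mu) {
    solve_lp(evaluate_at_mu(model, mu, bounds_override))$status == "optimal"
  }
  if (!feasible(0)) return(NA_real_)
  lo <- 0; hi <- grid
  while (hi < model$mu_max && feasible(hi)) { lo <- hi; hi <- 2 * hi }
  if (hi >= model$mu_max) hi <- model$mu_max
  mus <- seq(lo, hi, by = grid)
  best <- lo
  for (mu in mus) if (feasible(mu)) best <- mu
  best
}

# random single-substrate toy within well-scaled parameter ranges
random_toy1 <- function() {
  toy_model("TOY1",
            substrates = tibble::tibble(id = "A",
                                        keff = runif(1, 2, 20),
                                        conc0 = 10),
            biomass_cost = runif(1, 5, 20),
            enzyme_cost = runif(1, 50, 200),
            e_max = runif(1, 0.005, 0.05))
}

# Dirichlet draws via normalized gammas (for planted simplex weights)
gtools_rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

expect_no_violations <- function(model) {
  expect_identical(nrow(validate_model(model)), 0L)
}
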