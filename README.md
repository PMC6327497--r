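# mebatch

Dynamic batch-culture simulation of metabolism-and-expression (ME)
models, with the surrounding machinery needed to work with them:
rate-constant perturbation ensembles, archetypal analysis of time-course
profiles, metaheuristic calibration, and cross-correlation validation of
predicted proteome dynamics against measured expression.

## The problem

Constraint-based metabolic models predict flux distributions by linear
programming; dynamic flux balance analysis (dFBA) couples them to
extracellular mass balances to simulate a batch culture. ME models extend
metabolic models with the expression machinery itself: the stoichiometric
matrix and the flux bounds become functions of the growth rate μ, and
every catalyzed flux is tied to the concentration of its enzyme through an
effective rate constant (v = k_eff · e). Growth maximization is then

    max_{μ, v}  μ
    s.t.        S(μ) v = 0
                l(μ) ≤ v ≤ u(μ)

which is a linear program for any fixed μ and quasi-convex in μ, so the
optimum is found by bisection on μ. `mebatch` simulates batch growth of
such models in two modes:

* **event-driven** — exchange fluxes from one growth solve are propagated
  through the extracellular balances until substrate availability changes
  (depletion, feeding, or secretion of a re-consumable by-product), and
  only then is a new optimization performed;
* **protein inertia** — the proteome carries over between steps. Complex
  concentrations `p` become decision variables tied to the previous step
  via `p = p0 + δH` over an anticipation horizon `H`, with
  `v_form − μp = δ`, catalytic capacity `Σ_j v_j / k_eff ≤ p`, and no
  active degradation (`v_form ≥ 0`), so complex levels fall only by
  growth dilution. This problem is re-solved at every step.

A variable-time-step rule shortens any step that would drive an
extracellular or complex concentration negative, landing it exactly on
the zero crossing.

Around the simulator, the package implements the full analysis loop for
uncertain rate constants: log-uniform k_eff perturbation ensembles on
[0.1, 10]×, archetypal analysis (X ≈ ZA with Z = XB under column-simplex
constraints, fitted by alternating simplex-constrained least squares,
with an explicit distance-to-chord elbow rule for the number of
archetypes), calibration of k_eff multipliers by list-based threshold
accepting (including a deterministic multi-walker contract with
synchronized restarts), and validation of predicted proteome mass
fractions against measured expression profiles by lag-scanned
cross-correlation.

Everything is testable at desk scale through built-in toy models with
pencil-and-paper optima (see `?toy_model`).

## Worked example

`TOY2` has two substrates sharing one proteome budget: substrate A
(k_eff = 10/h) and substrate B (k_eff = 2/h). The budget-limited optimum
on A alone is μ\* = 1/110 ≈ 0.00909 h⁻¹.

```r
library(mebatch)

model <- toy_model("TOY2")
maximize_growth(model)$mu
#> [1] 0.009090424

setup <- toy_batch_setup("TOY2")
tc <- simulate_batch(model, setup$init, setup$config)
tc$events
#> # A tibble: 2 × 3
#>       t trigger      mu
#>   <dbl> <chr>     <dbl>
#> 1  0    initial 0.00909
#> 2  2.96 -A_e    0.00182
```

Exactly two optimizations were needed for the whole 10 h batch: one at
t = 0 and one when A runs out at t ≈ 2.96 h (`-A_e`), after which growth
continues on the five-fold less efficient substrate B at
μ = 0.02/11 ≈ 0.00182 h⁻¹ — the diauxic switch, produced purely by the
shared proteome budget. Between those two instants the exchange fluxes
are constant and no LP is solved. `autoplot(tc)` draws the concentration
and biomass profiles with the solve events marked;
`tidy(tc)`/`glance(tc)` return the trajectories and a one-row summary.

The same model family drives the rest of the pipeline:

```r
meas <- synth_measurements(model, setup$init, setup$config,
                           sigma = 0, lag = 1.2)   # "measured" data,
                                                   # delayed by 1.2 h
fr <- mass_fraction_timecourse(meas$timecourse)
sim <- dplyr::bind_cols(fr["time_h"],
                        tibble::as_tibble(log2_clamp(as.matrix(fr[-1]))))
best_common_lag(sim, meas$expression, lag_range = c(-1.7, 1.7), dt = 0.1)
#> <xcorr_result> best common lag: 1.2 h; median r = 1 over 2 proteins
```

The lag scan recovers the planted 1.2 h delay exactly, with the expected
sign convention: a positive lag means the predicted proteome dynamics run
ahead of the measurements.

A command-line wrapper (`inst/cli/mebatch`) exposes the pipeline as
subcommands (`make-toy`, `simulate`, `ensemble`, `archetypes`, `fit`,
`validate`) that chain through plain CSV/JSON artifacts; see
`?mebatch_cli`.

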