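#' Specification for a desk-scale toy ME model
#'
#' The toy family shares one architecture: each substrate `s` is imported
#' by a dedicated enzyme complex `E_s` (`UPT_s: s_e -> yield * M`,
#' coupled with rate constant `keff_s`), the common precursor `M` feeds
#' biomass (`GROWTH: biomass_cost * M -> 0`, with the growth flux pinned
#' to `mu` through linear bounds) and enzyme synthesis
#' (`FORM_E_s: enzyme_cost * M -> E_s`), and all complexes share a
#' proteome budget `sum(p_i) <= e_max`. Optionally one substrate
#' overflows: its uptake co-produces a secreted, re-consumable by-product.
#'
#' Because the budget is the single active constraint, the optimum is
#' pencil-and-paper: growing on substrate `s` alone,
#' `mu* = yield * keff_s * e_max / (biomass_cost + enzyme_cost * e_max)`,
#' and with the inertia horizon `H` starting from `p0 = 0`,
#' `mu*(H) = e_max * (yield * keff_s - enzyme_cost / H) /
#' (biomass_cost + enzyme_cost * e_max)` (clipped at 0). These closed
#' forms are the independent oracles for the solver tests.
#'
#' @param substrates data frame with columns `id`, `keff` (1/h) and
#'   optionally `conc0` (mmol/L), `cap` (uptake upper bound, mmol/gDW/h),
#'   `yield` (mmol M per mmol substrate).
#' @param biomass_cost mmol M per gDW biomass.
#' @param enzyme_cost mmol M per mmol complex.
#' @param e_max shared proteome budget, mmol/gDW.
#' @param overflow optional by-product: list with `from` (substrate id),
#'   `met`, `yield` (mmol by-product per mmol substrate taken up), `keff`
#'   (1/h, re-consumption), `m_yield` (mmol M per mmol by-product).
#' @param X0 initial biomass, gDW/L.
#' @param mu_max bisection bracket, 1/h.
#' @param id model id.
#' @return a `toy_spec` list.
#' @export
toy_spec <- function(substrates, biomass_cost = 10, enzyme_cost = 100,
                     e_max = 0.01, overflow = NULL, X0 = 0.1, mu_max = 2,
                     id = "toy") {
  substrates <- as_tibble(substrates)
  stopifnot(all(c("id", "keff") %in% names(substrates)))
  if (!"conc0" %in% names(substrates)) substrates$conc0 <- 10
  if (!"cap" %in% names(substrates)) substrates$cap <- Inf
  if (!"yield" %in% names(substrates)) substrates$yield <- 1
  if (any(substrates$keff <= 0) || biomass_cost <= 0 || enzyme_cost <= 0 ||
      e_max <= 0) {
    abort_domain("toy_spec requires positive keff, costs and e_max.")
  }
  structure(list(substrates = substrates, biomass_cost = biomass_cost,
                 enzyme_cost = enzyme_cost, e_max = e_max,
                 overflow = overflow, X0 = X0, mu_max = mu_max, id = id),
            class = "toy_spec")
}

#' Build an ME model from a toy specification
#'
#' @param spec a [toy_spec()].
#' @return a valid [me_model()] (zero [validate_model()] violations by
#'   construction).
#' @export
make_toy_model <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  sub <- spec$substrates
  ofl <- spec$overflow

  all_sub <- sub
  if (!is.null(ofl)) {
    stopifnot(ofl$from %in% sub$id)
    all_sub <- bind_rows(sub, tibble(id = ofl$met, keff = ofl$keff,
                                     conc0 = 0, cap = Inf,
                                     yield = ofl$m_yield))
  }
  s_e <- paste0(all_sub$id, "_e")
  mets <- tibble(id = c(s_e, "M", paste0("E_", all_sub$id)),
                 extracellular = c(rep(TRUE, length(s_e)),
                                   rep(FALSE, 1 + nrow(all_sub))))
  ex_r <- paste0("EX_", all_sub$id)
  up_r <- paste0("UPT_", all_sub$id)
  fm_r <- paste0("FORM_E_", all_sub$id)
  rxns <- tibble(id = c(ex_r, up_r, fm_r, "GROWTH"))

  st <- list()
  add <- function(met, rxn, coef) {
    st[[length(st) + 1L]] <<- tibble(met = met, rxn = rxn,
                                     expr = list(mu_expr("constant", coef)))
  }
  for (i in seq_len(nrow(all_sub))) {
    sid <- all_sub$id[i]
    add(paste0(sid, "_e"), paste0("EX_", sid), -1)
    add(paste0(sid, "_e"), paste0("UPT_", sid), -1)
    add("M", paste0("UPT_", sid), all_sub$yield[i])
    add("M", paste0("FORM_E_", sid), -spec$enzyme_cost)
    add(paste0("E_", sid), paste0("FORM_E_", sid), 1)
  }
  if (!is.null(ofl)) {
    add(paste0(ofl$met, "_e"), paste0("UPT_", ofl$from), ofl$yield)
  }
  add("M", "GROWTH", -spec$biomass_cost)

  bounds <- bind_rows(
    tibble(rxn = ex_r,
           lower = list(mu_expr("constant", -1000)),
           upper = list(mu_expr("constant", 1000))),
    tibble(rxn = up_r,
           lower = list(mu_expr("constant", 0)),
           upper = lapply(pmin(all_sub$cap, 1000), function(u)
             mu_expr("constant", u))),
    tibble(rxn = fm_r,
           lower = list(mu_expr("constant", 0)),
           upper = list(mu_expr("constant", 1000))),
    tibble(rxn = "GROWTH",
           lower = list(mu_expr("linear", a = 0, b = 1)),
           upper = list(mu_expr("linear", a = 0, b = 1))))

  complexes <- tibble(
    id = paste0("E_", all_sub$id),
    formation_rxn = fm_r,
    weight_kda = 30 + 10 * seq_len(nrow(all_sub)),
    keff = lapply(seq_len(nrow(all_sub)), function(i)
      setNames(all_sub$keff[i], paste0("UPT_", all_sub$id[i]))))
  proteins <- tibble(
    id = paste0("P_", all_sub$id),
    translation_rxn = fm_r,
    weight_kda = complexes$weight_kda)

  me_model(
    metabolites = mets, reactions = rxns, stoichiometry = bind_rows(st),
    bounds = bounds, complexes = complexes, proteins = proteins,
    exchanges = setNames(ex_r, s_e),
    budget = list(e_max = spec$e_max,
                  coefficients = setNames(rep(1, nrow(complexes)),
                                          complexes$id)),
    mu_max = spec$mu_max, id = spec$id)
}

toy_presets <- function(name) {
  switch(name,
    TOY1 = toy_spec(
      tibble(id = "A", keff = 10, conc0 = 10),
      biomass_cost = 10, enzyme_cost = 100, e_max = 0.01, id = "TOY1"),
    TOY2 = toy_spec(
      tibble(id = c("A", "B"), keff = c(10, 2), conc0 = c(0.03, 1)),
      biomass_cost = 10, enzyme_cost = 100, e_max = 0.01, id = "TOY2"),
    TOY5 = toy_spec(
      tibble(id = c("glc", "mal", "gal", "lac", "glyc"),
             keff = c(10, 5, 4, 3, 2),
             conc0 = c(0.3, 0.12, 0.12, 0.1, 0.1),
             cap = c(Inf, 0.3, Inf, Inf, Inf)),
      biomass_cost = 10, enzyme_cost = 100, e_max = 0.1,
      overflow = list(from = "glc", met = "ac", yield = 0.5, keff = 1,
                      m_yield = 0.5),
      id = "TOY5"),
    abort_domain(paste0("unknown toy preset: ", name)))
}

#' Canonical toy fixtures
#'
#' Three ready-made models with known behavior:
#' * `TOY1` — one substrate (`keff = 10`, biomass cost 10, enzyme cost
#'   100, `e_max = 0.01`), closed-form optimum `mu* = 1/110`.
#' * `TOY2` — two substrates (`keff` 10 vs 2) on a shared budget; the
#'   high-`keff` substrate is strictly preferred while present, the first
#'   depleting mid-batch.
#' * `TOY5` — five substrates with staggered `keff` (the second capped so
#'   a mixed-utilization phase appears) plus a secreted, re-consumable
#'   overflow by-product: single-substrate, mixed, and by-product
#'   re-consumption phases in one batch.
#'
#' @param name `"TOY1"`, `"TOY2"` or `"TOY5"`.
#' @param ... overrides passed to [toy_spec()] (e.g. `e_max = 0.02`).
#' @return an [me_model()].
#' @export
toy_model <- function(name = c("TOY1", "TOY2", "TOY5"), ...) {
  name <- match.arg(name)
  spec <- toy_presets(name)
  dots <- list(...)
  if (length(dots)) {
    args <- spec[c("substrates", "biomass_cost", "enzyme_cost", "e_max",
                   "overflow", "X0", "mu_max", "id")]
    for (nm in names(dots)) args[[nm]] <- dots[[nm]]
    spec <- do.call(toy_spec, args)
  }
  make_toy_model(spec)
}

#' Default batch setup for a toy fixture
#'
#' @param name toy preset name.
#' @param ... overrides passed to [sim_config()].
#' @return list with `init` ([batch_state()]) and `config`
#'   ([sim_config()]).
#' @export
toy_batch_setup <- function(name = c("TOY1", "TOY2", "TOY5"), ...) {
  name <- match.arg(name)
  spec <- toy_presets(name)
  sub <- spec$substrates
  c0 <- setNames(sub$conc0, paste0(sub$id, "_e"))
  if (!is.null(spec$overflow)) {
    c0[paste0(spec$overflow$met, "_e")] <- 0
  }
  cfg <- list(...)
  defaults <- list(dt0 = 0.1, t_batch = if (name == "TOY5") 20 else 10)
  for (nm in names(cfg)) defaults[[nm]] <- cfg[[nm]]
  list(init = batch_state(c = c0, X = spec$X0),
       config = do.call(sim_config, defaults))
}

#' Synthetic "measured" batch data
#'
#' Stand-in for measured batch concentration and expression time courses:
#' simulates the model, shifts every profile by `lag` (a positive lag
#' delays the measurements relative to the simulation), samples onto a
#' regular grid, and adds i.i.d. Gaussian noise — `sigma` to
#' concentrations (clamped at 0) and to log2 expression. Expression is
#' the log2 proteome mass-fraction profile (see
#' [mass_fraction_timecourse()], [log2_clamp()]). The noise model is a
#' deliberately simple testbed, not a claim about microarray error
#' structure.
#'
#' @param model an [me_model()].
#' @param init a [batch_state()].
#' @param config a [sim_config()].
#' @param sigma noise standard deviation (`>= 0`).
#' @param lag shift, h (within +/- 2 h).
#' @param seed RNG seed for reproducibility.
#' @return list with tibbles `concentrations` and `expression` (columns
#'   `time_h` + species), the underlying `timecourse`, and the `lag` and
#'   `sigma` used.
#' @export
synth_measurements <- function(model, init, config = sim_config(),
                               sigma = 0, lag = 0, seed = NULL) {
  stopifnot(sigma >= 0, abs(lag) <= 2)
  tc <- simulate_batch(model, init, config)
  fr <- mass_fraction_timecourse(tc)
  fr_log <- bind_cols(fr["time_h"],
                      as_tibble(log2_clamp(as.matrix(fr[-1]))))

  grid <- seq(0, config$t_batch, by = config$dt0)
  tmax <- max(tc$concentrations$time_h)
  grid <- grid[grid - lag >= 0 & grid - lag <= tmax + 1e-9]

  shift_tbl <- function(df) {
    out <- tibble(time_h = grid)
    for (sp in setdiff(names(df), "time_h")) {
      out[[sp]] <- approx(df$time_h, df[[sp]], xout = pmin(grid - lag, tmax),
                          rule = 2)$y
    }
    out
  }
  conc <- shift_tbl(tc$concentrations)
  expr <- shift_tbl(fr_log)
  with_seed(seed, {
    if (sigma > 0) {
      for (sp in setdiff(names(conc), "time_h")) {
        conc[[sp]] <- pmax(conc[[sp]] + rnorm(nrow(conc), 0, sigma), 0)
      }
      for (sp in setdiff(names(expr), "time_h")) {
        expr[[sp]] <- expr[[sp]] + rnorm(nrow(expr), 0, sigma)
      }
    }
  })
  list(concentrations = conc, expression = expr, timecourse = tc,
       lag = lag, sigma = sigma)
}
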