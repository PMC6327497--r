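#' Batch state and simulation configuration
#'
#' `batch_state()` holds the extracellular medium at one instant: time `t`
#' (h), named concentrations `c` (mmol/L) and biomass `X` (gDW/L).
#' `sim_config()` collects the simulation controls; defaults are a
#' time step of 0.1 h, a 10 h batch, and an anticipation horizon `H = 2` h
#' for the inertia mode. Available substrates get the effectively
#' unconstrained exchange lower bound `exchange_lb = -1000` mmol/gDW/h;
#' depleted ones get 0. `bounds_override` pins fixed exchange bounds that
#' bypass availability logic (e.g. an oxygen uptake cap of -20 mmol/gDW/h).
#'
#' @param t time, h.
#' @param c named numeric vector of extracellular concentrations, mmol/L.
#' @param X biomass, gDW/L.
#' @export
batch_state <- function(c, X, t = 0) {
  stopifnot(is.numeric(c), !is.null(names(c)), all(c >= 0),
            is_number(X), X > 0, is_number(t))
  structure(list(t = t, c = c, X = X), class = "batch_state")
}

#' @rdname batch_state
#' @param dt0 default time step, h.
#' @param t_batch total batch time, h.
#' @param H anticipation horizon for the inertia mode, h.
#' @param feed optional feed schedule: a data frame with columns `met`,
#'   `t_start`, `t_end`, `rate` (mmol/L/h).
#' @param exchange_lb,exchange_ub exchange bounds applied to available
#'   tracked substrates, mmol/gDW/h.
#' @param bounds_override named list `rxn -> c(lower, upper)` of fixed
#'   bounds applied after availability logic.
#' @param depletion_tol concentration below which a substrate counts as
#'   depleted (then clamped to 0), mmol/L.
#' @param solver_tol growth bisection tolerance, 1/h.
#' @export
sim_config <- function(dt0 = 0.1, t_batch = 10, H = 2, feed = NULL,
                       exchange_lb = -1000, exchange_ub = 1000,
                       bounds_override = NULL, depletion_tol = 1e-9,
                       solver_tol = 1e-6) {
  stopifnot(is_number(dt0), dt0 > 0, is_number(t_batch), t_batch > 0,
            is_number(H), H > 0)
  if (!is.null(feed)) {
    feed <- as_tibble(feed)
    stopifnot(all(c("met", "t_start", "t_end", "rate") %in% names(feed)))
  }
  structure(list(dt0 = dt0, t_batch = t_batch, H = H, feed = feed,
                 exchange_lb = exchange_lb, exchange_ub = exchange_ub,
                 bounds_override = bounds_override,
                 depletion_tol = depletion_tol, solver_tol = solver_tol),
            class = "sim_config")
}

feed_rates_at <- function(config, t, mets) {
  r <- setNames(rep(0, length(mets)), mets)
  f <- config$feed
  if (!is.null(f)) {
    act <- f$t_start <= t + 1e-12 & t < f$t_end - 1e-12 & f$met %in% mets
    for (i in which(act)) r[f$met[i]] <- r[f$met[i]] + f$rate[i]
  }
  r
}

availability_set <- function(c, t, config) {
  avail <- names(c)[c > config$depletion_tol]
  f <- config$feed
  if (!is.null(f)) {
    act <- f$t_start <= t + 1e-12 & t < f$t_end - 1e-12
    avail <- union(avail, f$met[act])
  }
  sort(avail)
}

#' Did substrate availability change?
#'
#' The event that triggers a re-optimization in the event-driven loop: a
#' substrate became depleted (fully consumed), or newly available through
#' feeding or secretion.
#'
#' @param prev_availability character vector of previously available
#'   metabolites.
#' @param state a [batch_state()].
#' @param config a [sim_config()] (supplies the depletion threshold and
#'   feed schedule).
#' @return list with `changed` (flag), `added`, `removed`, and the new
#'   `availability`.
#' @export
detect_environment_change <- function(prev_availability, state,
                                      config = sim_config()) {
  avail <- availability_set(state$c, state$t, config)
  added <- setdiff(avail, prev_availability)
  removed <- setdiff(prev_availability, avail)
  list(changed = length(added) + length(removed) > 0,
       added = added, removed = removed, availability = avail)
}

#' Advance the extracellular state by one time step
#'
#' Biomass grows exponentially at the (constant within the step) growth
#' rate, `X' = X exp(mu dt)`; concentrations follow forward Euler with the
#' start-of-step biomass, `c'_i = c_i + v_i X dt + feed_i dt`. The step is
#' assumed to have passed through [min_time_step()], so `c' >= 0`; a
#' violation beyond tolerance is an internal error.
#'
#' @param state a [batch_state()].
#' @param v_ex named exchange fluxes by metabolite, mmol/gDW/h (negative =
#'   uptake).
#' @param mu growth rate, 1/h.
#' @param dt step, h.
#' @param feed_rates optional named feed rates, mmol/L/h.
#' @return the advanced [batch_state()].
#' @export
step_update <- function(state, v_ex, mu, dt, feed_rates = NULL) {
  stopifnot(inherits(state, "batch_state"), is_number(dt), dt > 0)
  c2 <- state$c
  mets <- intersect(names(c2), names(v_ex))
  c2[mets] <- c2[mets] + v_ex[mets] * state$X * dt
  if (!is.null(feed_rates)) {
    mets <- intersect(names(c2), names(feed_rates))
    c2[mets] <- c2[mets] + feed_rates[mets] * dt
  }
  if (any(c2 < -1e-7)) {
    abort_solver(paste0("concentration went negative (missed MinTimeStep): ",
                        paste(names(c2)[c2 < -1e-7], collapse = ", ")))
  }
  c2[c2 < 0] <- 0
  batch_state(c = c2, X = state$X * exp(mu * dt), t = state$t + dt)
}

#' Variable time step: land exactly on depletion events
#'
#' If the default step would drive an extracellular concentration (or, in
#' inertia mode, a complex concentration) negative, the step is shortened
#' to the first zero crossing:
#' `dt = min(dt0, min_i c_i / (-r_i X), min_i p_i / (-delta_i))`
#' over the species that would be overshot (`r_i` the net per-biomass
#' rate including feed).
#'
#' @inheritParams step_update
#' @param dt0 default step, h.
#' @param p,delta optional complex concentrations and rates (inertia mode).
#' @return the realized step, h (`> 0`).
#' @export
min_time_step <- function(state, v_ex, dt0, p = NULL, delta = NULL,
                          feed_rates = NULL) {
  stopifnot(is_number(dt0), dt0 > 0)
  dt <- dt0
  mets <- intersect(names(state$c), names(v_ex))
  rate <- v_ex[mets] * state$X
  if (!is.null(feed_rates)) {
    rate <- rate + ifelse(mets %in% names(feed_rates), feed_rates[mets], 0)
  }
  for (m in mets) {
    # ignore solver-noise fluxes and already-empty pools (the updater
    # clamps sub-tolerance negatives to zero)
    if (rate[m] < -1e-12 && state$c[m] > 1e-12 &&
        state$c[m] + rate[m] * dt0 < 0) {
      dt <- min(dt, state$c[m] / (-rate[m]))
    }
  }
  if (!is.null(p) && !is.null(delta)) {
    for (i in intersect(names(p), names(delta))) {
      if (delta[i] < -1e-12 && p[i] > 1e-12 && p[i] + delta[i] * dt0 < 0) {
        dt <- min(dt, p[i] / (-delta[i]))
      }
    }
  }
  max(dt, 1e-12)
}

# assemble exchange-bound overrides from availability
avail_overrides <- function(model, tracked, avail, config) {
  ov <- list()
  for (m in tracked) {
    r <- model$exchanges[[m]]
    if (is.null(r)) {
      abort_model(paste0("tracked metabolite has no exchange reaction: ", m))
    }
    lbm <- if (m %in% avail) config$exchange_lb else 0
    ov[[r]] <- c(lbm, config$exchange_ub)
  }
  for (r in names(config$bounds_override)) ov[[r]] <- config$bounds_override[[r]]
  ov
}

new_me_timecourse <- function(rows, events, mode, model, error = NULL) {
  time_h <- map_dbl(rows, "t")
  conc <- bind_rows(lapply(rows, function(r) as_tibble(as.list(r$c))))
  fluxes <- bind_rows(lapply(rows, function(r) as_tibble(as.list(r$v))))
  prot <- bind_rows(lapply(rows, function(r) as_tibble(as.list(r$prot))))
  structure(list(
    concentrations = bind_cols(tibble(time_h = time_h), conc),
    biomass = tibble(time_h = time_h,
                     biomass_gdw_l = map_dbl(rows, "X"),
                     mu_per_h = map_dbl(rows, "mu")),
    fluxes = bind_cols(tibble(time_h = time_h), fluxes),
    proteome = bind_cols(tibble(time_h = time_h), prot),
    events = events,
    mode = mode,
    protein_weights = setNames(model$proteins$weight_kda, model$proteins$id),
    complex_weights = setNames(model$complexes$weight_kda, model$complexes$id),
    error = error
  ), class = "me_timecourse")
}

#' @export
print.me_timecourse <- function(x, ...) {
  cat("<me_timecourse> mode: ", x$mode, "; ",
      nrow(x$concentrations), " timepoints, ",
      ncol(x$concentrations) - 1L, " tracked metabolites, ",
      nrow(x$events), " solve events\n", sep = "")
  if (!is.null(x$error)) cat("  ! aborted early: ", x$error, "\n", sep = "")
  invisible(x)
}

#' Event-driven batch simulation
#'
#' Simulates a batch culture by coupling the growth-maximizing model to
#' extracellular mass balances. An optimization is performed at `t = 0`
#' and thereafter only when substrate availability changes (depletion,
#' feed-window boundary, or secretion making a metabolite newly
#' available); between solves the last exchange fluxes and growth rate
#' are propagated through [step_update()], with [min_time_step()]
#' shortening steps that would overshoot a depletion. Every optimization
#' is recorded in the solve-event log with its trigger.
#'
#' @param model an [me_model()].
#' @param init a [batch_state()]; its `c` names define the tracked
#'   metabolites (each must have an exchange reaction).
#' @param config a [sim_config()].
#' @return an `me_timecourse`: tibbles `concentrations`, `biomass`,
#'   `fluxes`, `proteome` (translation fluxes by protein) sharing the time
#'   grid, and the solve-event log `events`.
#' @examples
#' tb <- toy_batch_setup("TOY1")
#' tc <- simulate_batch(toy_model("TOY1"), tb$init, tb$config)
#' nrow(tc$events)  # single solve: substrate never runs out
#' @export
simulate_batch <- function(model, init, config = sim_config()) {
  stopifnot(is_me_model(model), inherits(init, "batch_state"),
            inherits(config, "sim_config"))
  tracked <- names(init$c)
  trsl <- setNames(model$proteins$translation_rxn, model$proteins$id)
  exch <- model$exchanges[tracked]

  rows <- list(); events <- list(); err <- NULL
  state <- init
  avail <- availability_set(state$c, state$t, config)

  solve_now <- function(trigger) {
    ov <- avail_overrides(model, tracked, avail, config)
    sol <- maximize_growth(model, tol = config$solver_tol, bounds_override = ov)
    if (sol$status != "optimal") {
      abort_solver(paste0("growth problem ", sol$status, " at t = ", state$t))
    }
    events[[length(events) + 1L]] <<-
      tibble(t = state$t, trigger = trigger, mu = sol$mu)
    sol
  }
  record <- function(sol) {
    rows[[length(rows) + 1L]] <<- list(
      t = state$t, c = state$c, X = state$X, mu = sol$mu, v = sol$v,
      prot = setNames(sol$v[trsl], names(trsl)))
  }

  res <- tryCatch({
    sol <- solve_now("initial")
    v_ex <- setNames(sol$v[unname(exch)], tracked)
    record(sol)
    while (state$t < config$t_batch - 1e-9) {
      dt0 <- min(config$dt0, config$t_batch - state$t)
      if (!is.null(config$feed)) {      # stop exactly at feed boundaries
        bnd <- c(config$feed$t_start, config$feed$t_end)
        bnd <- bnd[bnd > state$t + 1e-9]
        if (length(bnd)) dt0 <- min(dt0, min(bnd) - state$t)
      }
      fr <- feed_rates_at(config, state$t, tracked)
      dt <- min_time_step(state, v_ex, dt0, feed_rates = fr)
      state <- step_update(state, v_ex, sol$mu, dt, fr)
      record(sol)
      ch <- detect_environment_change(avail, state, config)
      if (ch$changed) {
        avail <- ch$availability
        trig <- paste(c(sprintf("-%s", ch$removed), sprintf("+%s", ch$added)),
                      collapse = ",")
        sol <- solve_now(trig)
        v_ex <- setNames(sol$v[unname(exch)], tracked)
      }
    }
    NULL
  }, mebatch_solver_error = function(e) conditionMessage(e))

  new_me_timecourse(rows, bind_rows(events), "base", model, error = res)
}

#' Batch simulation with protein inertia
#'
#' As [simulate_batch()], but the proteome carries over: at every step the
#' inertia problem is re-solved with `p0` set to the current complex
#' concentrations (re-solving every step is required because the proteome
#' may now change even when the environment does not), the realized step
#' passes through [min_time_step()] including the protein term, and the
#' concentrations advance by `p <- p0 + delta * dt` with the realized `dt`
#' (the optimization anticipates over the horizon `H`, which is
#' independent of `dt`).
#'
#' @inheritParams simulate_batch
#' @param p_init named complex concentrations at `t = 0`, mmol/gDW.
#' @return an `me_timecourse` whose `proteome` tibble holds the complex
#'   concentrations `p`.
#' @export
simulate_batch_inertia <- function(model, init, p_init, config = sim_config()) {
  stopifnot(is_me_model(model), inherits(init, "batch_state"),
            inherits(config, "sim_config"))
  cxid <- model$complexes$id
  miss <- setdiff(cxid, names(p_init))
  if (length(miss)) {
    abort_model(paste0("p_init missing complex(es): ", paste(miss, collapse = ", ")))
  }
  if (any(p_init < 0)) abort_domain("p_init must be >= 0.")
  tracked <- names(init$c)
  exch <- model$exchanges[tracked]

  rows <- list(); events <- list()
  state <- init
  p <- p_init[cxid]
  avail <- availability_set(state$c, state$t, config)

  record <- function(sol) {
    rows[[length(rows) + 1L]] <<- list(
      t = state$t, c = state$c, X = state$X, mu = sol$mu, v = sol$v,
      prot = p)
  }

  res <- tryCatch({
    first <- TRUE
    while (TRUE) {
      ov <- avail_overrides(model, tracked, avail, config)
      sol <- maximize_growth_inertia(model, p0 = p, H = config$H,
                                     tol = config$solver_tol,
                                     bounds_override = ov)
      if (sol$status != "optimal") {
        abort_solver(paste0("inertia problem ", sol$status, " at t = ", state$t))
      }
      events[[length(events) + 1L]] <-
        tibble(t = state$t, trigger = if (first) "initial" else "step",
               mu = sol$mu)
      if (first) { record(sol); first <- FALSE }
      if (state$t >= config$t_batch - 1e-9) break
      v_ex <- setNames(sol$v[unname(exch)], tracked)
      dt0 <- min(config$dt0, config$t_batch - state$t)
      if (!is.null(config$feed)) {
        bnd <- c(config$feed$t_start, config$feed$t_end)
        bnd <- bnd[bnd > state$t + 1e-9]
        if (length(bnd)) dt0 <- min(dt0, min(bnd) - state$t)
      }
      fr <- feed_rates_at(config, state$t, tracked)
      dt <- min_time_step(state, v_ex, dt0, p = p, delta = sol$delta,
                          feed_rates = fr)
      p <- pmax(p + sol$delta * dt, 0)
      state <- step_update(state, v_ex, sol$mu, dt, fr)
      record(sol)
      avail <- availability_set(state$c, state$t, config)
    }
    NULL
  }, mebatch_solver_error = function(e) conditionMessage(e))

  new_me_timecourse(rows, bind_rows(events), "inertia", model, error = res)
}
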