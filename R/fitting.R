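#' Configuration for list-based threshold accepting
#'
#' List-based threshold accepting (LTA) is a gradient-free local search:
#' a list of the `list_size` largest relative worsenings observed during
#' a warm-up random walk serves as an adaptive acceptance threshold; a
#' proposed neighbor is accepted when its relative worsening
#' `(Z_k - Z_0)/|Z_0|` is below the current list maximum `T_max`, and
#' each accepted worsening replaces `T_max` by the (smaller) realized
#' value, so the threshold list shrinks towards zero and the walk anneals
#' itself. Proposals multiply or divide one coordinate by a random factor
#' up to `neighborhood` (moves are made in log space, reflecting at the
#' bounds). With `walkers > 1` the first walker follows its local
#' trajectory and the others restart from the global best at
#' synchronization points every `restart_period` iterations; the schedule
#' is deterministic, so a serial run reproduces the parallel contract
#' exactly.
#'
#' @param list_size number of thresholds kept (`L >= 1`).
#' @param max_iter iterations per walker (after warm-up).
#' @param neighborhood multiplicative step span (`> 1`).
#' @param walkers number of walkers (`>= 1`).
#' @param restart_period iterations between synchronization points.
#' @param restart do non-local walkers jump to the global best at sync
#'   points?
#' @param warmup number of warm-up moves used to build the threshold
#'   list; default `5 * list_size`.
#' @param initial_thresholds optional explicit threshold list (skips the
#'   warm-up).
#' @param seed RNG seed.
#' @export
lta_config <- function(list_size = 8, max_iter = 300, neighborhood = 2,
                       walkers = 1, restart_period = 50, restart = TRUE,
                       warmup = NULL, initial_thresholds = NULL,
                       seed = NULL) {
  stopifnot(list_size >= 1, neighborhood > 1, walkers >= 1,
            restart_period >= 1, max_iter >= 1)
  structure(list(list_size = list_size, max_iter = max_iter,
                 neighborhood = neighborhood, walkers = walkers,
                 restart_period = restart_period, restart = restart,
                 warmup = warmup %||% 5 * list_size,
                 initial_thresholds = initial_thresholds, seed = seed),
            class = "lta_config")
}

#' Build the calibration objective for keff multipliers
#'
#' Returns the function minimized during calibration: a multiplier vector
#' (one per targeted coupling, applied multiplicatively to the nominal
#' keff values) is mapped to the sum of squared errors between the
#' measured extracellular concentration profiles and a fresh batch
#' simulation of the modified model. A simulation failure inside an
#' evaluation yields `+Inf` (the move is rejected). Evaluations are
#' memoized on the rounded log-multipliers, so repeated visits cost
#' nothing.
#'
#' @param model an [me_model()].
#' @param measured data frame `time_h` + species columns (mmol/L).
#' @param init a [batch_state()].
#' @param config a [sim_config()].
#' @param targets data frame with columns `complex`, `rxn` (default: all
#'   couplings).
#' @param species species to score (default: all shared).
#' @return a function `f(multipliers) -> SSE` with attributes `targets`
#'   and an evaluation counter accessible via `environment(f)$n_evals`.
#' @export
make_objective <- function(model, measured, init, config = sim_config(),
                           targets = NULL, species = NULL) {
  stopifnot(is_me_model(model))
  if (is.null(targets)) {
    targets <- bind_rows(lapply(seq_len(nrow(model$complexes)), function(i)
      tibble(complex = model$complexes$id[i],
             rxn = names(model$complexes$keff[[i]]))))
  }
  targets <- as_tibble(targets)
  if (nrow(targets) == 0) abort_domain("targets must be non-empty.")
  measured <- as_tibble(measured)

  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  f <- function(multipliers) {
    stopifnot(length(multipliers) == nrow(targets))
    key <- paste(round(log(multipliers), 10), collapse = ",")
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_evals <<- n_evals + 1L
    val <- tryCatch({
      m2 <- apply_keff_factors(model, mutate(targets, factor = multipliers))
      tc <- simulate_batch(m2, init, config)
      if (!is.null(tc$error)) Inf else {
        score_fit(tc, measured, species = species, grid = "measured")
      }
    }, error = function(e) Inf)
    cache[[key]] <- val
    val
  }
  attr(f, "targets") <- targets
  f
}

# one LTA chain as a resumable state machine (shared by the single- and
# multi-walker drivers); all randomness comes from the chain's own RNG
# substream so walker schedules are reproducible
lta_new_chain <- function(objective, x0, bounds, config, seed) {
  z0 <- objective(x0)
  list(x = x0, z = z0, best_x = x0, best_z = z0,
       thresholds = config$initial_thresholds, seed = seed,
       warmed = !is.null(config$initial_thresholds),
       trace = list(), iter = 0L)
}

lta_propose <- function(x, bounds, scale) {
  i <- sample.int(length(x), 1)
  step <- runif(1, 0, log(scale)) * sample(c(-1, 1), 1)
  lx <- log(x[i]) + step
  llo <- suppressWarnings(log(bounds[1])); lhi <- log(bounds[2])
  if (is.finite(lhi) && lx > lhi) lx <- lhi - (lx - lhi)   # reflect
  if (is.finite(llo) && lx < llo) lx <- llo + (llo - lx)
  x[i] <- min(max(exp(lx), bounds[1]), bounds[2])
  x
}

lta_warmup <- function(chain, objective, bounds, config) {
  rel <- c()
  x <- chain$x; z <- chain$z
  for (k in seq_len(config$warmup)) {
    xn <- lta_propose(x, bounds, config$neighborhood)
    zn <- objective(xn)
    if (is.finite(zn)) {
      r <- (zn - z) / max(abs(z), 1e-12)
      if (r > 0) rel <- c(rel, r)
      x <- xn; z <- zn       # warm-up walk accepts every finite move
      if (zn < chain$best_z) { chain$best_x <- xn; chain$best_z <- zn }
    }
  }
  L <- config$list_size
  th <- sort(rel, decreasing = TRUE)
  th <- if (length(th) >= L) th[seq_len(L)] else c(th, rep(max(th, 1), L - length(th)))
  chain$thresholds <- th
  chain$x <- x; chain$z <- z
  chain$warmed <- TRUE
  chain
}

lta_run_chunk <- function(chain, objective, bounds, config, n_iter, walker = 1L) {
  for (k in seq_len(n_iter)) {
    chain$iter <- chain$iter + 1L
    xn <- lta_propose(chain$x, bounds, config$neighborhood)
    zn <- objective(xn)
    tmax <- max(chain$thresholds)
    r <- (zn - chain$z) / max(abs(chain$z), 1e-12)
    accepted <- is.finite(zn) && r < tmax
    if (accepted) {
      if (r > 0) {      # replace T_max with the realized smaller worsening
        chain$thresholds[which.max(chain$thresholds)] <- r
      }
      chain$x <- xn; chain$z <- zn
      if (zn < chain$best_z) { chain$best_x <- xn; chain$best_z <- zn }
    }
    chain$trace[[length(chain$trace) + 1L]] <-
      tibble(iteration = chain$iter, walker = walker, z = zn,
             accepted = accepted, t_max = tmax, best_z = chain$best_z)
  }
  chain
}

new_lta_fit <- function(chain_or_best, trace, n_evals, targets = NULL) {
  structure(list(par = chain_or_best$best_x, value = chain_or_best$best_z,
                 trace = trace, n_evals = n_evals, targets = targets),
            class = "lta_fit")
}

#' @export
print.lta_fit <- function(x, ...) {
  cat("<lta_fit> best objective ", format(x$value, digits = 6), " after ",
      x$n_evals, " evaluations\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lta_fit <- function(x, ...) x$trace

#' @exportS3Method generics::glance
glance.lta_fit <- function(x, ...) {
  tibble(value = x$value, n_evals = x$n_evals,
         iterations = nrow(x$trace),
         acceptance_rate = mean(x$trace$accepted))
}

#' @exportS3Method ggplot2::autoplot
autoplot.lta_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$best_z,
                               colour = factor(.data$walker))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "iteration", y = "best objective", colour = "walker")
}

#' Minimize an objective by list-based threshold accepting
#'
#' @param objective function mapping a positive multiplier vector to a
#'   scalar (see [make_objective()]); `+Inf` marks a failed evaluation.
#' @param x0 starting point, within bounds.
#' @param bounds length-2 multiplicative bounds (default `c(0.1, 10)`).
#' @param config an [lta_config()].
#' @return an `lta_fit`: best parameters `par`, best objective `value`,
#'   per-iteration `trace` (tibble `iteration`, `walker`, `z`,
#'   `accepted`, `t_max`, `best_z`), evaluation count `n_evals`.
#' @examples
#' f <- function(x) (x - 3)^2
#' fit <- lta_optimize(f, x0 = 9, bounds = c(0.1, 10),
#'                     config = lta_config(max_iter = 2000, seed = 1))
#' abs(fit$par - 3) < 0.05
#' @export
lta_optimize <- function(objective, x0, bounds = c(0.1, 10),
                         config = lta_config()) {
  stopifnot(inherits(config, "lta_config"),
            all(x0 >= bounds[1] - 1e-12), all(x0 <= bounds[2] + 1e-12),
            bounds[1] > 0 || !any(x0 <= 0))
  counted <- count_evals(objective)
  with_seed(config$seed, {
    chain <- lta_new_chain(counted$f, x0, bounds, config, config$seed)
    if (!chain$warmed) chain <- lta_warmup(chain, counted$f, bounds, config)
    chain <- lta_run_chunk(chain, counted$f, bounds, config, config$max_iter)
  })
  new_lta_fit(chain, bind_rows(chain$trace), counted$n())
}

count_evals <- function(objective) {
  n <- 0L
  list(f = function(x) { n <<- n + 1L; objective(x) }, n = function() n)
}

#' Multi-walker threshold accepting with synchronized restarts
#'
#' Runs `config$walkers` LTA chains under the parallel contract: walker 1
#' is purely local; at every synchronization point (each
#' `config$restart_period` iterations) the remaining walkers restart
#' from the best solution found by any walker so far (when
#' `config$restart` and the global best improves on their current
#' point). Chains are executed serially in a fixed round-robin order with
#' per-walker RNG substreams, so results are identical to any concurrent
#' execution that exchanges the global best only at sync points.
#'
#' @inheritParams lta_optimize
#' @return an `lta_fit` (best over walkers; trace carries the walker id).
#' @export
run_walkers <- function(objective, x0, bounds = c(0.1, 10),
                        config = lta_config()) {
  stopifnot(inherits(config, "lta_config"))
  W <- config$walkers
  if (W == 1L) return(lta_optimize(objective, x0, bounds, config))
  counted <- count_evals(objective)

  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1, W))

  # each walker owns an RNG substream; save/restore the caller's stream
  old_rng <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_rng)) assign(".Random.seed", old_rng, envir = globalenv())
  })
  chains <- vector("list", W); rng <- vector("list", W)
  for (w in seq_len(W)) {
    set.seed(seeds[w])
    ch <- lta_new_chain(counted$f, x0, bounds, config, seeds[w])
    if (!ch$warmed) ch <- lta_warmup(ch, counted$f, bounds, config)
    chains[[w]] <- ch
    rng[[w]] <- get(".Random.seed", envir = globalenv())
  }

  done <- 0L
  while (done < config$max_iter) {
    chunk <- min(config$restart_period, config$max_iter - done)
    for (w in seq_len(W)) {
      assign(".Random.seed", rng[[w]], envir = globalenv())
      chains[[w]] <- lta_run_chunk(chains[[w]], counted$f, bounds, config,
                                   chunk, walker = w)
      rng[[w]] <- get(".Random.seed", envir = globalenv())
    }
    done <- done + chunk
    best_w <- which.min(map_dbl(chains, "best_z"))
    if (config$restart) {
      for (w in setdiff(seq_len(W), 1L)) {   # walker 1 stays local
        if (chains[[best_w]]$best_z < chains[[w]]$z) {
          chains[[w]]$x <- chains[[best_w]]$best_x
          chains[[w]]$z <- chains[[best_w]]$best_z
        }
      }
    }
  }
  best_w <- which.min(map_dbl(chains, "best_z"))
  trace <- bind_rows(lapply(chains, function(ch) bind_rows(ch$trace)))
  new_lta_fit(chains[[best_w]], arrange(trace, .data$iteration, .data$walker),
              counted$n())
}

#' Calibrate keff multipliers against measured concentrations
#'
#' Convenience wrapper tying [make_objective()] to [lta_optimize()] /
#' [run_walkers()].
#'
#' @inheritParams make_objective
#' @inheritParams lta_optimize
#' @param x0 starting multipliers (default all 1).
#' @return an `lta_fit` whose `par` is named by `complex:rxn` coupling.
#' @export
fit_keff <- function(model, measured, init, config = sim_config(),
                     targets = NULL, x0 = NULL, bounds = c(0.1, 10),
                     lta = lta_config()) {
  obj <- make_objective(model, measured, init, config, targets)
  tg <- attr(obj, "targets")
  if (is.null(x0)) x0 <- rep(1, nrow(tg))
  fit <- if (lta$walkers > 1) run_walkers(obj, x0, bounds, lta)
         else lta_optimize(obj, x0, bounds, lta)
  names(fit$par) <- paste(tg$complex, tg$rxn, sep = ":")
  fit$targets <- tg
  fit
}
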