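new_me_growth <- function(mu, v, status, mode = "base", p = NULL,
                          delta = NULL, tol = NA_real_) {
  structure(list(mu = mu, v = v, status = status, mode = mode,
                 p = p, delta = delta, tol = tol),
            class = "me_growth")
}

#' @export
print.me_growth <- function(x, ...) {
  cat("<me_growth> status: ", x$status,
      "  mu = ", format(x$mu, digits = 7), " 1/h",
      if (x$mode == "inertia") "  (inertia mode)", "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.me_growth <- function(x, ...) {
  out <- tibble(reaction = names(x$v), flux = unname(x$v))
  if (!is.null(x$p)) {
    out <- bind_rows(out,
      tibble(reaction = paste0("p[", names(x$p), "]"), flux = unname(x$p)),
      tibble(reaction = paste0("delta[", names(x$delta), "]"),
             flux = unname(x$delta)))
  }
  out
}

#' @exportS3Method generics::glance
glance.me_growth <- function(x, ...) {
  tibble(mu = x$mu, status = x$status, mode = x$mode,
         n_fluxes = length(x$v), tol = x$tol)
}

# shared bisection driver: `feasible(mu)` returns NULL or a solution list
bisect_mu <- function(feasible, mu_max, tol) {
  sol0 <- feasible(0)
  if (is.null(sol0)) return(list(mu = NA_real_, sol = NULL, status = "infeasible-at-zero"))
  sol_hi <- feasible(mu_max)
  if (!is.null(sol_hi)) return(list(mu = mu_max, sol = sol_hi, status = "optimal"))
  lo <- 0; hi <- mu_max; sol <- sol0
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    s <- feasible(mid)
    if (!is.null(s)) { lo <- mid; sol <- s } else hi <- mid
  }
  list(mu = lo, sol = sol, status = "optimal")
}

#' Maximize growth rate by bisection over fixed-mu linear programs
#'
#' Feasibility of the fixed-mu program is monotone (quasi-convex in mu), so
#' the growth optimum is the largest mu at which [evaluate_at_mu()] is
#' feasible; it is located by binary search on `[0, mu_max]`, tightening
#' the bracket until its width falls below `tol` and returning the last
#' feasible mu together with its flux vector. A model that is feasible at
#' `mu = 0` but at no positive mu returns `mu = 0` with status `"optimal"`
#' (a consistent, non-growing state); `"infeasible-at-zero"` is reserved
#' for truly inconsistent constraints.
#'
#' @param model an [me_model()].
#' @param tol bisection termination width, 1/h (default `1e-6`).
#' @param bounds_override optional named list `rxn -> c(lower, upper)`
#'   passed to [evaluate_at_mu()].
#' @return an `me_growth` object: `mu`, named flux vector `v`, `status`.
#' @examples
#' m <- toy_model("TOY1")
#' maximize_growth(m)$mu   # 1/110
#' @export
maximize_growth <- function(model, tol = 1e-6, bounds_override = NULL) {
  stopifnot(is_me_model(model), is_number(tol), tol > 0)
  feasible <- function(mu) {
    lp <- evaluate_at_mu(model, mu, bounds_override)
    s <- solve_lp(lp)
    if (s$status == "optimal") s$x else NULL
  }
  r <- bisect_mu(feasible, model$mu_max, tol)
  if (r$status == "infeasible-at-zero") {
    return(new_me_growth(NA_real_, NULL, "infeasible-at-zero", tol = tol))
  }
  v <- r$sol[model$reactions$id]
  new_me_growth(r$mu, v, "optimal", tol = tol)
}

#' Fixed-mu linear program with protein inertia constraints
#'
#' In the inertia formulation the complex concentrations `p` become
#' decision variables tied to their values `p0` at the previous time step.
#' The complex mass-balance rows are removed from `S(mu) v = 0` and
#' replaced, for every complex `i`, by
#' \deqn{v^{form}_i - \mu p_i = \delta_i}
#' \deqn{\sum_{j \in CAT(i)} v_{ij}/k^{eff}_{ij} \le p_i}
#' \deqn{p_i = p^0_i + \delta_i H}
#' with `v_form >= 0` and `p >= 0`; `delta` is free in sign, so complex
#' levels can only fall by growth dilution outpacing formation. `H` (h) is
#' the anticipation horizon over which the proteome may re-allocate; it
#' need not equal the simulation time step. A shared proteome budget, if
#' present, becomes `sum(coef_i * p_i) <= e_max` directly on the
#' concentration variables.
#'
#' @param model an [me_model()].
#' @param p0 named numeric vector of complex concentrations (mmol/gDW) at
#'   the previous step; must cover every complex.
#' @param H horizon, h, `> 0`.
#' @param mu growth rate at which to instantiate, 1/h.
#' @param bounds_override as in [evaluate_at_mu()].
#' @return a `linear_problem` over the variables `(v, p, delta, slacks)`.
#' @export
build_inertia_problem <- function(model, p0, H, mu, bounds_override = NULL) {
  stopifnot(is_me_model(model))
  check_mu_domain(model, mu)
  if (!is_number(H) || H <= 0) abort_domain("horizon H must be > 0.")
  cx <- model$complexes
  if (nrow(cx) == 0L) abort_model("inertia formulation requires at least one complex.")
  miss <- setdiff(cx$id, names(p0))
  if (length(miss)) {
    abort_model(paste0("p0 missing complex(es): ", paste(miss, collapse = ", ")))
  }
  if (any(p0[cx$id] < 0)) abort_domain("p0 must be >= 0 elementwise.")

  mets <- model$metabolites$id
  keep <- !(mets %in% cx$id)       # drop complex mass-balance rows
  rxns <- model$reactions$id
  n_r <- length(rxns); n_c <- nrow(cx)

  S <- matrix(0, nrow = length(mets), ncol = n_r, dimnames = list(mets, rxns))
  st <- model$stoichiometry
  for (i in seq_len(nrow(st))) {
    coef <- mu_eval(st$expr[[i]], mu)
    if (!is.finite(coef)) {
      abort_model(sprintf("coefficient for (%s, %s) is not finite at mu = %g",
                          st$met[i], st$rxn[i], mu))
    }
    S[st$met[i], st$rxn[i]] <- S[st$met[i], st$rxn[i]] + coef
  }
  S <- S[keep, , drop = FALSE]

  vars <- c(rxns, paste0("p.", cx$id), paste0("delta.", cx$id),
            paste0("cap_slack.", cx$id))
  has_budget <- !is.null(model$budget)
  if (has_budget) vars <- c(vars, ".budget_slack")
  n <- length(vars)
  col <- function(v) match(v, vars)

  rows <- list(); rhs <- c(); cons <- c()
  add_row <- function(idx, val, b, name) {
    r <- rep(0, n); r[idx] <- val
    rows[[length(rows) + 1L]] <<- r
    rhs <<- c(rhs, b); cons <<- c(cons, name)
  }

  for (i in seq_len(nrow(S))) {
    add_row(seq_len(n_r), S[i, ], 0, rownames(S)[i])
  }
  for (i in seq_len(n_c)) {
    cid <- cx$id[i]; frm <- cx$formation_rxn[i]; ke <- cx$keff[[i]]
    # v_form - mu p - delta = 0
    add_row(c(col(frm), col(paste0("p.", cid)), col(paste0("delta.", cid))),
            c(1, -mu, -1), 0, paste0("dilution.", cid))
    # sum v_j / keff_j - p + s = 0
    add_row(c(col(names(ke)), col(paste0("p.", cid)), col(paste0("cap_slack.", cid))),
            c(1 / ke, -1, 1), 0, paste0("capacity.", cid))
    # p - H delta = p0
    add_row(c(col(paste0("p.", cid)), col(paste0("delta.", cid))),
            c(1, -H), unname(p0[cid]), paste0("horizon.", cid))
  }
  if (has_budget) {
    coefs <- model$budget$coefficients
    add_row(c(col(paste0("p.", names(coefs))), col(".budget_slack")),
            c(unname(coefs), 1), model$budget$e_max, ".proteome_budget")
  }

  bb <- eval_bounds(model, mu, bounds_override)
  lb <- c(unname(bb$lb), rep(0, n_c), rep(-Inf, n_c), rep(0, n_c))
  ub <- c(unname(bb$ub), rep(Inf, n_c), rep(Inf, n_c), rep(Inf, n_c))
  if (has_budget) { lb <- c(lb, 0); ub <- c(ub, Inf) }
  # complex formation fluxes are non-negative in the inertia formulation
  fi <- col(cx$formation_rxn)
  lb[fi] <- pmax(lb[fi], 0)

  A <- do.call(rbind, rows)
  new_linear_problem(A, rhs, lb, ub, vars, cons)
}

#' Maximize growth under protein inertia constraints
#'
#' Bisection as in [maximize_growth()], but over the feasibility of
#' [build_inertia_problem()]; the solution additionally carries the complex
#' concentrations `p` and their rates of change `delta` (with
#' `v_form_i - mu*p_i = delta_i`, so `delta_i < 0` occurs only when growth
#' dilution outpaces complex formation).
#'
#' @inheritParams build_inertia_problem
#' @inheritParams maximize_growth
#' @return an `me_growth` with `mode = "inertia"`, fields `p` and `delta`.
#' @export
maximize_growth_inertia <- function(model, p0, H, tol = 1e-6,
                                    bounds_override = NULL) {
  stopifnot(is_me_model(model), is_number(tol), tol > 0)
  feasible <- function(mu) {
    lp <- build_inertia_problem(model, p0, H, mu, bounds_override)
    s <- solve_lp(lp)
    if (s$status == "optimal") s$x else NULL
  }
  r <- bisect_mu(feasible, model$mu_max, tol)
  if (r$status == "infeasible-at-zero") {
    return(new_me_growth(NA_real_, NULL, "infeasible-at-zero",
                         mode = "inertia", tol = tol))
  }
  x <- r$sol
  cxid <- model$complexes$id
  new_me_growth(r$mu, x[model$reactions$id], "optimal", mode = "inertia",
                p = setNames(unname(x[paste0("p.", cxid)]), cxid),
                delta = setNames(unname(x[paste0("delta.", cxid)]), cxid),
                tol = tol)
}

#' Independently re-check a growth solution against its model
#'
#' Rebuilds the constraints at `sol$mu` and reports the worst violation of
#' equalities and bounds (and, in inertia mode, of the dilution, capacity,
#' horizon and sign constraints). Used by the test-suite as a
#' solution-feasibility audit.
#'
#' @param model an [me_model()].
#' @param sol an `me_growth`.
#' @param p0,H,bounds_override the context the solution was computed in
#'   (inertia mode only).
#' @return largest absolute constraint violation (numeric scalar).
#' @export
check_growth_solution <- function(model, sol, p0 = NULL, H = NULL,
                                  bounds_override = NULL) {
  stopifnot(is_me_model(model), inherits(sol, "me_growth"),
            sol$status == "optimal")
  if (sol$mode == "inertia") {
    lp <- build_inertia_problem(model, p0, H, sol$mu, bounds_override)
    x <- c(sol$v, setNames(sol$p, paste0("p.", names(sol$p))),
           setNames(sol$delta, paste0("delta.", names(sol$delta))))
    # recover slack values from the defining rows
    cxid <- model$complexes$id
    cap <- map_dbl(seq_along(cxid), function(i) {
      ke <- model$complexes$keff[[i]]
      sol$p[cxid[i]] - sum(sol$v[names(ke)] / ke)
    })
    x <- c(x, setNames(cap, paste0("cap_slack.", cxid)))
    if (!is.null(model$budget)) {
      coefs <- model$budget$coefficients
      x <- c(x, ".budget_slack" =
               model$budget$e_max - sum(coefs * sol$p[names(coefs)]))
    }
    x <- x[lp$vars]
  } else {
    lp <- evaluate_at_mu(model, sol$mu, bounds_override)
    x <- sol$v
    if (!is.null(model$budget)) {
      coefs <- model$budget$coefficients
      frm <- model$complexes$formation_rxn[match(names(coefs), model$complexes$id)]
      x <- c(x, ".budget_slack" = sum(coefs * sol$v[frm]))
    }
    x <- x[lp$vars]
  }
  viol_eq <- if (nrow(lp$A)) max(abs(lp$A %*% x - lp$b)) else 0
  viol_lb <- max(c(0, lp$lb - x), na.rm = TRUE)
  viol_ub <- max(c(0, x - lp$ub), na.rm = TRUE)
  max(viol_eq, viol_lb, viol_ub)
}
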