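# Fixed-mu instantiation of a mu-parameterized model: a numeric linear
# problem in standard equality form
#   A x = b,  lb <= x <= ub
# Inequalities (proteome capacity/budget) are carried as equality rows with
# explicit non-negative slack variables, so a single form covers both the
# base and the inertia formulation.

new_linear_problem <- function(A, b, lb, ub, vars, cons) {
  stopifnot(nrow(A) == length(b), ncol(A) == length(lb),
            length(lb) == length(ub),
            ncol(A) == length(vars), nrow(A) == length(cons))
  if (any(!is.finite(A))) abort_model("linear problem has non-finite matrix entries.")
  if (any(!is.finite(b))) abort_model("linear problem has non-finite right-hand sides.")
  dimnames(A) <- list(cons, vars)
  structure(list(A = A, b = b, lb = lb, ub = ub, vars = vars, cons = cons),
            class = "linear_problem")
}

#' @export
print.linear_problem <- function(x, ...) {
  cat("<linear_problem> ", length(x$cons), " constraints x ",
      length(x$vars), " variables\n", sep = "")
  invisible(x)
}

check_mu_domain <- function(model, mu) {
  if (!is_number(mu) || mu < 0 || mu > model$mu_max) {
    abort_domain(sprintf("mu = %g outside [0, mu_max = %g].", mu, model$mu_max))
  }
}

# evaluate model bounds at mu and apply numeric overrides
# (override: named list rxn -> c(lower, upper), NA keeps the model value)
eval_bounds <- function(model, mu, bounds_override = NULL) {
  lb <- map_dbl(model$bounds$lower, mu_eval, mu = mu)
  ub <- map_dbl(model$bounds$upper, mu_eval, mu = mu)
  names(lb) <- names(ub) <- model$bounds$rxn
  if (!is.null(bounds_override)) {
    for (r in names(bounds_override)) {
      if (!r %in% names(lb)) {
        abort_model(paste0("bounds override for unknown reaction: ", r))
      }
      bo <- bounds_override[[r]]
      if (!is.na(bo[1])) lb[r] <- bo[1]
      if (length(bo) > 1 && !is.na(bo[2])) ub[r] <- bo[2]
    }
  }
  list(lb = lb, ub = ub)
}

#' Instantiate the linear program at a fixed growth rate
#'
#' Evaluates every growth-rate-dependent coefficient at `mu`, yielding the
#' numeric problem `S(mu) v = 0`, `l(mu) <= v <= u(mu)`. Enzyme use is
#' encoded on each complex's mass-balance row as a dilution coupling of
#' `-mu/keff` on every catalyzed reaction (the complex formation reaction
#' carries `+1` in the stoichiometry), so complex synthesis exactly
#' balances growth dilution of the enzyme pool. A shared proteome budget,
#' if present, contributes one slack-augmented row
#' `sum(coef_i * v_form_i) <= mu * e_max`.
#'
#' @param model an [me_model()].
#' @param mu growth rate, 1/h, in `[0, mu_max]`.
#' @param bounds_override optional named list `rxn -> c(lower, upper)` of
#'   numeric bounds replacing the model's evaluated bounds (used by the
#'   batch simulator to open/close exchanges).
#' @return a `linear_problem` (equality matrix, right-hand sides, variable
#'   bounds, variable and constraint ids).
#' @export
evaluate_at_mu <- function(model, mu, bounds_override = NULL) {
  stopifnot(is_me_model(model))
  check_mu_domain(model, mu)

  mets <- model$metabolites$id
  rxns <- model$reactions$id
  A <- matrix(0, nrow = length(mets), ncol = length(rxns),
              dimnames = list(mets, rxns))
  st <- model$stoichiometry
  for (i in seq_len(nrow(st))) {
    coef <- mu_eval(st$expr[[i]], mu)
    if (!is.finite(coef)) {
      abort_model(sprintf("coefficient for (%s, %s) is not finite at mu = %g",
                          st$met[i], st$rxn[i], mu))
    }
    A[st$met[i], st$rxn[i]] <- A[st$met[i], st$rxn[i]] + coef
  }
  # dilution coupling on the enzyme rows
  cx <- model$complexes
  for (i in seq_len(nrow(cx))) {
    ke <- cx$keff[[i]]
    for (j in seq_along(ke)) {
      if (!is.finite(ke[j]) || ke[j] <= 0) {
        abort_model(sprintf("keff for (%s, %s) must be positive",
                            cx$id[i], names(ke)[j]))
      }
      A[cx$id[i], names(ke)[j]] <- A[cx$id[i], names(ke)[j]] - mu / ke[j]
    }
  }

  bb <- eval_bounds(model, mu, bounds_override)
  b <- rep(0, length(mets))
  vars <- rxns
  cons <- mets
  lb <- unname(bb$lb); ub <- unname(bb$ub)

  if (!is.null(model$budget)) {
    coefs <- model$budget$coefficients
    row <- rep(0, ncol(A))
    names(row) <- colnames(A)
    for (cid in names(coefs)) {
      frm <- cx$formation_rxn[match(cid, cx$id)]
      row[frm] <- row[frm] + coefs[[cid]]
    }
    A <- rbind(A, row)
    A <- cbind(A, c(rep(0, length(mets)), -1))
    b <- c(b, 0)
    vars <- c(vars, ".budget_slack")
    cons <- c(cons, ".proteome_budget")
    lb <- c(lb, 0)
    ub <- c(ub, model$budget$e_max * mu)
  }
  new_linear_problem(A, b, lb, ub, vars, cons)
}
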