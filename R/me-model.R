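#' Construct a growth-rate-parameterized metabolism-and-expression model
#'
#' An ME-type model is a stoichiometric network whose coefficients and flux
#' bounds may depend on the growth rate \eqn{\mu} (see [mu_expr()]), plus
#' expression metadata: catalytic complexes with effective rate constants
#' (`keff`, 1/h) coupling each catalyzed reaction's flux to the enzyme
#' concentration (`v = keff * e`), one formation reaction per complex,
#' molecular weights, and one exchange reaction per extracellular
#' metabolite. At a fixed \eqn{\mu} the model instantiates to an ordinary
#' linear program ([evaluate_at_mu()]).
#'
#' @param metabolites data frame with columns `id`, `extracellular`.
#' @param reactions data frame with column `id`.
#' @param stoichiometry data frame with columns `met`, `rxn`, `expr`
#'   (`expr` may be a list of [mu_expr()] or a numeric column of constants).
#' @param bounds data frame with columns `rxn`, `lower`, `upper` (each a
#'   list of [mu_expr()] or numeric). Reactions absent from `bounds` get
#'   the defaults `lower`, `upper` given by `default_bounds`.
#' @param complexes data frame with columns `id`, `formation_rxn`,
#'   `weight_kda` and a list-column `keff` of named numeric vectors (names
#'   are catalyzed reaction ids, values in 1/h). May be `NULL`.
#' @param proteins data frame with columns `id`, `translation_rxn`,
#'   `weight_kda`. May be `NULL`.
#' @param exchanges named character vector, extracellular metabolite id ->
#'   exchange reaction id.
#' @param budget optional shared proteome budget: a list
#'   `list(e_max =, coefficients =)` where `coefficients` is a named
#'   numeric vector over complex ids; enforces
#'   `sum(coef_i * p_i) <= e_max` (mmol/gDW), encoded as
#'   `sum(coef_i * v_form_i) <= mu * e_max` when complex concentrations are
#'   not explicit variables.
#' @param mu_max upper bracket for growth-rate bisection, 1/h.
#' @param id optional model identifier string.
#' @param default_bounds length-2 numeric, default flux bounds.
#' @return an object of class `me_model`.
#' @seealso [validate_model()], [read_me_model()], [maximize_growth()]
#' @export
me_model <- function(metabolites, reactions, stoichiometry, bounds = NULL,
                     complexes = NULL, proteins = NULL, exchanges = character(),
                     budget = NULL, mu_max = 2, id = "me_model",
                     default_bounds = c(-1000, 1000)) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  stoichiometry <- as_tibble(stoichiometry)
  stopifnot(all(c("id", "extracellular") %in% names(metabolites)),
            "id" %in% names(reactions),
            all(c("met", "rxn", "expr") %in% names(stoichiometry)))
  stoichiometry$expr <- lapply(
    if (is.list(stoichiometry$expr)) stoichiometry$expr
    else as.list(stoichiometry$expr), as_mu_expr)

  bnd <- tibble(rxn = reactions$id,
                lower = list(mu_expr("constant", default_bounds[1])),
                upper = list(mu_expr("constant", default_bounds[2])))
  if (!is.null(bounds) && nrow(as_tibble(bounds)) > 0) {
    bounds <- as_tibble(bounds)
    bounds$lower <- lapply(if (is.list(bounds$lower)) bounds$lower else as.list(bounds$lower), as_mu_expr)
    bounds$upper <- lapply(if (is.list(bounds$upper)) bounds$upper else as.list(bounds$upper), as_mu_expr)
    idx <- match(bounds$rxn, bnd$rxn)
    bnd$lower[idx[!is.na(idx)]] <- bounds$lower[!is.na(idx)]
    bnd$upper[idx[!is.na(idx)]] <- bounds$upper[!is.na(idx)]
    if (anyNA(idx)) {
      abort_model(paste0("bounds given for unknown reaction(s): ",
                         paste(bounds$rxn[is.na(idx)], collapse = ", ")))
    }
  }

  if (!is.null(complexes)) {
    complexes <- as_tibble(complexes)
    stopifnot(all(c("id", "formation_rxn", "weight_kda", "keff") %in% names(complexes)))
  } else {
    complexes <- tibble(id = character(), formation_rxn = character(),
                        weight_kda = numeric(), keff = list())
  }
  if (!is.null(proteins)) {
    proteins <- as_tibble(proteins)
    stopifnot(all(c("id", "translation_rxn", "weight_kda") %in% names(proteins)))
  } else {
    proteins <- tibble(id = character(), translation_rxn = character(),
                       weight_kda = numeric())
  }
  if (!is.null(budget)) {
    stopifnot(is.list(budget), is_number(budget$e_max))
    if (is.null(budget$coefficients)) {
      budget$coefficients <- setNames(rep(1, nrow(complexes)), complexes$id)
    }
  }

  structure(list(
    id = id,
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = stoichiometry,
    bounds = bnd,
    complexes = complexes,
    proteins = proteins,
    exchanges = exchanges,
    budget = budget,
    mu_max = mu_max
  ), class = "me_model")
}

#' @export
print.me_model <- function(x, ...) {
  cat("<me_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      " (", sum(x$metabolites$extracellular), " extracellular)\n", sep = "")
  cat("  reactions:   ", nrow(x$reactions), "\n", sep = "")
  cat("  complexes:   ", nrow(x$complexes), "\n", sep = "")
  if (!is.null(x$budget)) {
    cat("  proteome budget: ", x$budget$e_max, " mmol/gDW\n", sep = "")
  }
  cat("  mu_max:      ", x$mu_max, " 1/h\n", sep = "")
  invisible(x)
}

is_me_model <- function(x) inherits(x, "me_model")

# named list complex -> numeric keff vector (names = catalyzed reactions)
model_keff <- function(model) {
  setNames(model$complexes$keff, model$complexes$id)
}

#' Diagnose structural problems in an ME model
#'
#' Checks the model invariants and returns a diagnostics table rather than
#' raising: every complex has exactly one formation reaction and a nonempty
#' catalyzed-reaction set, every `keff > 0`, every extracellular metabolite
#' has exactly one exchange reaction, all growth-rate expressions are valid
#' on `[0, mu_max]`, and all cross-references resolve.
#'
#' @param model an [me_model()].
#' @return a tibble with columns `check`, `object`, `message`; zero rows
#'   iff the model is well-formed.
#' @export
validate_model <- function(model) {
  stopifnot(is_me_model(model))
  out <- list()
  bad <- function(check, object, message) {
    out[[length(out) + 1L]] <<- tibble(check = check, object = object,
                                       message = message)
  }

  if (anyDuplicated(model$metabolites$id))
    bad("unique_ids", "metabolites", "duplicated metabolite ids")
  if (anyDuplicated(model$reactions$id))
    bad("unique_ids", "reactions", "duplicated reaction ids")

  rxns <- model$reactions$id
  mets <- model$metabolites$id
  miss <- setdiff(model$stoichiometry$met, mets)
  for (m in miss) bad("stoich_refs", m, "stoichiometry references unknown metabolite")
  miss <- setdiff(model$stoichiometry$rxn, rxns)
  for (r in miss) bad("stoich_refs", r, "stoichiometry references unknown reaction")

  cx <- model$complexes
  for (i in seq_len(nrow(cx))) {
    cid <- cx$id[i]
    frm <- cx$formation_rxn[i]
    if (length(frm) != 1L || is.na(frm) || !frm %in% rxns)
      bad("formation", cid, "complex lacks a (known) formation reaction")
    ke <- cx$keff[[i]]
    if (length(ke) == 0L)
      bad("cat_nonempty", cid, "complex catalyzes no reaction (empty keff map)")
    for (j in seq_along(ke)) {
      cpl <- paste0(cid, ":", names(ke)[j])
      if (!is.finite(ke[j]) || ke[j] <= 0)
        bad("keff_positive", cpl, sprintf("keff must be > 0 (got %g)", ke[j]))
      if (!names(ke)[j] %in% rxns)
        bad("keff_refs", cpl, "keff coupling references unknown reaction")
    }
    if (!cid %in% mets)
      bad("complex_row", cid, "complex id has no metabolite (mass-balance) row")
  }
  if (anyDuplicated(cx$formation_rxn))
    bad("formation", "complexes", "a formation reaction is shared by several complexes")

  ext <- model$metabolites$id[model$metabolites$extracellular]
  for (m in ext) {
    n <- sum(names(model$exchanges) == m)
    if (n != 1L)
      bad("exchange", m, sprintf("extracellular metabolite must have exactly one exchange reaction (found %d)", n))
  }
  miss <- setdiff(unname(model$exchanges), rxns)
  for (r in miss) bad("exchange", r, "exchange map references unknown reaction")

  # mu-expressions valid across the bracket (hyperbolic b > 0 is enforced at
  # construction; re-check finiteness numerically at the extremes)
  probe <- c(0, model$mu_max)
  for (i in seq_len(nrow(model$stoichiometry))) {
    v <- tryCatch(mu_eval(model$stoichiometry$expr[[i]], probe), error = function(e) NaN)
    if (any(!is.finite(v)))
      bad("mu_expr", paste0(model$stoichiometry$met[i], "/", model$stoichiometry$rxn[i]),
          "stoichiometric coefficient not finite on [0, mu_max]")
  }

  if (!is.null(model$budget)) {
    miss <- setdiff(names(model$budget$coefficients), cx$id)
    for (m in miss) bad("budget", m, "budget coefficient for unknown complex")
    if (!is_number(model$budget$e_max) || model$budget$e_max <= 0)
      bad("budget", "e_max", "budget e_max must be a positive number")
  }

  if (length(out) == 0L) {
    tibble(check = character(), object = character(), message = character())
  } else {
    bind_rows(out)
  }
}
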