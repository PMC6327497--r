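#' Read / write the model JSON format
#'
#' Models are serialized to a small JSON dialect:
#' ```
#' {"metabolites": [{"id", "extracellular"}],
#'  "reactions":   [{"id"}],
#'  "stoichiometry": [{"met", "rxn", "expr": {"form", "a", "b"}}],
#'  "bounds":      [{"rxn", "lower": expr, "upper": expr}],
#'  "complexes":   [{"id", "formation_rxn", "weight_kda", "keff": {rxn: value}}],
#'  "proteins":    [{"id", "translation_rxn", "weight_kda"}],
#'  "exchanges":   {met: rxn},
#'  "mu_max":      float}
#' ```
#' plus an optional `"budget": {"e_max": float, "coefficients": {complex:
#' coef}}` entry for a shared proteome budget. The round trip
#' model -> JSON -> model preserves all fields and all expression
#' coefficients exactly (numbers are written at full precision).
#'
#' @param path file path.
#' @param model an [me_model()].
#' @return `read_me_model()` returns an [me_model()]; `write_me_model()`
#'   returns `path` invisibly.
#' @export
read_me_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  need <- c("metabolites", "reactions", "stoichiometry", "bounds",
            "complexes", "proteins", "exchanges", "mu_max")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort_model(paste0("model JSON is missing key(s): ", paste(miss, collapse = ", ")))
  }
  mets <- tibble(
    id = map_chr(x$metabolites, "id"),
    extracellular = map_lgl(x$metabolites, "extracellular"))
  rxns <- tibble(id = map_chr(x$reactions, "id"))
  stoich <- tibble(
    met = map_chr(x$stoichiometry, "met"),
    rxn = map_chr(x$stoichiometry, "rxn"),
    expr = map(x$stoichiometry, function(e) as_mu_expr(e$expr)))
  bounds <- tibble(
    rxn = map_chr(x$bounds, "rxn"),
    lower = map(x$bounds, function(e) as_mu_expr(e$lower)),
    upper = map(x$bounds, function(e) as_mu_expr(e$upper)))
  complexes <- if (length(x$complexes)) tibble(
    id = map_chr(x$complexes, "id"),
    formation_rxn = map_chr(x$complexes, "formation_rxn"),
    weight_kda = map_dbl(x$complexes, "weight_kda"),
    keff = map(x$complexes, function(e) {
      k <- unlist(e$keff)
      setNames(as.numeric(k), names(k))
    })) else NULL
  proteins <- if (length(x$proteins)) tibble(
    id = map_chr(x$proteins, "id"),
    translation_rxn = map_chr(x$proteins, "translation_rxn"),
    weight_kda = map_dbl(x$proteins, "weight_kda")) else NULL
  budget <- if (!is.null(x$budget)) {
    cf <- unlist(x$budget$coefficients)
    list(e_max = as.numeric(x$budget$e_max),
         coefficients = setNames(as.numeric(cf), names(cf)))
  } else NULL
  me_model(metabolites = mets, reactions = rxns, stoichiometry = stoich,
           bounds = bounds, complexes = complexes, proteins = proteins,
           exchanges = unlist(x$exchanges) %||% character(),
           budget = budget, mu_max = as.numeric(x$mu_max),
           id = x$id %||% basename(path))
}

#' @rdname read_me_model
#' @export
write_me_model <- function(model, path) {
  stopifnot(is_me_model(model))
  x <- list(
    id = model$id,
    metabolites = pmap(model$metabolites[c("id", "extracellular")],
                       function(id, extracellular)
                         list(id = id, extracellular = extracellular)),
    reactions = lapply(model$reactions$id, function(r) list(id = r)),
    stoichiometry = pmap(model$stoichiometry, function(met, rxn, expr)
      list(met = met, rxn = rxn, expr = mu_expr_to_list(expr))),
    bounds = pmap(model$bounds, function(rxn, lower, upper)
      list(rxn = rxn, lower = mu_expr_to_list(lower),
           upper = mu_expr_to_list(upper))),
    complexes = pmap(model$complexes, function(id, formation_rxn, weight_kda, keff)
      list(id = id, formation_rxn = formation_rxn, weight_kda = weight_kda,
           keff = as.list(keff))),
    proteins = pmap(model$proteins, function(id, translation_rxn, weight_kda)
      list(id = id, translation_rxn = translation_rxn, weight_kda = weight_kda)),
    exchanges = as.list(model$exchanges),
    mu_max = model$mu_max)
  if (!is.null(model$budget)) {
    x$budget <- list(e_max = model$budget$e_max,
                     coefficients = as.list(model$budget$coefficients))
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
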