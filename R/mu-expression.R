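#' Growth-rate-dependent coefficients
#'
#' ME-type models have stoichiometric coefficients and flux bounds that are
#' functions of the growth rate \eqn{\mu}. Three functional forms cover the
#' dependencies that arise in these models: `constant` (`a`), `linear`
#' (`a + b*mu`, e.g. dilution terms proportional to growth), and
#' `hyperbolic` (`a*mu/(b + mu)` with `b > 0`, the saturating relation
#' between growth rate and translation rate). Restricting to these forms
#' keeps every fixed-\eqn{\mu} evaluation finite on `[0, mu_max]` and makes
#' models serializable to JSON.
#'
#' @param form one of `"constant"`, `"linear"`, `"hyperbolic"`.
#' @param a,b numeric coefficients; `b` is ignored for `constant`.
#' @return an object of class `mu_expr`.
#' @examples
#' e <- mu_expr("hyperbolic", a = 1, b = 1)
#' mu_eval(e, 0)    # 0
#' mu_eval(e, 1)    # 0.5
#' @export
mu_expr <- function(form = c("constant", "linear", "hyperbolic"), a, b = 0) {
  form <- match.arg(form)
  if (!is_number(a)) abort_domain("`a` must be a finite number.")
  if (form != "constant" && !is_number(b)) {
    abort_domain("`b` must be a finite number.")
  }
  if (form == "hyperbolic" && b <= 0) {
    abort_domain("hyperbolic form requires b > 0 so that a*mu/(b + mu) is finite on [0, mu_max].")
  }
  structure(list(form = form, a = as.numeric(a),
                 b = if (form == "constant") 0 else as.numeric(b)),
            class = "mu_expr")
}

#' @export
print.mu_expr <- function(x, ...) {
  s <- switch(x$form,
    constant = format(x$a),
    linear = paste0(format(x$a), " + ", format(x$b), "*mu"),
    hyperbolic = paste0(format(x$a), "*mu/(", format(x$b), " + mu)"))
  cat("<mu_expr> ", s, "\n", sep = "")
  invisible(x)
}

is_mu_expr <- function(x) inherits(x, "mu_expr")

#' Evaluate a growth-rate expression
#'
#' @param expr a [mu_expr()].
#' @param mu growth rate(s), 1/h; must be `>= 0`.
#' @return numeric vector of the same length as `mu`.
#' @export
mu_eval <- function(expr, mu) {
  if (!is_mu_expr(expr)) abort_domain("`expr` must be a mu_expr.")
  if (any(!is.finite(mu)) || any(mu < 0)) {
    abort_domain("`mu` must be finite and >= 0.")
  }
  switch(expr$form,
    constant = rep(expr$a, length(mu)),
    linear = expr$a + expr$b * mu,
    hyperbolic = expr$a * mu / (expr$b + mu))
}

# accept a bare number as shorthand for a constant expression
as_mu_expr <- function(x) {
  if (is_mu_expr(x)) return(x)
  if (is_number(x)) return(mu_expr("constant", a = x))
  if (is.list(x) && !is.null(x$form)) {
    return(mu_expr(x$form, a = x$a, b = x$b %na% 0))
  }
  abort_domain("cannot interpret value as a mu-dependent expression.")
}

mu_expr_to_list <- function(expr) {
  list(form = expr$form, a = expr$a, b = expr$b)
}
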