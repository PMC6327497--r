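#' Solve or test feasibility of a fixed-mu linear problem
#'
#' The polytope work is delegated to the Goldfarb--Idnani dual active-set
#' method in \pkg{quadprog}, which reports inconsistent constraints
#' exactly, making it a reliable feasibility oracle for growth-rate
#' bisection. With `objective = NULL` the returned point is the minimum-norm
#' feasible point (projection of the origin onto the polytope, the
#' deterministic canonical representative used throughout the package). A
#' linear objective is handled by adding a tiny quadratic ridge
#' (`min c'x + ridge*||x||^2`); for `ridge` below the problem's geometric
#' threshold this returns the minimum-norm point of the optimal face.
#' Unboundedness is detected when the regularized solution escapes to the
#' `O(1/ridge)` scale.
#'
#' @param problem a `linear_problem` from [evaluate_at_mu()] or
#'   [build_inertia_problem()].
#' @param objective `NULL` (feasibility / canonical point), a variable id,
#'   or a named numeric vector of objective coefficients.
#' @param sense `"max"` or `"min"`.
#' @param ridge quadratic regularization weight for linear objectives.
#' @param feas_tol equality feasibility tolerance used to double-check the
#'   returned point.
#' @return a list with elements `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `x` (named solution vector or `NULL`) and `value`
#'   (objective value or `NA`).
#' @examples
#' lp <- new_linear_problem(matrix(0, 0, 1), numeric(), 0, 3, "x", character())
#' solve_lp(lp, objective = "x", sense = "max")$value  # 3
#' @export
solve_lp <- function(problem, objective = NULL, sense = c("max", "min"),
                     ridge = 1e-8, feas_tol = 1e-9) {
  stopifnot(inherits(problem, "linear_problem"))
  sense <- match.arg(sense)
  n <- length(problem$vars)

  cvec <- NULL
  if (!is.null(objective)) {
    cvec <- rep(0, n)
    names(cvec) <- problem$vars
    if (is.character(objective)) {
      if (!all(objective %in% problem$vars)) {
        abort_model("objective names unknown variable(s).")
      }
      cvec[objective] <- 1
    } else if (is.numeric(objective) && !is.null(names(objective))) {
      if (!all(names(objective) %in% problem$vars)) {
        abort_model("objective names unknown variable(s).")
      }
      cvec[names(objective)] <- objective
    } else {
      abort_model("`objective` must be NULL, a variable id, or a named numeric vector.")
    }
    if (sense == "max") cvec <- -cvec   # internally always minimize
  }

  # drop all-zero equality rows (a zero row with b != 0 is already infeasible)
  A <- problem$A; b <- problem$b
  if (nrow(A) > 0) {
    rmax <- apply(abs(A), 1, max)
    zero <- rmax == 0
    if (any(zero & abs(b) > feas_tol)) {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    A <- A[!zero, , drop = FALSE]; b <- b[!zero]
    if (nrow(A) > 0) {          # row equilibration for conditioning
      s <- apply(abs(A), 1, max)
      A <- A / s; b <- b / s
    }
  }

  Amat <- t(A); bvec <- b; meq <- nrow(A)
  for (i in seq_len(n)) {
    if (is.finite(problem$lb[i])) {
      e <- rep(0, n); e[i] <- 1
      Amat <- cbind(Amat, e); bvec <- c(bvec, problem$lb[i])
    }
    if (is.finite(problem$ub[i])) {
      e <- rep(0, n); e[i] <- -1
      Amat <- cbind(Amat, e); bvec <- c(bvec, -problem$ub[i])
    }
  }

  if (is.null(cvec)) {
    Dmat <- diag(1, n); dvec <- rep(0, n)
  } else {
    Dmat <- diag(2 * ridge, n); dvec <- -cvec
  }

  res <- tryCatch(
    quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = meq),
    error = function(e) e)
  if (inherits(res, "error")) {
    return(list(status = "infeasible", x = NULL, value = NA_real_,
                message = conditionMessage(res)))
  }
  x <- res$solution
  names(x) <- problem$vars

  # guard: quadprog can in rare degenerate cases return a point violating
  # equalities; treat that as infeasible rather than trusting it
  if (meq > 0 && max(abs(A %*% x - b)) > max(1e-7, 100 * feas_tol)) {
    return(list(status = "infeasible", x = NULL, value = NA_real_,
                message = "equality residual above tolerance"))
  }

  if (!is.null(cvec)) {
    if (max(abs(x)) > 1e-2 / ridge) {
      return(list(status = "unbounded", x = NULL, value = NA_real_))
    }
    value <- sum(cvec * x) * if (sense == "max") -1 else 1
  } else {
    value <- 0
  }
  list(status = "optimal", x = x, value = value)
}
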