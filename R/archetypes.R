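# simplex-constrained least squares  min ||C x - d||^2, x >= 0, sum x = 1
# solved as a small QP (Goldfarb-Idnani); a tiny ridge keeps the Hessian
# positive definite when C is rank-deficient
simplex_lsq <- function(C, d, ridge = 1e-10) {
  n <- ncol(C)
  if (n == 1L) return(1)
  Dmat <- crossprod(C) + diag(ridge * max(1, sum(C^2)), n)
  dvec <- crossprod(C, d)
  Amat <- cbind(rep(1, n), diag(n))
  bvec <- c(1, rep(0, n))
  sol <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 1)$solution
  sol[sol < 0] <- 0
  sol / sum(sol)
}

# FurthestSum: pick p well-separated columns of X as the initial support
furthest_sum <- function(X, p, seed = NULL) {
  n <- ncol(X)
  with_seed(seed, start <- sample.int(n, 1))
  chosen <- start
  if (p > 1) {
    d2 <- colSums((X - X[, start])^2)
    for (k in 2:p) {
      dsum <- rep(0, n)
      for (j in chosen) dsum <- dsum + sqrt(colSums((X - X[, j])^2))
      dsum[chosen] <- -Inf
      chosen <- c(chosen, which.max(dsum))
    }
  }
  chosen
}

#' Flatten an ensemble of time courses into a feature matrix
#'
#' Collapses timepoints and metabolites: the returned matrix has one
#' column per run and one row per (timepoint, metabolite) pair, ordered
#' time-major with metabolites lexicographic within each timepoint. All
#' runs must share the time grid (resample first if necessary).
#'
#' @param runs list of `me_timecourse` objects or of data frames
#'   (`time_h` + species columns).
#' @param species character vector of species to include (non-empty).
#' @return numeric matrix, `(timepoints * species) x runs`, with
#'   row names `"<time>:<species>"`.
#' @export
flatten_timecourses <- function(runs, species) {
  if (length(species) == 0) abort_domain("species subset must be non-empty.")
  tabs <- lapply(runs, function(r) {
    if (inherits(r, "me_timecourse")) r <- r$concentrations
    as_tibble(r)
  })
  species <- sort(species)
  t0 <- tabs[[1]]$time_h
  for (tb in tabs) {
    if (length(tb$time_h) != length(t0) || any(abs(tb$time_h - t0) > 1e-9)) {
      abort_domain("all runs must share the same time grid; resample first.")
    }
    if (!all(species %in% names(tb))) {
      abort_domain("a run is missing one of the requested species.")
    }
  }
  X <- vapply(tabs, function(tb) {
    as.vector(t(as.matrix(tb[species])))   # time-major, species within time
  }, numeric(length(t0) * length(species)))
  X <- matrix(X, nrow = length(t0) * length(species))
  rownames(X) <- as.vector(t(outer(t0, species, paste, sep = ":")))
  colnames(X) <- names(runs) %||% paste0("run", seq_along(tabs))
  X
}

#' Archetypal analysis by alternating simplex-constrained least squares
#'
#' Factorizes `X ~ Z A` with `Z = X B`, where columns of `A` (one per
#' sample) and of `B` (one per archetype) lie on the probability simplex:
#' every sample is approximated as a convex combination of `p` archetypes
#' and every archetype is a convex combination of the data points, so
#' archetypes sit on the convex hull of the data and represent extreme
#' "pure" profiles. Fitting alternates exact block updates — each column
#' of `A` given `Z`, then each column of `B` given the others — so the
#' residual sum of squares is non-increasing; iteration stops when its
#' relative change falls below `tol` or after `max_iter` sweeps.
#' Initialization selects `p` mutually far data columns (FurthestSum),
#' reproducible under `seed`. Columns are not standardized; set `scale =
#' TRUE` to divide each feature row by its standard deviation first.
#'
#' @param X feature matrix, features x samples (see
#'   [flatten_timecourses()]).
#' @param p number of archetypes, `1 <= p <= ncol(X)`.
#' @param tol relative rss change for convergence.
#' @param max_iter maximum alternating sweeps.
#' @param seed RNG seed for initialization.
#' @param scale standardize feature rows first?
#' @return an `archetype_fit`: matrices `Z` (features x p), `A`
#'   (p x samples), `B` (samples x p), `rss`, `rss_path`, `p`.
#' @export
fit_archetypes <- function(X, p, tol = 1e-6, max_iter = 500, seed = NULL,
                           scale = FALSE) {
  X <- as.matrix(X)
  n <- ncol(X)
  if (p < 1 || p > n) abort_domain("need 1 <= p <= number of samples.")
  if (all(X == 0)) abort_domain("X has rank 0; nothing to factorize.")
  if (scale) {
    s <- apply(X, 1, sd); s[s == 0] <- 1
    X <- X / s
  }

  B <- matrix(0, n, p)
  B[cbind(furthest_sum(X, p, seed), seq_len(p))] <- 1
  Z <- X %*% B
  A <- matrix(1 / p, p, n)

  rss_path <- numeric(0)
  rss <- Inf
  for (it in seq_len(max_iter)) {
    for (j in seq_len(n)) A[, j] <- simplex_lsq(Z, X[, j])
    # block update of B: columns in turn, others fixed
    XtX <- crossprod(X)
    for (k in seq_len(p)) {
      ak <- A[k, ]
      if (sum(ak^2) == 0) next
      R <- X - X %*% B[, -k, drop = FALSE] %*% A[-k, , drop = FALSE]
      # min_b ||R - (X b) ak'||^2 = b' XtX b * ||ak||^2 - 2 b' X'R ak + c
      Dmat <- XtX * sum(ak^2)
      dvec <- crossprod(X, R %*% ak)
      Dmat <- Dmat + diag(1e-10 * max(1, sum(diag(Dmat))), n)
      Amat <- cbind(rep(1, n), diag(n))
      b <- quadprog::solve.QP(Dmat, dvec, Amat, c(1, rep(0, n)),
                              meq = 1)$solution
      b[b < 0] <- 0
      B[, k] <- b / sum(b)
    }
    Z <- X %*% B
    new_rss <- sum((X - Z %*% A)^2)
    rss_path <- c(rss_path, new_rss)
    if (is.finite(rss) && rss > 0 &&
        (rss - new_rss) / rss < tol) { rss <- new_rss; break }
    rss <- new_rss
  }
  for (j in seq_len(n)) A[, j] <- simplex_lsq(Z, X[, j])
  rss <- sum((X - Z %*% A)^2)
  rownames(Z) <- rownames(X)
  colnames(Z) <- rownames(B) <- NULL
  structure(list(Z = Z, A = A, B = B, rss = rss, rss_path = rss_path, p = p),
            class = "archetype_fit")
}

#' @export
print.archetype_fit <- function(x, ...) {
  cat("<archetype_fit> ", x$p, " archetypes, ", ncol(x$A), " samples, rss = ",
      format(x$rss, digits = 6), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.archetype_fit <- function(x, ...) {
  Z <- x$Z
  tibble(feature = rep(rownames(Z) %||% as.character(seq_len(nrow(Z))),
                       times = ncol(Z)),
         archetype = rep(seq_len(ncol(Z)), each = nrow(Z)),
         value = as.vector(Z))
}

#' @exportS3Method generics::glance
glance.archetype_fit <- function(x, ...) {
  tibble(p = x$p, rss = x$rss, n_samples = ncol(x$A),
         n_features = nrow(x$Z), iterations = length(x$rss_path))
}

#' @exportS3Method ggplot2::autoplot
autoplot.archetype_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$feature, y = .data$value,
                               group = .data$archetype,
                               colour = factor(.data$archetype))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "archetype profile", colour = "archetype") +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.ticks.x = ggplot2::element_blank())
}

#' Elbow rule for the number of archetypes
#'
#' An explicit version of the scree-plot elbow: among the interior points
#' of the (p, rss) scree, pick the one with the largest perpendicular
#' distance to the chord joining the first and last points; ties go to
#' the smallest p.
#'
#' @param rss_by_p data frame with columns `p`, `rss` (a contiguous p
#'   range, at least 3 points), or a named numeric vector.
#' @return the chosen number of archetypes `p*`.
#' @export
choose_num_archetypes <- function(rss_by_p) {
  if (is.numeric(rss_by_p) && !is.null(names(rss_by_p))) {
    rss_by_p <- tibble(p = as.numeric(names(rss_by_p)), rss = unname(rss_by_p))
  }
  rss_by_p <- as_tibble(rss_by_p) |> arrange(.data$p)
  if (nrow(rss_by_p) < 3) abort_domain("need at least 3 scree points for the elbow rule.")
  x <- rss_by_p$p; y <- rss_by_p$rss
  n <- length(x)
  x1 <- x[1]; y1 <- y[1]; x2 <- x[n]; y2 <- y[n]
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  d <- abs((x2 - x1) * (y1 - y) - (x1 - x) * (y2 - y1)) / len
  interior <- 2:(n - 1)
  # explicit tie rule: smallest p among maxima
  dmax <- max(d[interior])
  x[min(interior[d[interior] >= dmax - 1e-12])]
}

#' Map companion profiles to the archetypes
#'
#' Once archetypes are determined from one data view (e.g. metabolite
#' concentrations), companion views of the same runs — proteome or
#' exchange-flux profiles — are mapped through `B`: each archetypal
#' companion profile is the same convex combination of sample profiles
#' that defines the archetype.
#'
#' @param B samples x p coefficient matrix from [fit_archetypes()].
#' @param companion matrix with one column per sample (same order as the
#'   rows of `B`).
#' @return matrix `companion %*% B`, one column per archetype.
#' @export
map_profiles <- function(B, companion) {
  if (inherits(B, "archetype_fit")) B <- B$B
  companion <- as.matrix(companion)
  if (ncol(companion) != nrow(B)) {
    abort_domain("companion must have one column per sample (nrow(B)).")
  }
  companion %*% B
}

#' Scree of archetype fits over a range of p
#'
#' @param X feature matrix.
#' @param p_range integer vector of archetype counts.
#' @param ... passed to [fit_archetypes()].
#' @return tibble with columns `p`, `rss`.
#' @export
archetype_scree <- function(X, p_range, ...) {
  tibble(p = p_range,
         rss = map_dbl(p_range, function(p) fit_archetypes(X, p, ...)$rss))
}
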