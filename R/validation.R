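#' Proteome mass fractions
#'
#' Two definitions, matching the two simulation modes. Without inertia
#' constraints the proteome composition is read off the translation
#' fluxes: \eqn{f_j = v^{trsl}_j w_j / \sum_k v^{trsl}_k w_k}. With
#' inertia constraints the complex concentrations are themselves
#' variables and the fractions are \eqn{f_j = p_j w_j / \sum_k p_k w_k}.
#' Fractions always sum to 1 and are invariant to rescaling all fluxes or
#' concentrations.
#'
#' @param v_trsl named non-negative translation fluxes (mmol/gDW/h), not
#'   all zero.
#' @param p named non-negative complex concentrations (mmol/gDW), not all
#'   zero.
#' @param w named molecular weights, kDa, `> 0` (matched by name when
#'   both are named).
#' @return named numeric vector of fractions summing to 1.
#' @export
mass_fractions_translation <- function(v_trsl, w) {
  if (any(v_trsl < 0)) abort_domain("translation fluxes must be >= 0.")
  if (any(w <= 0)) abort_domain("weights must be > 0.")
  if (!is.null(names(v_trsl)) && !is.null(names(w))) w <- w[names(v_trsl)]
  m <- v_trsl * w
  tot <- sum(m)
  if (tot == 0) abort_domain("all translation fluxes are zero; mass fractions undefined.")
  m / tot
}

#' @rdname mass_fractions_translation
#' @export
mass_fractions_concentration <- function(p, w) {
  if (any(p < 0)) abort_domain("complex concentrations must be >= 0.")
  if (any(w <= 0)) abort_domain("weights must be > 0.")
  if (!is.null(names(p)) && !is.null(names(w))) w <- w[names(p)]
  m <- p * w
  tot <- sum(m)
  if (tot == 0) abort_domain("all concentrations are zero; mass fractions undefined.")
  m / tot
}

#' Floored log2 transform
#'
#' Values below `floor` are clamped before taking log2, since simulated
#' mass fractions can be exactly zero.
#'
#' @param x numeric (vector or matrix).
#' @param floor clamp value, default `1e-6`.
#' @export
log2_clamp <- function(x, floor = 1e-6) log2(pmax(x, floor))

#' Align two time-course tables on a common regular grid
#'
#' Each profile is linearly interpolated onto a regular grid whose
#' interval is the smaller of the two native sampling intervals (or `dt`
#' if given), restricted to the overlapping time window.
#'
#' @param a,b data frames with a `time_h` column and one column per
#'   species, each with at least two timepoints.
#' @param dt optional grid interval, h; default: the smaller native
#'   interval of the two inputs.
#' @return list of two tibbles (`a`, `b`) on the shared grid, plus `dt`.
#' @export
resample_profiles <- function(a, b, dt = NULL) {
  a <- as_tibble(a); b <- as_tibble(b)
  for (df in list(a, b)) {
    if (!"time_h" %in% names(df) || nrow(df) < 2) {
      abort_domain("each profile needs a time_h column and >= 2 timepoints.")
    }
  }
  t0 <- max(min(a$time_h), min(b$time_h))
  t1 <- min(max(a$time_h), max(b$time_h))
  if (t1 <= t0) abort_domain("profiles have no overlapping time support.")
  if (is.null(dt)) dt <- min(min(diff(sort(a$time_h))), min(diff(sort(b$time_h))))
  grid <- seq(t0, t1, by = dt)
  interp <- function(df) {
    out <- tibble(time_h = grid)
    for (sp in setdiff(names(df), "time_h")) {
      out[[sp]] <- approx(df$time_h, df[[sp]], xout = grid)$y
    }
    out
  }
  list(a = interp(a), b = interp(b), dt = dt)
}

#' Lagged cross-correlation between two series
#'
#' For lag `l` (an integer multiple of the grid interval), the Pearson
#' correlation of the overlapping pairs \eqn{(x_t, y_{t+l})}, with mean
#' and variance computed on the overlap. A series with zero variance on
#' the overlap yields `NA` for that lag (undefined, not 0).
#'
#' @param x,y numeric series sampled on the same regular grid.
#' @param lags lags in hours (multiples of `dt`).
#' @param dt grid interval, h.
#' @return tibble with columns `lag_h`, `r`.
#' @export
lagged_crosscorr <- function(x, y, lags, dt) {
  stopifnot(length(x) == length(y), is_number(dt), dt > 0)
  n <- length(x)
  ks <- lags / dt
  if (any(abs(ks - round(ks)) > 1e-6)) {
    abort_domain("every lag must be an integer multiple of the grid interval.")
  }
  ks <- as.integer(round(ks))
  r <- map_dbl(ks, function(k) {
    if (abs(k) >= n) return(NA_real_)
    if (k >= 0) { xi <- x[1:(n - k)]; yi <- y[(1 + k):n] }
    else { xi <- x[(1 - k):n]; yi <- y[1:(n + k)] }
    if (sd(xi) == 0 || sd(yi) == 0 || length(xi) < 3) return(NA_real_)
    sum((xi - mean(xi)) * (yi - mean(yi))) /
      ((length(xi) - 1) * sd(xi) * sd(yi))
  })
  tibble(lag_h = ks * dt, r = r)
}

#' Best common lag between simulated and measured proteome dynamics
#'
#' Resamples both tables onto a shared regular grid, scans every lag on
#' that grid within `lag_range` (default -1.7 to +1.7 h), computes the
#' per-protein lagged cross-correlation, and returns the single lag that
#' maximizes the median correlation across proteins (proteins with an
#' undefined correlation at a lag are excluded from that median). A
#' positive lag means the measurements trail the simulation, i.e. the
#' predicted dynamics run ahead of the data. Ties go to the smallest
#' absolute lag. Measured expression values are expected to be
#' log2-transformed upstream (see [log2_clamp()]).
#'
#' @param sim data frame `time_h` + one column per protein (simulated).
#' @param meas data frame `time_h` + one column per protein (measured).
#' @param lag_range length-2 numeric, h.
#' @param dt grid interval for resampling and the lag scan, h (default
#'   0.1).
#' @return an `xcorr_result`: `lags` (tibble `lag_h`, `median_r`),
#'   `by_protein` (tibble `protein`, `lag_h`, `r`), `best_lag`,
#'   `corr_at_best` (named), `median_at_best`.
#' @export
best_common_lag <- function(sim, meas, lag_range = c(-1.7, 1.7), dt = 0.1) {
  shared <- intersect(setdiff(names(sim), "time_h"),
                      setdiff(names(meas), "time_h"))
  if (length(shared) == 0) abort_domain("no shared protein ids between sim and meas.")
  rs <- resample_profiles(sim[c("time_h", shared)], meas[c("time_h", shared)],
                          dt = dt)
  kmax <- floor(lag_range[2] / rs$dt + 1e-9)
  kmin <- ceiling(lag_range[1] / rs$dt - 1e-9)
  lags <- (kmin:kmax) * rs$dt
  per <- bind_rows(lapply(shared, function(pr) {
    lagged_crosscorr(rs$a[[pr]], rs$b[[pr]], lags, rs$dt) |>
      mutate(protein = pr, .before = 1)
  }))
  med <- per |>
    group_by(.data$lag_h) |>
    summarise(median_r = median(.data$r, na.rm = TRUE), .groups = "drop")
  ok <- which(is.finite(med$median_r))
  if (length(ok) == 0) abort_domain("no lag has a defined median correlation.")
  best_i <- ok[order(-med$median_r[ok], abs(med$lag_h[ok]), med$lag_h[ok])][1]
  best <- med$lag_h[best_i]
  at_best <- per |> filter(.data$lag_h == best)
  structure(list(
    lags = med,
    by_protein = per,
    best_lag = best,
    corr_at_best = setNames(at_best$r, at_best$protein),
    median_at_best = med$median_r[best_i]
  ), class = "xcorr_result")
}

#' @export
print.xcorr_result <- function(x, ...) {
  cat("<xcorr_result> best common lag: ", x$best_lag, " h; median r = ",
      format(x$median_at_best, digits = 3), " over ",
      length(x$corr_at_best), " proteins\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.xcorr_result <- function(x, ...) x$by_protein

#' @exportS3Method generics::glance
glance.xcorr_result <- function(x, ...) {
  tibble(best_lag_h = x$best_lag, median_r = x$median_at_best,
         n_proteins = length(x$corr_at_best),
         min_r = min(x$corr_at_best, na.rm = TRUE),
         max_r = max(x$corr_at_best, na.rm = TRUE))
}

#' @exportS3Method ggplot2::autoplot
autoplot.xcorr_result <- function(object, ...) {
  ggplot2::ggplot(object$lags,
                  ggplot2::aes(x = .data$lag_h, y = .data$median_r)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_lag, linetype = "dashed") +
    ggplot2::labs(x = "lag (h)", y = "median cross-correlation")
}
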