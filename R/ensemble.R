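#' Random perturbation of effective rate constants
#'
#' Draws `n` models with the targeted `keff` couplings multiplied by
#' independent log-uniform factors on `range` (default `[0.1, 10]`, the
#' symmetric multiplicative band: the median factor is 1 and factors
#' below/above 1 are equally likely). Unlisted couplings keep factor
#' exactly 1.
#'
#' @param model an [me_model()].
#' @param targets couplings to perturb: `"all"`, or a data frame with
#'   columns `complex`, `rxn`.
#' @param n number of samples.
#' @param seed RNG seed; fixed seed gives bitwise-identical factors.
#' @param range length-2 numeric multiplicative range.
#' @return tibble with one row per sample: `sample` (id), `factors`
#'   (list-column of tibbles `complex`, `rxn`, `factor`) and `model`
#'   (list-column of perturbed models).
#' @export
perturb_keff <- function(model, targets = "all", n, seed = NULL,
                         range = c(0.1, 10)) {
  stopifnot(is_me_model(model), n >= 1)
  couplings <- bind_rows(lapply(seq_len(nrow(model$complexes)), function(i)
    tibble(complex = model$complexes$id[i],
           rxn = names(model$complexes$keff[[i]]))))
  if (is.character(targets) && identical(targets, "all")) {
    targets <- couplings
  } else {
    targets <- as_tibble(targets)
    stopifnot(all(c("complex", "rxn") %in% names(targets)))
    known <- paste(couplings$complex, couplings$rxn)
    bad <- !paste(targets$complex, targets$rxn) %in% known
    if (any(bad)) {
      abort_model(paste0("unknown keff coupling(s): ",
                         paste(paste(targets$complex[bad], targets$rxn[bad],
                                     sep = ":"), collapse = ", ")))
    }
  }
  m <- nrow(targets)
  with_seed(seed, {
    samples <- lapply(seq_len(n), function(s) {
      f <- exp(runif(m, log(range[1]), log(range[2])))
      tibble(complex = targets$complex, rxn = targets$rxn, factor = f)
    })
  })
  tibble(sample = seq_len(n),
         factors = samples,
         model = lapply(samples, function(f) apply_keff_factors(model, f)))
}

#' Apply multiplicative keff factors to a model
#'
#' @param model an [me_model()].
#' @param factors data frame with columns `complex`, `rxn`, `factor`.
#' @return the modified model.
#' @export
apply_keff_factors <- function(model, factors) {
  stopifnot(is_me_model(model))
  factors <- as_tibble(factors)
  out <- model
  for (i in seq_len(nrow(factors))) {
    ci <- match(factors$complex[i], out$complexes$id)
    if (is.na(ci)) abort_model(paste0("unknown complex: ", factors$complex[i]))
    ke <- out$complexes$keff[[ci]]
    if (!factors$rxn[i] %in% names(ke)) {
      abort_model(paste0("no keff coupling (", factors$complex[i], ", ",
                         factors$rxn[i], ")"))
    }
    ke[factors$rxn[i]] <- ke[factors$rxn[i]] * factors$factor[i]
    out$complexes$keff[[ci]] <- ke
  }
  out
}

#' Sum of squared errors between simulated and measured profiles
#'
#' Both tables are aligned on a common grid (see [resample_profiles()])
#' and the squared differences summed over the shared species and
#' timepoints. With `grid = "measured"` the simulation is interpolated at
#' the measured timepoints instead (the natural choice when fitting).
#'
#' @param simulated,measured data frames `time_h` + species columns (an
#'   `me_timecourse` is accepted for `simulated`: its concentrations are
#'   used).
#' @param species character vector of species to score; default: all
#'   shared columns.
#' @param grid `"common"` or `"measured"`.
#' @return non-negative SSE; 0 iff the profiles agree on the grid.
#' @export
score_fit <- function(simulated, measured, species = NULL,
                      grid = c("common", "measured")) {
  grid <- match.arg(grid)
  if (inherits(simulated, "me_timecourse")) simulated <- simulated$concentrations
  if (inherits(measured, "me_timecourse")) measured <- measured$concentrations
  shared <- intersect(setdiff(names(simulated), "time_h"),
                      setdiff(names(measured), "time_h"))
  if (!is.null(species)) shared <- intersect(shared, species)
  if (length(shared) == 0) abort_domain("no shared species between simulated and measured.")
  if (grid == "common") {
    rs <- resample_profiles(simulated[c("time_h", shared)],
                            measured[c("time_h", shared)])
    a <- rs$a; b <- rs$b
  } else {
    a <- tibble(time_h = measured$time_h)
    for (sp in shared) {
      a[[sp]] <- approx(simulated$time_h, simulated[[sp]],
                        xout = measured$time_h, rule = 2)$y
    }
    b <- measured[c("time_h", shared)]
  }
  sum((as.matrix(a[shared]) - as.matrix(b[shared]))^2)
}

#' Select the experimentally consistent ensemble
#'
#' @param scores data frame with columns `sample`, `sse` (one row per
#'   scored perturbation sample).
#' @param threshold SSE cutoff; default `1.5 * min(sse)`.
#' @return tibble of the samples with `sse <= threshold`, sorted
#'   ascending by `sse` (possibly zero rows).
#' @export
select_ensemble <- function(scores, threshold = NULL) {
  scores <- as_tibble(scores)
  stopifnot(all(c("sample", "sse") %in% names(scores)))
  if (is.null(threshold)) threshold <- 1.5 * min(scores$sse)
  scores |> filter(.data$sse <= threshold) |> arrange(.data$sse)
}
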