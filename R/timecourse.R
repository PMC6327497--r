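#' Tidy a batch time course
#'
#' Returns the trajectories in long form: one row per `(time_h, series,
#' id)` with `series` one of `"concentration"`, `"flux"`, `"proteome"`,
#' `"biomass"`, `"mu"`.
#'
#' @param x an `me_timecourse`.
#' @param ... unused.
#' @exportS3Method generics::tidy
tidy.me_timecourse <- function(x, ...) {
  long <- function(df, series) {
    tidyr::pivot_longer(df, -"time_h", names_to = "id", values_to = "value") |>
      mutate(series = series, .after = "time_h")
  }
  bind_rows(
    long(x$concentrations, "concentration"),
    long(x$fluxes, "flux"),
    long(x$proteome, "proteome"),
    x$biomass |>
      tidyr::pivot_longer(-"time_h", names_to = "id", values_to = "value") |>
      mutate(series = ifelse(.data$id == "mu_per_h", "mu", "biomass"),
             .after = "time_h"))
}

#' @exportS3Method generics::glance
glance.me_timecourse <- function(x, ...) {
  tibble(mode = x$mode,
         n_timepoints = nrow(x$concentrations),
         n_solves = nrow(x$events),
         t_end = max(x$concentrations$time_h),
         final_biomass = x$biomass$biomass_gdw_l[nrow(x$biomass)],
         completed = is.null(x$error))
}

#' Plot a batch time course
#'
#' Concentration profiles per metabolite with the biomass curve overlaid
#' on a separate facet; solve events are marked as vertical lines.
#'
#' @param object an `me_timecourse`.
#' @param ... unused.
#' @exportS3Method ggplot2::autoplot
autoplot.me_timecourse <- function(object, ...) {
  conc <- tidyr::pivot_longer(object$concentrations, -"time_h",
                              names_to = "species", values_to = "value") |>
    mutate(panel = "concentration (mmol/L)")
  bio <- tibble(time_h = object$biomass$time_h, species = "biomass",
                value = object$biomass$biomass_gdw_l,
                panel = "biomass (gDW/L)")
  ggplot2::ggplot(bind_rows(conc, bio),
                  ggplot2::aes(x = .data$time_h, y = .data$value,
                               colour = .data$species)) +
    ggplot2::geom_vline(data = object$events,
                        ggplot2::aes(xintercept = .data$t),
                        linetype = "dotted", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (h)", y = NULL, colour = NULL)
}

#' Write / read a time course as plain-text artifacts
#'
#' Four CSV files (first column `time_h`, one column per species):
#' `concentrations.csv`, `fluxes.csv`, `proteome.csv`, `biomass.csv`, plus
#' the solve-event log `events.jsonl` as JSON lines `{t, trigger, mu}`.
#'
#' @param tc an `me_timecourse`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly; `read_timecourse_dir()` returns a list of
#'   tibbles with the same names.
#' @export
write_timecourse <- function(tc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(tc$concentrations, file.path(dir, "concentrations.csv"),
            row.names = FALSE)
  write.csv(tc$fluxes, file.path(dir, "fluxes.csv"), row.names = FALSE)
  write.csv(tc$proteome, file.path(dir, "proteome.csv"), row.names = FALSE)
  write.csv(tc$biomass, file.path(dir, "biomass.csv"), row.names = FALSE)
  con <- file(file.path(dir, "events.jsonl"), "w")
  on.exit(close(con))
  for (i in seq_len(nrow(tc$events))) {
    writeLines(jsonlite::toJSON(as.list(tc$events[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  invisible(dir)
}

#' @rdname write_timecourse
#' @export
read_timecourse_dir <- function(dir) {
  rd <- function(f) as_tibble(read.csv(file.path(dir, f), check.names = FALSE))
  ev <- file.path(dir, "events.jsonl")
  events <- if (file.exists(ev)) {
    bind_rows(lapply(readLines(ev), function(l)
      as_tibble(jsonlite::fromJSON(l))))
  } else tibble(t = numeric(), trigger = character(), mu = numeric())
  list(concentrations = rd("concentrations.csv"),
       fluxes = rd("fluxes.csv"),
       proteome = rd("proteome.csv"),
       biomass = rd("biomass.csv"),
       events = events)
}

#' Proteome mass-fraction trajectory
#'
#' Converts the proteome trajectory of a time course into per-protein mass
#' fractions at every timepoint, using [mass_fractions_translation()]
#' (base mode, translation fluxes) or [mass_fractions_concentration()]
#' (inertia mode, complex concentrations). Timepoints where all entries
#' are zero (e.g. after growth has stopped) keep the last defined
#' composition, since a zero synthesis flux leaves the standing proteome
#' unchanged.
#'
#' @param tc an `me_timecourse`.
#' @return tibble `time_h` + one fraction column per protein/complex.
#' @export
mass_fraction_timecourse <- function(tc) {
  stopifnot(inherits(tc, "me_timecourse"))
  w <- if (tc$mode == "inertia") tc$complex_weights else tc$protein_weights
  ids <- setdiff(names(tc$proteome), "time_h")
  w <- w[ids]
  vals <- as.matrix(tc$proteome[ids])
  out <- matrix(NA_real_, nrow = nrow(vals), ncol = length(ids),
                dimnames = list(NULL, ids))
  last <- NULL
  for (i in seq_len(nrow(vals))) {
    x <- pmax(vals[i, ], 0)    # clip solver noise
    if (sum(x * w) > 0) {
      last <- if (tc$mode == "inertia") {
        mass_fractions_concentration(x, w)
      } else {
        mass_fractions_translation(x, w)
      }
    }
    if (!is.null(last)) out[i, ] <- last
  }
  bind_cols(tibble(time_h = tc$proteome$time_h), as_tibble(out))
}
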