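#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_chr map_lgl map2 pmap imap walk
#' @importFrom stats approx cor median runif rnorm setNames sd quantile
#' @importFrom utils head tail read.csv write.csv
NULL

# condition helpers: model/config problems exit differently from solver
# failures in the CLI, so tag the classes here
abort_model <- function(msg, ...) abort(msg, class = "mebatch_model_error", ...)
abort_domain <- function(msg, ...) abort(msg, class = "mebatch_domain_error", ...)
abort_solver <- function(msg, ...) abort(msg, class = "mebatch_solver_error", ...)

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# scalar %||% that also treats NA as empty
`%na%` <- function(x, y) if (is.null(x) || (length(x) == 1L && is.na(x))) y else x

# deterministic RNG scope: run code with a local seed without disturbing
# the caller's RNG stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
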