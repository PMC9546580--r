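#' Haldane map function
#'
#' Converts a genetic distance in centimorgans to a recombination fraction
#' assuming no crossover interference: `r(d) = (1 - exp(-2d/100)) / 2`.
#'
#' @param d Genetic distance in cM (vectorized).
#' @return Recombination fraction in `[0, 0.5)`.
#' @export
haldane_r <- function(d) {
  if (any(d < 0)) stop("map distances must be non-negative")
  0.5 * (1 - exp(-2 * d / 100))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## wrap an angle in degrees to (-180, 180]
wrap_angle <- function(a) {
  a <- a %% 360
  ifelse(a > 180, a - 360, a)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive number", name))
  invisible(x)
}
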