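## Synthetic genetic maps and two-state RIL genotypes.
##
## The generator emulates an intermated RIL population (two fixed homozygous
## states, no residual heterozygosity) on a map whose cM distances are taken
## at face value, i.e. already expansion-adjusted; recombination between
## adjacent markers follows the Haldane map function.

GENO_LEVELS <- c("AA", "BB")

#' Simulate an evenly spaced genetic map
#'
#' Places markers at `0, s, 2s, ...` along each chromosome.
#'
#' @param chromosomes Named numeric vector (or `data.frame` with columns
#'   `name`, `length`) of chromosome lengths in cM.
#' @param marker_spacing Marker spacing `s` in cM; must fit at least twice
#'   into every chromosome.
#' @return A `data.frame` of class `gmap` with columns `marker`, `chr`,
#'   `pos` (cM, monotone within chromosome; marker names unique).
#' @examples
#' simulate_genetic_map(c("1" = 100), 10)
#' @export
simulate_genetic_map <- function(chromosomes, marker_spacing) {
  stop_if_not_scalar_pos(marker_spacing, "marker_spacing")
  if (is.data.frame(chromosomes)) {
    len <- as.numeric(chromosomes$length)
    nm <- as.character(chromosomes$name)
  } else {
    len <- as.numeric(chromosomes)
    nm <- names(chromosomes) %||% as.character(seq_along(len))
  }
  if (length(len) == 0L || any(!is.finite(len)) || any(len <= 0))
    stop("chromosome lengths must be positive")
  if (any(len < 2 * marker_spacing))
    stop("marker_spacing must fit at least twice into every chromosome")
  pieces <- lapply(seq_along(len), function(i) {
    pos <- seq(0, len[i], by = marker_spacing)
    data.frame(
      marker = sprintf("c%s_m%03d", nm[i], seq_along(pos)),
      chr = nm[i], pos = pos,
      stringsAsFactors = FALSE
    )
  })
  map <- do.call(rbind, pieces)
  rownames(map) <- NULL
  class(map) <- c("gmap", "data.frame")
  map
}

validate_map <- function(map) {
  if (!all(c("marker", "chr", "pos") %in% names(map)))
    stop("map must have columns marker, chr, pos")
  if (anyDuplicated(map$marker))
    stop("marker names must be unique genome-wide")
  bad <- tapply(map$pos, factor(map$chr, levels = unique(map$chr)),
                function(p) any(diff(p) < 0))
  if (any(unlist(bad)))
    stop("marker positions must be non-decreasing within chromosomes")
  invisible(map)
}

#' Simulate two-state RIL genotypes on a map
#'
#' Each individual starts every chromosome in state AA or BB with
#' probability 1/2; the state switches between adjacent markers with the
#' Haldane recombination fraction of their map distance.  Observed calls
#' are then flipped with probability `error_rate` and masked with
#' probability `missing_rate`.
#'
#' @param map A `gmap` (see [simulate_genetic_map()]).
#' @param n Number of individuals (lines).
#' @param seed Optional integer seed.
#' @param error_rate,missing_rate Per-call genotyping error / missingness
#'   probabilities in `[0, 1]`.
#' @return A list of class `ril_cross` with elements `map`, `geno`
#'   (n x markers integer matrix, 1 = AA, 2 = BB, NA = missing) and
#'   `true_geno` (error-free states).
#' @export
simulate_ril_genotypes <- function(map, n, seed = NULL,
                                   error_rate = 0, missing_rate = 0) {
  validate_map(map)
  if (n < 1) stop("n must be >= 1")
  if (error_rate < 0 || error_rate > 1 || missing_rate < 0 || missing_rate > 1)
    stop("rates must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  m <- nrow(map)
  g <- matrix(NA_integer_, n, m, dimnames = list(
    sprintf("L%04d", seq_len(n)), map$marker))
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    state <- stats::rbinom(n, 1L, 0.5) + 1L
    g[, idx[1L]] <- state
    if (length(idx) > 1L) {
      r <- haldane_r(diff(map$pos[idx]))
      for (k in seq_along(r)) {
        switch_now <- stats::runif(n) < r[k]
        state <- ifelse(switch_now, 3L - state, state)
        g[, idx[k + 1L]] <- state
      }
    }
  }
  obs <- g
  if (error_rate > 0) {
    flip <- matrix(stats::runif(n * m) < error_rate, n, m)
    obs[flip] <- 3L - obs[flip]
  }
  if (missing_rate > 0) {
    obs[matrix(stats::runif(n * m) < missing_rate, n, m)] <- NA_integer_
  }
  structure(list(map = map, geno = obs, true_geno = g), class = "ril_cross")
}

#' @export
print.ril_cross <- function(x, ...) {
  cat(sprintf("RIL cross: %d individuals, %d markers on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chr))))
  invisible(x)
}
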