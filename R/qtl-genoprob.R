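## Hidden-Markov genotype probabilities for a two-state RIL population.
## Transitions between adjacent evaluation positions use the Haldane
## recombination fraction of their cM distance; emissions allow a
## symmetric genotyping error rate.

#' Compute genotype probabilities on a pseudomarker grid
#'
#' Forward-backward over the states {AA, BB} for every individual and
#' chromosome, with pseudomarkers inserted every `step_cM` so that
#' downstream scans evaluate between markers.  An individual with no
#' typed marker on a chromosome gets the uniform 1/2 / 1/2 prior
#' everywhere on it.
#'
#' @param cross A `ril_cross` (map + genotype matrix).
#' @param step_cM Pseudomarker spacing in cM.
#' @param error_prob Assumed genotyping error rate `epsilon`.
#' @return A list of class `genoprob`: per chromosome a list with
#'   `prob` (array individuals x positions x 2, states AA/BB) and `map`
#'   (`data.frame` of `marker` — `NA` for pseudomarkers — and `pos`);
#'   plus attributes `ind`, `step_cM`, `error_prob`.
#' @export
calc_genoprob <- function(cross, step_cM = 1, error_prob = 0.002) {
  stopifnot(inherits(cross, "ril_cross"))
  validate_map(cross$map)
  stop_if_not_scalar_pos(step_cM, "step_cM")
  if (error_prob < 0 || error_prob >= 0.5)
    stop("error_prob must lie in [0, 0.5)")
  map <- cross$map
  g <- cross$geno
  n <- nrow(g)
  out <- list()
  for (ch in unique(map$chr)) {
    midx <- which(map$chr == ch)
    mpos <- map$pos[midx]
    grid <- seq(min(mpos), max(mpos), by = step_cM)
    pos <- sort(unique(round(c(mpos, grid), 10)))
    K <- length(pos)
    mk <- rep(NA_character_, K)
    mk[match(round(mpos, 10), pos)] <- map$marker[midx]

    ## emission likelihoods per state
    E1 <- matrix(1, n, K); E2 <- matrix(1, n, K)
    for (j in seq_along(midx)) {
      k <- match(round(mpos[j], 10), pos)
      obs <- g[, midx[j]]
      E1[, k] <- ifelse(is.na(obs), 1,
                        ifelse(obs == 1L, 1 - error_prob, error_prob))
      E2[, k] <- ifelse(is.na(obs), 1,
                        ifelse(obs == 2L, 1 - error_prob, error_prob))
    }
    r <- haldane_r(diff(pos))

    fA <- matrix(0, n, K); fB <- matrix(0, n, K)
    fA[, 1] <- 0.5 * E1[, 1]; fB[, 1] <- 0.5 * E2[, 1]
    sc <- fA[, 1] + fB[, 1]
    fA[, 1] <- fA[, 1] / sc; fB[, 1] <- fB[, 1] / sc
    if (K > 1) for (k in 2:K) {
      a <- (fA[, k - 1] * (1 - r[k - 1]) + fB[, k - 1] * r[k - 1]) * E1[, k]
      b <- (fA[, k - 1] * r[k - 1] + fB[, k - 1] * (1 - r[k - 1])) * E2[, k]
      sc <- a + b
      fA[, k] <- a / sc; fB[, k] <- b / sc
    }
    bA <- matrix(1, n, K); bB <- matrix(1, n, K)
    if (K > 1) for (k in (K - 1):1) {
      ea <- E1[, k + 1] * bA[, k + 1]; eb <- E2[, k + 1] * bB[, k + 1]
      a <- (1 - r[k]) * ea + r[k] * eb
      b <- r[k] * ea + (1 - r[k]) * eb
      sc <- a + b
      bA[, k] <- a / sc; bB[, k] <- b / sc
    }
    pA <- fA * bA; pB <- fB * bB
    tot <- pA + pB
    prob <- array(c(pA / tot, pB / tot), dim = c(n, K, 2),
                  dimnames = list(rownames(g), NULL, c("AA", "BB")))
    out[[as.character(ch)]] <- list(
      prob = prob,
      map = data.frame(marker = mk, pos = pos, stringsAsFactors = FALSE))
  }
  structure(out, class = "genoprob", ind = rownames(g),
            step_cM = step_cM, error_prob = error_prob)
}

#' Expected-dosage matrix from genotype probabilities
#'
#' The Haley-Knott regressor at each evaluation position:
#' `P(BB) - P(AA)`, in `[-1, 1]`.
#'
#' @param gp A `genoprob` object.
#' @return List: `X` (individuals x positions matrix) and `info`
#'   (`data.frame` with `chr`, `pos`, `marker`).
#' @export
dosage_matrix <- function(gp) {
  stopifnot(inherits(gp, "genoprob"))
  Xs <- lapply(gp, function(cc) cc$prob[, , 2] - cc$prob[, , 1])
  info <- do.call(rbind, lapply(names(gp), function(ch)
    data.frame(chr = ch, pos = gp[[ch]]$map$pos,
               marker = gp[[ch]]$map$marker, stringsAsFactors = FALSE)))
  X <- do.call(cbind, Xs)
  rownames(X) <- attr(gp, "ind")
  list(X = X, info = info)
}
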