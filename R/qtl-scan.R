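## Haley-Knott single-QTL genome scans and permutation significance
## thresholds.  LOD = (n/2) log10(RSS0 / RSS1) comparing the regression
## of the phenotype on expected genotype dosage at each position to the
## intercept-only null.

## core: LOD for each column of centered X against centered y
hk_lod_core <- function(Xc, yc, xx = colSums(Xc^2)) {
  n <- length(yc)
  rss0 <- sum(yc^2)
  if (rss0 < 1e-24) return(rep(0, ncol(Xc)))
  xy <- as.numeric(crossprod(Xc, yc))
  rss1 <- rss0 - ifelse(xx > 1e-12, xy^2 / xx, 0)
  pmax(0, (n / 2) * log10(rss0 / pmax(rss1, 1e-300)))
}

#' Haley-Knott single-QTL genome scan
#'
#' Regresses the phenotype on the expected genotype dosage
#' `P(BB) - P(AA)` at every evaluation position; individuals with a
#' missing phenotype are dropped.
#'
#' @param gp A `genoprob` object.
#' @param pheno Numeric phenotype, one value per individual of `gp`.
#' @return `data.frame` of class `scanone` with `chr`, `pos`, `marker`,
#'   `lod`; attribute `n` is the number of individuals used.
#' @export
scanone_hk <- function(gp, pheno) {
  d <- dosage_matrix(gp)
  if (length(pheno) != nrow(d$X))
    stop("phenotype length must equal the number of individuals")
  keep <- !is.na(pheno)
  y <- pheno[keep]
  X <- d$X[keep, , drop = FALSE]
  if (stats::sd(y) == 0) {
    lod <- rep(0, ncol(X))
  } else {
    Xc <- sweep(X, 2, colMeans(X))
    lod <- hk_lod_core(Xc, y - mean(y))
  }
  out <- cbind(d$info, lod = lod)
  class(out) <- c("scanone", "data.frame")
  attr(out, "n") <- sum(keep)
  out
}

#' Genome-wide permutation significance threshold
#'
#' Shuffles phenotype labels `n_perm` times, records the genome-wide
#' maximum LOD of each permuted scan, and returns the empirical
#' `1 - alpha` quantile (type-7 interpolation).
#'
#' @param gp A `genoprob` object.
#' @param pheno Numeric phenotype (missing values dropped first).
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Genome-wide significance level.
#' @param seed Optional integer seed, recorded on the result.
#' @return Numeric threshold with attributes `maxima`, `n_perm`,
#'   `alpha`, `seed`.
#' @export
permutation_threshold <- function(gp, pheno, n_perm, alpha = 0.05,
                                  seed = NULL) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  d <- dosage_matrix(gp)
  keep <- !is.na(pheno)
  y <- pheno[keep]
  X <- d$X[keep, , drop = FALSE]
  n <- length(y)
  Xc <- sweep(X, 2, colMeans(X))
  xx <- colSums(Xc^2)
  yc <- y - mean(y)
  rss0 <- sum(yc^2)
  Yp <- vapply(seq_len(n_perm), function(i) yc[sample.int(n)], numeric(n))
  num <- crossprod(Xc, Yp)^2 / ifelse(xx > 1e-12, xx, Inf)
  lod <- (n / 2) * log10(rss0 / pmax(rss0 - num, 1e-300))
  maxima <- apply(lod, 2, max)
  thr <- stats::quantile(maxima, 1 - alpha, type = 7, names = FALSE)
  structure(thr, maxima = maxima, n_perm = n_perm, alpha = alpha,
            seed = seed)
}
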