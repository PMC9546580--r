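## Penalized-LOD stepwise multiple-QTL model selection: forward search
## with coordinate-wise position refinement after each addition, then
## backward elimination; the visited model with maximal
## pLOD = LOD - k * penalty is returned (the empty model, pLOD 0, is
## allowed).  Models are additive only.

## RSS of the additive model with the given dosage columns
model_rss <- function(Xc, yc, sel) {
  if (length(sel) == 0) return(sum(yc^2))
  sum(qr.resid(qr(Xc[, sel, drop = FALSE]), yc)^2)
}

## conditional scan: RSS of (sel + candidate) for every candidate column
cond_scan_rss <- function(Xc, yc, sel, cols = seq_len(ncol(Xc))) {
  if (length(sel) == 0) {
    RX <- Xc[, cols, drop = FALSE]; ry <- yc
  } else {
    qrM <- qr(Xc[, sel, drop = FALSE])
    ry <- qr.resid(qrM, yc)
    RX <- qr.resid(qrM, Xc[, cols, drop = FALSE])
  }
  xx <- colSums(RX^2)
  xy <- colSums(RX * ry)
  base <- sum(ry^2)
  rss <- base - ifelse(xx > 1e-8, xy^2 / xx, 0)
  list(rss = rss, ok = xx > 1e-8, base = base)
}

#' Stepwise multiple-QTL model selection
#'
#' @param gp A `genoprob` object.
#' @param pheno Numeric phenotype, one value per individual.
#' @param penalty Penalty per QTL on the LOD scale (> 0); typically the
#'   genome-wide permutation threshold.
#' @param max_qtl Maximum number of QTL in the forward search.
#' @return A list of class `qtl_model`: `qtl` (`data.frame` with `chr`,
#'   `pos`, `marker`, `effect` — the regression coefficient on the
#'   `P(BB) - P(AA)` dosage, i.e. half the between-homozygote
#'   difference — `se` and conditional `lod`), model `lod`, `plod`,
#'   `penalty`, per-QTL conditional `profiles` and 1.5-LOD support
#'   `intervals`, and `n`.
#' @export
stepwise_qtl <- function(gp, pheno, penalty, max_qtl = 6) {
  if (!is.numeric(penalty) || penalty <= 0) stop("penalty must be > 0")
  d <- dosage_matrix(gp)
  keep <- !is.na(pheno)
  y <- pheno[keep]
  X <- d$X[keep, , drop = FALSE]
  info <- d$info
  n <- length(y)
  empty <- structure(list(
    qtl = data.frame(chr = character(), pos = numeric(),
                     marker = character(), effect = numeric(),
                     se = numeric(), lod = numeric()),
    lod = 0, plod = 0, penalty = penalty, profiles = list(),
    intervals = data.frame(chr = character(), lo = numeric(),
                           hi = numeric(), flagged = logical()),
    n = n), class = "qtl_model")
  if (stats::sd(y) == 0) return(empty)
  yc <- y - mean(y)
  Xc <- sweep(X, 2, colMeans(X))
  rss0 <- sum(yc^2)
  ## floor guards the exact-fit limit: once a model explains the trait to
  ## numerical precision, further additions must not gain LOD
  floor_rss <- rss0 * 1e-10
  lod_of <- function(rss) (n / 2) * log10(rss0 / max(rss, floor_rss))

  refine <- function(sel) {
    if (length(sel) < 2) return(sel)
    for (it in 1:10) {
      moved <- FALSE
      for (j in seq_along(sel)) {
        chr_j <- info$chr[sel[j]]
        cols <- which(info$chr == chr_j)
        sc <- cond_scan_rss(Xc, yc, sel[-j], cols)
        cand <- cols[sc$ok]
        if (length(cand) == 0) next
        best <- cand[which.min(sc$rss[sc$ok])]
        if (best != sel[j]) { sel[j] <- best; moved <- TRUE }
      }
      if (!moved) break
    }
    sel
  }

  visited <- list(list(sel = integer(0), lod = 0))
  sel <- integer(0)
  while (length(sel) < max_qtl) {
    sc <- cond_scan_rss(Xc, yc, sel)
    ok <- sc$ok & !(seq_len(ncol(Xc)) %in% sel)
    if (!any(ok)) break
    rss <- ifelse(ok, sc$rss, Inf)
    best <- which.min(rss)  # ties -> first, i.e. lowest (chr, pos)
    sel <- refine(c(sel, best))
    visited[[length(visited) + 1]] <-
      list(sel = sel, lod = lod_of(model_rss(Xc, yc, sel)))
  }
  ## backward elimination from the largest model
  bsel <- sel
  while (length(bsel) > 1) {
    drop_rss <- vapply(seq_along(bsel), function(j)
      model_rss(Xc, yc, bsel[-j]), numeric(1))
    j <- which.min(drop_rss)
    bsel <- refine(bsel[-j])
    visited[[length(visited) + 1]] <-
      list(sel = bsel, lod = lod_of(model_rss(Xc, yc, bsel)))
  }
  plods <- vapply(visited, function(v) v$lod - length(v$sel) * penalty,
                  numeric(1))
  best <- visited[[which.max(plods)]]
  if (max(plods) <= 0 || length(best$sel) == 0) return(empty)
  sel <- sort(best$sel)

  fit <- stats::lm(y ~ X[, sel, drop = FALSE])
  cf <- suppressWarnings(summary(fit))$coefficients
  eff <- cf[-1, 1]; se <- cf[-1, 2]

  profiles <- vector("list", length(sel))
  cond_lod <- numeric(length(sel))
  intervals <- NULL
  for (j in seq_along(sel)) {
    chr_j <- info$chr[sel[j]]
    cols <- which(info$chr == chr_j)
    sc <- cond_scan_rss(Xc, yc, sel[-j], cols)
    plod <- (n / 2) * log10(max(sc$base, floor_rss) /
                              pmax(sc$rss, floor_rss))
    plod[!sc$ok] <- 0
    prof <- data.frame(chr = chr_j, pos = info$pos[cols],
                       lod = pmax(plod, 0), stringsAsFactors = FALSE)
    profiles[[j]] <- prof
    cond_lod[j] <- prof$lod[match(sel[j], cols)]
    intervals <- rbind(intervals,
                       support_interval(prof, info$pos[sel[j]]))
  }
  structure(list(
    qtl = data.frame(chr = info$chr[sel], pos = info$pos[sel],
                     marker = info$marker[sel], effect = unname(eff),
                     se = unname(se), lod = cond_lod,
                     stringsAsFactors = FALSE),
    lod = best$lod, plod = max(plods), penalty = penalty,
    profiles = profiles, intervals = intervals, n = n),
    class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat(sprintf("QTL model: %d QTL, LOD %.2f, pLOD %.2f (penalty %.2f)\n",
              nrow(x$qtl), x$lod, x$plod, x$penalty))
  if (nrow(x$qtl) > 0) print(x$qtl)
  invisible(x)
}

#' LOD-drop support interval around a scan peak
#'
#' The contiguous run of evaluated positions around the peak whose LOD
#' stays within `drop` of the peak LOD, expanded by one evaluated
#' position on each side.  A flat profile returns the whole chromosome,
#' flagged.
#'
#' @param profile `data.frame` with `chr`, `pos`, `lod` for one
#'   chromosome.
#' @param peak_pos Position (cM) of the peak; must be a profile maximum.
#' @param drop LOD drop defining the interval.
#' @return One-row `data.frame`: `chr`, `lo`, `hi`, `flagged`.
#' @export
support_interval <- function(profile, peak_pos, drop = 1.5) {
  stopifnot(all(c("chr", "pos", "lod") %in% names(profile)))
  o <- order(profile$pos)
  pos <- profile$pos[o]; lod <- profile$lod[o]
  if (max(lod) - min(lod) < 1e-9) {
    return(data.frame(chr = profile$chr[1], lo = min(pos), hi = max(pos),
                      flagged = TRUE, stringsAsFactors = FALSE))
  }
  pk <- which.min(abs(pos - peak_pos))
  if (drop <= 0) { # degenerate interval at the peak grid point
    return(data.frame(chr = profile$chr[1], lo = pos[pk], hi = pos[pk],
                      flagged = FALSE, stringsAsFactors = FALSE))
  }
  cut <- lod[pk] - drop
  lo <- pk
  while (lo > 1 && lod[lo - 1] >= cut) lo <- lo - 1
  hi <- pk
  while (hi < length(pos) && lod[hi + 1] >= cut) hi <- hi + 1
  lo <- max(1, lo - 1)
  hi <- min(length(pos), hi + 1)
  data.frame(chr = profile$chr[1], lo = pos[lo], hi = pos[hi],
             flagged = FALSE, stringsAsFactors = FALSE)
}
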