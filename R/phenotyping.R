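## Image-based root phenotyping: segmentation, skeletonization, tip-angle
## measurement, series assembly, initial-angle subtraction, per-line
## averaging and genotype-group comparison statistics.

#' Segment the root from a grayscale frame
#'
#' Otsu threshold followed by selection of the largest connected
#' component with at least `min_area_px` pixels.
#'
#' @param image Single-channel numeric matrix (rows = image rows).
#' @param min_area_px Minimum component area in pixels.
#' @return Logical mask matrix, or `NULL` when no sufficiently large
#'   component exists ("no root found"; the frame should be flagged).
#' @export
segment_root <- function(image, min_area_px = 50) {
  if (length(dim(image)) != 2L) stop("image must be a single-channel matrix")
  rng <- range(image, finite = TRUE)
  norm <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  th <- EBImage::otsu(EBImage::Image(t(norm)))
  mask <- norm > th
  if (!any(mask)) return(NULL)
  ## small opening removes speckle noise and detaches noise bridges
  ## before the largest component is taken
  mask <- t(EBImage::imageData(EBImage::opening(
    EBImage::Image(t(mask)), EBImage::makeBrush(3, shape = "diamond")))) > 0
  if (!any(mask)) return(NULL)
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  sizes <- tabulate(lab[lab > 0])
  if (max(sizes) < min_area_px) return(NULL)
  lab == which.max(sizes)
}

## Zhang-Suen thinning of a logical mask, vectorized over the image.
skeletonize <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
  nr <- nrow(m); nc <- ncol(m)
  sh <- function(x, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    out[max(1, 1 + dr):min(nr, nr + dr), max(1, 1 + dc):min(nc, nc + dc)] <-
      x[max(1, 1 - dr):min(nr, nr - dr), max(1, 1 - dc):min(nc, nc - dc)]
    out
  }
  repeat {
    changed <- FALSE
    for (pass in 1:2) {
      p2 <- sh(m, 1, 0);  p3 <- sh(m, 1, -1); p4 <- sh(m, 0, -1)
      p5 <- sh(m, -1, -1); p6 <- sh(m, -1, 0); p7 <- sh(m, -1, 1)
      p8 <- sh(m, 0, 1);  p9 <- sh(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seqs <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, nr, nc)
      for (k in 1:8) a <- a + (!seqs[[k]] & seqs[[k + 1]])
      if (pass == 1) {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- m & b >= 2 & b <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) { m[cond] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1), drop = FALSE]
}

## BFS over skeleton pixels (8-connected); returns geodesic distances and
## parents from a source pixel index into `px` (data.frame row, col)
skeleton_graph <- function(px, dims) {
  id <- matrix(NA_integer_, dims[1], dims[2])
  id[cbind(px$row, px$col)] <- seq_len(nrow(px))
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  nbrs <- lapply(seq_len(nrow(px)), function(i) {
    r <- px$row[i] + offs$dr; c <- px$col[i] + offs$dc
    ok <- r >= 1 & r <= dims[1] & c >= 1 & c <= dims[2]
    v <- id[cbind(r[ok], c[ok])]
    v[!is.na(v)]
  })
  nbrs
}

## Depth-limited BFS through the mask from a start pixel; the target is
## the visited pixel farthest along `direction` from the start.  Returns
## the (col, row) path beyond the start, or NULL.
extend_to_mask_tip <- function(mask, start, max_depth, direction) {
  nr <- nrow(mask); nc <- ncol(mask)
  w <- which(mask, arr.ind = TRUE)
  id <- matrix(NA_integer_, nr, nc)
  id[w] <- seq_len(nrow(w))
  s <- id[start["row"], start["col"]]
  if (is.na(s)) return(NULL)
  u <- direction / sqrt(sum(direction^2))
  dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  n <- nrow(w)
  dist <- rep(NA_integer_, n); parent <- rep(NA_integer_, n)
  dist[s] <- 0L
  queue <- integer(n); queue[1] <- s; qh <- 1L; qt <- 1L
  proj <- function(v) u[1] * (w[v, 2] - w[s, 2]) + u[2] * (w[v, 1] - w[s, 1])
  far <- s; far_proj <- 0
  while (qh <= qt) {
    cur <- queue[qh]; qh <- qh + 1L
    if (dist[cur] >= max_depth) next
    r0 <- w[cur, 1]; c0 <- w[cur, 2]
    for (k in 1:8) {
      r <- r0 + dr[k]; c <- c0 + dc[k]
      if (r < 1 || r > nr || c < 1 || c > nc) next
      v <- id[r, c]
      if (is.na(v) || !is.na(dist[v])) next
      dist[v] <- dist[cur] + 1L
      parent[v] <- cur
      qt <- qt + 1L; queue[qt] <- v
      pv <- proj(v)
      if (pv > far_proj) { far <- v; far_proj <- pv }
    }
  }
  if (far == s) return(NULL)
  path <- far
  while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
  path <- path[-1] # drop the start pixel itself
  cbind(col = w[path, 2], row = w[path, 1])
}

bfs_skeleton <- function(nbrs, from) {
  n <- length(nbrs)
  dist <- rep(NA_integer_, n); parent <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (v in nbrs[[cur]]) {
      if (is.na(dist[v])) {
        dist[v] <- dist[cur] + 1L
        parent[v] <- cur
        queue <- c(queue, v)
      }
    }
  }
  list(dist = dist, parent = parent)
}

#' Measure the root tip angle from a binary mask
#'
#' Skeletonizes the mask, takes the skeleton endpoint nearest the top
#' edge as the seed side, the endpoint geodesically farthest from it as
#' the tip, and fits a line (principal component) to the last
#' `ceiling(tail_mm * px_per_mm)` skeleton pixels of the geodesic path.
#' The returned angle is the signed direction of growth relative to the
#' image horizontal, in `(-180, 180]`; straight-down growth reads 90.
#'
#' @param mask Logical matrix from [segment_root()].
#' @param px_per_mm Image resolution.
#' @param tail_mm Length of the tip segment used for the direction fit.
#' @return Angle in degrees, or `NA` when the skeleton has fewer than
#'   3 pixels or no endpoints (frame should be flagged).
#' @export
measure_tip_angle <- function(mask, px_per_mm = 10, tail_mm = 0.5) {
  if (is.null(mask) || !any(mask)) return(NA_real_)
  sk <- skeletonize(mask)
  w <- which(sk, arr.ind = TRUE)
  if (nrow(w) < 3) return(NA_real_)
  px <- data.frame(row = w[, 1], col = w[, 2])
  nbrs <- skeleton_graph(px, dim(mask))
  deg <- lengths(nbrs)
  ends <- which(deg == 1L)
  if (length(ends) < 2) return(NA_real_)
  seed_end <- ends[which.min(px$row[ends])]
  b <- bfs_skeleton(nbrs, seed_end)
  reach <- ends[!is.na(b$dist[ends])]
  tip <- reach[which.max(b$dist[reach])]
  ## walk back from the tip along BFS parents
  path <- tip
  while (!is.na(b$parent[path[1]])) path <- c(b$parent[path[1]], path)
  pts <- cbind(col = px$col[path], row = px$row[path])
  ## thinning erodes line ends by roughly the root width, so the
  ## skeleton stops short of the real tip: extend the path through the
  ## mask, a limited depth, in the direction the skeleton was heading
  if (nrow(pts) >= 6) {
    width_est <- sum(mask) / max(nrow(px), 1)
    dirv <- pts[nrow(pts), ] - pts[nrow(pts) - 5, ]
    ext <- extend_to_mask_tip(mask, pts[nrow(pts), c("row", "col")],
                              max_depth = ceiling(3 * width_est) + 3,
                              direction = dirv)
    if (!is.null(ext)) pts <- rbind(pts, ext)
  }
  tip_tangent_angle(mask, pts, px_per_mm, tail_mm)
}

## End-tangent estimator for the rasterized centerline path `pts`
## (col/row matrix ordered seed -> tip).
##
## Raw path pixels jog in whole-pixel steps, so each tail point is
## snapped to the iterated local mask centroid for subpixel coordinates.
## A quadratic fitted over a long window then classifies the tip:
## * straight tip (tangent turns < `span_thresh` deg over the window):
##   a line fit over the long window — for a straight segment this has
##   no curvature bias, and the long lever arm averages out the single
##   rasterization step into which a slow lateral drift collapses;
## * curved tip: a locally weighted quadratic (weights decaying with
##   arc distance from the tip) whose derivative is taken at the tip,
##   keeping the tangent local without being dominated by pixel steps.
tip_tangent_angle <- function(mask, pts, px_per_mm, tail_mm,
                              span_thresh = 4) {
  k_local <- max(ceiling(tail_mm * px_per_mm), round(4 * px_per_mm))
  k_long <- max(2 * k_local, round(7 * px_per_mm))
  rad <- max(3, round(0.5 * px_per_mm))
  wscale <- 1.5 * px_per_mm
  mw <- which(mask, arr.ind = TRUE)
  snap <- function(p) {
    for (it in 1:4) {
      d2 <- (mw[, 2] - p[1])^2 + (mw[, 1] - p[2])^2
      sel <- mw[d2 <= rad^2, , drop = FALSE]
      if (nrow(sel) == 0) break
      p <- c(mean(sel[, 2]), mean(sel[, 1]))
    }
    p
  }
  centerline <- function(k) {
    tl <- pts[max(1L, nrow(pts) - k + 1L):nrow(pts), , drop = FALSE]
    cent <- t(apply(tl, 1, function(r) snap(c(r["col"], r["row"]))))
    dn <- sqrt(diff(cent[, 1])^2 + diff(cent[, 2])^2)
    cent[c(dn >= 0.7, TRUE), , drop = FALSE] # iterated snaps collapse at
    # the tip cap; drop the duplicates
  }
  arc <- function(cent) {
    s <- c(0, cumsum(sqrt(diff(cent[, 1])^2 + diff(cent[, 2])^2)))
    s - s[length(s)]
  }
  cl <- centerline(k_long)
  if (nrow(cl) < 5) {
    if (nrow(cl) < 2) return(NA_real_)
    v <- cl[nrow(cl), ] - cl[1, ]
    return(wrap_angle(atan2(v[2], v[1]) * 180 / pi))
  }
  sL <- arc(cl)
  BL <- cbind(1, sL, sL^2)
  cx <- stats::lm.fit(BL, cl[, 1])$coefficients
  cy <- stats::lm.fit(BL, cl[, 2])$coefficients
  vend <- c(cx[2], cy[2])
  vbeg <- c(cx[2] + 2 * cx[3] * sL[1], cy[2] + 2 * cy[3] * sL[1])
  span <- abs(wrap_angle((atan2(vend[2], vend[1]) -
                            atan2(vbeg[2], vbeg[1])) * 180 / pi))
  if (is.finite(span) && span < span_thresh) {
    v <- c(stats::lm.fit(BL[, 1:2], cl[, 1])$coefficients[2],
           stats::lm.fit(BL[, 1:2], cl[, 2])$coefficients[2])
  } else {
    cent <- centerline(k_local)
    if (nrow(cent) < 4) return(NA_real_)
    s <- arc(cent)
    w <- sqrt(exp(s / wscale))
    B <- cbind(1, s, s^2)
    v <- c(stats::lm.fit(B * w, cent[, 1] * w)$coefficients[2],
           stats::lm.fit(B * w, cent[, 2] * w)$coefficients[2])
  }
  if (!all(is.finite(v)) || sum(v^2) == 0) return(NA_real_)
  wrap_angle(atan2(v[2], v[1]) * 180 / pi)
}

#' Assemble a tip-angle series from per-frame measurements
#'
#' Flagged (NA) frames standing alone between valid neighbors are
#' linearly interpolated; runs of two or more flagged frames stay
#' missing.
#'
#' @param angles Per-frame angle vector (degrees; `NA` = flagged frame).
#' @param times Frame times, minutes (strictly increasing).
#' @param id,line Seedling and line identifiers.
#' @return A list of class `tip_series` with `times`, `angles`, `flags`
#'   (`"ok"`, `"interpolated"`, `"missing"`), `id`, `line`,
#'   `initial_subtracted`.
#' @export
build_series <- function(angles, times, id = "s1", line = "L1") {
  stopifnot(length(angles) == length(times))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (sum(!is.na(angles)) < 2) stop("fewer than 2 valid frames")
  flags <- ifelse(is.na(angles), "missing", "ok")
  filled <- zoo::na.approx(angles, x = times, maxgap = 1, na.rm = FALSE)
  ## na.approx never extrapolates, so leading/trailing NAs stay missing
  flags[is.na(angles) & !is.na(filled)] <- "interpolated"
  structure(list(times = times, angles = as.numeric(filled), flags = flags,
                 id = id, line = line, initial_subtracted = FALSE),
            class = "tip_series")
}

#' Measure a full image stack into a tip-angle series
#'
#' Convenience wrapper: segment, measure and assemble each frame.
#'
#' @param frames List of single-channel matrices.
#' @inheritParams build_series
#' @inheritParams measure_tip_angle
#' @param min_area_px Passed to [segment_root()].
#' @return A `tip_series`.
#' @export
measure_series <- function(frames, times, px_per_mm = 10, tail_mm = 0.5,
                           min_area_px = 50, id = "s1", line = "L1") {
  angles <- vapply(frames, function(f) {
    m <- segment_root(f, min_area_px = min_area_px)
    if (is.null(m)) NA_real_ else measure_tip_angle(m, px_per_mm, tail_mm)
  }, numeric(1))
  build_series(angles, times, id = id, line = line)
}

#' Subtract the initial angle from a series
#'
#' Removes the angle at the first retained time from every time point so
#' the series starts at zero; idempotent.  When the first frame is
#' missing, the earliest valid frame is used and the substitution is
#' recorded in the `initial_source` field.
#'
#' @param series A `tip_series`.
#' @return The shifted `tip_series` with `initial_subtracted = TRUE`.
#' @export
subtract_initial <- function(series) {
  stopifnot(inherits(series, "tip_series"))
  if (isTRUE(series$initial_subtracted)) return(series)
  valid <- which(!is.na(series$angles))
  if (length(valid) == 0) stop("no valid frame to anchor the subtraction")
  f <- valid[1]
  series$initial_source <- if (f == 1L) "first_frame" else
    sprintf("substituted_t%g", series$times[f])
  series$angles <- series$angles - series$angles[f]
  series$initial_subtracted <- TRUE
  series
}

#' Average tip-angle series by line
#'
#' Pointwise mean and SEM (`SD/sqrt(n)`) over the seedlings of each line,
#' with missing values excluded pairwise; lines with a single seedling
#' get `NA` SEM, lines with no series are dropped with a warning.
#'
#' @param series_list List of `tip_series` on a common time grid.
#' @param lines Optional character vector of line ids to retain.
#' @return `data.frame` of class `line_means` with columns `line`,
#'   `time`, `mean`, `sem`, `n`.
#' @export
average_by_line <- function(series_list, lines = NULL) {
  got <- vapply(series_list, function(s) s$line, character(1))
  lines <- lines %||% unique(got)
  empty <- setdiff(lines, got)
  if (length(empty) > 0) {
    warning("dropping line(s) with no series: ", paste(empty, collapse = ", "))
    lines <- setdiff(lines, empty)
  }
  times <- series_list[[1]]$times
  out <- do.call(rbind, lapply(lines, function(ln) {
    mat <- do.call(rbind, lapply(series_list[got == ln], `[[`, "angles"))
    n <- colSums(!is.na(mat))
    mu <- colMeans(mat, na.rm = TRUE)
    sdv <- apply(mat, 2, stats::sd, na.rm = TRUE)
    sem <- ifelse(n >= 2, sdv / sqrt(n), NA_real_)
    data.frame(line = ln, time = times, mean = ifelse(n > 0, mu, NA_real_),
               sem = sem, n = n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("line_means", "data.frame")
  out
}

#' Per-line mean matrix from line averages
#'
#' @param line_means Output of [average_by_line()].
#' @return Numeric matrix, lines x times (column names `t_<minutes>`).
#' @export
line_mean_matrix <- function(line_means) {
  lines <- unique(line_means$line)
  times <- sort(unique(line_means$time))
  mat <- matrix(NA_real_, length(lines), length(times),
                dimnames = list(lines, paste0("t_", times)))
  mat[cbind(match(line_means$line, lines),
            match(line_means$time, times))] <- line_means$mean
  mat
}

## letter display from a symmetric "significantly different" matrix:
## letters are the maximal cliques of the not-significantly-different
## graph, ordered by descending group mean
letters_from_pairs <- function(signif, means) {
  gnames <- rownames(signif)
  adj <- !signif
  diag(adj) <- TRUE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  cl <- igraph::max_cliques(g)
  cl_max <- vapply(cl, function(v) max(means[gnames[as.integer(v)]]),
                   numeric(1))
  cl <- cl[order(-cl_max)]
  lab <- vapply(gnames, function(gn) {
    hits <- which(vapply(cl, function(v) gn %in% gnames[as.integer(v)],
                         logical(1)))
    paste(letters[hits], collapse = "")
  }, character(1))
  lab
}

#' Compare genotype groups at selected time points
#'
#' One-way ANOVA with Tukey HSD letter groupings (the default) or an
#' equal-variance two-sample t test, applied independently at each
#' requested time point (no correction across time points).  When every
#' group has zero within-group variance the exact-tie convention is
#' used: p = 1 if all means are equal, otherwise p = 0.
#'
#' @param groups Named list of matrices (seedlings x times), one per
#'   genotype group; all on the same time grid.
#' @param times Time grid in minutes.
#' @param test_times Times at which to test (default: all).
#' @param alpha Significance level for the Tukey letters.
#' @param method `"anova_tukey"` or `"ttest"` (exactly two groups).
#' @return List of class `group_comparison`: `summary` (long data frame
#'   of per-group mean/SEM/n by time) and `tests` (per test time:
#'   statistic, p, and letter groupings for ANOVA).
#' @export
compare_groups <- function(groups, times, test_times = NULL, alpha = 0.1,
                           method = c("anova_tukey", "ttest")) {
  method <- match.arg(method)
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  ns <- vapply(groups, nrow, integer(1))
  if (any(ns < 2)) stop("each group needs n >= 2")
  if (method == "ttest" && length(groups) != 2)
    stop("ttest requires exactly 2 groups")
  test_times <- test_times %||% times
  ti <- match(test_times, times)
  if (anyNA(ti)) stop("test_times must lie on the time grid")

  summary <- do.call(rbind, lapply(names(groups), function(gn) {
    m <- groups[[gn]]
    n <- colSums(!is.na(m))
    data.frame(group = gn, time = times, mean = colMeans(m, na.rm = TRUE),
               sem = apply(m, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n, 1)),
               n = n, stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL

  tests <- lapply(seq_along(ti), function(k) {
    j <- ti[k]
    vals <- unlist(lapply(groups, function(m) m[, j]))
    grp <- factor(rep(names(groups), ns), levels = names(groups))
    keep <- !is.na(vals)
    vals <- vals[keep]; grp <- droplevels(grp[keep])
    means <- tapply(vals, grp, mean)
    wvar <- tapply(vals, grp, stats::var)
    if (all(wvar < 1e-24)) { # exact ties
      equal <- max(means) - min(means) < 1e-12
      p <- if (equal) 1 else 0
      sig <- outer(means, means, function(a, b) abs(a - b) > 1e-12)
      dimnames(sig) <- list(names(means), names(means))
      return(list(time = test_times[k], method = method,
                  statistic = if (equal) 0 else Inf, p = p,
                  letters = letters_from_pairs(sig, means)))
    }
    if (method == "ttest") {
      tt <- stats::t.test(vals ~ grp, var.equal = TRUE)
      list(time = test_times[k], method = method,
           statistic = unname(tt$statistic), p = tt$p.value, letters = NULL)
    } else {
      fit <- stats::aov(vals ~ grp)
      an <- summary(fit)[[1]]
      tuk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$grp
      gnames <- levels(grp)
      sig <- matrix(FALSE, length(gnames), length(gnames),
                    dimnames = list(gnames, gnames))
      prs <- strsplit(rownames(tuk), "-", fixed = TRUE)
      for (r in seq_along(prs)) {
        a <- prs[[r]][1]; b <- prs[[r]][2]
        sig[a, b] <- sig[b, a] <- tuk[r, "p adj"] < alpha
      }
      list(time = test_times[k], method = method,
           statistic = an[["F value"]][1], p = an[["Pr(>F)"]][1],
           letters = letters_from_pairs(sig, means))
    }
  })
  structure(list(summary = summary, tests = tests, alpha = alpha,
                 method = method), class = "group_comparison")
}
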