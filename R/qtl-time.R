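## Function-valued mapping: per-time-point tQTL maps (each time point an
## independent trait), per-parameter pQTL maps, linking of tQTL across
## consecutive time points into tracks, and tQTL <-> pQTL matching.

#' Map time-point QTL (tQTL)
#'
#' Runs a permutation threshold and a stepwise model independently for
#' every time point of a per-line angle matrix.  Time points with zero
#' variance (e.g. t = 0 after initial-angle subtraction) are excluded;
#' time points with more than 50% missing lines are skipped with a
#' warning.  The heatmap holds, at each (position, time), the
#' conditional LOD of a model QTL where it reaches that time's
#' threshold, 0 (rendered white) elsewhere.
#'
#' @param gp A `genoprob` object.
#' @param angles Lines x times matrix, rows aligned with the individuals
#'   of `gp`.
#' @param times Time grid, minutes.
#' @param n_perm Permutations per time point (>= 100).
#' @param alpha Genome-wide significance level per trait.
#' @param seed Base seed; time point `k` uses `seed + k`.
#' @param max_qtl Maximum QTL per time-point model.
#' @return List of class `tqtl_result`: `models` (per mapped time),
#'   `thresholds`, `heatmap` (positions x mapped times), `info`
#'   (position table), `times` (mapped times), `frame_min`.
#' @export
map_tqtl <- function(gp, angles, times, n_perm = 200, alpha = 0.05,
                     seed = 1, max_qtl = 6) {
  stopifnot(ncol(angles) == length(times))
  d <- dosage_matrix(gp)
  n <- nrow(d$X)
  if (nrow(angles) != n)
    stop("angle matrix rows must match genoprob individuals")
  usable <- logical(length(times))
  for (k in seq_along(times)) {
    y <- angles[, k]
    if (mean(is.na(y)) > 0.5) {
      warning(sprintf("time point %g min skipped: >50%% missing", times[k]))
    } else if (stats::sd(y, na.rm = TRUE) > 0) {
      usable[k] <- TRUE
    }
  }
  kept <- which(usable)
  models <- vector("list", length(kept))
  thresholds <- numeric(length(kept))
  hm <- matrix(0, nrow(d$info), length(kept))
  for (i in seq_along(kept)) {
    k <- kept[i]
    y <- angles[, k]
    thr <- permutation_threshold(gp, y, n_perm = n_perm, alpha = alpha,
                                 seed = if (is.null(seed)) NULL else seed + k)
    thresholds[i] <- as.numeric(thr)
    mod <- stepwise_qtl(gp, y, penalty = as.numeric(thr), max_qtl = max_qtl)
    models[[i]] <- mod
    if (nrow(mod$qtl) > 0) {
      for (j in seq_len(nrow(mod$qtl))) {
        prof <- mod$profiles[[j]]
        rows <- which(d$info$chr == mod$qtl$chr[j])
        vals <- prof$lod[match(d$info$pos[rows], prof$pos)]
        vals[is.na(vals) | vals < thresholds[i]] <- 0
        hm[rows, i] <- pmax(hm[rows, i], vals)
      }
    }
  }
  frame_min <- if (length(times) > 1) stats::median(diff(times)) else NA_real_
  structure(list(models = models, thresholds = thresholds, heatmap = hm,
                 info = d$info, times = times[kept], frame_min = frame_min),
            class = "tqtl_result")
}

#' Map curve-parameter QTL (pQTL)
#'
#' Runs a permutation threshold and a stepwise model for each response
#' parameter of a fitted-parameter table.
#'
#' @param gp A `genoprob` object.
#' @param params Parameter table from [fit_parameter_table()] (needs a
#'   `line` column naming individuals of `gp`).
#' @param traits Parameter columns to map.
#' @param n_perm,alpha,seed,max_qtl As in [map_tqtl()].
#' @return List of class `pqtl_result`: `models` (named by trait) and
#'   `thresholds`; all-missing traits are skipped.
#' @export
map_pqtl <- function(gp, params,
                     traits = c("lambda", "mu", "A", "P", "overshoot", "I"),
                     n_perm = 200, alpha = 0.05, seed = 1, max_qtl = 6) {
  ind <- attr(gp, "ind")
  traits <- intersect(traits, names(params))
  models <- list()
  thresholds <- numeric(0)
  for (i in seq_along(traits)) {
    tr <- traits[i]
    y <- params[[tr]][match(ind, params$line)]
    if (all(is.na(y))) {
      warning("trait ", tr, " skipped: all missing")
      next
    }
    thr <- permutation_threshold(gp, y, n_perm = n_perm, alpha = alpha,
                                 seed = if (is.null(seed)) NULL else seed + i)
    mod <- stepwise_qtl(gp, y, penalty = as.numeric(thr), max_qtl = max_qtl)
    models[[tr]] <- mod
    thresholds[tr] <- as.numeric(thr)
  }
  structure(list(models = models, thresholds = thresholds),
            class = "pqtl_result")
}

#' Link per-time QTL into tQTL tracks
#'
#' A track is a maximal run of consecutive mapped time points, each with
#' a significant QTL on the same chromosome whose peak lies within
#' `link_dist_cM` of the previous time point's peak.  Duration is the
#' run length times the frame interval; onset is the first time of the
#' run.
#'
#' @param tqtl A `tqtl_result` (or a list of `qtl_model`s plus `times`).
#' @param times Mapped time points (taken from `tqtl` if missing).
#' @param link_dist_cM Maximal peak drift between consecutive frames.
#' @param frame_min Frame interval in minutes (taken from `tqtl` if
#'   missing).
#' @return `data.frame` of class `tqtl_tracks` with `track`, `chr`,
#'   `onset`, `duration`, `n_frames`, `pos_lo`, `pos_hi`; attribute
#'   `peaks` holds a per-track `data.frame` of `(time, pos, lod)`.
#' @export
link_tqtl_over_time <- function(tqtl, times = NULL, link_dist_cM = 10,
                                frame_min = NULL) {
  if (inherits(tqtl, "tqtl_result")) {
    models <- tqtl$models
    times <- times %||% tqtl$times
    frame_min <- frame_min %||% tqtl$frame_min
  } else {
    models <- tqtl
  }
  if (is.null(frame_min))
    frame_min <- if (length(times) > 1) stats::median(diff(times)) else 1
  open <- list()   # active runs
  done <- list()
  for (k in seq_along(models)) {
    q <- models[[k]]$qtl
    peaks <- if (is.null(q)) data.frame(chr = character(), pos = numeric(),
                                        lod = numeric()) else q
    used_peak <- rep(FALSE, nrow(peaks))
    still <- list()
    for (tr in open) {
      cand <- which(!used_peak & peaks$chr == tr$chr &
                      abs(peaks$pos - tr$last_pos) <= link_dist_cM)
      if (length(cand) > 0) {
        j <- cand[which.min(abs(peaks$pos[cand] - tr$last_pos))]
        used_peak[j] <- TRUE
        tr$last_pos <- peaks$pos[j]
        tr$frames <- rbind(tr$frames,
                           data.frame(time = times[k], pos = peaks$pos[j],
                                      lod = peaks$lod[j]))
        still[[length(still) + 1]] <- tr
      } else {
        done[[length(done) + 1]] <- tr
      }
    }
    open <- still
    if (nrow(peaks) > 0) for (j in which(!used_peak)) {
      open[[length(open) + 1]] <- list(
        chr = peaks$chr[j], last_pos = peaks$pos[j],
        frames = data.frame(time = times[k], pos = peaks$pos[j],
                            lod = peaks$lod[j]))
    }
  }
  done <- c(done, open)
  if (length(done) == 0) {
    out <- data.frame(track = integer(), chr = character(),
                      onset = numeric(), duration = numeric(),
                      n_frames = integer(), pos_lo = numeric(),
                      pos_hi = numeric())
    attr(out, "peaks") <- list()
    class(out) <- c("tqtl_tracks", "data.frame")
    return(out)
  }
  out <- do.call(rbind, lapply(seq_along(done), function(i) {
    tr <- done[[i]]
    data.frame(track = i, chr = tr$chr, onset = tr$frames$time[1],
               duration = nrow(tr$frames) * frame_min,
               n_frames = nrow(tr$frames),
               pos_lo = min(tr$frames$pos), pos_hi = max(tr$frames$pos),
               stringsAsFactors = FALSE)
  }))
  attr(out, "peaks") <- lapply(done, `[[`, "frames")
  class(out) <- c("tqtl_tracks", "data.frame")
  out
}

#' Match tQTL tracks with pQTL
#'
#' A track matches a pQTL when both sit on the same chromosome and the
#' minimum distance between the track's per-frame peaks and the pQTL
#' peak is at most `match_dist_cM`.  Returns the matched and unmatched
#' track sets and the mean +/- SD duration of each class.
#'
#' @param tracks A `tqtl_tracks` object.
#' @param pqtl A `pqtl_result` (or named list of `qtl_model`s).
#' @param match_dist_cM Co-location distance in cM.
#' @return List of class `tqtl_match`: `matched`, `unmatched` (track
#'   data frames; `matched` gains a `params` column), `summary`
#'   (`data.frame` with `class`, `n`, `mean_duration`, `sd_duration`).
#' @export
match_tqtl_pqtl <- function(tracks, pqtl, match_dist_cM = 10) {
  models <- if (inherits(pqtl, "pqtl_result")) pqtl$models else pqtl
  ppk <- do.call(rbind, lapply(names(models), function(tr) {
    q <- models[[tr]]$qtl
    if (is.null(q) || nrow(q) == 0) return(NULL)
    data.frame(param = tr, chr = q$chr, pos = q$pos,
               stringsAsFactors = FALSE)
  }))
  peaks <- attr(tracks, "peaks")
  hit <- character(nrow(tracks))
  for (i in seq_len(nrow(tracks))) {
    if (is.null(ppk)) break
    cand <- ppk[ppk$chr == tracks$chr[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    ok <- vapply(seq_len(nrow(cand)), function(j)
      min(abs(peaks[[tracks$track[i]]]$pos - cand$pos[j])) <= match_dist_cM,
      logical(1))
    if (any(ok)) hit[i] <- paste(unique(cand$param[ok]), collapse = ",")
  }
  matched <- tracks[hit != "", , drop = FALSE]
  if (nrow(matched) > 0) matched$params <- hit[hit != ""]
  unmatched <- tracks[hit == "", , drop = FALSE]
  summ <- function(x) if (length(x) == 0) c(NA_real_, NA_real_) else
    c(mean(x), if (length(x) > 1) stats::sd(x) else NA_real_)
  sm <- rbind(summ(matched$duration), summ(unmatched$duration))
  summary <- data.frame(class = c("matched", "unmatched"),
                        n = c(nrow(matched), nrow(unmatched)),
                        mean_duration = sm[, 1], sd_duration = sm[, 2],
                        stringsAsFactors = FALSE)
  structure(list(matched = matched, unmatched = unmatched,
                 summary = summary), class = "tqtl_match")
}
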