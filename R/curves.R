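## Sigmoid response-curve fitting and extraction of the six mappable
## gravitropism parameters: lambda (lag, min), mu (maximal slope,
## deg/min), A (asymptotic angle, deg), P (spline peak angle, deg),
## overshoot P - A (deg) and I (integral of the fitted curve, deg*min).

sigmoid_start <- function(times, angles) {
  A0 <- max(angles)
  if (A0 <= 0) A0 <- max(abs(angles), 1)
  slopes <- diff(angles) / diff(times)
  ctr <- (slopes[-1] + slopes[-length(slopes)]) / 2
  i <- which.max(ctr) + 1L
  mu0 <- max(ctr, 1e-3)
  lam0 <- max(0, times[i] - angles[i] / mu0)
  c(A = A0, mu = mu0, lambda = lam0)
}

fit_sigmoid <- function(times, angles, model, restarts = 5) {
  if (length(times) < 6) stop("need at least 6 time points")
  if (stats::sd(angles) == 0) stop("constant series cannot be fitted")
  fun <- if (model == "logistic") logistic_curve else gompertz_curve
  start <- sigmoid_start(times, angles)
  best <- NULL
  for (k in 0:restarts) {
    st <- if (k == 0) start else
      start * exp(stats::rnorm(3, 0, 0.15))
    fit <- try(minpack.lm::nlsLM(
      angles ~ fun(times, A, mu, lambda),
      start = as.list(st),
      lower = c(A = 1e-8, mu = 1e-8, lambda = -Inf),
      control = minpack.lm::nls.lm.control(
        maxiter = 200, ftol = 1e-10, ptol = 1e-12)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$RSS) {
        cf <- stats::coef(fit)
        n <- length(times)
        best <- list(model = model, A = unname(cf["A"]),
                     mu = unname(cf["mu"]), lambda = unname(cf["lambda"]),
                     RSS = rss,
                     AIC = n * log(max(rss, 1e-300) / n) + 2 * 4,
                     converged = fit$convInfo$isConv %||% TRUE,
                     times = times)
        class(best) <- "sigmoid_fit"
      }
      if (best$converged) break
    }
  }
  if (is.null(best)) {
    best <- structure(list(model = model, A = unname(start["A"]),
                           mu = unname(start["mu"]),
                           lambda = unname(start["lambda"]),
                           RSS = Inf, AIC = Inf, converged = FALSE,
                           times = times), class = "sigmoid_fit")
  }
  best
}

#' Fit the logistic response model
#'
#' Nonlinear least squares on
#' `y = A / (1 + exp(4 mu (lambda - t)/A + 2))`, initialized from the
#' data maximum, the maximal central-difference slope and the implied
#' lag, with up to 5 jittered restarts on failure.
#'
#' @param times Time in minutes (>= 6 points).
#' @param angles Tip angles, degrees (non-constant).
#' @return A `sigmoid_fit`: `model`, `A`, `mu`, `lambda`, `RSS`, `AIC`,
#'   `converged`.
#' @export
fit_logistic <- function(times, angles) fit_sigmoid(times, angles, "logistic")

#' Fit the Gompertz response model
#'
#' As [fit_logistic()] but on `y = A exp(-exp(mu e (lambda - t)/A + 1))`.
#'
#' @inheritParams fit_logistic
#' @return A `sigmoid_fit`.
#' @export
fit_gompertz <- function(times, angles) fit_sigmoid(times, angles, "gompertz")

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf("%s fit: A = %.3f deg, mu = %.4f deg/min, lambda = %.3f min",
              x$model, x$A, x$mu, x$lambda),
      sprintf("(RSS %.4g%s)\n", x$RSS,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Select between the logistic and Gompertz fits
#'
#' The lower-AIC fit wins (both models have the same parameter count, so
#' this equals the lower-RSS rule); ties go to the logistic.  If only
#' one fit converged, it is selected; if neither did, `NULL` is returned
#' and the series should be flagged.
#'
#' @param logistic,gompertz `sigmoid_fit` objects.
#' @return The selected `sigmoid_fit`, or `NULL`.
#' @export
select_model <- function(logistic, gompertz) {
  lc <- isTRUE(logistic$converged)
  gc <- isTRUE(gompertz$converged)
  if (!lc && !gc) return(NULL)
  if (lc && !gc) return(logistic)
  if (gc && !lc) return(gompertz)
  if (logistic$AIC <= gompertz$AIC) logistic else gompertz
}

#' Smoothing-spline peak extraction
#'
#' Cubic smoothing spline with GCV-chosen smoothing, evaluated on a
#' 0.1-minute grid over the observation window; returns the peak angle
#' `P`, its time `t_P`, and the integral of the spline.
#'
#' @param times Time in minutes (>= 8 points).
#' @param angles Tip angles, degrees.
#' @return List with `P`, `t_P`, `I_spline`.
#' @export
fit_spline <- function(times, angles) {
  if (length(times) < 8) stop("need at least 8 time points")
  if (stats::sd(angles) == 0)
    return(list(P = angles[1], t_P = times[1],
                I_spline = angles[1] * diff(range(times))))
  sp <- stats::smooth.spline(times, angles, cv = FALSE)
  grid <- seq(min(times), max(times), by = 0.1)
  yy <- stats::predict(sp, grid)$y
  i <- which.max(yy)
  list(P = yy[i], t_P = grid[i], I_spline = pracma::trapz(grid, yy))
}

#' Extract the mappable response parameters
#'
#' Overshoot is `P - A` (left unclipped by default, as responses without
#' an overshoot give values near or slightly below zero); `I` is the
#' composite-trapezoid integral of the selected sigmoid on a 0.1-min
#' grid over the window.
#'
#' @param fit Selected `sigmoid_fit`.
#' @param spline Result of [fit_spline()].
#' @param window Integration window `c(lo, hi)` in minutes (defaults to
#'   the fit's observation window).
#' @param clip_overshoot Clip negative overshoot at zero?
#' @return One-row `data.frame`: `model`, `A`, `mu`, `lambda`, `P`,
#'   `t_P`, `overshoot`, `I`, `RSS`, `converged`.
#' @export
extract_parameters <- function(fit, spline, window = NULL,
                               clip_overshoot = FALSE) {
  if (is.null(fit)) stop("no converged fit to extract from")
  window <- window %||% range(fit$times)
  grid <- seq(window[1], window[2], by = 0.1)
  yy <- sigmoid_curve(grid, fit$A, fit$mu, fit$lambda, fit$model)
  ov <- spline$P - fit$A
  if (clip_overshoot) ov <- max(0, ov)
  data.frame(model = fit$model, A = fit$A, mu = fit$mu,
             lambda = fit$lambda, P = spline$P, t_P = spline$t_P,
             overshoot = ov, I = pracma::trapz(grid, yy),
             RSS = fit$RSS, converged = fit$converged,
             stringsAsFactors = FALSE)
}

#' Fit one mean response curve end to end
#'
#' Fits both sigmoids, selects by AIC, runs the spline peak extraction
#' and returns the parameter row; `NULL` if neither model converged.
#'
#' @inheritParams fit_logistic
#' @param window Optional integration window.
#' @return One-row `data.frame` as in [extract_parameters()], or `NULL`.
#' @export
fit_response <- function(times, angles, window = NULL) {
  fl <- try(fit_logistic(times, angles), silent = TRUE)
  fg <- try(fit_gompertz(times, angles), silent = TRUE)
  if (inherits(fl, "try-error") && inherits(fg, "try-error")) return(NULL)
  sel <- select_model(
    if (inherits(fl, "try-error")) list(converged = FALSE) else fl,
    if (inherits(fg, "try-error")) list(converged = FALSE) else fg)
  if (is.null(sel)) return(NULL)
  extract_parameters(sel, fit_spline(times, angles), window = window)
}

#' Fit response parameters for every line of an angle matrix
#'
#' @param angles Matrix, lines x times (rownames = line ids).
#' @param times Time grid, minutes.
#' @param window Optional integration window.
#' @return `data.frame` with a `line` column followed by the parameter
#'   columns of [extract_parameters()]; lines whose fits both failed are
#'   dropped with a warning.
#' @export
fit_parameter_table <- function(angles, times, window = NULL) {
  rows <- lapply(rownames(angles) %||% as.character(seq_len(nrow(angles))),
                 function(ln) {
    i <- if (is.null(rownames(angles))) as.integer(ln) else ln
    p <- fit_response(times, angles[i, ], window = window)
    if (is.null(p)) return(NULL)
    cbind(data.frame(line = ln, stringsAsFactors = FALSE), p)
  })
  failed <- vapply(rows, is.null, logical(1))
  if (any(failed))
    warning(sum(failed), " line(s) dropped: no converged fit")
  out <- do.call(rbind, rows[!failed])
  rownames(out) <- NULL
  out
}
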