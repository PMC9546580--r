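## Synthetic tip-angle trajectories with additive QTL effects on the
## parameters of a sigmoid gravitropic response.

#' Logistic and Gompertz response curves
#'
#' Sigmoid forms parameterized by the asymptote `A` (deg), the maximal
#' slope `mu` (deg/min) and the lag time `lambda` (min):
#' logistic `y = A / (1 + exp(4 mu (lambda - t)/A + 2))`,
#' Gompertz `y = A exp(-exp(mu e (lambda - t)/A + 1))`.
#'
#' @param t Time in minutes (vectorized).
#' @param A,mu,lambda Curve parameters.
#' @return Tip angle in degrees.
#' @export
logistic_curve <- function(t, A, mu, lambda) {
  A / (1 + exp(4 * mu * (lambda - t) / A + 2))
}

#' @rdname logistic_curve
#' @export
gompertz_curve <- function(t, A, mu, lambda) {
  A * exp(-exp(mu * exp(1) * (lambda - t) / A + 1))
}

sigmoid_curve <- function(t, A, mu, lambda, model = c("logistic", "gompertz")) {
  model <- match.arg(model)
  if (model == "logistic") logistic_curve(t, A, mu, lambda)
  else gompertz_curve(t, A, mu, lambda)
}

SIM_PARAMS <- c("lambda", "mu", "A", "overshoot")

#' Define a phenotype-simulation scenario
#'
#' Bundles the generative conditions for [simulate_phenotypes()]: a
#' baseline sigmoid, additive QTL effects acting on curve parameters
#' (genotypes coded -1/2, +1/2, so an "effect" is the between-homozygote
#' difference in parameter units), between-line parameter noise and
#' per-time-point observation noise.  The default time grid is the
#' 3-minute / 3-hour maize protocol (61 points).
#'
#' @param qtl_effects `data.frame` with columns `chr`, `pos` (cM),
#'   `param` (one of `"lambda"`, `"mu"`, `"A"`, `"overshoot"`), `effect`.
#' @param baseline Named list: `A` (deg), `mu` (deg/min), `lambda` (min),
#'   `model` (`"logistic"` or `"gompertz"`).
#' @param overshoot_amp Baseline overshoot-bump amplitude, deg.
#' @param line_sd Named per-parameter between-line SDs.
#' @param obs_sd Observation noise SD, deg per time point.
#' @param times Observation times, minutes.
#' @param seed Optional integer seed used by [simulate_phenotypes()].
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(qtl_effects = NULL,
                         baseline = list(A = 60, mu = 0.7, lambda = 20,
                                         model = "logistic"),
                         overshoot_amp = 0,
                         line_sd = c(lambda = 3, mu = 0.07, A = 6,
                                     overshoot = 0.5),
                         obs_sd = 3,
                         times = seq(0, 180, by = 3),
                         seed = NULL) {
  if (is.null(qtl_effects))
    qtl_effects <- data.frame(chr = character(), pos = numeric(),
                              param = character(), effect = numeric())
  stopifnot(all(c("chr", "pos", "param", "effect") %in% names(qtl_effects)))
  if (!all(qtl_effects$param %in% SIM_PARAMS))
    stop("QTL effects must target one of: ",
         paste(SIM_PARAMS, collapse = ", "))
  if (obs_sd < 0) stop("obs_sd must be >= 0")
  ls <- c(lambda = 0, mu = 0, A = 0, overshoot = 0)
  ls[names(line_sd)] <- line_sd
  if (any(ls < 0)) stop("line_sd must be >= 0")
  structure(list(qtl_effects = qtl_effects, baseline = baseline,
                 overshoot_amp = overshoot_amp, line_sd = ls,
                 obs_sd = obs_sd, times = times, seed = seed),
            class = "sim_scenario")
}

## nearest marker on the requested chromosome
nearest_marker_idx <- function(map, chr, pos) {
  idx <- which(map$chr == as.character(chr))
  if (length(idx) == 0L)
    stop(sprintf("QTL chromosome '%s' not on the map", chr))
  span <- range(map$pos[idx])
  if (pos < span[1] || pos > span[2])
    stop(sprintf("QTL position %.1f cM lies off chromosome %s", pos, chr))
  idx[which.min(abs(map$pos[idx] - pos))]
}

#' Simulate tip-angle time courses carrying QTL effects
#'
#' Per-line curve parameters are `baseline + sum(effect_j * x_j) + noise`
#' with `x_j` the -1/2 / +1/2 coding of the true genotype at the marker
#' nearest each planted QTL.  The trajectory is the baseline sigmoid plus,
#' when the line's overshoot parameter is non-zero, a Gaussian bump of
#' that amplitude centered at `lambda + A/mu` with SD `A/(2 mu)` minutes,
#' plus N(0, obs_sd^2) observation noise.
#'
#' @param cross A `ril_cross` (needs `true_geno` or complete `geno`).
#' @param scenario A [sim_scenario()].
#' @return List of class `sim_phenotypes`: `angles` (lines x times matrix),
#'   `times`, and `truth` (per-line parameters, planted QTL with the
#'   marker actually used, and the scenario).
#' @export
simulate_phenotypes <- function(cross, scenario) {
  stopifnot(inherits(cross, "ril_cross"), inherits(scenario, "sim_scenario"))
  if (!is.null(scenario$seed)) set.seed(scenario$seed)
  g <- cross$true_geno %||% cross$geno
  n <- nrow(g)
  times <- scenario$times
  bl <- scenario$baseline

  theta <- cbind(
    lambda = rep(bl$lambda, n), mu = rep(bl$mu, n), A = rep(bl$A, n),
    overshoot = rep(scenario$overshoot_amp, n))
  qe <- scenario$qtl_effects
  qe$marker <- rep(NA_character_, nrow(qe))
  if (nrow(qe) > 0) {
    for (j in seq_len(nrow(qe))) {
      mi <- nearest_marker_idx(cross$map, qe$chr[j], qe$pos[j])
      qe$marker[j] <- cross$map$marker[mi]
      x <- ifelse(is.na(g[, mi]), 0, ifelse(g[, mi] == 1L, -0.5, 0.5))
      theta[, qe$param[j]] <- theta[, qe$param[j]] + qe$effect[j] * x
    }
  }
  for (p in SIM_PARAMS) {
    sd_p <- scenario$line_sd[[p]]
    if (sd_p > 0) theta[, p] <- theta[, p] + stats::rnorm(n, 0, sd_p)
  }
  ## keep curve parameters physical
  theta[, "A"] <- pmax(theta[, "A"], 1e-6)
  theta[, "mu"] <- pmax(theta[, "mu"], 1e-6)

  angles <- matrix(0, n, length(times),
                   dimnames = list(rownames(g), paste0("t_", times)))
  for (i in seq_len(n)) {
    y <- sigmoid_curve(times, theta[i, "A"], theta[i, "mu"],
                       theta[i, "lambda"], bl$model)
    os <- theta[i, "overshoot"]
    if (os != 0) {
      ctr <- theta[i, "lambda"] + theta[i, "A"] / theta[i, "mu"]
      wid <- theta[i, "A"] / (2 * theta[i, "mu"])
      y <- y + os * exp(-(times - ctr)^2 / (2 * wid^2))
    }
    angles[i, ] <- y
  }
  if (scenario$obs_sd > 0)
    angles <- angles + matrix(stats::rnorm(length(angles), 0, scenario$obs_sd),
                              nrow = n)
  truth <- list(
    params = data.frame(line = rownames(g), theta,
                        stringsAsFactors = FALSE, row.names = NULL),
    qtl = qe, times = times, scenario = scenario)
  structure(list(angles = angles, times = times, truth = truth),
            class = "sim_phenotypes")
}
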