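## Synthetic backlit root images: a bright, thick, smoothly bending root
## attached to a seed blob on a dark background, with known tip angle per
## frame.  The angle convention is the one used throughout the package:
## 0 deg = horizontal (image x axis), 90 deg = straight down.

#' Simulate a stack of root images with known tip angles
#'
#' Draws, for each requested tip angle, a root of constant arc length
#' whose tangent direction turns linearly from `start_angle` at the seed
#' to the target tip angle at the tip, so the stored truth is the drawn
#' terminal tangent.  A bright elliptical seed blob sits at the top of
#' the frame; optional additive Gaussian noise is applied per pixel.
#'
#' @param angles_deg True tip angle per frame (degrees; 90 = down).
#' @param px_per_mm Image resolution, pixels per millimeter.
#' @param width_px Root width in pixels (> 1).
#' @param noise_sd Additive Gaussian noise SD (image intensities are 0/1).
#' @param dims Image `c(rows, cols)`.
#' @param root_len_mm Root arc length in millimeters.
#' @param start_angle Tangent at the seed end, degrees.
#' @param seed Optional integer seed (noise only).
#' @return List of class `sim_images`: `frames` (list of numeric
#'   matrices), `truth` (`data.frame` with `frame`, `angle`), and the
#'   geometry parameters.
#' @export
simulate_root_image_series <- function(angles_deg, px_per_mm = 10,
                                       width_px = 5, noise_sd = 0,
                                       dims = c(220, 220),
                                       root_len_mm = 10,
                                       start_angle = 90, seed = NULL) {
  if (width_px <= 1) stop("width_px must be > 1")
  if (!is.null(seed)) set.seed(seed)
  L <- root_len_mm * px_per_mm
  step <- 0.5
  s <- seq(0, L, by = step)
  seed_xy <- c(x = dims[2] / 2, y = 18)

  rad <- width_px / 2
  dd <- seq(-ceiling(rad), ceiling(rad))
  disk <- expand.grid(dy = dd, dx = dd)
  disk <- disk[disk$dx^2 + disk$dy^2 <= rad^2, ]

  frames <- vector("list", length(angles_deg))
  for (f in seq_along(angles_deg)) {
    th <- start_angle + (angles_deg[f] - start_angle) * s / L
    thr <- th * pi / 180
    ## y grows downward, so angle 90 points down the image
    x <- seed_xy["x"] + c(0, cumsum(cos(thr[-1]) * step))
    y <- seed_xy["y"] + c(0, cumsum(sin(thr[-1]) * step))
    img <- matrix(0, dims[1], dims[2])
    rows <- round(rep(y, each = nrow(disk)) + disk$dy)
    cols <- round(rep(x, each = nrow(disk)) + disk$dx)
    ok <- rows >= 1 & rows <= dims[1] & cols >= 1 & cols <= dims[2]
    img[cbind(rows[ok], cols[ok])] <- 1
    ## seed blob: ellipse above the root origin
    er <- 9; ec <- 6
    br <- seq(-er, er); bc <- seq(-ec, ec)
    blob <- expand.grid(dy = br, dx = bc)
    blob <- blob[(blob$dy / er)^2 + (blob$dx / ec)^2 <= 1, ]
    rows <- round(seed_xy["y"] - 6 + blob$dy)
    cols <- round(seed_xy["x"] + blob$dx)
    ok <- rows >= 1 & rows <= dims[1] & cols >= 1 & cols <= dims[2]
    img[cbind(rows[ok], cols[ok])] <- 1
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          nrow = dims[1])
    frames[[f]] <- img
  }
  structure(list(frames = frames,
                 truth = data.frame(frame = seq_along(angles_deg),
                                    angle = angles_deg),
                 px_per_mm = px_per_mm, width_px = width_px,
                 dims = dims, start_angle = start_angle),
            class = "sim_images")
}

#' Write an image stack as PNG files
#'
#' @param sim A `sim_images` object (or list of matrices).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Character vector of file paths.
#' @export
write_image_stack <- function(sim, dir, prefix = "frame") {
  frames <- if (inherits(sim, "sim_images")) sim$frames else sim
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vapply(seq_along(frames), function(i) {
    path <- file.path(dir, sprintf("%s_%03d.png", prefix, i))
    img <- pmin(pmax(frames[[i]], 0), 1)
    EBImage::writeImage(EBImage::Image(t(img)), path)
    path
  }, character(1))
}

#' Read an image stack from PNG/TIFF files
#'
#' @param paths Image file paths, in frame order.
#' @return List of numeric matrices (rows = image rows).
#' @export
read_image_stack <- function(paths) {
  lapply(paths, function(p) {
    img <- EBImage::imageData(EBImage::readImage(p))
    if (length(dim(img)) > 2) img <- img[, , 1]
    t(img)
  })
}
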