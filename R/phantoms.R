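# Reference phantoms for simulation studies.
#
# Two models, both deliberately susceptible to the missing wedge (long edges
# perpendicular to the 0-degree beam): a binary doughnut + bar, and a
# grey-gradient model (thick doughnut, rectangle with an internal dark-to-
# bright gradient, small punched holes and cone-shaped bumps, peak grey 255).
# Shape coordinates are a frozen package convention, expressed as fractions
# of the grid side; all structures lie inside the inscribed circle so that no
# projection mass leaves the detector at any tilt. Shapes are rasterised with
# 4x4 subpixel area sampling so steep edges span about one pixel.

subgrid_coords <- function(n, oversample = 4L) {
  nn <- n * oversample
  u <- (seq_len(nn) - 0.5) / nn - 0.5   # in [-0.5, 0.5], unit = grid side
  list(x = matrix(u, nn, nn, byrow = TRUE), z = matrix(u, nn, nn), nn = nn)
}

downsample_mean <- function(big, n, oversample = 4L) {
  # average oversample x oversample blocks
  arr <- array(big, dim = c(oversample, n, oversample, n))
  out <- apply(arr, c(2, 4), sum) / oversample^2
  matrix(out, n, n)
}

#' Binary doughnut + bar phantom
#'
#' A binary (0/1) cross-section model of an annulus and a horizontal bar.
#' The long horizontal edges are perpendicular to the 0-degree beam, so
#' limited-tilt reconstructions of this model show clear missing-wedge blur.
#' Deterministic for a fixed grid size.
#'
#' @param n grid side in pixels (>= 16).
#' @param oversample subpixel sampling factor; edge pixels are resolved by
#'   majority subpixel coverage so the result stays strictly binary.
#' @return `n` x `n` numeric matrix with values exactly 0 or 1.
#' @export
phantom_binary <- function(n = 512L, oversample = 4L) {
  n <- as.integer(n)
  if (n < 16L) stop("n must be >= 16")
  g <- subgrid_coords(n, oversample)
  r <- sqrt((g$x + 0.17)^2 + (g$z + 0.08)^2)
  annulus <- r <= 0.21 & r >= 0.115
  bar <- g$x >= -0.02 & g$x <= 0.36 & g$z >= 0.16 & g$z <= 0.245
  cov <- downsample_mean((annulus | bar) * 1.0, n, oversample)
  # binarise on majority subpixel coverage: the model is strictly 0/1
  (cov >= 0.5) * 1.0
}

#' General grey-gradient phantom
#'
#' A grey-level cross-section model: a thick annulus with a smooth radial
#' grey gradient, a tall rectangle whose interior changes monotonically from
#' dark to bright along z, three punched circular holes (grey 0) and two
#' cone-shaped linear radial ramps. Edges are steep (about one pixel); the
#' interior gradients are smooth; the maximum grey level is exactly
#' `max_grey`.
#'
#' @param n grid side in pixels (>= 16).
#' @param max_grey peak grey value (default 255).
#' @param oversample subpixel sampling factor for edge anti-aliasing.
#' @return `n` x `n` numeric matrix with values in \[0, `max_grey`\].
#' @export
phantom_general <- function(n = 512L, max_grey = 255, oversample = 4L) {
  n <- as.integer(n)
  if (n < 16L) stop("n must be >= 16")
  if (max_grey < 1) stop("max_grey must be >= 1")
  g <- subgrid_coords(n, oversample)
  img <- matrix(0, g$nn, g$nn)

  # thick doughnut, radial grey gradient 140 -> 230 from inner to outer edge
  cx <- -0.175; cz <- -0.02
  r <- sqrt((g$x - cx)^2 + (g$z - cz)^2)
  ring <- r <= 0.265 & r >= 0.10
  grad <- 140 + 90 * (r - 0.10) / (0.265 - 0.10)
  img[ring] <- grad[ring]

  # rectangle, interior grey rises monotonically from dark (bottom) to bright
  rect <- g$x >= 0.13 & g$x <= 0.385 & g$z >= -0.30 & g$z <= 0.27
  rgrad <- 60 + 195 * (0.27 - g$z) / 0.57   # bright at low z (top)
  img[rect] <- rgrad[rect]

  # small punched holes (grey 0)
  holes <- cbind(c(-0.175, -0.08, 0.30), c(-0.255, 0.10, -0.17),
                 c(0.022, 0.016, 0.028))
  for (i in seq_len(nrow(holes))) {
    d <- sqrt((g$x - holes[i, 1])^2 + (g$z - holes[i, 2])^2)
    img[d <= holes[i, 3]] <- 0
  }

  # cones: linear radial ramps peaking at their centres, in free space
  cones <- cbind(c(0.05, -0.02), c(0.38, -0.40), c(0.075, 0.06), c(235, 210))
  for (i in seq_len(nrow(cones))) {
    d <- sqrt((g$x - cones[i, 1])^2 + (g$z - cones[i, 2])^2)
    cone <- pmax(0, 1 - d / cones[i, 3]) * cones[i, 4]
    img <- pmax(img, cone)
  }

  out <- downsample_mean(img, n, oversample)
  out * (max_grey / max(out))
}

#' Reference phantom by name
#'
#' @param kind `"binary"` (doughnut + bar, values 0/1) or `"general"`
#'   (grey-gradient model, peak 255).
#' @param n grid side in pixels.
#' @param max_grey peak grey for the general model.
#' @return square numeric matrix.
#' @export
phantom <- function(kind = c("binary", "general"), n = 512L, max_grey = 255) {
  kind <- match.arg(kind)
  switch(kind,
         binary = phantom_binary(n),
         general = phantom_general(n, max_grey))
}
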