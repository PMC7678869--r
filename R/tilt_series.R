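# Tilt series container: per-angle 1D projections of one cross-section.

#' Tilt series of 1D projections
#'
#' @param projections numeric matrix, one column per angle (`detector_bins`
#'   rows), or a list of equal-length vectors.
#' @param angles tilt angles in degrees (numeric vector or `tilt_geometry`).
#' @return an object of class `tilt_series` with elements `projections`
#'   (bins x angles matrix), `angles` and `n` (detector bins).
#' @export
tilt_series <- function(projections, angles) {
  if (inherits(angles, "tilt_geometry")) angles <- angles$angles
  if (is.list(projections)) projections <- do.call(cbind, projections)
  projections <- as.matrix(projections)
  storage.mode(projections) <- "double"
  geom <- tilt_geometry(angles, nrow(projections))
  if (ncol(projections) != length(geom$angles)) {
    stop("one projection per angle is required")
  }
  structure(list(projections = projections, angles = geom$angles,
                 n = geom$detector_bins),
            class = "tilt_series")
}

#' @export
print.tilt_series <- function(x, ...) {
  cat(sprintf(paste0("Tilt series: %d projections of %d bins, ",
                     "angles %g..%g deg (step ~%g)\n"),
              length(x$angles), x$n, min(x$angles), max(x$angles),
              stats::median(diff(x$angles))))
  cat(sprintf("  total intensity per projection: %.6g (median)\n",
              stats::median(colSums(x$projections))))
  invisible(x)
}

#' Simulate a tilt series from a cross-section model
#'
#' Forward-projects the model at every angle; optionally corrupts each bin
#' with shot noise: a Poisson draw with mean `scale * p`, divided by `scale`
#' (so `scale` plays the role of incident dose per unit intensity).
#'
#' @param model square non-negative numeric matrix.
#' @param angles tilt angles in degrees (numeric vector or `tilt_geometry`).
#' @param noise `"none"` or `"poisson"`.
#' @param scale Poisson dose factor (counts per intensity unit).
#' @param seed optional integer seed; the caller's RNG state is restored.
#' @return a [tilt_series()].
#' @export
simulate_tilt_series <- function(model, angles,
                                 noise = c("none", "poisson"),
                                 scale = 1e4, seed = NULL) {
  check_image(model)
  if (any(model < 0)) stop("model must be non-negative")
  noise <- match.arg(noise)
  p <- forward_project(model, angles, drop = FALSE)
  if (noise == "poisson") {
    if (scale <= 0) stop("poisson scale must be positive")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) {
        get(".Random.seed", globalenv())
      }
      on.exit({
        if (!is.null(old)) assign(".Random.seed", old, globalenv())
      }, add = TRUE)
      set.seed(seed)
    }
    p[] <- rpois(length(p), lambda = scale * p) / scale
  }
  tilt_series(p, angles)
}
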