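# Tilt geometry and the forward/back projector pair.
#
# Conventions: a cross-section image is a square numeric matrix with
# image[row, col] = f(x = col, z = row); theta = 0 degrees projects along z
# (so the 0-degree projection is the column sums), positive theta rotates
# counter-clockwise, and the detector has one bin per pixel column.

#' Tilt geometry for a single-axis tilt series
#'
#' @param angles numeric vector of tilt angles in degrees, strictly
#'   increasing, each in (-90, 90] (and -90 itself is allowed).
#' @param detector_bins number of detector samples per projection; equals the
#'   reconstruction grid side.
#' @return an object of class `tilt_geometry`.
#' @examples
#' tilt_geometry(seq(-70, 70, by = 2), 128)
#' @export
tilt_geometry <- function(angles, detector_bins) {
  angles <- as.numeric(angles)
  if (length(angles) < 1L || anyNA(angles)) {
    stop("at least one finite tilt angle is required")
  }
  if (any(diff(angles) <= 0)) {
    stop("tilt angles must be strictly increasing (no duplicates)")
  }
  if (any(angles > 90 | angles < -90)) {
    stop("tilt angles must lie in [-90, 90] degrees")
  }
  detector_bins <- as.integer(detector_bins)
  if (detector_bins < 1L) stop("detector_bins must be >= 1")
  structure(list(angles = angles, detector_bins = detector_bins),
            class = "tilt_geometry")
}

#' @export
print.tilt_geometry <- function(x, ...) {
  cat(sprintf("Tilt geometry: %d angles in [%g, %g] deg, %d detector bins\n",
              length(x$angles), min(x$angles), max(x$angles), x$detector_bins))
  invisible(x)
}

#' Tilt angle grid
#'
#' Convenience constructor for symmetric tilt schemes such as
#' `tilt_angles(70, 2)` (the +/-70 degree, 2 degree step scheme with 71
#' projections).
#'
#' @param max_tilt half-range in degrees.
#' @param step angular step in degrees.
#' @return numeric vector of angles from `-max_tilt` to `max_tilt`.
#' @export
tilt_angles <- function(max_tilt, step) {
  seq(-max_tilt, max_tilt, by = step)
}

check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("image must be a numeric matrix")
  }
  if (nrow(image) != ncol(image)) stop("image must be square")
  invisible(image)
}

#' Forward projection (line integrals) of a cross-section image
#'
#' Exact strip-integral projector: each pixel's square footprint is projected
#' onto the detector as a trapezoid and integrated per bin in closed form.
#' Mass is conserved exactly for objects contained in the inscribed circle of
#' the grid (the standard field-of-view assumption; parts of an object
#' projecting outside the detector are lost, as in the physical experiment).
#'
#' @param image square numeric matrix.
#' @param angles tilt angles in degrees (numeric vector or `tilt_geometry`).
#' @param drop if `TRUE` (default) a single-angle result is returned as a
#'   vector rather than a one-column matrix.
#' @return matrix with one detector column per angle (`detector_bins` rows).
#' @examples
#' forward_project(rbind(c(1, 0), c(2, 3)), 0)  # column sums: 3 3
#' @export
forward_project <- function(image, angles, drop = TRUE) {
  check_image(image)
  if (inherits(angles, "tilt_geometry")) angles <- angles$angles
  angles <- as.numeric(angles)
  if (any(abs(angles) > 90)) stop("angles must lie in [-90, 90] degrees")
  out <- cpp_fp(image, angles)
  if (drop && length(angles) == 1L) out[, 1L] else out
}

#' Simple (unfiltered) back projection
#'
#' The exact transpose of [forward_project()], normalised by the number of
#' angles, i.e. filtered back projection without the filter. This is the
#' `BP[]` operator used to turn projection residuals into the QURT error map.
#'
#' @param residuals matrix with one column per angle (or a vector for a
#'   single angle), `detector_bins` values per column.
#' @param angles tilt angles in degrees (numeric vector or `tilt_geometry`).
#' @return square numeric matrix of side `detector_bins`.
#' @export
back_project <- function(residuals, angles) {
  if (inherits(angles, "tilt_geometry")) angles <- angles$angles
  angles <- as.numeric(angles)
  if (is.null(dim(residuals))) residuals <- matrix(residuals, ncol = 1L)
  if (ncol(residuals) != length(angles)) {
    stop("need exactly one residual column per angle")
  }
  cpp_bp(residuals, angles)
}

#' Detector column of every pixel under a base tilt angle
#'
#' Assigns each pixel to the detector bin its centre falls into after
#' rotation by the base angle; this is the x'_j column used for the per-column
#' QU budgets. Every pixel maps to exactly one column.
#'
#' @param n grid side in pixels.
#' @param base_angle base tilt angle Theta in degrees.
#' @return integer matrix (same layout as the image) of 1-based column ids.
#' @export
column_index <- function(n, base_angle) {
  n <- as.integer(n)
  if (n < 1L) stop("n must be >= 1")
  if (abs(base_angle) > 90) stop("base angle must lie in [-90, 90] degrees")
  cpp_colindex(n, as.numeric(base_angle)) + 1L
}
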