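# The QURT error map: simple back projection of the projection residuals.

#' Error map of a candidate reconstruction
#'
#' Computes the per-angle residuals `E_theta(x') = FP[g](x') - p_theta(x')`
#' and the error map `E_map(x,z) = BP[E_theta]`, the simple back projection
#' of the residuals. Negative map values mark a deficiency of QU pieces at
#' that pixel, positive values an excess; a reconstruction reproducing every
#' projection has an identically zero map.
#'
#' @param g current reconstructed image (square numeric matrix).
#' @param series the measured [tilt_series()].
#' @return object of class `error_map`: list with `emap` (image grid),
#'   `resid` (bins x angles) and `angles`.
#' @export
error_map <- function(g, series) {
  stopifnot(inherits(series, "tilt_series"))
  check_image(g)
  if (nrow(g) != series$n) stop("image and series geometry differ")
  resid <- forward_project(g, series$angles, drop = FALSE) - series$projections
  structure(list(emap = back_project(resid, series$angles),
                 resid = resid, angles = series$angles),
            class = "error_map")
}

#' Incrementally update an error map after a local change
#'
#' Applies the residual and map change caused by adding `delta` grey units
#' over a square block of the reconstruction, touching only the detector
#' bins and rays crossing the block (cost proportional to the ray footprint,
#' not the full grid). Equivalent to recomputing [error_map()] after the
#' change.
#'
#' @param em an [error_map()].
#' @param x,z 1-based pixel coordinates of the block corner (x = column,
#'   z = row).
#' @param size block side length in pixels (the QU piece size).
#' @param delta signed grey-level change (e.g. `+q` when placing a piece).
#' @return the updated `error_map`.
#' @export
update_error_map <- function(em, x, z, size, delta) {
  stopifnot(inherits(em, "error_map"))
  n <- nrow(em$emap)
  x <- as.integer(x); z <- as.integer(z); size <- as.integer(size)
  if (x < 1L || z < 1L || x + size - 1L > n || z + size - 1L > n) {
    stop("block out of bounds")
  }
  upd <- cpp_emap_update(em$resid, em$emap, em$angles,
                         x - 1L, z - 1L, size, delta)
  em$resid <- upd$resid
  em$emap <- upd$emap
  em
}

#' @export
print.error_map <- function(x, ...) {
  cat(sprintf("Error map %dx%d: range [%.4g, %.4g], residual RSS %.6g\n",
              nrow(x$emap), ncol(x$emap), min(x$emap), max(x$emap),
              sum(x$resid^2)))
  invisible(x)
}
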