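# S3 methods shared by the reconstruction objects (qurt, sirt, fbp).

#' @export
fitted.tomo2d <- function(object, ...) object$reconstruction

#' Reconstructed image of a fit
#' @param object a `tomo2d` reconstruction object.
#' @param ... unused.
#' @return the reconstructed cross-section (square numeric matrix).
#' @export
reconstruction <- function(object, ...) UseMethod("reconstruction")

#' @export
reconstruction.tomo2d <- function(object, ...) object$reconstruction

#' @export
residuals.tomo2d <- function(object, ...) {
  forward_project(object$reconstruction, object$series$angles, drop = FALSE) -
    object$series$projections
}

#' @export
predict.tomo2d <- function(object, angles = NULL, ...) {
  if (is.null(angles)) angles <- object$series$angles
  forward_project(object$reconstruction, angles, drop = FALSE)
}

#' @export
print.tomo2d <- function(x, ...) {
  r <- residuals(x)
  cat(sprintf("%s reconstruction, %dx%d pixels from %d projections\n",
              toupper(x$method), nrow(x$reconstruction),
              ncol(x$reconstruction), length(x$series$angles)))
  cat(sprintf("  grey range [%.4g, %.4g], residual norm %.6g\n",
              min(x$reconstruction), max(x$reconstruction), sqrt(sum(r^2))))
  invisible(x)
}

#' @export
summary.qurt <- function(object, ...) {
  out <- list(fit = object, accounting = qu_accounting(object),
              residual_norm = sqrt(sum(residuals(object)^2)))
  class(out) <- "summary.qurt"
  out
}

#' @export
print.summary.qurt <- function(x, ...) {
  print(x$fit)
  cat("\nQU accounting per level:\n")
  print(x$accounting, row.names = FALSE)
  invisible(x)
}

#' @export
plot.tomo2d <- function(x, main = NULL, ...) {
  img <- x$reconstruction
  if (is.null(main)) main <- paste(toupper(x$method), "reconstruction")
  # image() draws columns left-right, rows bottom-up; transpose so x runs
  # horizontally and z vertically (top row of the matrix at the top)
  graphics::image(t(img[nrow(img):1, ]), col = grDevices::gray(seq(0, 1, length.out = 256)),
                  axes = FALSE, asp = 1, main = main, ...)
  invisible(x)
}

#' Change-rate convergence test between reconstruction snapshots
#'
#' Returns `TRUE` when the mean absolute change between two snapshots taken
#' `check_interval` iterations apart, relative to the current mean intensity,
#' falls below `tol` (default 1e-6), the stopping rule of the refinement
#' stage.
#'
#' @param g_now,g_prev current and previous reconstruction snapshots.
#' @param tol change-rate threshold.
#' @return logical.
#' @export
qu_converged <- function(g_now, g_prev, tol = 1e-6) {
  if (is.null(g_now) || is.null(g_prev)) stop("two snapshots are required")
  if (!all(dim(g_now) == dim(g_prev))) stop("snapshot sizes differ")
  m <- mean(g_now)
  if (m <= 0) return(all(g_now == g_prev))
  mean(abs(g_now - g_prev)) / m < tol
}
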