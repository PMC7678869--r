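# Projection-integral constraint system.
#
# The projection integral of a cross-section is the same for every tilt
# angle (in the ideal, fully-in-view case), so the total grey mass N*q and
# its per-column split n_Theta(x'_j) at a chosen base angle constrain how
# many quantisation units the reconstruction may use and where.

#' Check the projection-integral invariance across angles
#'
#' Diagnostic for the constancy of the projection sums: every projection of
#' the same object should integrate to the same total. Reports each angle's
#' sum and its relative deviation from the median sum, flagging angles whose
#' deviation exceeds `tol` (background errors, beam-current drift or strong
#' noise show up here).
#'
#' @param series a [tilt_series()].
#' @param tol relative deviation above which an angle is flagged.
#' @return data frame with columns `angle`, `sum`, `deviation`, `flagged`.
#' @export
integral_invariance <- function(series, tol = 1e-3) {
  stopifnot(inherits(series, "tilt_series"))
  s <- colSums(series$projections)
  m <- stats::median(s)
  dev <- if (m != 0) abs(s - m) / abs(m) else abs(s)
  data.frame(angle = series$angles, sum = s, deviation = dev,
             flagged = dev > tol)
}

#' Quantisation-unit budget from the base-angle projection
#'
#' Splits the base-angle projection into per-column QU counts
#' `n_Theta(x'_j) = round(p_Theta(x'_j) / q)` (round half to even) and
#' defines the total `N` as their sum, so the budget identity
#' `sum(column_counts) == N` holds exactly.
#'
#' @param projection non-negative numeric vector: the base-angle projection.
#' @param q QU value (positive grey-level quantum).
#' @param base_angle optional base angle recorded in the result.
#' @return object of class `qu_constraints`: list with `column_counts`,
#'   `total_count` (N), `q`, `base_angle`.
#' @examples
#' qu_constraints(c(4, 2, 0), q = 2)  # counts 2 1 0, N = 3
#' @export
qu_constraints <- function(projection, q, base_angle = NA_real_) {
  projection <- as.numeric(projection)
  if (q < 1) stop("q must be >= 1")
  neg <- projection < -1e-9 * max(abs(projection), 1)
  if (any(neg)) stop("projection must be non-negative")
  projection[projection < 0] <- 0
  counts <- as.integer(round(projection / q))
  structure(list(column_counts = counts, total_count = sum(counts),
                 q = q, base_angle = base_angle),
            class = "qu_constraints")
}

#' @export
print.qu_constraints <- function(x, ...) {
  cat(sprintf("QU constraints: N = %d pieces of value q = %g over %d columns",
              x$total_count, x$q, length(x$column_counts)))
  if (is.finite(x$base_angle)) cat(sprintf(" (base angle %g deg)", x$base_angle))
  cat("\n")
  invisible(x)
}

#' Amplify projection data to large integers
#'
#' Experimental intensities are in arbitrary units; QURT counts QU pieces, so
#' the projections are scaled by `scale = target_peak / max(projections)` and
#' rounded to integers (the amplified bin values then play the role of QU
#' piece numbers). The returned scale maps the final reconstruction back to
#' the original intensity units.
#'
#' @param series a [tilt_series()] with non-negative projections.
#' @param target_peak desired maximum integer bin value after amplification.
#' @return list with `series` (integer-valued projections) and `scale`.
#' @export
amplify_projections <- function(series, target_peak = 1e4) {
  stopifnot(inherits(series, "tilt_series"))
  mx <- max(series$projections)
  if (mx <= 0) stop("cannot amplify an all-zero series")
  scale <- target_peak / mx
  p <- round(series$projections * scale)
  list(series = tilt_series(p, series$angles), scale = scale)
}

#' Subtract background intensity from a tilt series
#'
#' Removes a constant or per-angle background offset (vacuum level, support
#' film, camera pedestal) and clips at zero, since QU counts are non-negative
#' by construction. The fraction of clipped bins is recorded as attribute
#' `clipped_fraction`.
#'
#' @param series a [tilt_series()].
#' @param background single number or one offset per angle.
#' @return the corrected [tilt_series()].
#' @export
subtract_background <- function(series, background) {
  stopifnot(inherits(series, "tilt_series"))
  background <- as.numeric(background)
  if (!length(background) %in% c(1L, length(series$angles))) {
    stop("background must be a constant or one offset per angle")
  }
  if (anyNA(background) || any(!is.finite(background))) {
    stop("background offsets must be finite")
  }
  p <- sweep(series$projections, 2L, background, `-`)
  clipped <- mean(p < 0)
  p[p < 0] <- 0
  out <- tilt_series(p, series$angles)
  attr(out, "clipped_fraction") <- clipped
  out
}

# bin detector samples by the QU piece size: group-sum over `s` bins divided
# by s^2, so that a coarse image on the mean-grey scale forward-projects onto
# the binned data with unit coarse pixels (this is what makes N quadruple
# when the linear image definition doubles)
bin_projections <- function(projections, s) {
  n <- nrow(projections)
  if (s == 1L) return(projections)
  if (n %% s != 0L) stop("detector bins must be divisible by the QU size")
  m <- n %/% s
  grp <- rep(seq_len(m), each = s)
  out <- rowsum(projections, grp, reorder = TRUE)
  out / s^2
}
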