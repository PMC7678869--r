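# Quantitative evaluation: normalized average error, Fourier missing-wedge
# diagnostics, QU accounting.

#' Normalized average reconstruction error
#'
#' Mean absolute deviation between reconstruction and model, divided by the
#' maximum grey value of the model. The standard figure of merit for the
#' phantom studies in this package.
#'
#' @param recon reconstructed image (matrix or a `tomo2d` fit).
#' @param model ground-truth image of the same size.
#' @return non-negative scalar.
#' @export
normalized_error <- function(recon, model) {
  if (inherits(recon, "tomo2d")) recon <- recon$reconstruction
  check_image(model)
  if (!all(dim(recon) == dim(model))) stop("image sizes differ")
  mx <- max(model)
  if (mx <= 0) stop("model maximum must be positive")
  mean(abs(recon - model)) / mx
}

#' Fourier missing-wedge energy report
#'
#' Conventional limited-angle reconstructions only populate Fourier space
#' along the radial lines of the acquired projections (projection slice
#' theorem), leaving a wedge around the z* axis empty. This report measures
#' the mean spectral magnitude inside versus outside that wedge: the wedge
#' mask covers orientations beyond the maximum tilt, excluding a small
#' low-frequency disc (radius `dc_radius`) whose dominant DC energy both
#' methods share.
#'
#' @param image reconstructed image (matrix or a `tomo2d` fit).
#' @param max_tilt half tilt range in degrees (< 90).
#' @param dc_radius radius (pixels) of the excluded low-frequency disc.
#' @return list with `in_wedge`, `out_wedge` (mean magnitudes), `ratio`
#'   (in/out) and `wedge_fraction` (mask area fraction).
#' @export
wedge_energy <- function(image, max_tilt, dc_radius = 3) {
  if (inherits(image, "tomo2d")) image <- image$reconstruction
  check_image(image)
  if (max_tilt >= 90) {
    return(list(in_wedge = NA_real_, out_wedge = NA_real_, ratio = NA_real_,
                wedge_fraction = 0))
  }
  n <- nrow(image)
  mag <- Mod(stats::fft(image))
  idx <- seq_len(n) - 1L
  f <- ifelse(idx <= n / 2, idx, idx - n)     # signed frequency index
  kz <- matrix(f, n, n)                        # rows = z frequency
  kx <- matrix(f, n, n, byrow = TRUE)          # cols = x frequency
  rad <- sqrt(kx^2 + kz^2)
  # acquired slices lie within +/-max_tilt of the kx axis; the wedge is the
  # remaining sector around the kz axis
  orient <- atan2(abs(kx), abs(kz)) * 180 / pi
  wedge <- orient < (90 - max_tilt) & rad > dc_radius
  outside <- !wedge & rad > dc_radius
  list(in_wedge = mean(mag[wedge]), out_wedge = mean(mag[outside]),
       ratio = mean(mag[wedge]) / mean(mag[outside]),
       wedge_fraction = mean(wedge))
}

#' QU accounting across the multiresolution schedule
#'
#' Tabulates, per level, the total QU budget N, the pieces placed, moved and
#' erased, summed over base angles, plus the ratio of N between consecutive
#' image-definition levels at the same q (doubling the linear definition
#' multiplies N by four).
#'
#' @param fit a [qurt()] fit (or its `$log` data frame).
#' @return data frame with one row per (qu_size, q) level.
#' @export
qu_accounting <- function(fit) {
  n_full <- if (inherits(fit, "qurt")) fit$series$n else NA_integer_
  log <- if (inherits(fit, "qurt")) fit$log else fit
  if (is.null(log) || nrow(log) == 0L) stop("empty reconstruction log")
  key <- paste(log$qu_size, log$q, sep = "/")
  lev <- unique(key)
  out <- do.call(rbind, lapply(lev, function(k) {
    rows <- log[key == k, , drop = FALSE]
    data.frame(qu_size = rows$qu_size[1L], q = rows$q[1L],
               definition = as.integer(n_full %/% rows$qu_size[1L]),
               n_base_angles = nrow(rows),
               N = max(rows$N),
               placed = sum(rows$placed), moved = sum(rows$moved),
               erased = sum(rows$erased))
  }))
  out$N_ratio <- NA_real_
  for (i in seq_len(nrow(out))) {
    if (i > 1L && out$q[i] == out$q[i - 1L] &&
        out$qu_size[i - 1L] == 2L * out$qu_size[i]) {
      out$N_ratio[i] <- out$N[i] / out$N[i - 1L]
    }
  }
  out
}
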