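# File formats and the slice-wise volume driver.
#
# Tilt stacks are ingested from MRC or multi-page TIFF plus a plain-text
# angle list (one value in degrees per line). The MRC reader/writer here is
# a minimal implementation of the standard 1024-byte-header format (modes 0,
# 1, 2 and 6), sufficient for tilt stacks and reconstructed volumes.

MRC_MODES <- list(`0` = list(what = "integer", size = 1L, signed = TRUE),
                  `1` = list(what = "integer", size = 2L, signed = TRUE),
                  `2` = list(what = "numeric", size = 4L, signed = TRUE),
                  `6` = list(what = "integer", size = 2L, signed = FALSE))

#' Read an MRC file
#'
#' @param path file path.
#' @return numeric array of dimension (nx, ny, nz); x is the fastest axis,
#'   as stored in the file.
#' @export
read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  nx <- hdr[1L]; ny <- hdr[2L]; nz <- hdr[3L]; mode <- hdr[4L]
  if (nx <= 0 || ny <= 0 || nz <= 0 || nx > 1e5 || ny > 1e5 || nz > 1e5) {
    stop("not a readable MRC file (bad dimensions)")
  }
  spec <- MRC_MODES[[as.character(mode)]]
  if (is.null(spec)) stop(sprintf("unsupported MRC mode %d", mode))
  seek(con, 92L)
  nsymbt <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  seek(con, 1024L + max(0L, nsymbt))
  nvals <- nx * ny * nz
  dat <- readBin(con, spec$what, n = nvals, size = spec$size,
                 signed = spec$signed, endian = "little")
  if (length(dat) != nvals) stop("truncated MRC data block")
  array(as.numeric(dat), dim = c(nx, ny, nz))
}

#' Write an MRC file (mode 2, 32-bit float)
#'
#' @param data numeric array (nx, ny, nz), matrix (treated as nz = 1) or a
#'   `tomo2d` fit.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(data, path) {
  if (inherits(data, "tomo2d")) data <- data$reconstruction
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  if (length(dim(data)) != 3L) stop("data must be a matrix or 3D array")
  dm <- dim(data)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- integer(256L)
  header[1:3] <- dm
  header[4L] <- 2L            # mode 2: float32
  header[8:10] <- dm          # mx, my, mz
  writeBin(header[1:10], con, size = 4L, endian = "little")
  writeBin(as.numeric(dm), con, size = 4L, endian = "little")  # cell in px
  writeBin(c(90, 90, 90), con, size = 4L, endian = "little")   # cell angles
  writeBin(1:3, con, size = 4L, endian = "little")             # axis order
  rng <- range(data)
  writeBin(c(rng[1L], rng[2L], mean(data)), con, size = 4L, endian = "little")
  writeBin(integer(2L), con, size = 4L, endian = "little")     # ispg, nsymbt
  writeBin(integer(25L), con, size = 4L, endian = "little")    # extra
  writeBin(numeric(3L), con, size = 4L, endian = "little")     # origin
  writeChar("MAP ", con, nchars = 4L, eos = NULL)
  writeBin(as.integer(c(68L, 68L, 0L, 0L)), con, size = 1L)    # machine stamp
  writeBin(stats::sd(data), con, size = 4L, endian = "little")
  writeBin(integer(1L + 200L), con, size = 4L, endian = "little")  # nlabl+labels
  writeBin(as.numeric(data), con, size = 4L, endian = "little")
  invisible(path)
}

#' Export a 2D image as TIFF or PNG
#'
#' TIFF output stores `image / scale` as 32-bit float (TIFF floats live in
#' \[0, 1\]); multiply by the returned scale after reading to recover the
#' original grey values. PNG output is a scaled 8-bit preview.
#'
#' @param image square numeric matrix (or a `tomo2d` fit).
#' @param path output path; format follows the extension (.tif/.tiff/.png).
#' @param scale grey value mapped to 1.0 in TIFF output (default: the image
#'   maximum).
#' @return `path`, invisibly, with the applied `scale` as an attribute.
#' @export
export_image <- function(image, path, scale = NULL) {
  if (inherits(image, "tomo2d")) image <- image$reconstruction
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    if (is.null(scale)) scale <- max(image, 1e-12)
    tiff::writeTIFF(pmin(pmax(image / scale, 0), 1), path,
                    bits.per.sample = 32L)
  } else if (ext == "png") {
    rng <- range(image)
    scl <- if (diff(rng) > 0) (image - rng[1L]) / diff(rng) else image * 0
    grDevices::png(path, width = ncol(image), height = nrow(image))
    op <- graphics::par(mar = c(0, 0, 0, 0))
    on.exit(graphics::par(op), add = TRUE)
    graphics::image(t(scl[nrow(scl):1, ]),
                    col = grDevices::gray(seq(0, 1, length.out = 256)),
                    axes = FALSE, useRaster = TRUE)
    grDevices::dev.off()
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(structure(path, scale = if (ext != "png") scale))
}

#' Read a tilt stack and its angle list
#'
#' Loads an aligned tilt stack (MRC or multi-page TIFF) together with a
#' plain-text tilt-angle file (one angle in degrees per line) and validates
#' that the angles are strictly increasing and match the stack depth. The
#' tilt axis is assumed to run along the image rows: row `i` of every image
#' yields the 1D projections of cross-section slice `i`.
#'
#' @param stack_path MRC or TIFF stack of projection images.
#' @param angles_path text file of tilt angles in degrees.
#' @return object of class `tilt_stack`: list with `data` (rows x bins x
#'   angles array), `angles`, `n_slices`, `n_bins`.
#' @export
read_tilt_stack <- function(stack_path, angles_path) {
  angles <- scan(angles_path, what = numeric(), quiet = TRUE)
  ext <- tolower(tools::file_ext(stack_path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(stack_path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    dat <- simplify2array(pages)            # rows x cols x pages
  } else {
    vol <- read_mrc(stack_path)              # nx x ny x nz, x fastest
    dat <- aperm(vol, c(2L, 1L, 3L))         # rows(y) x cols(x) x angles
  }
  if (length(dim(dat)) == 2L) dat <- array(dat, dim = c(dim(dat), 1L))
  if (dim(dat)[3L] != length(angles)) {
    stop(sprintf("stack depth (%d) does not match the angle list (%d)",
                 dim(dat)[3L], length(angles)))
  }
  geom <- tilt_geometry(angles, dim(dat)[2L])  # validates ordering/duplicates
  structure(list(data = dat, angles = geom$angles,
                 n_slices = dim(dat)[1L], n_bins = dim(dat)[2L]),
            class = "tilt_stack")
}

#' @export
print.tilt_stack <- function(x, ...) {
  cat(sprintf("Tilt stack: %d slices x %d bins x %d angles (%g..%g deg)\n",
              x$n_slices, x$n_bins, length(x$angles), min(x$angles),
              max(x$angles)))
  invisible(x)
}

#' Tilt series of one cross-section slice of a stack
#'
#' @param stack a [read_tilt_stack()] object.
#' @param slice 1-based slice index along the tilt axis.
#' @return a [tilt_series()].
#' @export
slice_series <- function(stack, slice) {
  stopifnot(inherits(stack, "tilt_stack"))
  slice <- as.integer(slice)
  if (slice < 1L || slice > stack$n_slices) stop("slice out of range")
  tilt_series(stack$data[slice, , ], stack$angles)
}

#' Slice-wise volume reconstruction
#'
#' Reconstructs every cross-section of a tilt stack independently (no
#' inter-slice coupling) and stacks the results along the tilt axis. A slice
#' that fails is filled with zeros and reported in the `failed` attribute.
#'
#' @param stack a [read_tilt_stack()] object.
#' @param method `"qurt"`, `"sirt"` or `"fbp"`.
#' @param ... passed to the reconstruction function.
#' @param out_mrc optional path: write the volume as MRC (x fastest, slices
#'   along z).
#' @return numeric array (n, n, n_slices) of reconstructed cross-sections,
#'   with attribute `failed` (integer vector of failed slice indices).
#' @export
reconstruct_volume <- function(stack, method = c("qurt", "sirt", "fbp"), ...,
                               out_mrc = NULL) {
  stopifnot(inherits(stack, "tilt_stack"))
  method <- match.arg(method)
  fun <- switch(method, qurt = qurt, sirt = sirt, fbp = fbp)
  n <- stack$n_bins
  vol <- array(0, dim = c(n, n, stack$n_slices))
  failed <- integer(0)
  for (i in seq_len(stack$n_slices)) {
    res <- tryCatch(fun(slice_series(stack, i), ...), error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("slice %d failed: %s", i, conditionMessage(res)))
      failed <- c(failed, i)
    } else {
      vol[, , i] <- res$reconstruction
    }
  }
  attr(vol, "failed") <- failed
  if (!is.null(out_mrc)) write_mrc(vol, out_mrc)
  vol
}
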