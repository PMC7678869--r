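# QURT: quantisation units reconstruction technique.
#
# The reconstruction is built by stacking grey-level quantisation units (QU
# pieces) one by one at the most QU-deficient pixel of the error map, under
# the per-column budgets derived from a base-angle projection; placed pieces
# are then rearranged inside their column to further reduce the residuals.
# A coarse-to-fine schedule over the QU piece size (one piece = one pixel of
# a binned working grid) and the QU value q, together with averaging over
# several base angles, steers the combinatorial search away from local
# minima and from the square-piece mosaic artefacts of a single base angle.

#' Multiresolution QURT schedule
#'
#' Builds the default coarse-to-fine level sequence: QU piece sizes halving
#' from `start_size` down to 1 pixel, each size visited with the QU values in
#' `q_values` (coarse to fine), the final level always (size 1, q = 1).
#' Default base angles are the extreme tilts plus 0 degrees; for step angles
#' above 5 degrees, +/-50 degrees (snapped to acquired angles) are added,
#' five base angles giving better reconstructions when projections are few.
#'
#' @param series a [tilt_series()] (supplies the grid size and tilt angles).
#' @param start_size initial QU piece side in pixels (reduced to the largest
#'   power of two dividing the grid if needed).
#' @param q_values QU values visited at each size, in order; the last size
#'   uses only q = 1.
#' @param base_angles base tilt angles Theta in degrees; `NULL` for the
#'   default selection. Angles are snapped to the nearest acquired angle.
#' @param convergence_tol change-rate threshold of the refinement stage.
#' @param check_interval iterations between convergence checks.
#' @return object of class `qurt_schedule`.
#' @export
qurt_schedule <- function(series, start_size = 32L, q_values = c(8, 1),
                          base_angles = NULL, convergence_tol = 1e-6,
                          check_interval = 100L) {
  stopifnot(inherits(series, "tilt_series"))
  n <- series$n
  s <- as.integer(start_size)
  while (s > 1L && (n %% s != 0L)) s <- s %/% 2L
  sizes <- c()
  while (s >= 1L) { sizes <- c(sizes, s); s <- s %/% 2L }
  q_values <- sort(unique(as.integer(q_values)), decreasing = TRUE)
  if (any(q_values < 1L)) stop("q values must be >= 1")
  levels <- do.call(rbind, lapply(sizes, function(sz) {
    qs <- if (sz == 1L) 1L else q_values
    data.frame(qu_size = sz, q = qs)
  }))
  if (is.null(base_angles)) {
    amax <- max(abs(series$angles))
    step <- stats::median(diff(series$angles))
    base_angles <- if (step > 5) c(-amax, -50, 0, 50, amax) else c(-amax, 0, amax)
  }
  base_angles <- unique(vapply(base_angles, function(th) {
    series$angles[which.min(abs(series$angles - th))]
  }, numeric(1)))
  structure(list(levels = levels, base_angles = base_angles,
                 convergence_tol = convergence_tol,
                 check_interval = as.integer(check_interval)),
            class = "qurt_schedule")
}

#' @export
print.qurt_schedule <- function(x, ...) {
  lv <- paste(sprintf("(%d,%d)", x$levels$qu_size, x$levels$q), collapse = " ")
  cat("QURT schedule (qu_size, q):", lv, "\n")
  cat("  base angles:", paste(x$base_angles, collapse = ", "), "deg\n")
  cat(sprintf("  convergence: change rate < %g per %d iterations\n",
              x$convergence_tol, x$check_interval))
  invisible(x)
}

validate_schedule <- function(schedule) {
  lv <- schedule$levels
  if (nrow(lv) < 1L) stop("schedule has no levels")
  last <- lv[nrow(lv), ]
  if (last$qu_size != 1L || last$q != 1L) {
    stop("the schedule must end at QU size 1 and q = 1")
  }
  dsz <- diff(lv$qu_size)
  if (any(!(dsz == 0 | lv$qu_size[-1] * 2L == lv$qu_size[-nrow(lv)]))) {
    stop("QU sizes must stay constant or halve between consecutive levels")
  }
  if (length(schedule$base_angles) < 1L) stop("at least one base angle needed")
  invisible(schedule)
}

# block-replicate a coarse image onto a grid `f` times finer
upsample_block <- function(img, f) {
  if (f == 1L) return(img)
  img[rep(seq_len(nrow(img)), each = f), rep(seq_len(ncol(img)), each = f)]
}

# bilinear upsampling (edge-extended); the default inter-level warm start:
# seeding the finer level with interpolated grey avoids planting the coarse
# mosaic edges that intra-column moves then have to undo
upsample_bilinear <- function(img, f) {
  if (f == 1L) return(img)
  m <- nrow(img)
  xs <- (seq_len(m) - 0.5) / m
  xf <- (seq_len(m * f) - 0.5) / (m * f)
  t1 <- apply(img, 2, function(v) stats::approx(xs, v, xf, rule = 2)$y)
  t(apply(t1, 1, function(v) stats::approx(xs, v, xf, rule = 2)$y))
}

#' Run one QURT level (one QU size and value) over its base angles
#'
#' For each base angle Theta: bins the projections by the QU size, derives
#' the per-column budgets from the base-angle projection, seeds the QU
#' arrangement from `init` (re-quantised to multiples of q; columns exceeding
#' their budget are relieved from their most excessive pixels, deficits are
#' placed at the most QU-deficient error-map pixels), then alternates
#' erasure of excess pieces, re-placement and intra-column refinement until
#' quiescent or converged. The level result is the pixelwise average of the
#' per-Theta reconstructions (continuous grey values).
#'
#' @param series the measured [tilt_series()].
#' @param qu_size QU piece side length in pixels (must divide the grid).
#' @param q QU value.
#' @param base_angles base tilt angles (must be acquired angles).
#' @param init starting image on the level's working grid (grey scale), or
#'   `NULL` for a null start.
#' @param control list of solver settings (see [qurt()]).
#' @return list with `image` (the averaged level result), `log` (one row per
#'   base angle: N, placed, moved, erased, converged, rss) and `solutions`
#'   (per-Theta grey images).
#' @export
qurt_level <- function(series, qu_size, q, base_angles, init = NULL,
                       control = list()) {
  stopifnot(inherits(series, "tilt_series"))
  n <- series$n
  qu_size <- as.integer(qu_size)
  if (n %% qu_size != 0L) stop("QU size must divide the grid side")
  m <- n %/% qu_size
  p_m <- bin_projections(series$projections, qu_size)
  if (is.null(init)) init <- matrix(0, m, m)
  if (!all(dim(init) == m)) stop("init grid does not match the level definition")
  opts <- list(
    tol = control$convergence_tol %||% 1e-6,
    interval = control$check_interval %||% 100L,
    margin = control$erase_margin %||% (q / 2),
    exhaustive_limit = control$exhaustive_limit %||% 12L,
    max_outer = control$max_outer %||% 40L,
    min_gain = control$min_gain %||% 1e-10,
    move_cap = control$move_cap %||% 50
  )
  idx <- vapply(base_angles, function(th) {
    i <- which.min(abs(series$angles - th))
    if (abs(series$angles[i] - th) > 1e-9) {
      stop("base angles must be acquired tilt angles")
    }
    i
  }, integer(1))
  chain <- isTRUE(control$chain %||% FALSE)
  sols <- vector("list", length(idx))
  logs <- vector("list", length(idx))
  init_counts <- matrix(as.integer(round(init / q)), m, m)
  for (i in seq_along(idx)) {
    th <- series$angles[idx[i]]
    cs <- qu_constraints(p_m[, idx[i]], q, base_angle = th)
    sol <- cpp_qurt_solve(p_m, series$angles, th, q, init_counts,
                          cs$column_counts, opts)
    # each base angle continues from the previous one's arrangement; the
    # alternating column constraints steer the search out of local minima
    if (chain) init_counts <- sol$counts
    if (any(sol$placed_col != sol$ncol)) {
      stop("internal error: column budgets not met after placement")
    }
    sols[[i]] <- sol$counts * q
    logs[[i]] <- data.frame(
      qu_size = qu_size, q = q, theta = th, N = sol$N,
      placed = sol$n_place, moved = sol$n_move, erased = sol$n_erase,
      clamped = sol$n_clamp, converged = sol$converged,
      move_cap_hit = sol$move_cap_hit, rss = sol$rss)
  }
  img <- Reduce(`+`, sols) / length(sols)
  list(image = img, log = do.call(rbind, logs), solutions = sols)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' QURT reconstruction of a cross-section from a tilt series
#'
#' Reconstructs a 2D cross-section by placing grey-level quantisation units
#' under projection-integral constraints, running the multiresolution
#' schedule from the coarsest QU piece size down to single pixels with q = 1,
#' averaging over the base angles at every level, and warm-starting each
#' level from the previous one (block-replicated and re-quantised). Starting
#' point is the null image.
#'
#' @param series a [tilt_series()].
#' @param schedule a [qurt_schedule()]; `NULL` for the default built from
#'   `series`.
#' @param target_peak if not `NULL`, projections are first amplified to
#'   integers peaking at this value (see [amplify_projections()]) and the
#'   final image is mapped back to the original intensity scale.
#' @param control named list of solver settings: `erase_margin` (error-map
#'   threshold above which an occupied pixel loses a piece, default q/2),
#'   `move_cap` (refinement move budget per level, multiple of N, default
#'   50), `max_outer` (erase/place/refine rounds per level, default 40),
#'   `exhaustive_limit` (grid size up to which the refinement move search is
#'   exhaustive, default 12), `min_gain` (smallest accepted residual-norm
#'   improvement, default 1e-10).
#' @param verbose print per-level progress.
#' @param ... arguments passed to [qurt_schedule()] when `schedule` is NULL
#'   (e.g. `base_angles`, `start_size`, `q_values`).
#' @return an object of class `c("qurt", "tomo2d")` with the reconstruction
#'   in `$reconstruction`, the per-level log in `$log`, and the schedule,
#'   series and call.
#' @examples
#' model <- phantom_binary(32)
#' ts <- simulate_tilt_series(model, tilt_angles(60, 10))
#' fit <- qurt(ts, start_size = 8L, q_values = 1L, base_angles = 0)
#' normalized_error(fitted(fit), model)
#' @export
qurt <- function(series, schedule = NULL, target_peak = NULL,
                 control = list(), verbose = FALSE, ...) {
  stopifnot(inherits(series, "tilt_series"))
  if (is.null(schedule)) schedule <- qurt_schedule(series, ...)
  validate_schedule(schedule)
  scale <- 1
  work <- series
  if (!is.null(target_peak)) {
    amp <- amplify_projections(series, target_peak)
    work <- amp$series
    scale <- amp$scale
  }
  control$convergence_tol <- control$convergence_tol %||% schedule$convergence_tol
  control$check_interval <- control$check_interval %||% schedule$check_interval
  lv <- schedule$levels
  g <- NULL
  prev_size <- lv$qu_size[1L]
  logs <- vector("list", nrow(lv))
  for (i in seq_len(nrow(lv))) {
    sz <- lv$qu_size[i]; q <- lv$q[i]
    if (!is.null(g) && sz != prev_size) {
      up <- if (identical(control$upsample %||% "bilinear", "block")) {
        upsample_block
      } else {
        upsample_bilinear
      }
      g <- up(g, prev_size %/% sz)
    }
    t0 <- Sys.time()
    out <- qurt_level(work, sz, q, schedule$base_angles, init = g,
                      control = control)
    g <- out$image
    logs[[i]] <- out$log
    prev_size <- sz
    if (verbose) {
      message(sprintf(
        "level (size %d, q %d): N=%s placed=%s moved=%s erased=%s [%.1fs]",
        sz, q, format(sum(out$log$N)), format(sum(out$log$placed)),
        format(sum(out$log$moved)), format(sum(out$log$erased)),
        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    }
  }
  structure(list(reconstruction = g / scale, series = series,
                 schedule = schedule, log = do.call(rbind, logs),
                 scale = scale, method = "qurt", call = match.call()),
            class = c("qurt", "tomo2d"))
}
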