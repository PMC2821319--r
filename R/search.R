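#' Define the exhaustive search space
#'
#' Integer translation ranges in x and y, a rotation-angle range in degrees,
#' per-axis step sizes, and a minimum-overlap guard.  The defaults are the
#' bounds used for brain NMR/PET registration with a rough pre-alignment:
#' translations from -30 to +30 pixels and rotation from -20 to +20 degrees
#' at step 1, giving 61 * 61 * 41 = 152,561 candidate poses per slice.
#'
#' Grid points whose valid-overlap fraction falls below `min_overlap`
#' (default 0.25) are skipped rather than scored: similarity estimated from
#' a sliver of overlap is unreliable and could outrank genuine alignments.
#'
#' @param tx,ty integer `c(min, max)` translation bounds in pixels.
#' @param theta `c(min, max)` rotation bounds in degrees.
#' @param tx_step,ty_step integer grid steps in pixels (default 1).
#' @param theta_step grid step in degrees (default 1).
#' @param min_overlap minimum valid-pixel fraction in (0, 1], default 0.25.
#' @return object of class `search_space`.
#' @export
search_space <- function(tx = c(-30L, 30L), ty = c(-30L, 30L),
                         theta = c(-20, 20), tx_step = 1L, ty_step = 1L,
                         theta_step = 1, min_overlap = 0.25) {
  chk_range <- function(r, nm) {
    if (length(r) != 2L || anyNA(r) || r[1] > r[2]) {
      slicereg_error(sprintf("%s must be c(min, max) with min <= max", nm),
                     "slicereg_domain_error")
    }
  }
  chk_range(tx, "tx")
  chk_range(ty, "ty")
  chk_range(theta, "theta")
  if (any(c(tx, ty) != round(c(tx, ty))) ||
      tx_step != round(tx_step) || ty_step != round(ty_step)) {
    slicereg_error("translation bounds and steps must be integers",
                   "slicereg_domain_error")
  }
  if (tx_step <= 0 || ty_step <= 0 || theta_step <= 0) {
    slicereg_error("steps must be > 0", "slicereg_domain_error")
  }
  if (min_overlap <= 0 || min_overlap > 1) {
    slicereg_error("min_overlap must lie in (0, 1]", "slicereg_domain_error")
  }
  structure(list(tx = as.integer(tx), ty = as.integer(ty),
                 theta = as.numeric(theta), tx_step = as.integer(tx_step),
                 ty_step = as.integer(ty_step),
                 theta_step = as.numeric(theta_step),
                 min_overlap = as.numeric(min_overlap)),
            class = "search_space")
}

axis_values <- function(lo, hi, step) {
  lo + step * 0:floor((hi - lo) / step)
}

#' Enumerate the pose grid of a search space
#'
#' Rows are ordered ascending lexicographically by `(theta, ty, tx)`; this
#' scan order, together with first-strict-maximum selection, defines the
#' deterministic tie rule of the search (smallest theta, then ty, then tx).
#'
#' @param space `search_space` object.
#' @return data.frame with columns `theta`, `tx`, `ty`, one row per
#'   candidate pose.
#' @export
grid_points <- function(space) {
  stopifnot(inherits(space, "search_space"))
  g <- expand.grid(tx = axis_values(space$tx[1], space$tx[2], space$tx_step),
                   ty = axis_values(space$ty[1], space$ty[2], space$ty_step),
                   theta = axis_values(space$theta[1], space$theta[2],
                                       space$theta_step),
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("theta", "tx", "ty")]
}

#' Exhaustive rigid 2D/2D alignment of a floating image to one target slice
#'
#' Every pose in the search grid is scored against the target.  A candidate
#' pose is scored by sampling the floating image at forward-transformed
#' target coordinates (see [rigid_resample()] with `invert = TRUE`): the
#' reported pose is the rigid displacement of the floating image relative to
#' the target, so at the optimum `rigid_resample(target, pose)` reproduces
#' the floating image.  The highest score wins; ties are broken by scan
#' order (smallest theta, then ty, then tx).  Poses with insufficient
#' overlap are skipped and counted.
#'
#' @param target,floating `[y, x]` 8-bit matrices of identical size.
#' @param space `search_space` object.
#' @param metric `"nmi"` (normalized mutual information, default) or
#'   `"cross_correlation"`.
#' @param interpolation `"nearest"` (default) or `"bilinear"`.
#' @return object of class `slice_result`: list with `k` (slice number,
#'   `NA` for a standalone 2D/2D alignment), `theta`, `tx`, `ty`, `score`,
#'   `metric`, `evaluations`, `skipped`.
#' @export
align_2d2d <- function(target, floating, space = search_space(),
                       metric = c("nmi", "cross_correlation"),
                       interpolation = c("nearest", "bilinear")) {
  t_img <- image2d(target)
  f_img <- image2d(floating)
  metric <- match.arg(metric)
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(space, "search_space"))
  if (!identical(dim(t_img), dim(f_img))) {
    slicereg_error("target and floating dimensions differ",
                   "slicereg_domain_error")
  }
  res <- cpp_align_slice(
    t_img, f_img,
    axis_values(space$theta[1], space$theta[2], space$theta_step),
    as.integer(axis_values(space$tx[1], space$tx[2], space$tx_step)),
    as.integer(axis_values(space$ty[1], space$ty[2], space$ty_step)),
    space$min_overlap,
    if (metric == "nmi") 0L else 1L,
    if (interpolation == "nearest") 0L else 1L)
  if (!res$found) {
    slicereg_error("no valid candidate: every grid point was skipped",
                   "slicereg_no_valid_candidate")
  }
  structure(list(k = NA_integer_, theta = res$theta, tx = res$tx,
                 ty = res$ty, score = res$score, metric = metric,
                 evaluations = res$evaluations, skipped = res$skipped),
            class = "slice_result")
}

#' Re-evaluate the similarity of one pose
#'
#' Scores a single pose exactly as the exhaustive search does (pullback
#' resampling of the floating image, metric over the validity mask); used
#' to verify stored results.
#'
#' @inheritParams align_2d2d
#' @param theta,tx,ty the pose.
#' @return numeric score.
#' @export
score_pose <- function(target, floating, theta, tx, ty,
                       metric = c("nmi", "cross_correlation"),
                       interpolation = c("nearest", "bilinear")) {
  metric <- match.arg(metric)
  interpolation <- match.arg(interpolation)
  r <- rigid_resample(floating, theta, tx, ty, interpolation, invert = TRUE)
  if (metric == "nmi") {
    normalized_mutual_information(joint_histogram(target, r$image, r$mask))
  } else {
    cross_correlation(target, floating = r$image, mask = r$mask)
  }
}

#' Register a 2D image into a 3D volume
#'
#' Runs [align_2d2d()] for every slice of the volume (optionally in
#' parallel, see [run_jobs()]) and returns the per-slice results together
#' with the global optimum over all slices and poses.  Ties across slices go
#' to the smallest slice number; the result is identical for any worker
#' count.
#'
#' @param volume `[y, x, k]` integer array.
#' @param floating `[y, x]` 8-bit matrix matching the slice dimensions.
#' @param space `search_space` object.
#' @param metric `"nmi"` or `"cross_correlation"`.
#' @param workers number of parallel workers (default 1).
#' @param interpolation `"nearest"` or `"bilinear"`.
#' @return object of class `registration_result`: list with `best` (a
#'   `slice_result` carrying the winning slice number `k`), `per_slice`
#'   (list of `slice_result`, one per slice), `space`, `metric`,
#'   `interpolation`.
#' @export
align_2d3d <- function(volume, floating, space = search_space(),
                       metric = c("nmi", "cross_correlation"), workers = 1L,
                       interpolation = c("nearest", "bilinear")) {
  metric <- match.arg(metric)
  interpolation <- match.arg(interpolation)
  f_img <- image2d(floating)
  d <- dim(volume)
  if (length(d) != 3L) {
    slicereg_error("volume must be a 3D array", "slicereg_format_error")
  }
  if (d[1] != nrow(f_img) || d[2] != ncol(f_img)) {
    slicereg_error("floating image does not match slice dimensions",
                   "slicereg_domain_error")
  }
  per_slice <- run_jobs(volume, f_img, space, metric, workers, interpolation)
  best <- per_slice[[1L]]
  for (k in seq_along(per_slice)) {
    if (per_slice[[k]]$score > best$score) {
      best <- per_slice[[k]]
    }
  }
  structure(list(best = best, per_slice = per_slice, space = space,
                 metric = metric, interpolation = interpolation),
            class = "registration_result")
}

#' @export
print.slice_result <- function(x, ...) {
  cat(sprintf(
    "2D/2D alignment: k=%s theta=%g tx=%d ty=%d  %s=%.6f  (%d scored, %d skipped)\n",
    ifelse(is.na(x$k), "-", x$k), x$theta, x$tx, x$ty, x$metric, x$score,
    x$evaluations, x$skipped))
  invisible(x)
}

#' @export
print.registration_result <- function(x, ...) {
  b <- x$best
  cat(sprintf("2D/3D registration over %d slices (%s, %s interpolation)\n",
              length(x$per_slice), x$metric, x$interpolation))
  cat(sprintf("  best: slice k=%d  theta=%g deg  tx=%d  ty=%d  score=%.6f\n",
              b$k, b$theta, b$tx, b$ty, b$score))
  invisible(x)
}
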