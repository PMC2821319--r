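#' Rigid resampling of a 2D image
#'
#' Applies the rigid pose "rotate by `theta` degrees (counterclockwise
#' positive) about the image center `((width-1)/2, (height-1)/2)`, then
#' translate by `(tx, ty)` pixels" using inverse mapping: each output pixel
#' looks up its source location `R(-theta)(p - c - t) + c` in the input.
#' Output pixels whose source falls outside the input domain are set to 0 and
#' flagged invalid in the returned mask; only valid pixels should feed
#' similarity computations.
#'
#' With `invert = TRUE` the inverse pose is applied (source location
#' `R(theta)(p - c) + c + t`), which undoes the forward pose up to
#' resampling; the exhaustive search uses this to test whether a candidate
#' pose explains the floating image.
#'
#' Nearest-neighbour interpolation preserves the 8-bit value set exactly;
#' bilinear re-quantizes with round-half-to-even.
#'
#' @param image `[y, x]` 8-bit matrix.
#' @param theta rotation angle in degrees, counterclockwise positive.
#' @param tx,ty integer translation in pixels along x (columns) and y (rows).
#' @param interpolation `"nearest"` (default) or `"bilinear"`.
#' @param invert apply the inverse of the pose instead of the pose.
#' @return list with `image` (integer matrix, invalid pixels 0) and `mask`
#'   (logical matrix, `TRUE` where the pixel carries data).
#' @export
rigid_resample <- function(image, theta, tx, ty,
                           interpolation = c("nearest", "bilinear"),
                           invert = FALSE) {
  img <- image2d(image)
  interpolation <- match.arg(interpolation)
  if (tx != round(tx) || ty != round(ty)) {
    slicereg_error("tx and ty must be integer pixel offsets",
                   "slicereg_domain_error")
  }
  cpp_rigid_resample(img, as.numeric(theta), as.integer(tx), as.integer(ty),
                     if (interpolation == "nearest") 0L else 1L,
                     isTRUE(invert))
}
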