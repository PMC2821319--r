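#' Construct / validate an 8-bit 2D image
#'
#' A 2D image is a plain integer matrix indexed `[y, x]` (row = y, column =
#' x) with every value in `[0, 255]`.  `image2d()` coerces a numeric matrix
#' and checks the invariants; most package functions accept any matrix that
#' passes this check.
#'
#' @param pixels numeric matrix of integral gray values in `[0, 255]`.
#' @return integer matrix indexed `[y, x]`.
#' @export
image2d <- function(pixels) {
  px <- as.matrix(pixels)
  if (!is.numeric(px)) {
    slicereg_error("image pixels must be numeric", "slicereg_format_error")
  }
  if (nrow(px) < 1L || ncol(px) < 1L) {
    slicereg_error("image must be at least 1x1", "slicereg_format_error")
  }
  if (anyNA(px) || any(px != round(px)) || any(px < 0) || any(px > 255)) {
    slicereg_error("pixel values must be integers in [0, 255]",
                   "slicereg_format_error")
  }
  storage.mode(px) <- "integer"
  px
}

assert_image2d <- function(img, what = "image") {
  if (!is.matrix(img) || !is.numeric(img)) {
    slicereg_error(paste(what, "must be a numeric matrix"),
                   "slicereg_format_error")
  }
  invisible(image2d(img))
}

#' Construct a 3D volume from slices
#'
#' A volume is an integer array indexed `[y, x, k]`: a stack of equally sized
#' 8-bit slices along z.  Accepts a list of image matrices or a 3D array.
#'
#' @param slices list of `[y, x]` matrices sharing one size, or a 3D array.
#' @return integer array `[height, width, depth]`.
#' @export
volume3d <- function(slices) {
  if (is.array(slices) && length(dim(slices)) == 3L) {
    arr <- slices
  } else if (is.list(slices) && length(slices) >= 1L) {
    dims <- vapply(slices, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      slicereg_error("all slices must share identical width and height",
                     "slicereg_format_error")
    }
    arr <- array(unlist(slices, use.names = FALSE),
                 dim = c(dims[1, 1], dims[2, 1], length(slices)))
  } else {
    slicereg_error("volume must be a 3D array or a non-empty list of slices",
                   "slicereg_format_error")
  }
  if (anyNA(arr) || any(arr != round(arr)) || any(arr < 0) || any(arr > 255)) {
    slicereg_error("voxel values must be integers in [0, 255]",
                   "slicereg_format_error")
  }
  storage.mode(arr) <- "integer"
  arr
}

#' Convert an RGB(A) raster to 8-bit grayscale
#'
#' Applies the ITU-R BT.601 luma weights
#' `round(0.299 R + 0.587 G + 0.114 B)` (round half to even), clamped to
#' `[0, 255]`.  A grayscale matrix (or single-channel array) passes through
#' unchanged; an alpha channel is ignored.
#'
#' @param x matrix (grayscale) or `[y, x, channels]` array with 1, 3 or 4
#'   channels, 8-bit values in `[0, 255]`.
#' @return integer `[y, x]` matrix.
#' @export
to_grayscale <- function(x) {
  if (is.matrix(x)) {
    return(image2d(x))
  }
  if (!is.array(x) || length(dim(x)) != 3L) {
    slicereg_error("expected a matrix or a [y, x, channel] array",
                   "slicereg_format_error")
  }
  nc <- dim(x)[3]
  if (nc == 1L) {
    return(image2d(x[, , 1]))
  }
  if (!(nc %in% c(3L, 4L))) {
    slicereg_error(sprintf("unsupported channel count: %d", nc),
                   "slicereg_format_error")
  }
  luma <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  image2d(pmin(pmax(round(luma), 0), 255))
}

# fractional block-overlap weights mapping n_src samples onto n_dst bins;
# rows sum to 1 so the result is an area average
overlap_weights <- function(n_src, n_dst) {
  scale <- n_src / n_dst
  w <- matrix(0, n_dst, n_src)
  for (i in seq_len(n_dst)) {
    lo <- (i - 1) * scale
    hi <- i * scale
    for (j in floor(lo):(ceiling(hi) - 1)) {
      ov <- min(hi, j + 1) - max(lo, j)
      if (ov > 0) w[i, j + 1] <- ov
    }
  }
  w / scale
}

#' Downscale an image by area averaging
#'
#' Each target pixel is the area-weighted mean of the source pixels inside
#' its footprint (anti-aliased block averaging), re-quantized to 8-bit with
#' round-half-to-even.  Upscaling is not supported.
#'
#' @param image `[y, x]` 8-bit matrix.
#' @param target_width,target_height output size; must not exceed the source.
#' @return integer `[target_height, target_width]` matrix.
#' @export
downscale <- function(image, target_width, target_height) {
  img <- image2d(image)
  h <- nrow(img)
  w <- ncol(img)
  if (target_width < 1 || target_height < 1) {
    slicereg_error("target dimensions must be >= 1", "slicereg_domain_error")
  }
  if (target_width > w || target_height > h) {
    slicereg_error("upscaling is not supported", "slicereg_domain_error")
  }
  if (target_width == w && target_height == h) {
    return(img)
  }
  out <- overlap_weights(h, target_height) %*% img %*%
    t(overlap_weights(w, target_width))
  image2d(pmin(pmax(round(out), 0), 255))
}

#' Extract one slice of a volume
#'
#' @param volume `[y, x, k]` integer array.
#' @param k slice number, 1-based, `1 <= k <= depth`.
#' @return integer `[y, x]` matrix (a copy; mutating it never alters the
#'   volume).
#' @export
extract_slice <- function(volume, k) {
  d <- dim(volume)
  if (length(d) != 3L) {
    slicereg_error("volume must be a 3D array", "slicereg_format_error")
  }
  if (length(k) != 1L || is.na(k) || k != round(k) || k < 1 || k > d[3]) {
    slicereg_error(sprintf("slice index %s out of range [1, %d]",
                           format(k), d[3]),
                   "slicereg_index_error")
  }
  volume[, , as.integer(k)]
}
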