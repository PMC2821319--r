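#' Specify a multimodal registration phantom
#'
#' A phantom is a smooth 8-bit volume (a sum of seeded anisotropic 3D
#' Gaussian blobs) together with a floating image manufactured from a known
#' slice by a known rigid pose, an intensity remapping that simulates a
#' modality change, and optional detector noise.  It stands in for paired
#' real acquisitions (for example NMR volume + PET scan) and carries exact
#' ground truth, so registration accuracy can be measured without external
#' data.
#'
#' Defaults (64 x 64 x 32 voxels, 8 blobs) keep a full exhaustive
#' registration at desk-scale runtimes while retaining smooth structure that
#' varies between consecutive slices.
#'
#' @param width,height,depth voxel counts, each `>= 8`.
#' @param n_blobs number of Gaussian blobs, `>= 1`.
#' @param seed RNG seed; identical specs regenerate byte-identical phantoms.
#' @param noise_sigma Gaussian noise standard deviation in gray levels
#'   (`>= 0`), added to the floating image after the intensity remap.
#' @param lut_kind intensity remapping of the floating image: `"identity"`,
#'   `"gamma"`, `"random_monotone"` or `"random_permutation"`.
#' @param truth ground-truth pose: list with `k` (slice number, 1-based),
#'   `theta` (degrees), `tx`, `ty` (pixels).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 64L, height = 64L, depth = 32L,
                         n_blobs = 8L, seed = 1L, noise_sigma = 0,
                         lut_kind = c("identity", "gamma", "random_monotone",
                                      "random_permutation"),
                         truth = list(k = depth %/% 2L, theta = 0, tx = 0L,
                                      ty = 0L)) {
  lut_kind <- match.arg(lut_kind)
  if (width < 8 || height < 8 || depth < 8) {
    slicereg_error("phantom dimensions must each be >= 8",
                   "slicereg_domain_error")
  }
  if (n_blobs < 1) {
    slicereg_error("n_blobs must be >= 1", "slicereg_domain_error")
  }
  if (noise_sigma < 0) {
    slicereg_error("noise_sigma must be >= 0", "slicereg_domain_error")
  }
  if (truth$k < 1 || truth$k > depth) {
    slicereg_error("truth$k out of range", "slicereg_index_error")
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 depth = as.integer(depth), n_blobs = as.integer(n_blobs),
                 seed = as.integer(seed), noise_sigma = as.numeric(noise_sigma),
                 lut_kind = lut_kind,
                 truth = list(k = as.integer(truth$k),
                              theta = as.numeric(truth$theta),
                              tx = as.integer(truth$tx),
                              ty = as.integer(truth$ty))),
            class = "phantom_spec")
}

#' Generate the phantom volume
#'
#' Sums `n_blobs` axis-aligned anisotropic 3D Gaussian blobs with seeded
#' random centers, widths and amplitudes, then min-max scales to `[0, 255]`
#' and quantizes to 8-bit.  Blob widths along z span at least two slices, so
#' consecutive slices are correlated but not identical -- emulating smooth
#' anatomy sampled along the cut direction.
#'
#' @param spec `phantom_spec` object.
#' @return `[y, x, k]` integer array (see [volume3d()]).
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  w <- spec$width
  h <- spec$height
  d <- spec$depth
  xs <- 0:(w - 1)
  ys <- 0:(h - 1)
  zs <- 0:(d - 1)
  acc <- withr::with_seed(spec$seed, {
    a <- array(0, dim = c(h, w, d))
    for (b in seq_len(spec$n_blobs)) {
      cx <- runif(1, 0, w - 1)
      cy <- runif(1, 0, h - 1)
      cz <- runif(1, 0, d - 1)
      sx <- runif(1, w / 10, w / 4)
      sy <- runif(1, h / 10, h / 4)
      sz <- runif(1, 2, max(2.5, d / 6))
      amp <- runif(1, 0.5, 1.5)
      gx <- exp(-(xs - cx)^2 / (2 * sx^2))
      gy <- exp(-(ys - cy)^2 / (2 * sy^2))
      gz <- exp(-(zs - cz)^2 / (2 * sz^2))
      a <- a + amp * outer(outer(gy, gx), gz)
    }
    a
  })
  rng <- range(acc)
  if (rng[2] == rng[1]) {
    slicereg_error("degenerate phantom: constant volume",
                   "slicereg_domain_error")
  }
  volume3d(round((acc - rng[1]) / (rng[2] - rng[1]) * 255))
}

#' Intensity lookup tables simulating a modality change
#'
#' All LUTs map the 8-bit alphabet onto itself; `apply_lut()` remaps an
#' image through one.
#'
#' * `identity_lut()`: `v -> v`.
#' * `gamma_lut(gamma)`: `v -> round(255 (v/255)^gamma)` -- a smooth
#'   nonlinear contrast change; quantization can merge neighbouring levels,
#'   so it is monotone but not necessarily injective.
#' * `random_monotone_lut(seed)`: piecewise-linear interpolation through
#'   seeded sorted random knots.  The underlying real-valued map is strictly
#'   increasing (a vanishing-slope repair term is added); after 8-bit
#'   quantization the integer table is monotone non-decreasing (a strictly
#'   increasing integer self-map of 256 levels could only be the identity).
#' * `random_permutation_lut(seed)`: a seeded random bijection of the 256
#'   gray levels -- the adversarial multimodal case, defeating every
#'   intensity-difference metric while leaving NMI unchanged.
#'
#' @param gamma exponent of the gamma curve (default 0.6).
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return integer vector of length 256: element `v + 1` is the image of
#'   gray value `v`.
#' @name luts
NULL

#' @rdname luts
#' @export
identity_lut <- function() 0:255

#' @rdname luts
#' @export
gamma_lut <- function(gamma = 0.6) {
  as.integer(round(255 * ((0:255) / 255)^gamma))
}

#' @rdname luts
#' @export
random_monotone_lut <- function(seed = NULL) {
  build <- function() {
    kx <- c(0, sort(runif(6, 0, 255)), 255)
    ky <- c(0, sort(runif(6, 0, 255)), 255)
    y <- approx(kx, ky, xout = 0:255, ties = "ordered")$y
    # strictness repair on the real-valued map before quantization
    y <- y + (0:255) * 1e-6
    as.integer(pmin(pmax(round(y), 0), 255))
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' @rdname luts
#' @export
random_permutation_lut <- function(seed = NULL) {
  build <- function() as.integer(sample(0:255))
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' @rdname luts
#' @param image `[y, x]` 8-bit matrix.
#' @param lut integer vector of length 256 with values in `[0, 255]`.
#' @export
apply_lut <- function(image, lut) {
  img <- image2d(image)
  if (length(lut) != 256L || any(lut < 0) || any(lut > 255)) {
    slicereg_error("lut must map [0,255] into [0,255]",
                   "slicereg_domain_error")
  }
  matrix(as.integer(lut)[img + 1L], nrow(img), ncol(img))
}

build_lut <- function(kind, gamma = 0.6) {
  switch(kind,
         identity = identity_lut(),
         gamma = gamma_lut(gamma),
         random_monotone = random_monotone_lut(),
         random_permutation = random_permutation_lut(),
         slicereg_error(paste("unknown lut_kind:", kind),
                        "slicereg_domain_error"))
}

#' Manufacture the floating image of a phantom
#'
#' Extracts slice `truth$k`, applies the forward ground-truth pose with
#' [rigid_resample()] (nearest interpolation; the registration must recover
#' exactly this grid point), remaps intensities through the LUT, then adds
#' seeded Gaussian noise, clamped and re-quantized to `[0, 255]`.  Noise is
#' added after the remap, modelling detector noise on the second modality.
#'
#' @param volume `[y, x, k]` integer array.
#' @param truth ground-truth pose: list with `k`, `theta`, `tx`, `ty`.
#' @param lut_kind see [phantom_spec()].
#' @param noise_sigma Gaussian noise SD in gray levels.
#' @param seed seed driving both the LUT randomness and the noise.
#' @param gamma exponent when `lut_kind = "gamma"`.
#' @return `[y, x]` integer matrix.
#' @export
make_floating <- function(volume, truth, lut_kind = "identity",
                          noise_sigma = 0, seed = 1L, gamma = 0.6) {
  slice <- extract_slice(volume, truth$k)
  warped <- rigid_resample(slice, truth$theta, truth$tx, truth$ty,
                           interpolation = "nearest")$image
  withr::with_seed(as.integer(seed), {
    img <- apply_lut(warped, build_lut(lut_kind, gamma))
    if (noise_sigma > 0) {
      img <- matrix(
        as.integer(pmin(pmax(round(img + rnorm(length(img), 0, noise_sigma)),
                             0), 255)),
        nrow(img), ncol(img))
    }
    img
  })
}

#' Generate a complete phantom (volume + floating image + truth)
#'
#' @param spec `phantom_spec` object.
#' @return list with `volume`, `floating`, `truth` and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vol <- generate_volume(spec)
  flo <- make_floating(vol, spec$truth, spec$lut_kind, spec$noise_sigma,
                       seed = spec$seed)
  list(volume = vol, floating = flo, truth = spec$truth, spec = spec)
}
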