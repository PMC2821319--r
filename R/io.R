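#' Read a 2D image file
#'
#' PNG or TIFF, 8-bit grayscale or RGB(A); RGB is converted to grayscale
#' with [to_grayscale()].
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return `[y, x]` integer matrix.
#' @export
read_image2d <- function(path) {
  if (!file.exists(path)) {
    slicereg_error(paste("cannot read image:", path), "slicereg_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                slicereg_error(paste("unsupported image format:", path),
                               "slicereg_format_error"))
  to_grayscale(round(raw * 255))
}

#' Write a 2D image file (8-bit grayscale PNG or TIFF)
#'
#' @param image `[y, x]` 8-bit matrix.
#' @param path output path ending in .png, .tif or .tiff.
#' @export
write_image2d <- function(image, path) {
  img <- image2d(image)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(img / 255, path),
         tif = ,
         tiff = tiff::writeTIFF(img / 255, path, bits.per.sample = 8L),
         slicereg_error(paste("unsupported image format:", path),
                        "slicereg_format_error"))
  invisible(path)
}

#' Read a 3D volume
#'
#' Accepts a NIfTI file (.nii / .nii.gz) or a directory of equally sized
#' PNG/TIFF slices, stacked in lexicographic filename order.  Sources that
#' are not already 8-bit integers are min-max rescaled to `[0, 255]` with a
#' warning.
#'
#' @param path NIfTI file or slice directory.
#' @return `[y, x, k]` integer array.
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (length(files) == 0L) {
      slicereg_error(paste("no image slices found in", path),
                     "slicereg_format_error")
    }
    slices <- vector("list", length(files))
    ref <- NULL
    for (i in seq_along(files)) {
      s <- read_image2d(files[i])
      if (is.null(ref)) {
        ref <- dim(s)
      } else if (!identical(dim(s), ref)) {
        slicereg_error(sprintf("slice %s has size %dx%d, expected %dx%d",
                               basename(files[i]), ncol(s), nrow(s),
                               ref[2], ref[1]),
                       "slicereg_format_error")
      }
      slices[[i]] <- s
    }
    return(volume3d(slices))
  }
  if (!file.exists(path)) {
    slicereg_error(paste("cannot read volume:", path), "slicereg_io_error")
  }
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 3L) {
    slicereg_error("NIfTI volume must be 3-dimensional",
                   "slicereg_format_error")
  }
  if (anyNA(arr) || any(arr != round(arr)) || min(arr) < 0 || max(arr) > 255) {
    warning("volume is not 8-bit; min-max rescaling to [0, 255]")
    rng <- range(arr)
    arr <- if (rng[2] > rng[1]) {
      round((arr - rng[1]) / (rng[2] - rng[1]) * 255)
    } else {
      array(0, dim(arr))
    }
  }
  # NIfTI stores [x, y, z]; internal layout is [y, x, k]
  volume3d(aperm(arr, c(2, 1, 3)))
}

#' Write a 3D volume
#'
#' A path ending in .nii or .nii.gz writes a uint8 NIfTI file; any other
#' path is treated as a directory and one PNG per slice
#' (`slice_0001.png`, ...) is written.
#'
#' @param volume `[y, x, k]` integer array.
#' @param path output NIfTI file or directory.
#' @export
write_volume <- function(volume, path) {
  vol <- volume3d(volume)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(aperm(vol, c(2, 1, 3)), path, datatype = "uint8")
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(dim(vol)[3])) {
      write_image2d(vol[, , k], file.path(path, sprintf("slice_%04d.png", k)))
    }
  }
  invisible(path)
}

result_to_list <- function(result) {
  stopifnot(inherits(result, "registration_result"))
  per <- lapply(result$per_slice, function(r) {
    list(k = r$k, theta = r$theta, tx = r$tx, ty = r$ty, score = r$score,
         evaluations = r$evaluations, skipped = r$skipped)
  })
  b <- result$best
  list(best = list(k = b$k, theta = b$theta, tx = b$tx, ty = b$ty,
                   score = b$score, metric = result$metric),
       per_slice = per,
       search_space = unclass(result$space),
       metric = result$metric,
       interpolation = result$interpolation,
       software_version = as.character(packageVersion("slicereg")))
}

#' Write a registration result as JSON
#'
#' The document holds the best pose, the per-slice table, the search space
#' and a config echo, and round-trips losslessly through [read_result()].
#'
#' @param result `registration_result` object.
#' @param path output path.
#' @export
write_result <- function(result, path) {
  jsonlite::write_json(result_to_list(result), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a registration result written by [write_result()]
#'
#' @param path JSON file.
#' @return `registration_result` object.
#' @export
read_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  mk_slice <- function(r) {
    structure(list(k = as.integer(r$k), theta = as.numeric(r$theta),
                   tx = as.integer(r$tx), ty = as.integer(r$ty),
                   score = as.numeric(r$score), metric = x$metric,
                   evaluations = as.numeric(r$evaluations),
                   skipped = as.numeric(r$skipped)),
              class = "slice_result")
  }
  per <- lapply(x$per_slice, mk_slice)
  sp <- x$search_space
  space <- search_space(tx = unlist(sp$tx), ty = unlist(sp$ty),
                        theta = unlist(sp$theta), tx_step = sp$tx_step,
                        ty_step = sp$ty_step, theta_step = sp$theta_step,
                        min_overlap = sp$min_overlap)
  best_k <- as.integer(x$best$k)
  structure(list(best = per[[best_k]], per_slice = per, space = space,
                 metric = x$metric, interpolation = x$interpolation),
            class = "registration_result")
}

#' Read a YAML run configuration
#'
#' Recognized keys: `volume`, `floating`, `out`, `tx`, `ty`, `theta`
#' (2-element min/max), `tx_step`, `ty_step`, `theta_step`, `min_overlap`,
#' `metric`, `interpolation`, `workers`.  Missing keys fall back to package
#' defaults.
#'
#' @param path YAML file.
#' @param overrides named list taking precedence over file values (CLI
#'   flags).
#' @return named list (a run config).
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  for (nm in names(overrides)) {
    if (!is.null(overrides[[nm]])) cfg[[nm]] <- overrides[[nm]]
  }
  defaults <- list(tx = c(-30, 30), ty = c(-30, 30), theta = c(-20, 20),
                   tx_step = 1, ty_step = 1, theta_step = 1,
                   min_overlap = 0.25, metric = "nmi",
                   interpolation = "nearest", workers = 1)
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  }
  cfg
}

#' Run a full registration from a config
#'
#' Reads the volume and floating image, resolution-matches the floating
#' image to the slice size by [to_grayscale()] + [downscale()] when needed,
#' runs [align_2d3d()] and optionally writes the JSON result.
#'
#' @param config list as returned by [read_run_config()].
#' @return `registration_result` (invisibly when `config$out` is set).
#' @export
run_registration <- function(config) {
  vol <- read_volume(config$volume)
  flo <- read_image2d(config$floating)
  d <- dim(vol)
  if (nrow(flo) != d[1] || ncol(flo) != d[2]) {
    if (nrow(flo) < d[1] || ncol(flo) < d[2]) {
      slicereg_error("floating image is smaller than the volume slices",
                     "slicereg_domain_error")
    }
    message(sprintf("downscaling floating image %dx%d -> %dx%d",
                    ncol(flo), nrow(flo), d[2], d[1]))
    flo <- downscale(flo, d[2], d[1])
  }
  space <- search_space(tx = config$tx, ty = config$ty, theta = config$theta,
                        tx_step = config$tx_step, ty_step = config$ty_step,
                        theta_step = config$theta_step,
                        min_overlap = config$min_overlap)
  res <- align_2d3d(vol, flo, space, metric = config$metric,
                    workers = config$workers,
                    interpolation = config$interpolation)
  if (!is.null(config$out)) {
    write_result(res, config$out)
    return(invisible(res))
  }
  res
}
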