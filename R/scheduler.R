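#' Run per-slice alignment jobs through a dynamic worker pool
#'
#' Each slice of the volume is one independent job: align the floating image
#' to that slice over the full search grid.  Jobs are pulled from a dynamic
#' queue (`parallel::mclapply` with `mc.preschedule = FALSE`), so a free
#' worker always takes the next pending slice -- tolerant of heterogeneous
#' per-slice cost.  The merged result is keyed by slice number and is
#' identical, entry for entry, to a sequential loop: completion order never
#' influences the output, and any worker count yields byte-identical
#' results.  A failing job propagates as an error naming the slice.
#'
#' @param volume `[y, x, k]` integer array.
#' @param floating `[y, x]` 8-bit matrix.
#' @param space `search_space` object.
#' @param metric `"nmi"` or `"cross_correlation"`.
#' @param workers number of worker processes, `>= 1`.
#' @param interpolation `"nearest"` or `"bilinear"`.
#' @param .job alignment function `(k) -> slice_result` used for one slice;
#'   overridable for testing the queue contract, defaults to [align_2d2d()]
#'   on `extract_slice(volume, k)`.
#' @return list of `slice_result`, element `k` for slice `k`.
#' @export
run_jobs <- function(volume, floating, space, metric = "nmi", workers = 1L,
                     interpolation = "nearest", .job = NULL) {
  if (length(workers) != 1L || is.na(workers) || workers < 1) {
    slicereg_error("workers must be >= 1", "slicereg_domain_error")
  }
  workers <- as.integer(workers)
  depth <- dim(volume)[3]
  job <- .job %||% function(k) {
    align_2d2d(extract_slice(volume, k), floating, space, metric,
               interpolation)
  }
  safe_job <- function(k) {
    tryCatch({
      r <- job(k)
      r$k <- as.integer(k)
      r
    }, error = function(e) {
      structure(list(k = k, message = conditionMessage(e)),
                class = "slicereg_job_failure")
    })
  }
  out <- if (workers == 1L) {
    lapply(seq_len(depth), safe_job)
  } else {
    parallel::mclapply(seq_len(depth), safe_job, mc.cores = workers,
                       mc.preschedule = FALSE)
  }
  for (k in seq_len(depth)) {
    r <- out[[k]]
    if (inherits(r, "slicereg_job_failure")) {
      slicereg_error(sprintf("alignment job for slice %d failed: %s",
                             k, r$message),
                     "slicereg_job_failure_error")
    }
    if (inherits(r, "try-error") || is.null(r)) {
      slicereg_error(sprintf("worker crashed on slice %d", k),
                     "slicereg_job_failure_error")
    }
  }
  out
}
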