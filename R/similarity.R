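#' Joint intensity histogram of two 8-bit images
#'
#' Counts co-occurring gray-value pairs `(t, f)` of the target and floating
#' image over the valid overlap: `counts[t+1, f+1]` is the number of pixels
#' where the mask is `TRUE`, the target holds `t` and the floating holds
#' `f`.  Normalizing by the number of valid pairs `n` gives the joint
#' probability `p_TF(t, f)`; its row and column sums are the marginal
#' distributions `p_T(t)` and `p_F(f)`.  Bins are fixed at 256 x 256 over
#' the 8-bit alphabet.
#'
#' @param target,floating `[y, x]` 8-bit matrices of identical size.
#' @param mask logical matrix of the same size, or `NULL` for all-valid.
#' @return object of class `joint_histogram`: list with `counts` (256 x 256
#'   integer), `n`, `p_joint`, `p_target`, `p_floating`.
#' @export
joint_histogram <- function(target, floating, mask = NULL) {
  t_img <- image2d(target)
  f_img <- image2d(floating)
  if (!identical(dim(t_img), dim(f_img))) {
    slicereg_error("target and floating dimensions differ",
                   "slicereg_domain_error")
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(t_img), ncol(t_img))
  }
  if (!is.logical(mask) || !identical(dim(mask), dim(t_img))) {
    slicereg_error("mask must be a logical matrix matching the images",
                   "slicereg_domain_error")
  }
  tv <- t_img[mask]
  fv <- f_img[mask]
  n <- length(tv)
  if (n == 0L) {
    slicereg_error("empty overlap: no valid pixel pairs",
                   "slicereg_empty_overlap")
  }
  counts <- matrix(tabulate(tv * 256L + fv + 1L, nbins = 65536L),
                   nrow = 256L, byrow = TRUE)
  as_joint_histogram(counts)
}

#' Build a joint histogram object from a matrix of counts
#'
#' Smaller matrices are embedded in the top-left corner of the 256 x 256
#' table (value `i-1` in row/column `i`).
#'
#' @param counts non-negative integer matrix, at most 256 x 256.
#' @return `joint_histogram` object.
#' @export
as_joint_histogram <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    slicereg_error("counts must be non-negative integers",
                   "slicereg_domain_error")
  }
  if (nrow(counts) > 256L || ncol(counts) > 256L) {
    slicereg_error("at most 256 x 256 bins", "slicereg_domain_error")
  }
  full <- matrix(0L, 256L, 256L)
  full[seq_len(nrow(counts)), seq_len(ncol(counts))] <- as.integer(counts)
  n <- sum(full)
  if (n < 1L) {
    slicereg_error("histogram must contain at least one pair",
                   "slicereg_empty_overlap")
  }
  p <- full / n
  structure(list(counts = full, n = n, p_joint = p,
                 p_target = rowSums(p), p_floating = colSums(p)),
            class = "joint_histogram")
}

assert_joint_histogram <- function(h) {
  if (!inherits(h, "joint_histogram")) {
    slicereg_error("expected a joint_histogram object",
                   "slicereg_domain_error")
  }
  invisible(h)
}

#' Shannon entropy in bits
#'
#' `-sum(p * log2(p))` with the `0 * log 0 = 0` convention.  Accepts a
#' probability vector or matrix (a joint distribution).
#'
#' @param p non-negative values summing to 1 (tolerance 1e-9).
#' @return entropy in bits, `>= 0`.
#' @export
shannon_entropy <- function(p) {
  p <- as.numeric(p)
  if (anyNA(p) || any(p < 0)) {
    slicereg_error("probabilities must be non-negative",
                   "slicereg_domain_error")
  }
  if (abs(sum(p) - 1) > 1e-9) {
    slicereg_error("probabilities must sum to 1", "slicereg_domain_error")
  }
  pos <- p[p > 0]
  -sum(pos * log2(pos))
}

#' Mutual information of a joint histogram (bits)
#'
#' The Kullback-Leibler divergence between the joint distribution and the
#' product of its marginals:
#' `MI = sum p_TF(t,f) log2( p_TF(t,f) / (p_T(t) p_F(f)) )`, zero-probability
#' terms contributing 0.  Equals `H(T) + H(F) - H(T,F)`.
#'
#' @param h `joint_histogram` object.
#' @return mutual information in bits, `>= 0`.
#' @export
mutual_information <- function(h) {
  assert_joint_histogram(h)
  p <- h$p_joint
  idx <- which(p > 0, arr.ind = TRUE)
  pj <- p[idx]
  sum(pj * log2(pj / (h$p_target[idx[, 1]] * h$p_floating[idx[, 2]])))
}

#' Normalized mutual information of a joint histogram
#'
#' The entropy-ratio normalization `NMI = (H(T) + H(F)) / H(T,F)`, bounded
#' in `[1, 2]`: 1 for independent images, 2 for images related by a
#' bijective gray-level mapping.  When the overlap is constant on both sides
#' (`H(T,F) = 0`) the supremum 2 is returned by convention; combined with
#' the search's minimum-overlap guard this degenerate case never decides a
#' real registration.
#'
#' Because NMI depends on the joint distribution only through probabilities,
#' it is invariant under any bijective relabeling of either image's gray
#' levels -- the property that makes it suitable for multimodal data.
#'
#' @param h `joint_histogram` object.
#' @return NMI value in `[1, 2]`.
#' @export
normalized_mutual_information <- function(h) {
  assert_joint_histogram(h)
  htf <- shannon_entropy(h$p_joint)
  if (htf == 0) {
    return(2)
  }
  (shannon_entropy(h$p_target) + shannon_entropy(h$p_floating)) / htf
}

#' Pearson cross-correlation of two images over a valid mask
#'
#' @param target,floating `[y, x]` 8-bit matrices of identical size.
#' @param mask logical matrix or `NULL` for all-valid.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
cross_correlation <- function(target, floating, mask = NULL) {
  t_img <- image2d(target)
  f_img <- image2d(floating)
  if (!identical(dim(t_img), dim(f_img))) {
    slicereg_error("target and floating dimensions differ",
                   "slicereg_domain_error")
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(t_img), ncol(t_img))
  }
  tv <- as.numeric(t_img[mask])
  fv <- as.numeric(f_img[mask])
  if (length(tv) < 2L) {
    slicereg_error("need at least 2 valid pixels", "slicereg_degenerate_input")
  }
  if (var(tv) == 0 || var(fv) == 0) {
    slicereg_error("zero variance on the valid overlap",
                   "slicereg_degenerate_input")
  }
  cor(tv, fv)
}

#' @importFrom stats var
NULL
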