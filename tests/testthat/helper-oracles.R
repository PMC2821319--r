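# Independent naive reference implementations used to cross-check the
# package; deliberately written with explicit loops and no shared code with
# the implementation under test.

rand_img <- function(h, w) {
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

# per-pixel joint co-occurrence counting by explicit loops
oracle_joint_counts <- function(target, floating, mask = NULL) {
  if (is.null(mask)) mask <- matrix(TRUE, nrow(target), ncol(target))
  counts <- matrix(0, 256, 256)
  for (y in seq_len(nrow(target))) {
    for (x in seq_len(ncol(target))) {
      if (mask[y, x]) {
        tt <- target[y, x]
        ff <- floating[y, x]
        counts[tt + 1, ff + 1] <- counts[tt + 1, ff + 1] + 1
      }
    }
  }
  counts
}

# term-by-term Kullback-Leibler / entropy sums over the observed gray levels
oracle_scores <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  pt <- rowSums(p)
  pf <- colSums(p)
  mi <- 0
  htf <- 0
  for (t in which(pt > 0)) {
    for (f in which(pf > 0)) {
      if (p[t, f] > 0) {
        mi <- mi + p[t, f] * log2(p[t, f] / (pt[t] * pf[f]))
        htf <- htf - p[t, f] * log2(p[t, f])
      }
    }
  }
  ht <- 0
  for (q in pt) if (q > 0) ht <- ht - q * log2(q)
  hf <- 0
  for (q in pf) if (q > 0) hf <- hf - q * log2(q)
  list(mi = mi, nmi = if (htf == 0) 2 else (ht + hf) / htf,
       ht = ht, hf = hf, htf = htf)
}

oracle_counts_embed <- function(counts) {
  full <- matrix(0, 256, 256)
  full[seq_len(nrow(counts)), seq_len(ncol(counts))] <- counts
  full
}

oracle_nmi <- function(target, floating, mask = NULL) {
  oracle_scores(oracle_joint_counts(target, floating, mask))$nmi
}

# pixel-by-pixel nearest-neighbour rigid resampler (0-based geometry,
# rotation about ((w-1)/2, (h-1)/2), rotate-then-translate forward pose)
oracle_resample <- function(img, theta, tx, ty, invert = FALSE) {
  h <- nrow(img)
  w <- ncol(img)
  cx <- (w - 1) / 2
  cy <- (h - 1) / 2
  a <- theta * pi / 180
  out <- matrix(0L, h, w)
  mask <- matrix(FALSE, h, w)
  for (y0 in 0:(h - 1)) {
    for (x0 in 0:(w - 1)) {
      if (!invert) {
        dx <- x0 - cx - tx
        dy <- y0 - cy - ty
        sx <- cos(a) * dx + sin(a) * dy + cx
        sy <- -sin(a) * dx + cos(a) * dy + cy
      } else {
        dx <- x0 - cx
        dy <- y0 - cy
        sx <- cos(a) * dx - sin(a) * dy + cx + tx
        sy <- sin(a) * dx + cos(a) * dy + cy + ty
      }
      ix <- round(sx)
      iy <- round(sy)
      if (ix >= 0 && ix < w && iy >= 0 && iy < h) {
        out[y0 + 1, x0 + 1] <- img[iy + 1, ix + 1]
        mask[y0 + 1, x0 + 1] <- TRUE
      }
    }
  }
  list(image = out, mask = mask)
}

# exhaustive triple-loop 2D/3D reference: slices ascending, grid in
# ascending (theta, ty, tx) order, first strict maximum wins
oracle_align_2d3d <- function(volume, floating, thetas, txs, tys,
                              min_overlap = 0.25) {
  depth <- dim(volume)[3]
  npix <- dim(volume)[1] * dim(volume)[2]
  per <- vector("list", depth)
  best <- NULL
  for (k in seq_len(depth)) {
    slice <- volume[, , k]
    kb <- NULL
    for (theta in thetas) {
      for (ty in tys) {
        for (tx in txs) {
          r <- oracle_resample(floating, theta, tx, ty, invert = TRUE)
          if (sum(r$mask) < ceiling(min_overlap * npix)) next
          s <- oracle_nmi(slice, r$image, r$mask)
          if (is.null(kb) || s > kb$score) {
            kb <- list(k = k, theta = theta, tx = tx, ty = ty, score = s)
          }
        }
      }
    }
    per[[k]] <- kb
    if (!is.null(kb) && (is.null(best) || kb$score > best$score)) {
      best <- kb
    }
  }
  list(best = best, per_slice = per)
}

# small smooth phantom shared by several tests
ci_phantom <- function(seed = 1, truth = list(k = 12L, theta = 3, tx = 2L,
                                              ty = -1L),
                       lut_kind = "identity", noise_sigma = 0) {
  generate_phantom(phantom_spec(seed = seed, truth = truth,
                                lut_kind = lut_kind,
                                noise_sigma = noise_sigma))
}

# seeded random ground-truth pose inside the +/-5 px / +/-5 deg box
random_truth <- function(seed, depth = 32L) {
  withr::with_seed(seed, list(k = sample(4:(depth - 4), 1),
                              theta = sample(-5:5, 1),
                              tx = sample(-5:5, 1),
                              ty = sample(-5:5, 1)))
}

recovery_space <- function() {
  search_space(tx = c(-6L, 6L), ty = c(-6L, 6L), theta = c(-6, 6))
}
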