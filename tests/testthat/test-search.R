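test_that("grid enumeration has the documented size and scan order", {
  expect_equal(nrow(grid_points(search_space())), 61 * 61 * 41)
  degenerate <- search_space(tx = c(2, 2), ty = c(-1, -1), theta = c(5, 5))
  expect_equal(nrow(grid_points(degenerate)), 1)
  g <- grid_points(search_space(tx = c(-1, 1), ty = c(0, 0),
                                theta = c(0, 0)))
  expect_equal(g$theta, c(0, 0, 0))
  expect_equal(g$ty, c(0, 0, 0))
  expect_equal(g$tx, c(-1, 0, 1))
  # theta slowest, then ty, then tx
  g2 <- grid_points(search_space(tx = c(0, 1), ty = c(0, 1),
                                 theta = c(0, 1)))
  expect_equal(g2$theta, c(0, 0, 0, 0, 1, 1, 1, 1))
  expect_equal(g2$ty, c(0, 0, 1, 1, 0, 0, 1, 1))
  expect_equal(g2$tx, c(0, 1, 0, 1, 0, 1, 0, 1))
  # steps shrink the grid per axis
  expect_equal(nrow(grid_points(search_space(tx = c(-4, 4), ty = c(0, 0),
                                             theta = c(0, 0),
                                             tx_step = 2))), 5)
})

test_that("aligning an image to itself returns the identity pose", {
  # a coarse gray alphabet avoids accidental value-bijective poses (which
  # would legitimately tie at NMI = 2), and 64x64 is large enough that a
  # 1-degree rotation moves at least one pixel
  set.seed(19)
  img <- matrix(sample(c(0L, 51L, 102L, 153L, 204L, 255L), 64 * 64,
                       replace = TRUE), 64, 64)
  sp <- search_space(tx = c(-3, 3), ty = c(-3, 3), theta = c(-3, 3))
  r <- align_2d2d(img, img, sp)
  expect_equal(r$theta, 0)
  expect_equal(r$tx, 0)
  expect_equal(r$ty, 0)
  expect_equal(r$score, 2)
  expect_equal(r$evaluations + r$skipped, nrow(grid_points(sp)))
})

test_that("a single-point space returns that pose with its recomputed score", {
  set.seed(21)
  t_img <- rand_img(12, 12)
  f_img <- rand_img(12, 12)
  sp <- search_space(tx = c(3, 3), ty = c(-2, -2), theta = c(5, 5))
  r <- align_2d2d(t_img, f_img, sp)
  expect_equal(c(r$theta, r$tx, r$ty), c(5, 3, -2))
  expect_equal(r$score, score_pose(t_img, f_img, 5, 3, -2),
               tolerance = 1e-12)
  expect_equal(r$evaluations, 1)
})

test_that("the reported score equals re-evaluating the metric at the pose", {
  ph <- ci_phantom(seed = 4, truth = list(k = 7L, theta = -2, tx = 1L,
                                          ty = 3L))
  sp <- search_space(tx = c(-4, 4), ty = c(-4, 4), theta = c(-4, 4))
  target <- extract_slice(ph$volume, 7)
  for (metric in c("nmi", "cross_correlation")) {
    r <- align_2d2d(target, ph$floating, sp, metric = metric)
    expect_equal(r$score,
                 score_pose(target, ph$floating, r$theta, r$tx, r$ty, metric),
                 tolerance = 1e-10)
  }
})

test_that("a forward-constructed pose is recovered by the exhaustive search", {
  vol <- generate_volume(phantom_spec(width = 24, height = 24, depth = 8,
                                      n_blobs = 4, seed = 3))
  target <- extract_slice(vol, 5)
  f_img <- rigid_resample(target, 5, 3, -2)$image
  sp <- search_space(tx = c(-10, 10), ty = c(-10, 10), theta = c(-10, 10))
  r <- align_2d2d(target, f_img, sp)
  expect_lte(abs(r$theta - 5), 1)
  expect_lte(abs(r$tx - 3), 1)
  expect_lte(abs(r$ty + 2), 1)
})

test_that("enlarging the search space never decreases the best score", {
  set.seed(31)
  t_img <- rand_img(16, 16)
  f_img <- rigid_resample(t_img, 2, 1, -1)$image
  scores <- sapply(1:4, function(half) {
    sp <- search_space(tx = c(-half, half), ty = c(-half, half),
                       theta = c(-half, half))
    align_2d2d(t_img, f_img, sp)$score
  })
  expect_true(all(diff(scores) >= -1e-12))
})

test_that("search is deterministic and errors when every point is skipped", {
  set.seed(41)
  t_img <- rand_img(10, 10)
  f_img <- rand_img(10, 10)
  sp <- search_space(tx = c(-2, 2), ty = c(-2, 2), theta = c(-2, 2))
  r1 <- align_2d2d(t_img, f_img, sp)
  r2 <- align_2d2d(t_img, f_img, sp)
  expect_identical(r1, r2)
  strict <- search_space(tx = c(5, 8), ty = c(5, 8), theta = c(0, 0),
                         min_overlap = 1)
  expect_error(align_2d2d(t_img, f_img, strict),
               class = "slicereg_no_valid_candidate")
})

test_that("2D/3D alignment finds the source slice of an extracted image", {
  vol <- generate_volume(phantom_spec(width = 16, height = 16, depth = 8,
                                      n_blobs = 4, seed = 6))
  # translation-only space: sub-degree rotations of a 16x16 image alias to
  # the identity pixel map and would tie with the true pose
  sp <- search_space(tx = c(-2, 2), ty = c(-2, 2), theta = c(0, 0))
  res <- align_2d3d(vol, extract_slice(vol, 3), sp)
  expect_equal(res$best$k, 3)
  expect_equal(c(res$best$theta, res$best$tx, res$best$ty), c(0, 0, 0))
  expect_equal(length(res$per_slice), 8)
  # best is the maximum of the per-slice scores
  expect_equal(res$best$score, max(sapply(res$per_slice, `[[`, "score")))
  # a depth-1 volume always matches its only slice
  v1 <- vol[, , 3, drop = FALSE]
  res1 <- align_2d3d(v1, extract_slice(vol, 3), sp)
  expect_equal(res1$best$k, 1)
  expect_error(align_2d3d(vol, rand_img(4, 4), sp),
               class = "slicereg_domain_error")
})
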