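test_that("joint histogram counts co-occurring gray-value pairs exactly", {
  t_img <- matrix(c(0L, 255L, 0L, 255L), 2, 2)
  f_img <- matrix(c(0L, 255L, 0L, 255L), 2, 2)
  h <- joint_histogram(t_img, f_img)
  expect_equal(h$n, 4)
  expect_equal(h$counts[1, 1], 2L)
  expect_equal(h$counts[256, 256], 2L)
  expect_equal(sum(h$counts), 4L)

  t2 <- matrix(c(0L, 0L, 255L, 255L), 2, 2, byrow = TRUE)
  f2 <- matrix(c(0L, 255L, 0L, 255L), 2, 2, byrow = TRUE)
  h2 <- joint_histogram(t2, f2)
  expect_equal(h2$counts[1, 1], 1L)
  expect_equal(h2$counts[1, 256], 1L)
  expect_equal(h2$counts[256, 1], 1L)
  expect_equal(h2$counts[256, 256], 1L)

  m <- matrix(TRUE, 2, 2)
  m[1, 1] <- FALSE
  expect_equal(joint_histogram(t2, f2, m)$n, 3)
  expect_error(joint_histogram(t2, f2, matrix(FALSE, 2, 2)),
               class = "slicereg_empty_overlap")
  expect_error(joint_histogram(t2, rand_img(3, 3)),
               class = "slicereg_domain_error")
})

test_that("joint histogram normalization and marginals are exact", {
  set.seed(3)
  a <- rand_img(8, 8)
  b <- rand_img(8, 8)
  m <- matrix(sample(c(TRUE, FALSE), 64, replace = TRUE, prob = c(.8, .2)),
              8, 8)
  h <- joint_histogram(a, b, m)
  expect_equal(sum(h$p_joint), 1, tolerance = 1e-12)
  expect_equal(h$p_target, rowSums(h$p_joint))
  expect_equal(h$p_floating, colSums(h$p_joint))
  # marginals equal the masked per-image 256-bin histograms exactly
  expect_equal(h$p_target * h$n, tabulate(a[m] + 1L, 256L))
  expect_equal(h$p_floating * h$n, tabulate(b[m] + 1L, 256L))
})

test_that("entropy has the closed-form values and the 0 log 0 convention", {
  expect_equal(shannon_entropy(rep(0.25, 4)), 2)
  expect_equal(shannon_entropy(c(1, 0, 0)), 0)
  expect_equal(shannon_entropy(c(0.5, 0.25, 0.25)), 1.5)
  expect_equal(shannon_entropy(matrix(c(0.5, 0.5, 0, 0), 2, 2)), 1)
  expect_error(shannon_entropy(c(0.7, 0.4)), class = "slicereg_domain_error")
  expect_error(shannon_entropy(c(-0.1, 1.1)), class = "slicereg_domain_error")
})

test_that("MI and NMI have their analytic values on canonical joints", {
  diag2 <- as_joint_histogram(matrix(c(5L, 0L, 0L, 5L), 2, 2))
  expect_equal(mutual_information(diag2), 1)
  expect_equal(normalized_mutual_information(diag2), 2)

  prod2 <- as_joint_histogram(matrix(c(1L, 1L, 1L, 1L), 2, 2))
  expect_equal(mutual_information(prod2), 0)
  expect_equal(normalized_mutual_information(prod2), 1)

  # [[0.4, 0.1], [0.1, 0.4]] against the term-by-term KL oracle
  c4 <- matrix(c(4L, 1L, 1L, 4L), 2, 2)
  h4 <- as_joint_histogram(c4)
  o <- oracle_scores(oracle_counts_embed(c4))
  expect_equal(mutual_information(h4), o$mi, tolerance = 1e-12)
  expect_equal(normalized_mutual_information(h4), o$nmi, tolerance = 1e-12)
  expect_equal(mutual_information(h4),
               shannon_entropy(h4$p_target) + shannon_entropy(h4$p_floating) -
                 shannon_entropy(h4$p_joint),
               tolerance = 1e-10)
})

test_that("MI/NMI are symmetric and invariant under gray-level relabeling", {
  set.seed(5)
  a <- rand_img(8, 8)
  b <- rand_img(8, 8)
  h <- joint_histogram(a, b)
  ht <- as_joint_histogram(t(h$counts))
  expect_equal(mutual_information(h), mutual_information(ht),
               tolerance = 1e-12)
  expect_equal(normalized_mutual_information(h),
               normalized_mutual_information(ht), tolerance = 1e-12)
  for (i in 1:5) {
    perm <- random_permutation_lut(seed = i)
    hp <- joint_histogram(a, apply_lut(b, perm))
    expect_equal(normalized_mutual_information(hp),
                 normalized_mutual_information(h), tolerance = 1e-12)
    hq <- joint_histogram(apply_lut(a, perm), b)
    expect_equal(mutual_information(hq), mutual_information(h),
                 tolerance = 1e-12)
  }
})

test_that("MI and NMI respect their information-theoretic bounds", {
  set.seed(9)
  for (i in 1:20) {
    h <- joint_histogram(rand_img(6, 6), rand_img(6, 6))
    mi <- mutual_information(h)
    nmi <- normalized_mutual_information(h)
    expect_gte(mi, 0)
    expect_lte(mi, min(shannon_entropy(h$p_target),
                       shannon_entropy(h$p_floating)) + 1e-12)
    expect_gte(nmi, 1 - 1e-12)
    expect_lte(nmi, 2 + 1e-12)
  }
})

test_that("cross-correlation matches Pearson and flags degenerate inputs", {
  set.seed(13)
  a <- rand_img(6, 6)
  expect_equal(cross_correlation(a, a), 1)
  expect_equal(cross_correlation(a, 255L - a), -1)
  b <- rand_img(6, 6)
  expect_equal(cross_correlation(a, b), cor(as.numeric(a), as.numeric(b)))
  expect_error(cross_correlation(a, matrix(7L, 6, 6)),
               class = "slicereg_degenerate_input")
})
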