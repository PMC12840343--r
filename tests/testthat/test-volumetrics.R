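test_that("compartment volume converts voxel counts to cm^3", {
  expect_equal(compartment_volume(array(1, dim = c(10, 10, 10)), 1), 1.0)
  expect_equal(compartment_volume(array(0, dim = c(5, 5, 5)), 1), 0.0)
  expect_equal(compartment_volume(array(1, dim = c(20, 10, 10)), 0.5), 1.0)
  expect_error(compartment_volume(array(1, dim = c(2, 2, 2)), 0))
})

test_that("two-sided Mann-Whitney follows the midrank exact convention", {
  # perfectly overlapping samples -> p = 1 under the two-sided convention
  res <- compare_volumes(list(a = 1:10, b = 1:10))
  expect_identical(res$test, "mann_whitney_u")
  expect_equal(res$p_value, 1.0)
  # complete separation of 3 vs 3: U = 0, exact two-sided p = 2/20
  res <- compare_volumes(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$p_value, 0.1)
  expect_error(compare_volumes(list(a = 1, b = 1:5)), "at least 2")
})

test_that("exact Mann-Whitney agrees with wilcox.test for tie-free samples", {
  set.seed(42)
  for (rep in 1:20) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    x <- sample(seq_len(100), n1 + n2)  # distinct values, no ties
    ours <- compare_volumes(list(x[seq_len(n1)], x[n1 + seq_len(n2)]))
    ref <- stats::wilcox.test(x[seq_len(n1)], x[n1 + seq_len(n2)],
                              exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("three-group comparison keeps its nominal type-I error", {
  set.seed(7)
  rejections <- vapply(1:1000, function(i) {
    groups <- list(rnorm(20), rnorm(20), rnorm(20))
    compare_volumes(groups)$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.035)
  expect_lte(mean(rejections), 0.065)
})

test_that("center of mass is the mean world coordinate of mask voxels", {
  affine <- diag(c(2, 2, 4, 1)); affine[1:3, 4] <- c(-10, -10, -20)
  m <- array(FALSE, dim = c(11, 11, 11))
  m[4, 6, 2] <- TRUE
  expect_equal(center_of_mass(m, affine),
               affine[1:3, 1:3] %*% c(3, 5, 1) + affine[1:3, 4],
               ignore_attr = TRUE)
  # two voxels symmetric about their midpoint
  m[8, 6, 2] <- TRUE
  expect_equal(center_of_mass(m, affine)[1], (2 * 3 - 10 + 2 * 7 - 10) / 2)
  expect_error(center_of_mass(array(FALSE, dim = c(2, 2, 2)), diag(4)),
               "empty")
})

test_that("center of mass matches a brute-force voxel loop (oracle)", {
  set.seed(11)
  affine <- diag(c(1.5, 1, 2, 1)); affine[1:3, 4] <- c(-5, 3, -7)
  m <- array(runif(8^3) < 0.2, dim = c(8, 8, 8))
  acc <- c(0, 0, 0); n <- 0
  for (i in 1:8) for (j in 1:8) for (k in 1:8) {
    if (m[i, j, k]) {
      acc <- acc + affine[1:3, 1:3] %*% c(i - 1, j - 1, k - 1) + affine[1:3, 4]
      n <- n + 1
    }
  }
  expect_equal(center_of_mass(m, affine), as.numeric(acc / n),
               ignore_attr = TRUE)
})

test_that("hemisphere classification follows RAS and is antisymmetric", {
  expect_identical(classify_hemisphere(c(5, 0, 0), 0), "right")
  expect_identical(classify_hemisphere(c(-5, 0, 0), 0), "left")
  expect_identical(classify_hemisphere(c(0, 12, -4), 0), "midline")
  expect_identical(classify_hemisphere(c(7, 0, 0), midline_x_mm = 10), "left")
  swap <- c(left = "right", right = "left", midline = "midline")
  for (x in c(-20, -0.5, 0, 0.5, 20)) {
    expect_identical(classify_hemisphere(c(-x, 1, 1), 0),
                     unname(swap[classify_hemisphere(c(x, 1, 1), 0)]))
  }
})

test_that("goodness-of-fit laterality test has no continuity correction", {
  expect_equal(laterality_gof(50, 50)$statistic, 0)
  expect_equal(laterality_gof(50, 50)$p_value, 1.0)
  res <- laterality_gof(60, 40)
  expect_equal(res$statistic, 4.0)
  expect_equal(res$p_value, 0.0455, tolerance = 1e-3)
  expect_equal(laterality_gof(60, 40)$p_value, laterality_gof(40, 60)$p_value)
  expect_error(laterality_gof(0, 0), "at least one")
})

test_that("contingency test applies Yates only to 2x2 tables", {
  expect_equal(laterality_contingency(rbind(c(10, 10), c(10, 10)))$statistic, 0)
  expect_equal(laterality_contingency(rbind(c(10, 10), c(10, 10)))$p_value, 1)
  # independent oracle: base chisq.test, both correction regimes
  set.seed(3)
  for (rep in 1:10) {
    t2 <- matrix(sample(5:60, 4), 2, 2)
    ours <- laterality_contingency(t2)
    ref <- stats::chisq.test(t2, correct = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  t3 <- rbind(c(56, 29), c(35, 34), c(26, 28))
  ours <- laterality_contingency(t3)
  ref <- stats::chisq.test(t3, correct = FALSE)
  expect_equal(ours$statistic, 5.50, tolerance = 1e-2)
  expect_identical(ours$df, 2L)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  # row-permutation invariance
  expect_equal(laterality_contingency(t3[c(3, 1, 2), ])$statistic,
               ours$statistic)
  expect_error(laterality_contingency(rbind(c(0, 0), c(3, 4))), "margin")
})

test_that("volume table carries the partition identity per patient", {
  g <- generate_cohort(small_world_spec(31L, groups = c(A = 4L, B = 4L)))
  v <- volume_table(g$volumes, g$cohort)
  expect_equal(v$whole_tumor, v$tumor_core + v$non_enhancing,
               tolerance = 1e-9)
  # volumes tie back to ground-truth voxel counts (1 mm^3 voxels)
  gt <- g$ground_truth$voxel_counts
  expect_equal(v$whole_tumor * 1000,
               gt$necrosis + gt$enhancing + gt$edema)
})

test_that("locate_cohort + hemisphere_counts exclude midline patients", {
  lm <- label_dialect()
  mk <- function(xs) {
    vox <- array(0L, dim = c(9, 5, 5))
    for (x in xs) vox[x, 3, 3] <- lm[["edema"]]
    affine <- diag(4); affine[1, 4] <- -4  # world x = index-1 - 4
    segmentation_volume(vox, affine, lm)
  }
  # centers at world x = -2, +2, 0 (midline)
  vols <- list(mk(3), mk(7), mk(5))
  cohort <- cohort_table(c("L", "R", "M"), c("MES", "MES", "RTK_I"))
  loc <- locate_cohort(vols, cohort, "whole_tumor")
  expect_identical(loc$hemisphere, c("left", "right", "midline"))
  counts <- hemisphere_counts(loc, "subtype", c("MES", "RTK_I"))
  expect_identical(as.vector(counts["MES", ]), c(1L, 1L))
  expect_identical(sum(counts["RTK_I", ]), 0L)
})
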