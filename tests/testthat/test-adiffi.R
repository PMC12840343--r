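test_that("two-sided Fisher p follows the point-probability rule", {
  expect_equal(fisher_two_sided(0, 0, 10, 10), 1.0)
  expect_equal(fisher_two_sided(5, 5, 10, 10), 1.0)
  # enumeration: support {0..5}, sum of point probs <= P(X = 5)
  expect_equal(fisher_two_sided(5, 0, 10, 10), fisher_oracle(5, 0, 10, 10),
               tolerance = 1e-12)
  expect_equal(fisher_two_sided(5, 0, 10, 10), 0.03250774, tolerance = 1e-7)
  expect_error(fisher_two_sided(11, 0, 10, 10), "out of range")
  expect_error(fisher_two_sided(0, -1, 10, 10), "out of range")
})

test_that("Fisher p agrees with the enumeration oracle on random cases", {
  set.seed(5)
  for (rep in 1:200) {
    n1 <- sample(1:25, 1); n2 <- sample(1:25, 1)
    a <- sample(0:n1, 1); b <- sample(0:n2, 1)
    expect_equal(fisher_two_sided(a, b, n1, n2), fisher_oracle(a, b, n1, n2),
                 tolerance = 1e-12)
  }
})

test_that("the p-value lookup table equals the scalar operation", {
  ptab <- fisher_p_table(7, 9)
  for (a in 0:7) for (b in 0:9) {
    expect_identical(ptab[a + 1, b + 1], fisher_two_sided(a, b, 7, 9))
  }
})

test_that("voxel-wise Fisher equals a per-voxel loop on random masks", {
  set.seed(61)
  d <- c(16L, 16L, 16L)
  mk <- function() array(runif(prod(d)) < 0.15, dim = d)
  masks_a <- replicate(8, mk(), simplify = FALSE)
  masks_b <- replicate(8, mk(), simplify = FALSE)
  p_map <- voxelwise_fisher(masks_a, masks_b)
  ca <- Reduce(`+`, masks_a); cb <- Reduce(`+`, masks_b)
  brute <- array(1, dim = d)
  for (v in which(ca + cb > 0)) {
    brute[v] <- fisher_two_sided(ca[v], cb[v], 8, 8)
  }
  expect_equal(p_map, brute)
  # balanced counts on equal group sizes are never suprathreshold
  expect_true(all(p_map[ca == cb] == 1))
  # outside the union mask p is exactly 1
  expect_true(all(p_map[ca + cb == 0] == 1))
})

test_that("group swap leaves the p-map unchanged and negates the differential", {
  g <- generate_cohort(small_world_spec(41L, groups = c(A = 9L, B = 7L)))
  ma <- group_masks(g, "A"); mb <- group_masks(g, "B")
  expect_equal(voxelwise_fisher(ma, mb), voxelwise_fisher(mb, ma))
  fa <- frequency_map(ma, "A"); fb <- frequency_map(mb, "B")
  expect_equal(differential_map(fa, fb)$values,
               -differential_map(fb, fa)$values)
})

test_that("suprathreshold clustering respects connectivity and ordering", {
  d <- c(8L, 8L, 8L)
  p <- array(1, dim = d)
  expect_identical(suprathreshold_clusters(p, 0.005), list())

  # two voxels sharing only a corner
  p <- array(1, dim = d)
  p[2, 2, 2] <- 1e-4; p[3, 3, 3] <- 1e-4
  expect_length(suprathreshold_clusters(p, 0.005, connectivity = 26), 1L)
  expect_length(suprathreshold_clusters(p, 0.005, connectivity = 6), 2L)
  # edge-sharing: one cluster at 18, two at 6
  p <- array(1, dim = d)
  p[2, 2, 2] <- 1e-4; p[3, 3, 2] <- 1e-4
  expect_length(suprathreshold_clusters(p, 0.005, connectivity = 18), 1L)
  expect_length(suprathreshold_clusters(p, 0.005, connectivity = 6), 2L)

  # solid 3x3x3 block
  p <- array(1, dim = d)
  p[3:5, 3:5, 3:5] <- 1e-6
  cl <- suprathreshold_clusters(p, 0.005)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$size, 27L)
  expect_equal(cl[[1]]$min_p, 1e-6)

  # threshold is strict: p exactly at the threshold does not enter
  p <- array(1, dim = d); p[1, 1, 1] <- 0.005
  expect_identical(suprathreshold_clusters(p, 0.005), list())

  # ordering: size descending, ties by smallest linear index
  p <- array(1, dim = d)
  p[6:7, 6, 6] <- 1e-4          # size 2
  p[1, 1, 1] <- 1e-4            # size 1, smallest index
  p[4, 4, 4] <- 1e-4            # size 1
  cl <- suprathreshold_clusters(p, 0.005)
  expect_identical(vapply(cl, `[[`, integer(1), "size"), c(2L, 1L, 1L))
  expect_identical(cl[[2]]$voxels, 1L)
})

test_that("permutation null is deterministic and degenerate without signal", {
  d <- c(8L, 8L, 8L)
  m <- array(FALSE, dim = d); m[3:5, 3:5, 3:5] <- TRUE
  masks <- replicate(10, m, simplify = FALSE)  # identical masks: no signal
  labels <- rep(c("A", "B"), each = 5)
  cfg <- adiffi_config(n_permutations = 15L, seed = 3L)  # < 1/alpha
  expect_warning(null <- permutation_null(masks, labels, cfg),
                 "unreliable")
  expect_identical(null$null_max_sizes, rep(0L, 15L))
  expect_identical(null$cluster_size_threshold, 1L)

  cfg2 <- adiffi_config(n_permutations = 25L, seed = 9L)
  g <- generate_cohort(small_world_spec(8L, groups = c(A = 8L, B = 8L)))
  masks <- c(group_masks(g, "A"), group_masks(g, "B"))
  labels <- g$cohort$subtype
  n1 <- suppressWarnings(permutation_null(masks, labels, cfg2))
  n2 <- suppressWarnings(permutation_null(masks, labels, cfg2))
  expect_identical(n1, n2)
  expect_error(permutation_null(masks, rep("A", 16), cfg2), "two groups")
})

test_that("the cluster-size threshold is the smallest k below alpha exceedance", {
  null <- c(rep(0L, 90), rep(5L, 6), rep(9L, 4))
  # k = 5: 10/100 >= 0.05; k = 6: 4/100 < 0.05
  expect_identical(adiffi:::.size_threshold(null, 0.05), 6L)
  expect_identical(adiffi:::.size_threshold(rep(0L, 100), 0.05), 1L)
})

test_that("adiffi results are internally consistent", {
  g <- generate_cohort(planted_effect_spec(77L, n = 40L))
  cfg <- adiffi_config(n_permutations = 60L, seed = 5L)
  res <- adiffi(group_masks(g, "A"), group_masks(g, "B"), cfg,
                group_labels = c("A", "B"))
  sig <- Filter(function(cl) cl$significant, res$clusters)
  expect_identical(res$n_significant_clusters, length(sig))
  expect_identical(res$n_significant_voxels,
                   sum(vapply(sig, `[[`, numeric(1), "size")))
  expect_equal(res$min_raw_p, min(res$p_map[res$analysis_mask]))
  if (length(res$clusters)) {
    expect_lte(res$min_raw_p, cfg$raw_p_threshold)
    for (cl in res$clusters) {
      expect_true(all(res$p_map[cl$voxels] < cfg$raw_p_threshold))
    }
  }
  # rank consistency: a significant observed max implies its null exceedance
  # frequency is below alpha, i.e. corrected p below alpha + 1/(B+1)
  if (res$n_significant_clusters > 0) {
    obs_max <- res$clusters[[1]]$size
    expect_lt(sum(res$null_max_sizes >= obs_max) /
                length(res$null_max_sizes), cfg$fwe_alpha)
    expect_lt(res$corrected_p, cfg$fwe_alpha + 1 / (cfg$n_permutations + 1))
  }
})

test_that("cluster effect is the relative in-cluster mean frequency difference", {
  d <- c(4L, 4L, 4L)
  fa <- list(values = array(33.9, dim = d))
  fb <- list(values = array(10.0, dim = d))
  expect_equal(cluster_effect(1:5, fa, fb), 239.0)
  expect_equal(cluster_effect(1:5, fa, fa), 0)
  # scale invariance
  fa2 <- list(values = fa$values * 2); fb2 <- list(values = fb$values * 2)
  expect_equal(cluster_effect(1:5, fa2, fb2), cluster_effect(1:5, fa, fb))
  # undefined reference, reported as NA rather than infinity
  f0 <- list(values = array(0, dim = d))
  expect_true(is.na(cluster_effect(1:5, fa, f0)))
})
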