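#' Analysis of differential involvement (ADIFFI)
#'
#' Voxel-wise comparison of lesion presence between two patient groups:
#' Fisher's exact test at every atlas voxel, a raw cluster-forming threshold
#' (default p < 0.005), and family-wise error control by the max-statistic
#' permutation scheme — group labels are randomly reassigned (group sizes
#' preserved), the largest suprathreshold cluster size is recorded per
#' permutation, and the empirical null of max cluster sizes sets the minimum
#' significant cluster size at level `fwe_alpha`.
#'
#' @name adiffi-inference
NULL

#' ADIFFI configuration
#'
#' @param raw_p_threshold cluster-forming raw p-value threshold (strict
#'   inequality; default 0.005).
#' @param n_permutations number of label permutations (default 500).
#' @param connectivity cluster connectivity, 6/18/26 (default 26).
#' @param fwe_alpha family-wise error level for the cluster-size threshold
#'   (default 0.05).
#' @param seed master seed; permutation j uses the substream
#'   `derive_seed(seed, 2, j)`.
#' @return list of class `adiffi_config`.
#' @export
adiffi_config <- function(raw_p_threshold = 0.005, n_permutations = 500L,
                          connectivity = 26L, fwe_alpha = 0.05, seed = 1L) {
  stopifnot(raw_p_threshold > 0, raw_p_threshold < 1, n_permutations >= 1,
            fwe_alpha > 0, fwe_alpha < 1,
            connectivity %in% c(6L, 18L, 26L))
  structure(list(raw_p_threshold = raw_p_threshold,
                 n_permutations = as.integer(n_permutations),
                 connectivity = as.integer(connectivity),
                 fwe_alpha = fwe_alpha, seed = as.integer(seed)),
            class = "adiffi_config")
}

# Internal stacked representation: lesion indicator matrix restricted to the
# analysis mask (rows = in-mask voxels, columns = patients).
.stack_masks <- function(masks, mask_idx) {
  vapply(masks, function(m) as.numeric(m[mask_idx] != 0),
         numeric(length(mask_idx)))
}

.union_mask_idx <- function(masks) {
  u <- masks[[1]] != 0
  for (m in masks[-1]) u <- u | (m != 0)
  which(u)
}

# p-values for in-mask voxels given group-A counts, via table lookup.
.lookup_p <- function(ptab, ca, cb, n1) {
  ptab[ca + 1L + (n1 + 1L) * cb]
}

#' Voxel-wise Fisher's exact test between two groups
#'
#' Each in-mask voxel v is tested with [fisher_two_sided()] on the counts of
#' patients with lesion presence at v in each group; the (n1+1) x (n2+1)
#' p-value table is precomputed so each distinct count pair is evaluated
#' once. Voxels outside the analysis mask carry p = 1.
#'
#' @param masks_a,masks_b lists of logical/0-1 3D masks (one per patient).
#' @param analysis_mask logical 3D array, or `NULL` for the default policy:
#'   the union of all lesion voxels of both groups (outside it every table
#'   is degenerate and p = 1, so results are unchanged).
#' @return 3D array of raw p-values.
#' @export
voxelwise_fisher <- function(masks_a, masks_b, analysis_mask = NULL) {
  if (!length(masks_a) || !length(masks_b)) stop("both groups must be non-empty")
  d <- dim(masks_a[[1]])
  mask_idx <- if (is.null(analysis_mask)) {
    .union_mask_idx(c(masks_a, masks_b))
  } else {
    stopifnot(identical(dim(analysis_mask), d))
    which(analysis_mask != 0)
  }
  n1 <- length(masks_a); n2 <- length(masks_b)
  p_map <- array(1, dim = d)
  if (!length(mask_idx)) return(p_map)
  M <- .stack_masks(c(masks_a, masks_b), mask_idx)
  ca <- as.integer(round(rowSums(M[, seq_len(n1), drop = FALSE])))
  cb <- as.integer(round(rowSums(M[, n1 + seq_len(n2), drop = FALSE])))
  ptab <- fisher_p_table(n1, n2)
  p_map[mask_idx] <- .lookup_p(ptab, ca, cb, n1)
  p_map
}

# One permutation pass on the stacked matrix: p-values for in-mask voxels.
.perm_pvalues <- function(M, total, in_a, ptab, n1) {
  ca <- as.integer(round(drop(M %*% in_a)))
  .lookup_p(ptab, ca, total - ca, n1)
}

# Max suprathreshold cluster size among in-mask voxels.
.max_cluster_size <- function(pvals, mask_idx, dims, thr, connectivity) {
  sup <- mask_idx[pvals < thr]
  if (!length(sup)) return(0L)
  comp <- .label_components(sup, dims, connectivity)
  max(tabulate(comp))
}

#' Permutation null of maximum cluster sizes
#'
#' For each of `config$n_permutations` seeded relabelings of the pooled
#' patients (group sizes preserved), recomputes the voxel-wise Fisher p-map,
#' forms suprathreshold clusters at `config$raw_p_threshold`, and records
#' the maximum cluster size (0 if none). The minimum significant cluster
#' size is the smallest integer k whose null exceedance frequency is below
#' `config$fwe_alpha`.
#'
#' @param masks pooled list of masks (both groups).
#' @param labels character/factor vector of group labels, parallel to
#'   `masks`, exactly two distinct values.
#' @param config an [adiffi_config()].
#' @param analysis_mask optional logical 3D mask (default: union policy).
#' @return list with `null_max_sizes` (integer, length `n_permutations`) and
#'   `cluster_size_threshold` (integer k).
#' @export
permutation_null <- function(masks, labels, config = adiffi_config(),
                             analysis_mask = NULL) {
  labels <- as.character(labels)
  stopifnot(length(masks) == length(labels))
  lv <- unique(labels)
  if (length(lv) != 2L) stop("permutation null needs exactly two groups")
  if (config$n_permutations < 1 / config$fwe_alpha) {
    warning("n_permutations < 1/fwe_alpha: cluster-size threshold is ",
            "unreliable")
  }
  d <- dim(masks[[1]])
  mask_idx <- if (is.null(analysis_mask)) .union_mask_idx(masks)
              else which(analysis_mask != 0)
  n1 <- sum(labels == lv[1]); n2 <- sum(labels == lv[2])
  null_max <- integer(config$n_permutations)
  if (length(mask_idx)) {
    M <- .stack_masks(masks, mask_idx)
    total <- as.integer(round(rowSums(M)))
    ptab <- fisher_p_table(n1, n2)
    base <- as.numeric(labels == lv[1])
    for (j in seq_len(config$n_permutations)) {
      perm <- with_seed(derive_seed(config$seed, 2L, j), sample(base))
      pv <- .perm_pvalues(M, total, perm, ptab, n1)
      null_max[j] <- .max_cluster_size(pv, mask_idx, d,
                                       config$raw_p_threshold,
                                       config$connectivity)
    }
  }
  list(null_max_sizes = null_max,
       cluster_size_threshold = .size_threshold(null_max, config$fwe_alpha))
}

# Smallest integer k with (# null max sizes >= k) / B < alpha.
.size_threshold <- function(null_max, alpha) {
  b <- length(null_max)
  for (k in seq_len(max(null_max) + 1L)) {
    if (sum(null_max >= k) / b < alpha) return(k)
  }
  max(null_max) + 1L
}

#' Relative in-cluster effect size
#'
#' Relative percent difference of the two groups' mean frequencies over the
#' cluster's voxels: `(mean(F_a) - mean(F_b)) / mean(F_b) x 100`. A value of
#' 239 means the frequency of group A is 239 percent higher than group B
#' inside the cluster. Undefined (`NA`) when the reference mean is zero.
#'
#' @param cluster_voxels 1-based linear voxel indices of the cluster.
#' @param fa,fb the two groups' [frequency_map()]s (A = tested group,
#'   B = reference).
#' @return relative difference in percent, or `NA` if undefined.
#' @export
cluster_effect <- function(cluster_voxels, fa, fb) {
  stopifnot(length(cluster_voxels) >= 1L)
  ma <- mean(fa$values[cluster_voxels])
  mb <- mean(fb$values[cluster_voxels])
  if (mb == 0) return(NA_real_)
  (ma - mb) / mb * 100
}

#' Run the full ADIFFI procedure
#'
#' Observed voxel-wise Fisher p-map, suprathreshold clusters, permutation
#' null of max cluster sizes, empirical cluster-size threshold, and the
#' significant-cluster report: number of significant clusters, minimum raw
#' p-value over the analysis mask, and total significantly different voxels.
#' Each cluster is annotated with its mean differential (sign = direction:
#' positive means more frequent in group A) and the relative in-cluster
#' effect.
#'
#' @param masks_a,masks_b per-patient compartment masks of the two groups.
#' @param config an [adiffi_config()].
#' @param group_labels labels for the two groups (reporting only).
#' @param affine shared affine (kept for map export).
#' @param analysis_mask optional logical 3D mask (default: union of both
#'   groups' lesion voxels).
#' @return object of class `adiffi_result`.
#' @export
adiffi <- function(masks_a, masks_b, config = adiffi_config(),
                   group_labels = c("A", "B"), affine = diag(4),
                   analysis_mask = NULL) {
  d <- dim(masks_a[[1]])
  if (is.null(analysis_mask)) {
    analysis_mask <- array(FALSE, dim = d)
    analysis_mask[.union_mask_idx(c(masks_a, masks_b))] <- TRUE
  }
  p_map <- voxelwise_fisher(masks_a, masks_b, analysis_mask)
  clusters <- suprathreshold_clusters(p_map, config$raw_p_threshold,
                                      config$connectivity)
  labels <- rep(group_labels, c(length(masks_a), length(masks_b)))
  null <- permutation_null(c(masks_a, masks_b), labels, config, analysis_mask)

  fa <- frequency_map(masks_a, group_labels[1], affine = affine)
  fb <- frequency_map(masks_b, group_labels[2], affine = affine)
  diff_map <- fa$values - fb$values
  clusters <- lapply(clusters, function(cl) {
    cl$mean_differential <- mean(diff_map[cl$voxels])
    cl$direction <- sign(cl$mean_differential)
    cl$relative_effect <- cluster_effect(cl$voxels, fa, fb)
    cl$significant <- cl$size >= null$cluster_size_threshold
    cl
  })
  sig <- vapply(clusters, `[[`, logical(1), "significant")
  obs_max <- if (length(clusters)) clusters[[1]]$size else 0L
  mask_idx <- which(analysis_mask != 0)
  structure(list(
    p_map = p_map, analysis_mask = analysis_mask, clusters = clusters,
    null_max_sizes = null$null_max_sizes,
    cluster_size_threshold = null$cluster_size_threshold,
    n_significant_clusters = sum(sig),
    min_raw_p = if (length(mask_idx)) min(p_map[mask_idx]) else 1,
    n_significant_voxels = sum(vapply(clusters[sig], `[[`, numeric(1),
                                      "size")),
    corrected_p = (1 + sum(null$null_max_sizes >= obs_max)) /
      (1 + length(null$null_max_sizes)),
    group_labels = group_labels, config = config, affine = affine),
    class = "adiffi_result")
}

#' @export
print.adiffi_result <- function(x, ...) {
  cat("<adiffi_result>", x$group_labels[1], "vs", x$group_labels[2], "\n",
      " raw p <", x$config$raw_p_threshold, "|",
      x$config$n_permutations, "permutations | min cluster size",
      x$cluster_size_threshold, "\n",
      " significant clusters:", x$n_significant_clusters,
      "| significant voxels:", x$n_significant_voxels,
      "| min raw p:", signif(x$min_raw_p, 3), "\n")
  invisible(x)
}

#' Per-cluster report table
#'
#' @param result an [adiffi_result()].
#' @return data.frame: cluster id, size, min raw p, mean differential,
#'   direction, relative effect (percent), significance flag.
#' @export
cluster_table <- function(result) {
  stopifnot(inherits(result, "adiffi_result"))
  cl <- result$clusters
  if (!length(cl)) {
    return(data.frame(cluster = integer(), size = integer(),
                      min_p = numeric(), mean_differential = numeric(),
                      direction = numeric(), relative_effect = numeric(),
                      significant = logical()))
  }
  data.frame(
    cluster = seq_along(cl),
    size = vapply(cl, `[[`, numeric(1), "size"),
    min_p = vapply(cl, `[[`, numeric(1), "min_p"),
    mean_differential = vapply(cl, `[[`, numeric(1), "mean_differential"),
    direction = vapply(cl, `[[`, numeric(1), "direction"),
    relative_effect = vapply(cl, `[[`, numeric(1), "relative_effect"),
    significant = vapply(cl, `[[`, logical(1), "significant"))
}
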