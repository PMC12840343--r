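#' Synthetic lesion cohorts with known ground truth
#'
#' Generates cohorts of atlas-space tumor segmentations under a fully
#' specified stochastic model, so that every downstream stage (volumetrics,
#' laterality, frequency maps, permutation-cluster inference) can be tested
#' with a known answer and no external data.
#'
#' Each synthetic lesion is three nested spheres in world mm — a necrosis
#' core inside an enhancing shell inside an edema halo — rasterized on the
#' shared grid by voxel-center inclusion. Spheres are not realistic tumor
#' morphology; they are chosen because volumes, centers of mass and nesting
#' are analytically checkable. Under `effect = NULL` the group labels are
#' exchangeable by construction: the spatial model is identical for all
#' groups, which is exactly the permutation null hypothesis of no spatial
#' difference in lesion distribution between groups.
#'
#' A planted effect makes one group spatially distinct, via a mean shift of
#' its lesion-center distribution and/or a probability boost that re-draws a
#' fraction of its centers inside a spherical predilection region (rejection
#' sampling from the same base distribution). The predilection region is
#' returned as a binary mask so recovery can be scored with Dice overlap.
#'
#' @name synthetic-cohort
NULL

#' Specify a synthetic cohort
#'
#' @param grid_shape three positive integers, grid size in voxels.
#' @param voxel_size voxel edge lengths in mm (length 3).
#' @param groups named integer vector: group label -> number of patients.
#' @param center_mean mean of the lesion-center distribution, world mm.
#' @param center_cov 3x3 covariance of lesion centers (mm^2); must be
#'   positive definite.
#' @param radius_model list with elements `necrosis`, `core`, `edema`, each
#'   `c(mean, sd)` in mm: the equivalent-sphere radius of the necrosis core,
#'   the tumor core (necrosis + enhancing) and the edema halo (whole-tumor
#'   extent). Sampled radii are truncated at 3 sd and nesting
#'   (necrosis <= core <= edema) is enforced per patient.
#' @param effect `NULL` (exchangeable null) or a list with `group` (target
#'   group label) plus `offset` (length-3 mm shift of that group's center
#'   mean) and/or `boost` (`list(center, radius, prob)`: with probability
#'   `prob` a patient's center is re-drawn, by rejection, inside the sphere).
#' @param mgmt_prob,sex_prob cohort-level allocation proportions for the
#'   MGMT (`methylated`, `unmethylated`, `missing`) and sex (`male`,
#'   `female`) columns; converted to deterministic counts by largest
#'   remainder, then shuffled.
#' @param label_map label dialect for the written masks.
#' @param master_seed integer; the single source of randomness. Per-patient
#'   substreams are derived with [derive_seed()].
#' @return an object of class `synthetic_cohort_spec`.
#' @export
synthetic_cohort_spec <- function(grid_shape = c(64L, 64L, 64L),
                                  voxel_size = c(3, 3, 3),
                                  groups = c(MES = 85L, RTK_I = 69L,
                                             RTK_II = 54L, OTHER = 19L),
                                  center_mean = c(0, 0, 0),
                                  center_cov = diag(c(12, 12, 10)^2),
                                  radius_model = list(
                                    necrosis = c(mean = 13, sd = 2.5),
                                    core = c(mean = 20.3, sd = 3),
                                    edema = c(mean = 29, sd = 4)),
                                  effect = NULL,
                                  mgmt_prob = c(methylated = 0.489,
                                                unmethylated = 0.502,
                                                missing = 0.009),
                                  sex_prob = c(male = 0.648, female = 0.352),
                                  label_map = label_dialect(),
                                  master_seed = 1L) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1),
            length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named vector")
  }
  if (any(groups < 1)) stop("each group needs n_patients >= 1")
  for (k in c("necrosis", "core", "edema")) {
    rm_ <- radius_model[[k]]
    if (is.null(rm_) || rm_[["mean"]] <= 0 || rm_[["sd"]] < 0) {
      stop("radius_model$", k, " must have positive mean and sd >= 0")
    }
  }
  chol_cov <- tryCatch(chol(center_cov),
                       error = function(e) stop("non-positive covariance"))
  if (!is.null(effect)) {
    if (is.null(effect$group) || !effect$group %in% names(groups)) {
      stop("effect$group must name one of the groups")
    }
    if (is.null(effect$offset) && is.null(effect$boost)) {
      stop("effect needs an offset and/or a boost")
    }
    if (!is.null(effect$boost)) {
      b <- effect$boost
      if (is.null(b$center) || is.null(b$radius) || b$radius <= 0) {
        stop("effect$boost needs center and positive radius")
      }
      if (is.null(b$prob)) effect$boost$prob <- 1
    }
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size = as.numeric(voxel_size),
                 groups = groups, center_mean = as.numeric(center_mean),
                 center_cov = center_cov, chol_cov = chol_cov,
                 radius_model = radius_model, effect = effect,
                 mgmt_prob = mgmt_prob, sex_prob = sex_prob,
                 label_map = label_map,
                 master_seed = as.integer(master_seed)),
            class = "synthetic_cohort_spec")
}

#' @export
print.synthetic_cohort_spec <- function(x, ...) {
  cat("<synthetic_cohort_spec>", sum(x$groups), "patients (",
      paste(sprintf("%s=%d", names(x$groups), x$groups), collapse = ", "),
      ") on", paste(x$grid_shape, collapse = "x"), "grid @",
      paste(x$voxel_size, collapse = "x"), "mm; effect:",
      if (is.null(x$effect)) "none" else x$effect$group, "\n")
  invisible(x)
}

# Grid affine: axis-aligned, grid centered on world origin so that the
# midsagittal plane x = 0 splits the volume in half.
.grid_affine <- function(grid_shape, voxel_size) {
  a <- diag(c(voxel_size, 1))
  a[1:3, 4] <- -(grid_shape - 1) / 2 * voxel_size
  a
}

# Largest-remainder allocation of n into round(n * prob) integer counts.
.allocate <- function(n, prob) {
  raw <- n * prob / sum(prob)
  k <- floor(raw)
  left <- n - sum(k)
  if (left > 0) {
    k[order(raw - k, decreasing = TRUE)[seq_len(left)]] <-
      k[order(raw - k, decreasing = TRUE)[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(k), names(prob))
}

.sample_center <- function(spec, mean_shift, boost) {
  draw <- function() {
    as.numeric(mean_shift + drop(crossprod(spec$chol_cov, stats::rnorm(3))))
  }
  c0 <- draw()
  if (!is.null(boost) && stats::runif(1) < boost$prob) {
    for (i in seq_len(10000L)) {
      if (sqrt(sum((c0 - boost$center)^2)) <= boost$radius) return(c0)
      c0 <- draw()
    }
    stop("boost region has negligible probability mass under the center ",
         "distribution")
  }
  c0
}

.sample_radii <- function(spec) {
  r <- vapply(c("necrosis", "core", "edema"), function(k) {
    m <- spec$radius_model[[k]]
    z <- max(-3, min(3, stats::rnorm(1)))
    max(m[["mean"]] + z * m[["sd"]], min(spec$voxel_size) / 2)
  }, numeric(1))
  cummax(r)  # enforce necrosis <= core <= edema
}

# Rasterize nested spheres around `center` (world mm) on the axis-aligned
# grid; returns an integer label array. Voxel-center inclusion, boundaries
# inclusive (d <= r).
.rasterize_lesion <- function(center, radii, grid_shape, affine, label_map) {
  vox <- diag(affine)[1:3]
  org <- affine[1:3, 4]
  ax <- lapply(1:3, function(a) org[a] + (seq_len(grid_shape[a]) - 1) * vox[a])
  r_e <- radii[["edema"]]
  idx <- lapply(1:3, function(a) {
    which(abs(ax[[a]] - center[a]) <= r_e)
  })
  labels <- array(0L, dim = grid_shape)
  if (any(lengths(idx) == 0L)) return(labels)
  d2 <- outer(
    outer((ax[[1]][idx[[1]]] - center[1])^2,
          (ax[[2]][idx[[2]]] - center[2])^2, `+`),
    (ax[[3]][idx[[3]]] - center[3])^2, `+`)
  sub <- array(0L, dim = dim(d2))
  sub[d2 <= r_e^2] <- label_map[["edema"]]
  sub[d2 <= radii[["core"]]^2] <- label_map[["enhancing"]]
  sub[d2 <= radii[["necrosis"]]^2] <- label_map[["necrosis"]]
  labels[idx[[1]], idx[[2]], idx[[3]]] <- sub
  labels
}

.lesion_fits <- function(center, r, grid_shape, affine) {
  vox <- diag(affine)[1:3]
  org <- affine[1:3, 4]
  lo <- org - vox / 2
  hi <- org + (grid_shape - 0.5) * vox
  all(center - r >= lo) && all(center + r <= hi)
}

# Sphere mask around a world-mm center (voxel-center inclusion).
.sphere_mask <- function(center, radius, grid_shape, affine) {
  vox <- diag(affine)[1:3]
  org <- affine[1:3, 4]
  ax <- lapply(1:3, function(a) org[a] + (seq_len(grid_shape[a]) - 1) * vox[a])
  d2 <- outer(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2, `+`),
              (ax[[3]] - center[3])^2, `+`)
  array(d2 <= radius^2, dim = grid_shape)
}

#' Generate a synthetic cohort
#'
#' Draws one lesion per patient from the spec's stochastic model and
#' rasterizes it on the shared grid. Deterministic given
#' `spec$master_seed`: patient i uses the substream
#' `derive_seed(master_seed, 1, i)` regardless of execution order.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param dir optional output directory; if given, masks (NIfTI), the cohort
#'   CSV and a `ground_truth.json` are written there and `mask_path` is
#'   filled in.
#' @return list with `cohort` ([cohort_table()]), `volumes` (list of
#'   [segmentation_volume()]) and `ground_truth` (list: `centers` and
#'   `voxel_counts` data frames, `effect_region_mask` logical array — empty
#'   iff `spec$effect` is `NULL`).
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_cohort_spec"))
  n <- sum(spec$groups)
  affine <- .grid_affine(spec$grid_shape, spec$voxel_size)
  group_of <- rep(names(spec$groups), times = spec$groups)
  ids <- sprintf("P%04d", seq_len(n))

  # cohort-level covariates: deterministic counts, shuffled order
  mgmt <- rep(names(spec$mgmt_prob), times = .allocate(n, spec$mgmt_prob))
  sex <- rep(names(spec$sex_prob), times = .allocate(n, spec$sex_prob))
  mgmt <- with_seed(derive_seed(spec$master_seed, 4L, 1L), sample(mgmt))
  sex <- with_seed(derive_seed(spec$master_seed, 4L, 2L), sample(sex))

  eff <- spec$effect
  volumes <- vector("list", n)
  centers <- matrix(NA_real_, n, 3)
  counts <- matrix(0L, n, 3,
                   dimnames = list(NULL, c("necrosis", "enhancing", "edema")))
  for (i in seq_len(n)) {
    in_eff <- !is.null(eff) && group_of[i] == eff$group
    shift <- spec$center_mean +
      if (in_eff && !is.null(eff$offset)) eff$offset else 0
    boost <- if (in_eff) eff$boost else NULL
    draw <- with_seed(derive_seed(spec$master_seed, 1L, i), {
      center <- .sample_center(spec, shift, boost)
      radii <- .sample_radii(spec)
      list(center = center, radii = radii)
    })
    if (!.lesion_fits(draw$center, draw$radii[["edema"]],
                      spec$grid_shape, affine)) {
      stop("lesion for patient ", i, " (", ids[i],
           ") would exceed grid bounds; enlarge the grid or tighten the ",
           "center/radius model")
    }
    lab <- .rasterize_lesion(draw$center, draw$radii, spec$grid_shape,
                             affine, spec$label_map)
    volumes[[i]] <- segmentation_volume(lab, affine, spec$label_map)
    centers[i, ] <- draw$center
    for (k in colnames(counts)) {
      counts[i, k] <- sum(lab == spec$label_map[[k]])
    }
  }

  cohort <- cohort_table(ids, group_of, mgmt, sex,
                         subtype_levels = names(spec$groups))
  region <- if (is.null(eff)) {
    array(FALSE, dim = spec$grid_shape)
  } else if (!is.null(eff$boost)) {
    .sphere_mask(eff$boost$center, eff$boost$radius, spec$grid_shape, affine)
  } else {
    .sphere_mask(spec$center_mean + eff$offset,
                 spec$radius_model$edema[["mean"]], spec$grid_shape, affine)
  }
  ground_truth <- list(
    centers = data.frame(id = ids, group = group_of, x = centers[, 1],
                         y = centers[, 2], z = centers[, 3],
                         stringsAsFactors = FALSE),
    voxel_counts = data.frame(id = ids, counts, stringsAsFactors = FALSE),
    effect_region_mask = region
  )

  if (!is.null(dir)) {
    csv <- write_cohort(cohort, volumes, dir)
    cohort$mask_path <- sprintf("%s.nii", cohort$id)
    jsonlite::write_json(
      list(centers = ground_truth$centers,
           voxel_counts = ground_truth$voxel_counts,
           effect_region_voxels = which(region),
           master_seed = spec$master_seed),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
    attr(ground_truth, "paths") <- list(
      table = csv, ground_truth = file.path(dir, "ground_truth.json"))
  }
  list(cohort = cohort, volumes = volumes, ground_truth = ground_truth)
}

#' Permute group labels, preserving group sizes
#'
#' One draw from the permutation null: patients keep their masks, the
#' grouping labels are randomly reassigned, so the multiset of labels is
#' preserved exactly.
#'
#' @param cohort a [cohort_table()].
#' @param seed integer seed for this relabeling.
#' @param variable which column to permute (`"subtype"`, `"mgmt"` or
#'   `"sex"`).
#' @return a [cohort_table()] with permuted labels.
#' @export
null_relabel_cohort <- function(cohort, seed, variable = "subtype") {
  stopifnot(inherits(cohort, "cohort_table"),
            variable %in% c("subtype", "mgmt", "sex"))
  labs <- cohort[[variable]]
  if (length(unique(labs)) < 2L) {
    stop("cannot relabel a single-group cohort")
  }
  cohort[[variable]] <- with_seed(seed, sample(labs))
  cohort
}
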