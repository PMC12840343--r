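#' Voxel-wise lesion frequency and differential maps
#'
#' For a group of N patients, the frequency map holds at each atlas voxel v
#' the percentage F(v) = N_tumor(v) / N_total x 100 of patients whose lesion
#' (in the chosen compartment) covers v. A differential map is the signed
#' voxel-wise difference of two groups' frequency maps, bounded in
#' [-100, 100].
#'
#' @name frequency-maps
NULL

# Stack a list of logical masks into per-voxel counts (integer array).
.mask_counts <- function(masks) {
  counts <- masks[[1]] != 0
  storage.mode(counts) <- "integer"
  for (m in masks[-1]) counts <- counts + (m != 0)
  counts
}

#' Build a frequency map
#'
#' @param masks list of logical/0-1 3D compartment masks, one per patient in
#'   the group, all on the shared grid.
#' @param group_label label for the group.
#' @param compartment compartment the masks represent.
#' @param affine shared voxel-to-world transform (kept for map export).
#' @return object of class `frequency_map`: `values` (percent), `counts`
#'   (N_tumor per voxel), `n_total`, `group_label`, `compartment`, `affine`.
#' @export
frequency_map <- function(masks, group_label = "group",
                          compartment = "whole_tumor", affine = diag(4)) {
  if (!length(masks)) stop("frequency map of an empty group is undefined")
  d <- dim(masks[[1]])
  if (!all(vapply(masks, function(m) identical(dim(m), d), logical(1)))) {
    stop("masks do not share one grid")
  }
  counts <- .mask_counts(masks)
  structure(list(values = counts / length(masks) * 100, counts = counts,
                 n_total = length(masks), group_label = group_label,
                 compartment = compartment, affine = affine),
            class = "frequency_map")
}

#' @export
print.frequency_map <- function(x, ...) {
  s <- map_summary(x)
  cat("<frequency_map>", x$group_label, "/", x$compartment, "| n =",
      x$n_total, "| max F(v) =", round(s$max_frequency, 1), "%\n")
  invisible(x)
}

#' Differential map between two groups
#'
#' @param fa,fb [frequency_map()]s of the two groups, same grid and
#'   compartment, different groups.
#' @return object of class `differential_map` with `values` = F_a - F_b.
#' @export
differential_map <- function(fa, fb) {
  stopifnot(inherits(fa, "frequency_map"), inherits(fb, "frequency_map"))
  if (!identical(fa$compartment, fb$compartment)) {
    stop("compartment mismatch: ", fa$compartment, " vs ", fb$compartment)
  }
  if (!identical(dim(fa$values), dim(fb$values))) stop("grid mismatch")
  if (identical(fa$group_label, fb$group_label)) {
    stop("differential map needs two different groups")
  }
  structure(list(values = fa$values - fb$values,
                 group_a = fa$group_label, group_b = fb$group_label,
                 compartment = fa$compartment, affine = fa$affine),
            class = "differential_map")
}

#' Frequency-map summary statistics
#'
#' The maximum frequency across voxels and, for each threshold, the number
#' of voxels with frequency strictly above it.
#'
#' @param f a [frequency_map()].
#' @param thresholds percentage thresholds in (0, 100); defaults to the
#'   clinically motivated 10 and 20 percent.
#' @return list with `max_frequency` and `n_above` (named integer vector).
#' @export
map_summary <- function(f, thresholds = c(10, 20)) {
  stopifnot(inherits(f, "frequency_map"),
            all(thresholds > 0), all(thresholds < 100))
  v <- f$values
  n_above <- vapply(thresholds, function(t) sum(v > t), numeric(1))
  list(max_frequency = max(v),
       n_above = stats::setNames(as.integer(n_above),
                                 paste0("gt_", thresholds)))
}
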