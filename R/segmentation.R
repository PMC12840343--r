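#' Tumor segmentation volumes and analysis compartments
#'
#' A segmentation volume is one patient's multi-label tumor mask on the
#' shared atlas grid: an integer 3D array, a 4x4 voxel-to-world affine
#' (0-based voxel indices, world mm, RAS: +x is subject-right), and a label
#' map assigning each nonzero label to one of the three tissue classes
#' `necrosis`, `enhancing` (contrast-enhancing tumor) and `edema`.
#'
#' The three analysis compartments are fixed unions of tissue classes:
#' `whole_tumor` = necrosis + enhancing + edema, `tumor_core` = necrosis +
#' enhancing, `non_enhancing` = edema alone. Labels are disjoint (one label
#' per voxel), so the core and non-enhancing compartments partition the
#' whole tumor.
#'
#' @name segmentation
NULL

.tissue_classes <- c("necrosis", "edema", "enhancing")

#' @export
compartments <- function() c("whole_tumor", "tumor_core", "non_enhancing")

#' Default label dialect: classic BraTS labels 1 = necrosis, 2 = edema,
#' 4 = enhancing. An alternate `{1, 2, 3}` dialect is available via
#' `label_dialect("123")`.
#'
#' @param dialect `"124"` (default) or `"123"`.
#' @return named integer vector mapping tissue class to label value.
#' @export
label_dialect <- function(dialect = "124") {
  switch(dialect,
    "124" = c(necrosis = 1L, edema = 2L, enhancing = 4L),
    "123" = c(necrosis = 1L, edema = 2L, enhancing = 3L),
    stop("unknown label dialect: ", dialect))
}

#' Construct a segmentation volume
#'
#' @param voxels integer 3D label array (0 = background).
#' @param affine 4x4 voxel-to-world transform (mm, 0-based indices).
#' @param label_map named integer vector: names in
#'   `c("necrosis", "edema", "enhancing")`, values the numeric labels used
#'   in `voxels`.
#' @return an object of class `segmentation_volume`.
#' @export
segmentation_volume <- function(voxels, affine = diag(4),
                                label_map = label_dialect()) {
  stopifnot(length(dim(voxels)) == 3L)
  if (!all(names(label_map) %in% .tissue_classes)) {
    stop("label_map names must be among: ",
         paste(.tissue_classes, collapse = ", "))
  }
  if (anyDuplicated(label_map)) stop("label_map values must be distinct")
  if (abs(det(affine)) < .Machine$double.eps) stop("affine is not invertible")
  present <- setdiff(unique(as.vector(voxels)), 0)
  unknown <- setdiff(present, label_map)
  if (length(unknown)) {
    stop("labels present in voxels but absent from label_map: ",
         paste(sort(unknown), collapse = ", "))
  }
  structure(
    list(voxels = voxels, affine = affine, label_map = label_map),
    class = "segmentation_volume"
  )
}

#' @export
print.segmentation_volume <- function(x, ...) {
  cat("<segmentation_volume> grid", paste(dim(x$voxels), collapse = "x"),
      "| voxel size", paste(signif(.voxel_size(x$affine), 4), collapse = "x"),
      "mm |", sum(x$voxels != 0), "lesion voxels\n")
  invisible(x)
}

.voxel_size <- function(affine) sqrt(colSums(affine[1:3, 1:3]^2))

.voxel_volume_mm3 <- function(affine) abs(det(affine[1:3, 1:3]))

#' Derive an analysis compartment mask
#'
#' @param seg a [segmentation_volume()].
#' @param compartment one of `"whole_tumor"`, `"tumor_core"`,
#'   `"non_enhancing"`.
#' @return logical 3D mask on the same grid.
#' @export
derive_compartment <- function(seg, compartment = compartments()) {
  compartment <- match.arg(compartment)
  stopifnot(inherits(seg, "segmentation_volume"))
  classes <- switch(compartment,
    whole_tumor   = c("necrosis", "enhancing", "edema"),
    tumor_core    = c("necrosis", "enhancing"),
    non_enhancing = "edema")
  labels <- seg$label_map[intersect(classes, names(seg$label_map))]
  array(seg$voxels %in% labels, dim = dim(seg$voxels))
}

# World-mm coordinates (matrix, one row per voxel) of 1-based linear indices.
.world_coords <- function(lin, dim, affine) {
  ijk <- arrayInd(lin, dim) - 1L
  sweep(ijk %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], `+`)
}
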