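#' Suprathreshold clusters in a p-value map
#'
#' Connected components of the voxel set where the raw p-value is strictly
#' below the cluster-forming threshold, under 6-, 18- or 26-neighborhood
#' connectivity in 3D.
#'
#' @name clusters
NULL

.connectivity_offsets <- function(connectivity) {
  d <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(abs(d))
  keep <- switch(as.character(connectivity),
    "6" = nz == 1, "18" = nz >= 1 & nz <= 2, "26" = nz >= 1,
    stop("connectivity must be 6, 18 or 26"))
  unname(d[keep, , drop = FALSE])
}

# Connected-component labels for a sparse voxel set. `lin`: 1-based linear
# indices into a grid of dimensions `dims`. Returns an integer component id
# per element of `lin` (ids in first-seed order). Vectorized frontier BFS.
.label_components <- function(lin, dims, connectivity = 26) {
  n <- length(lin)
  comp <- integer(n)
  if (!n) return(comp)
  slot <- array(0L, dim = dims)
  slot[lin] <- seq_len(n)
  coords <- arrayInd(lin, dims)
  offs <- .connectivity_offsets(connectivity)
  no <- nrow(offs)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    comp[s] <- ncomp
    frontier <- s
    while (length(frontier)) {
      fc <- coords[frontier, , drop = FALSE]
      nf <- nrow(fc)
      nb <- fc[rep(seq_len(nf), each = no), , drop = FALSE] +
        offs[rep(seq_len(no), times = nf), , drop = FALSE]
      ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
            nb[, 2] >= 1L & nb[, 2] <= dims[2] &
            nb[, 3] >= 1L & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) break
      nlin <- nb[, 1] + dims[1] * (nb[, 2] - 1L) +
        dims[1] * dims[2] * (nb[, 3] - 1L)
      sl <- unique(slot[nlin])
      sl <- sl[sl > 0L]
      sl <- sl[comp[sl] == 0L]
      comp[sl] <- ncomp
      frontier <- sl
    }
  }
  comp
}

#' Find suprathreshold clusters
#'
#' @param p_map 3D array of raw p-values.
#' @param raw_p_threshold cluster-forming threshold; voxels with
#'   `p < raw_p_threshold` (strict) enter clustering.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return list of clusters sorted by size descending (ties: smallest linear
#'   voxel index first); each cluster is a list with `voxels` (1-based
#'   linear indices, ascending), `size` and `min_p`.
#' @export
suprathreshold_clusters <- function(p_map, raw_p_threshold = 0.005,
                                    connectivity = 26) {
  stopifnot(length(dim(p_map)) == 3L)
  lin <- which(p_map < raw_p_threshold)
  if (!length(lin)) return(list())
  comp <- .label_components(lin, dim(p_map), connectivity)
  clusters <- lapply(split(lin, comp), function(v) {
    list(voxels = sort(v), size = length(v), min_p = min(p_map[v]))
  })
  sizes <- vapply(clusters, `[[`, numeric(1), "size")
  firsts <- vapply(clusters, function(cl) cl$voxels[1], numeric(1))
  unname(clusters[order(-sizes, firsts)])
}
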