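#' Compartment volumetrics and laterality statistics
#'
#' Per-patient compartment volumes in cm^3, nonparametric group comparisons
#' (Mann–Whitney U for two groups, Kruskal–Wallis for three or more),
#' center-of-mass hemisphere classification against a configurable
#' midsagittal plane, and the two chi-square laterality tests: a
#' goodness-of-fit test of the overall right/left split against 50/50, and a
#' contingency test of hemisphere by group.
#'
#' Continuity-correction policy (fixed, documented): the 1-df goodness-of-fit
#' test uses no correction; 2x2 contingency tables use the Yates correction;
#' Rx2 tables with R > 2 use the plain Pearson statistic. This is the policy
#' that matches standard scientific-stack defaults.
#'
#' @name volumetrics
NULL

#' Volume of a binary mask in cm^3
#'
#' @param mask logical/0-1 3D array.
#' @param voxel_volume_mm3 volume of one voxel in mm^3 (> 0).
#' @return volume in cm^3 (voxel count x voxel volume / 1000).
#' @export
compartment_volume <- function(mask, voxel_volume_mm3) {
  stopifnot(voxel_volume_mm3 > 0)
  sum(mask != 0) * voxel_volume_mm3 / 1000
}

#' Per-patient volume table
#'
#' @param volumes list of [segmentation_volume()].
#' @param cohort matching [cohort_table()] (optional, adds id/subtype/mgmt).
#' @return data.frame with one row per patient and columns
#'   `whole_tumor`, `tumor_core`, `non_enhancing` (cm^3).
#' @export
volume_table <- function(volumes, cohort = NULL) {
  vv <- vapply(volumes, function(s) .voxel_volume_mm3(s$affine), numeric(1))
  out <- as.data.frame(lapply(stats::setNames(nm = compartments()),
    function(cc) {
      vapply(seq_along(volumes), function(i) {
        compartment_volume(derive_compartment(volumes[[i]], cc), vv[i])
      }, numeric(1))
    }))
  if (!is.null(cohort)) {
    out <- cbind(as.data.frame(cohort)[, c("id", "subtype", "mgmt", "sex")],
                 out)
  }
  out
}

#' Rank-based comparison of volumes between groups
#'
#' Two groups: two-sided Mann–Whitney U with midranks — exact by full
#' enumeration of label assignments when the combined sample size is at most
#' 20, tie-corrected normal approximation (no continuity correction) above.
#' Three or more groups: Kruskal–Wallis with tie correction.
#'
#' @param values_by_group named list of numeric vectors, one per group; each
#'   group needs at least 2 observations.
#' @param exact_max combined-n cutoff for the exact Mann–Whitney path.
#' @return list with `test` (`"mann_whitney_u"` or `"kruskal_wallis"`),
#'   `statistic` and `p_value`.
#' @export
compare_volumes <- function(values_by_group, exact_max = 20L) {
  stopifnot(is.list(values_by_group), length(values_by_group) >= 2L)
  sizes <- lengths(values_by_group)
  if (any(sizes < 2L)) {
    stop("each group needs at least 2 observations; got sizes ",
         paste(sizes, collapse = ", "))
  }
  if (length(values_by_group) == 2L) {
    mw <- .mann_whitney(values_by_group[[1]], values_by_group[[2]], exact_max)
    list(test = "mann_whitney_u", statistic = mw$U, p_value = mw$p)
  } else {
    x <- unlist(values_by_group, use.names = FALSE)
    g <- factor(rep(seq_along(values_by_group), times = sizes))
    kt <- stats::kruskal.test(x, g)
    list(test = "kruskal_wallis", statistic = unname(kt$statistic),
         p_value = kt$p.value)
  }
}

# Two-sided Mann–Whitney U on midranks. Exact path: enumerate all
# choose(n1+n2, n1) assignments of the pooled midranks to group 1 and take
# 2 * min(tail probabilities), capped at 1.
.mann_whitney <- function(x, y, exact_max = 20L) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w1 <- sum(r[seq_len(n1)])
  u1 <- w1 - n1 * (n1 + 1) / 2
  if (n1 + n2 <= exact_max) {
    sets <- utils::combn(n1 + n2, n1)
    ws <- colSums(matrix(r[sets], nrow = n1))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(ws <= w1 + eps), mean(ws >= w1 - eps)))
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    if (sigma2 <= 0) return(list(U = u1, p = 1))
    z <- (u1 - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = u1, p = p)
}

#' Center of mass of a binary mask, in world mm
#'
#' Unweighted mean of the world coordinates of all mask-voxel centers.
#'
#' @param mask logical/0-1 3D array.
#' @param affine 4x4 voxel-to-world transform.
#' @return length-3 numeric (x, y, z in mm).
#' @export
center_of_mass <- function(mask, affine) {
  lin <- which(mask != 0)
  if (!length(lin)) stop("center of mass of an empty mask is undefined")
  colMeans(.world_coords(lin, dim(mask), affine))
}

#' Classify a center of mass by hemisphere
#'
#' RAS convention: world +x is subject-right. Centers within `tol` mm of the
#' midline plane are classified `"midline"` and are excluded from laterality
#' counts by the table helpers.
#'
#' @param com_mm length-3 world coordinate (mm), or just its x component.
#' @param midline_x_mm x position of the midsagittal plane (default 0,
#'   the atlas midplane).
#' @param tol half-width of the midline band, mm.
#' @return `"left"`, `"right"` or `"midline"`.
#' @export
classify_hemisphere <- function(com_mm, midline_x_mm = 0, tol = 1e-9) {
  x <- com_mm[1]
  stopifnot(is.finite(x))
  if (abs(x - midline_x_mm) <= tol) return("midline")
  if (x > midline_x_mm) "right" else "left"
}

#' Chi-square goodness of fit of a right/left split against 50/50
#'
#' One degree of freedom, no continuity correction.
#'
#' @param n_right,n_left hemisphere counts (midline cases already excluded).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
laterality_gof <- function(n_right, n_left) {
  n <- n_right + n_left
  if (n < 1) stop("laterality test needs at least one classified patient")
  e <- n / 2
  stat <- (n_right - e)^2 / e + (n_left - e)^2 / e
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Chi-square test of independence for group x hemisphere counts
#'
#' Yates continuity correction for 2x2 tables; plain Pearson statistic for
#' Rx2 tables with more than two rows. Degrees of freedom R - 1 (two
#' columns).
#'
#' @param table matrix of nonnegative counts, rows = groups,
#'   columns = (right, left).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @export
laterality_contingency <- function(table) {
  table <- as.matrix(table)
  stopifnot(nrow(table) >= 2L, ncol(table) == 2L, all(table >= 0))
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("contingency table has a zero row or column margin")
  }
  expected <- outer(rs, cs) / sum(table)
  dev <- abs(table - expected)
  if (nrow(table) == 2L) dev <- pmax(dev - 0.5, 0)  # Yates
  stat <- sum(dev^2 / expected)
  df <- (nrow(table) - 1L)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       expected = expected)
}

#' Per-patient tumor locations
#'
#' @param volumes list of [segmentation_volume()].
#' @param cohort matching [cohort_table()].
#' @param compartment compartment whose center of mass is classified
#'   (whole-tumor and tumor-core analyses in practice).
#' @param midline_x_mm midsagittal plane, world mm.
#' @return data.frame: id, subtype, mgmt, sex, com_x/y/z, hemisphere.
#'   Patients with an empty compartment get `NA` coordinates and hemisphere
#'   `"midline"`-excluded `NA`.
#' @export
locate_cohort <- function(volumes, cohort, compartment = "whole_tumor",
                          midline_x_mm = 0) {
  stopifnot(length(volumes) == nrow(cohort))
  com <- t(vapply(volumes, function(s) {
    m <- derive_compartment(s, compartment)
    if (!any(m)) return(c(NA_real_, NA_real_, NA_real_))
    center_of_mass(m, s$affine)
  }, numeric(3)))
  hemi <- ifelse(is.na(com[, 1]), NA_character_,
                 vapply(seq_len(nrow(com)), function(i) {
                   if (is.na(com[i, 1])) NA_character_
                   else classify_hemisphere(com[i, ], midline_x_mm)
                 }, character(1)))
  data.frame(as.data.frame(cohort)[, c("id", "subtype", "mgmt", "sex")],
             com_x = com[, 1], com_y = com[, 2], com_z = com[, 3],
             hemisphere = hemi, stringsAsFactors = FALSE)
}

#' Hemisphere counts by group
#'
#' Midline and unclassifiable patients are excluded from the counts.
#'
#' @param locations output of [locate_cohort()].
#' @param variable grouping column (`"subtype"`, `"mgmt"`, `"sex"`).
#' @param groups optional subset/order of group levels.
#' @return integer matrix, rows = groups, columns = c(right, left).
#' @export
hemisphere_counts <- function(locations, variable = "subtype",
                              groups = NULL) {
  keep <- !is.na(locations$hemisphere) & locations$hemisphere != "midline"
  d <- locations[keep, ]
  if (is.null(groups)) groups <- sort(unique(d[[variable]]))
  out <- t(vapply(groups, function(g) {
    h <- d$hemisphere[d[[variable]] == g]
    c(right = sum(h == "right"), left = sum(h == "left"))
  }, integer(2)))
  rownames(out) <- groups
  out
}
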