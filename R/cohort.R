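#' Cohort metadata tables
#'
#' A cohort table binds patient ids to the molecular subtype
#' (`MES`, `RTK_I`, `RTK_II`, `OTHER`), MGMT promoter methylation status
#' (`methylated`, `unmethylated`, `missing`), sex (`male`, `female`) and the
#' path of the patient's segmentation mask. Missing MGMT status is a valid
#' value (those patients are retained in summaries and excluded from
#' MGMT-stratified comparisons), not an error.
#'
#' @name cohort
NULL

.subtypes <- c("MES", "RTK_I", "RTK_II", "OTHER")
.mgmt_levels <- c("methylated", "unmethylated", "missing")
.sex_levels <- c("male", "female")

#' Construct a cohort table
#'
#' @param id character or integer patient ids, unique.
#' @param subtype molecular subtype, one of `MES`, `RTK_I`, `RTK_II`, `OTHER`.
#' @param mgmt MGMT status, one of `methylated`, `unmethylated`, `missing`.
#' @param sex `male` or `female`.
#' @param mask_path segmentation file path per patient (may be `NA` for
#'   in-memory cohorts).
#' @param subtype_levels allowed subtype values; the default is the four
#'   molecular subtype codes. `NULL` admits arbitrary group labels
#'   (synthetic cohorts with custom groups).
#' @return a `data.frame` of class `cohort_table`.
#' @export
cohort_table <- function(id, subtype, mgmt = "missing", sex = "female",
                         mask_path = NA_character_,
                         subtype_levels = .subtypes) {
  df <- data.frame(id = as.character(id), subtype = as.character(subtype),
                   mgmt = as.character(mgmt), sex = as.character(sex),
                   mask_path = as.character(mask_path),
                   stringsAsFactors = FALSE)
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    stop("duplicated patient id(s): ", paste(unique(dup), collapse = ", "))
  }
  if (!is.null(subtype_levels)) {
    bad <- setdiff(unique(df$subtype), subtype_levels)
    if (length(bad)) {
      stop("unknown subtype value(s): ", paste(bad, collapse = ", "))
    }
  }
  bad <- setdiff(unique(df$mgmt), .mgmt_levels)
  if (length(bad)) stop("unknown MGMT value(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$sex), .sex_levels)
  if (length(bad)) stop("unknown sex value(s): ", paste(bad, collapse = ", "))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table>", nrow(x), "patients;",
      paste(sprintf("%s=%d", names(table(x$subtype)), table(x$subtype)),
            collapse = ", "), "\n")
  invisible(as.data.frame(x))
}

#' Load a cohort from disk
#'
#' Reads the cohort CSV (columns `id,subtype,mgmt,sex,mask_path`) and every
#' referenced NIfTI mask, validating that all masks share one grid: equal
#' shape and affines agreeing entrywise within `grid_tol` mm.
#'
#' @param table_path cohort CSV path.
#' @param label_map label dialect for the masks (see [label_dialect()]).
#' @param grid_tol tolerance on affine entries, mm.
#' @param subtype_levels allowed subtype values (`NULL` = arbitrary group
#'   labels, for synthetic cohorts).
#' @return list with `cohort` ([cohort_table()]) and `volumes`
#'   (list of [segmentation_volume()], in row order).
#' @export
load_cohort <- function(table_path, label_map = label_dialect(),
                        grid_tol = 1e-4, subtype_levels = .subtypes) {
  df <- utils::read.csv(table_path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("id", "subtype", "mgmt", "sex", "mask_path")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort table lacks column(s): ",
                         paste(miss, collapse = ", "))
  cohort <- cohort_table(df$id, df$subtype, df$mgmt, df$sex, df$mask_path,
                         subtype_levels = subtype_levels)

  base <- dirname(table_path)
  volumes <- vector("list", nrow(cohort))
  ref <- NULL
  for (i in seq_len(nrow(cohort))) {
    p <- cohort$mask_path[i]
    if (!file.exists(p)) p <- file.path(base, cohort$mask_path[i])
    if (!file.exists(p)) stop("mask file not found: ", cohort$mask_path[i])
    nii <- read_nifti(p)
    vox <- array(as.integer(round(nii$data)), dim = dim(nii$data))
    if (is.null(ref)) {
      ref <- nii
    } else {
      if (!identical(dim(nii$data), dim(ref$data))) {
        stop("grid shape mismatch in ", cohort$mask_path[i])
      }
      if (max(abs(nii$affine - ref$affine)) > grid_tol) {
        stop("affine mismatch (> ", grid_tol, " mm) in ", cohort$mask_path[i])
      }
    }
    volumes[[i]] <- segmentation_volume(vox, nii$affine, label_map)
  }
  list(cohort = cohort, volumes = volumes)
}

#' Write a cohort (masks + table) to a directory
#'
#' @param cohort a [cohort_table()].
#' @param volumes list of [segmentation_volume()] in cohort row order.
#' @param dir output directory (created if needed).
#' @return path of the written cohort CSV, invisibly.
#' @export
write_cohort <- function(cohort, volumes, dir) {
  stopifnot(inherits(cohort, "cohort_table"),
            length(volumes) == nrow(cohort))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort$mask_path <- sprintf("%s.nii", cohort$id)
  for (i in seq_len(nrow(cohort))) {
    write_nifti(volumes[[i]]$voxels, file.path(dir, cohort$mask_path[i]),
                volumes[[i]]$affine, datatype = "int16")
  }
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(as.data.frame(cohort), csv, row.names = FALSE, quote = FALSE)
  invisible(csv)
}

#' Cohort composition summary
#'
#' Absolute counts and percentages per level of subtype, MGMT status and sex
#' (the layout of a clinical characteristics table).
#'
#' @param cohort a [cohort_table()].
#' @return data.frame with columns `variable`, `level`, `n`, `percent`
#'   (percent of the full cohort, one decimal).
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_table"))
  n <- nrow(cohort)
  one <- function(var, levels) {
    tab <- table(factor(cohort[[var]], levels = levels))
    data.frame(variable = var, level = names(tab), n = as.integer(tab),
               percent = round(100 * as.integer(tab) / n, 1),
               stringsAsFactors = FALSE)
  }
  rbind(one("subtype", .subtypes), one("mgmt", .mgmt_levels),
        one("sex", .sex_levels))
}
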