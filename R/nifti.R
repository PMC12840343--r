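#' Minimal NIfTI-1 input/output
#'
#' The package reads and writes uncompressed single-file NIfTI-1 (`.nii`)
#' volumes: 3D images, sform affine, datatypes uint8/int16/int32/float32/
#' float64. This is deliberately small — enough to round-trip atlas-space
#' label masks and statistical maps — not a general neuroimaging I/O layer.
#' Both byte orders are read; files are written little-endian with
#' `sform_code = 2` (aligned/atlas space).
#'
#' @name nifti-io
NULL

.nifti_dtypes <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "double", "double"),
  size = c(1L, 2L, 4L, 4L, 8L),
  bitpix = c(8L, 16L, 32L, 32L, 64L),
  stringsAsFactors = FALSE
)

#' Read a NIfTI-1 volume
#'
#' @param path path to an uncompressed `.nii` file.
#' @return a list with `data` (numeric array, dimensions from the header),
#'   `affine` (4x4 voxel-to-world matrix, 0-based voxel indices, mm) and
#'   `voxel_size` (length-3, mm).
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- "little"
  sizeof_hdr <- readBin(con, "integer", 1, 4, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    if (.swap_int4(sizeof_hdr) != 348L) {
      stop("not a NIfTI-1 file (sizeof_hdr != 348): ", path)
    }
  }
  seek(con, 40)
  dims <- readBin(con, "integer", 8, 2, endian = endian)
  ndim <- dims[1]
  if (ndim < 3L) stop("expected a 3D volume: ", path)
  shape <- dims[2:4]
  if (any(dims[5:8] > 1L)) stop("only 3D volumes are supported: ", path)
  seek(con, 70)
  datatype <- readBin(con, "integer", 1, 2, endian = endian)
  seek(con, 76)
  pixdim <- readBin(con, "numeric", 8, 4, endian = endian)
  vox_offset <- readBin(con, "numeric", 1, 4, endian = endian)
  seek(con, 112)
  scl_slope <- readBin(con, "numeric", 1, 4, endian = endian)
  scl_inter <- readBin(con, "numeric", 1, 4, endian = endian)
  seek(con, 252)
  qform_code <- readBin(con, "integer", 1, 2, endian = endian)
  sform_code <- readBin(con, "integer", 1, 2, endian = endian)
  seek(con, 280)
  srow <- readBin(con, "numeric", 12, 4, endian = endian)

  dt <- .nifti_dtypes[.nifti_dtypes$code == datatype, ]
  if (nrow(dt) != 1L) stop("unsupported NIfTI datatype code ", datatype)

  seek(con, max(vox_offset, 352))
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, dt$size, signed = dt$size > 1L,
                  endian = endian)
  if (length(vals) != n) stop("truncated NIfTI data: ", path)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(vals, dim = shape)

  if (sform_code > 0L) {
    affine <- rbind(matrix(srow, nrow = 3, byrow = TRUE), c(0, 0, 0, 1))
  } else if (qform_code == 0L) {
    # "analyze-like": scale only, centered at origin per NIfTI default
    affine <- diag(c(pixdim[2:4], 1))
  } else {
    stop("qform-only NIfTI files are not supported: ", path)
  }
  list(data = data, affine = affine,
       voxel_size = sqrt(colSums(affine[1:3, 1:3]^2)))
}

.swap_int4 <- function(x) {
  b <- writeBin(as.integer(x), raw(), 4, endian = "little")
  readBin(rev(b), "integer", 1, 4, endian = "little")
}

#' Write a NIfTI-1 volume
#'
#' @param data 3D numeric or integer array.
#' @param path output path (`.nii`, uncompressed).
#' @param affine 4x4 voxel-to-world matrix (0-based voxel indices, mm).
#' @param datatype one of `"int16"`, `"uint8"`, `"int32"`, `"float32"`,
#'   `"float64"`. Integer label volumes default to `int16`, continuous maps
#'   to `float32`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(data, path, affine = diag(4), datatype = NULL) {
  stopifnot(length(dim(data)) == 3L, is.matrix(affine),
            all(dim(affine) == c(4L, 4L)))
  if (is.null(datatype)) {
    datatype <- if (is.integer(data) ||
                    all(data == round(data))) "int16" else "float32"
  }
  code <- switch(datatype,
    uint8 = 2L, int16 = 4L, int32 = 8L, float32 = 16L, float64 = 64L,
    stop("unsupported datatype: ", datatype))
  dt <- .nifti_dtypes[.nifti_dtypes$code == code, ]
  if (dt$what == "integer") {
    lim <- c(uint8 = 255, int16 = 32767, int32 = 2147483647)[[datatype]]
    if (any(abs(data) > lim)) stop("data exceeds ", datatype, " range")
  }

  voxdim <- sqrt(colSums(affine[1:3, 1:3]^2))
  hdr <- raw(348)
  put <- function(hdr, offset, value, what, size) {
    b <- writeBin(value, raw(), size = size, endian = "little")
    hdr[(offset + 1):(offset + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0, 348L, "integer", 4)
  hdr <- put(hdr, 40, as.integer(c(3L, dim(data), 1L, 1L, 1L, 1L)), "integer", 2)
  hdr <- put(hdr, 70, code, "integer", 2)
  hdr <- put(hdr, 72, dt$bitpix, "integer", 2)
  hdr <- put(hdr, 76, c(1, voxdim, 0, 0, 0, 0), "double", 4)
  hdr <- put(hdr, 108, 352, "double", 4)          # vox_offset
  hdr <- put(hdr, 112, c(1, 0), "double", 4)      # scl_slope, scl_inter
  hdr <- put(hdr, 123, 10L, "integer", 1)         # xyzt_units: mm
  hdr <- put(hdr, 252, c(0L, 2L), "integer", 2)   # qform_code, sform_code
  hdr <- put(hdr, 280, as.numeric(t(affine[1:3, ])), "double", 4)
  magic <- charToRaw("n+1")
  hdr[345:347] <- magic

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)  # extension flag
  vals <- as.vector(data)
  if (dt$what == "integer") {
    writeBin(as.integer(vals), con, size = dt$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = dt$size, endian = "little")
  }
  invisible(path)
}
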