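# Minimal NIfTI-1 I/O: single-file .nii / .nii.gz, diagonal affines only.
# Scalar volumes are stored as 3D float64; deformation fields as 5D
# (nx,ny,nz,1,3) with the vector intent code, one component per 5th-dim index.

NIFTI_DT <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                 `4` = list(what = "integer", size = 2, signed = TRUE),
                 `8` = list(what = "integer", size = 4, signed = TRUE),
                 `16` = list(what = "double", size = 4, signed = TRUE),
                 `64` = list(what = "double", size = 8, signed = TRUE),
                 `256` = list(what = "integer", size = 1, signed = TRUE),
                 `512` = list(what = "integer", size = 2, signed = FALSE))

nifti_connection <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

write_nifti_raw <- function(path, arr, dim5, spacing, origin, intent_code = 0L) {
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, n) {
    raw_s <- charToRaw(s)
    writeBin(c(raw_s, raw(n - length(raw_s))), con)
  }
  ndim <- max(which(dim5 > 1), 3L)
  dim8 <- c(ndim, dim5, rep(1L, 7 - length(dim5)))
  wi(348, 4)                              # sizeof_hdr
  wc("", 10); wc("", 18)                  # data_type, db_name
  wi(0, 4); wi(0, 2); wc("r", 1); wc("", 1)  # extents, session_error, regular, dim_info
  wi(dim8, 2)                             # dim[8]
  wf(c(0, 0, 0))                          # intent_p1..p3
  wi(intent_code, 2)                      # intent_code
  wi(64, 2); wi(64, 2); wi(0, 2)          # datatype float64, bitpix, slice_start
  wf(c(1, spacing, rep(1, 4)))            # pixdim[8] (qfac = 1)
  wf(352)                                 # vox_offset
  wf(1); wf(0)                            # scl_slope, scl_inter
  wi(0, 2); wc("", 1); writeBin(as.raw(2L), con)  # slice_end, slice_code, xyzt_units (mm)
  wf(c(0, 0, 0, 0))                       # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0), 4)                          # glmax, glmin
  wc("brainshiftr", 80); wc("", 24)       # descrip, aux_file
  wi(0, 2); wi(1, 2)                      # qform_code 0, sform_code 1
  wf(c(0, 0, 0)); wf(origin)              # quatern b,c,d; qoffset x,y,z
  wf(c(spacing[1], 0, 0, origin[1]))      # srow_x
  wf(c(0, spacing[2], 0, origin[2]))      # srow_y
  wf(c(0, 0, spacing[3], origin[3]))      # srow_z
  wc("", 16)                              # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)  # magic
  writeBin(raw(4), con)                   # extension flag
  writeBin(as.numeric(arr), con, size = 8, endian = "little")
  invisible(path)
}

read_nifti_raw <- function(path) {
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("NIfTI parse error: truncated header in ", path)
  rd <- function(off, what, n, size, signed = TRUE, endian = "little") {
    readBin(hdr[(off + 1):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = endian)
  }
  endian <- "little"
  if (rd(0, "integer", 1, 4) != 348L) {
    endian <- "big"
    if (rd(0, "integer", 1, 4, endian = "big") != 348L)
      stop("NIfTI parse error: bad sizeof_hdr in ", path)
  }
  magic <- rawToChar(hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("NIfTI parse error: bad magic field in ", path)
  dim8 <- rd(40, "integer", 8, 2, endian = endian)
  datatype <- rd(70, "integer", 1, 2, endian = endian)
  pixdim <- rd(76, "double", 8, 4, endian = endian)
  vox_offset <- rd(108, "double", 1, 4, endian = endian)
  scl_slope <- rd(112, "double", 1, 4, endian = endian)
  scl_inter <- rd(116, "double", 1, 4, endian = endian)
  sform_code <- rd(254, "integer", 1, 2, endian = endian)
  qform_code <- rd(252, "integer", 1, 2, endian = endian)
  srow <- rbind(rd(280, "double", 4, 4, endian = endian),
                rd(296, "double", 4, 4, endian = endian),
                rd(312, "double", 4, 4, endian = endian))
  quat <- rd(256, "double", 3, 4, endian = endian)
  qoffset <- rd(268, "double", 3, 4, endian = endian)
  dt <- NIFTI_DT[[as.character(datatype)]]
  if (is.null(dt))
    stop("NIfTI parse error: unsupported datatype code ", datatype, " in ", path)
  nd <- dim8[1]
  dims <- dim8[2:(1 + max(nd, 3))]
  dims[dims == 0] <- 1L
  n <- prod(dims)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  vals <- readBin(con, dt$what, n = n, size = dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n) stop("NIfTI parse error: truncated data in ", path)
  vals <- as.numeric(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  if (sform_code > 0) {
    if (any(abs(srow[1:3, 1:3] - diag(diag(srow[1:3, 1:3]))) > 1e-6) ||
        any(diag(srow[1:3, 1:3]) <= 0))
      stop("NIfTI parse error: non-diagonal sform orientation not supported (", path, ")")
    spacing <- diag(srow[1:3, 1:3]); origin <- srow[, 4]
  } else if (qform_code > 0) {
    if (any(abs(quat) > 1e-6))
      stop("NIfTI parse error: rotated qform orientation not supported (", path, ")")
    spacing <- pixdim[2:4]; origin <- qoffset
  } else {
    spacing <- pixdim[2:4]; origin <- c(0, 0, 0)
  }
  list(data = array(vals, dims), spacing = spacing, origin = origin)
}

#' Read / write volumes and deformation fields as NIfTI
#'
#' Scalar volumes round-trip as 3D float64 NIfTI-1 (`.nii` or `.nii.gz`);
#' deformation fields as 5D `nx x ny x nz x 1 x 3` vector images. Only
#' axis-aligned (diagonal affine) orientations are supported.
#'
#' @param path file path; `.gz` suffix selects gzip compression.
#' @param vol an [image_volume()] / [label_volume()].
#' @param labels if `TRUE`, [read_volume()] returns a [label_volume()].
#' @return [read_volume()] returns an [image_volume()]; [read_field()] a
#'   [deformation_field()].
#' @export
read_volume <- function(path, labels = FALSE) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  raw <- read_nifti_raw(path)
  dims <- raw$data
  if (length(dim(raw$data)) > 3) {
    if (prod(dim(raw$data)[-(1:3)]) != 1)
      stop("read_volume: ", path, " is not a scalar 3D volume")
    raw$data <- array(raw$data, dim(raw$data)[1:3])
  }
  if (labels) label_volume(round(raw$data), raw$spacing, raw$origin)
  else image_volume(raw$data, raw$spacing, raw$origin)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  write_nifti_raw(path, vol$data, dim(vol$data), vol$spacing, vol$origin)
}

#' @rdname read_volume
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("cannot read field: no such file: ", path)
  raw <- read_nifti_raw(path)
  d <- dim(raw$data)
  if (length(d) == 5 && d[4] == 1 && d[5] == 3)
    vec <- array(raw$data, c(d[1:3], 3))
  else if (length(d) == 4 && d[4] == 3)
    vec <- raw$data
  else stop("read_field: ", path, " does not hold a 3-component vector image")
  deformation_field(vec, raw$spacing, raw$origin)
}

#' @rdname read_volume
#' @param field a [deformation_field()].
#' @export
write_field <- function(field, path) {
  d <- dim(field$vectors)
  write_nifti_raw(path, field$vectors, c(d[1:3], 1L, 3L),
                  field$spacing, field$origin, intent_code = 1007L)
}
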