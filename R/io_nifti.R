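# Minimal NIfTI-1 reader/writer (single-file .nii / .nii.gz, little-endian
# write, endian-detecting read). Only what the pipeline needs: dim, datatype,
# pixdim/TR, scl slope/intercept, and the sform affine. No preinstalled R
# NIfTI package is assumed.

.nifti_dtypes <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                      `4` = list(what = "integer", size = 2, signed = TRUE),
                      `8` = list(what = "integer", size = 4, signed = TRUE),
                      `16` = list(what = "numeric", size = 4, signed = TRUE),
                      `64` = list(what = "numeric", size = 8, signed = TRUE))

#' Write a 3D or 4D array as a NIfTI-1 image
#'
#' Data are stored as float32 with an sform affine; `.gz` suffixes are
#' compressed transparently.
#'
#' @param data 3D or 4D numeric array
#' @param path output path (`.nii` or `.nii.gz`)
#' @param affine 4x4 matrix mapping 1-based voxel indices to world mm
#' @param tr_s repetition time stored in pixdim[4] (seconds)
#' @return `path`, invisibly
#' @export
write_nifti <- function(data, path, affine = diag(4), tr_s = 0) {
  nd <- length(dim(data))
  stopifnot(nd %in% c(3, 4))
  dims <- dim(data)
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  # sform maps 0-based indices; shift our 1-based convention
  sform <- affine
  sform[1:3, 4] <- affine[1:3, 4] + affine[1:3, 1:3] %*% rep(1, 3)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wc <- function(s, n) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(n - length(raw))), con)
  }
  wi(348, 4)                       # sizeof_hdr
  wc("", 10); wc("", 18)           # data_type, db_name
  wi(0, 4); wi(0, 2)               # extents, session_error
  wc("r", 1); wc("", 1)            # regular, dim_info
  dimfield <- c(nd, dims, rep(1, 7 - nd))
  wi(dimfield, 2)                  # dim[8]
  wf(c(0, 0, 0)); wi(0, 2)         # intent_p1-3, intent_code
  wi(16, 2); wi(32, 2); wi(0, 2)   # datatype float32, bitpix, slice_start
  wf(c(1, vs, tr_s, 0, 0, 0))      # pixdim[8]
  wf(352)                          # vox_offset
  wf(1); wf(0)                     # scl_slope, scl_inter
  wi(0, 2); wc("", 1)              # slice_end, slice_code
  writeBin(as.raw(10L), con)       # xyzt_units: mm | sec
  wf(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wi(c(0, 0), 4)                   # glmax, glmin
  wc("dmnpredict", 80); wc("", 24) # descrip, aux_file
  wi(0, 2); wi(2, 2)               # qform_code 0, sform_code 2
  wf(rep(0, 6))                    # quaternions + qoffsets
  wf(sform[1, ]); wf(sform[2, ]); wf(sform[3, ])
  wc("", 16)                       # intent_name
  wc("n+1", 4)                     # magic
  writeBin(raw(4), con)            # extension flag
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a NIfTI-1 image written by this package (or any single-file NIfTI-1)
#'
#' Supports uint8/int16/int32/float32/float64 data, scl slope/intercept
#' scaling, gzip transparently, and both endiannesses.
#'
#' @param path `.nii` or `.nii.gz` file
#' @return list with `data` (array), `affine` (1-based voxel-to-world),
#'   `tr_s`
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")          # reads plain files transparently
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  if (length(hdr) < 348) stop("truncated NIfTI header in ", path)
  rd <- function(off, what, n, size, endian, signed = TRUE)
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            endian = endian, signed = signed)
  endian <- "little"
  if (rd(0, "integer", 1, 4, "little") != 348) {
    if (rd(0, "integer", 1, 4, "big") == 348) endian <- "big"
    else stop(path, " is not a NIfTI-1 file")
  }
  dimf <- rd(40, "integer", 8, 2, endian)
  nd <- dimf[1]
  if (!nd %in% c(3, 4)) stop("unsupported dimensionality ", nd)
  dims <- dimf[2:(1 + nd)]
  datatype <- rd(70, "integer", 1, 2, endian)
  dt <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype)
  pixdim <- rd(76, "numeric", 8, 4, endian)
  vox_offset <- rd(108, "numeric", 1, 4, endian)
  scl_slope <- rd(112, "numeric", 1, 4, endian)
  scl_inter <- rd(116, "numeric", 1, 4, endian)
  sform_code <- rd(254, "integer", 1, 2, endian)
  srow <- rbind(rd(280, "numeric", 4, 4, endian),
                rd(296, "numeric", 4, 4, endian),
                rd(312, "numeric", 4, 4, endian))
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = skip)
  n <- prod(dims)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = dt$signed)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (is.na(scl_slope) || scl_slope == 0) scl_slope <- 1
  if (is.na(scl_inter)) scl_inter <- 0
  vals <- vals * scl_slope + scl_inter
  if (sform_code > 0) {
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else {
    affine <- diag(4); diag(affine)[1:3] <- pixdim[2:4]
  }
  affine[1:3, 4] <- affine[1:3, 4] - affine[1:3, 1:3] %*% rep(1, 3)
  list(data = array(vals, dim = dims), affine = affine, tr_s = pixdim[5])
}
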