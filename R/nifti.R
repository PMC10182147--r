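#' Minimal NIfTI-1 input/output
#'
#' Reads and writes single-volume NIfTI-1 files (`.nii`, `.nii.gz`),
#' sufficient for the CT/PET volumes and label maps this package exchanges.
#' On disk NIfTI stores x fastest; in memory this package uses (z, y, x)
#' axis order, so arrays are permuted on the way in and out. Voxel spacing
#' is carried in `pixdim` and a diagonal sform. Supported datatypes:
#' uint8, int16, int32, float32, float64.
#'
#' @param x a `ct_volume`/`pet_volume`, or a 3D array (then `spacing_mm` is
#'   required).
#' @param path file path; a `.gz` suffix triggers gzip compression.
#' @param spacing_mm per-axis voxel size (z, y, x) when `x` is a bare array.
#' @param datatype `"float32"` (default) or `"int32"` (for label maps).
#' @return `write_nifti` returns `path` invisibly; `read_nifti` returns a
#'   list with `values` (array, (z, y, x) order), `spacing_mm`, `origin_mm`.
#' @export
write_nifti <- function(x, path, spacing_mm = NULL, datatype = "float32") {
  if (inherits(x, "pc_volume")) {
    values <- x$values; spacing_mm <- x$spacing_mm; origin <- x$origin_mm
  } else {
    stop_if_not(is.array(x) && length(dim(x)) == 3, "x must be a 3D array")
    stop_if_not(!is.null(spacing_mm), "spacing_mm required for a bare array")
    values <- x; origin <- c(0, 0, 0)
  }
  dt <- match.arg(datatype, c("float32", "int32"))
  code <- if (dt == "float32") 16L else 8L
  bitpix <- 32L
  # disk order: x fastest -> permute (z,y,x) to (x,y,z)
  vx <- aperm(values, c(3, 2, 1))
  nd <- dim(vx)                      # (nx, ny, nz)
  sp <- rev(spacing_mm)              # (dx, dy, dz)
  orig <- rev(origin)

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  wI <- function(v, size) writeBin(as.integer(v), con, size = size,
                                   endian = "little")
  wF <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wC <- function(s, len) {
    r <- raw(len)
    b <- charToRaw(s)
    r[seq_along(b)] <- b
    writeBin(r, con)
  }
  wI(348, 4)                         # sizeof_hdr
  writeBin(raw(36), con)             # data_type..dim_info (unused)
  wI(c(3, nd, 1, 1, 1, 1), 2)       # dim[8]
  wF(c(0, 0, 0))                     # intent_p1..p3
  wI(0, 2)                           # intent_code
  wI(code, 2)                        # datatype
  wI(bitpix, 2)                      # bitpix
  wI(0, 2)                           # slice_start
  wF(c(1, sp, 1, 1, 1, 1))          # pixdim[8]
  wF(352)                            # vox_offset
  wF(1); wF(0)                       # scl_slope, scl_inter
  wI(0, 2); writeBin(as.raw(c(0, 2)), con)  # slice_end, slice_code, xyzt_units (mm)
  wF(c(0, 0, 0, 0))                  # cal_max, cal_min, slice_duration, toffset
  wI(c(0, 0), 4)                     # glmax, glmin
  wC("petctdetect", 80)              # descrip
  wC("", 24)                         # aux_file
  wI(c(0, 1), 2)                     # qform_code, sform_code
  wF(c(0, 0, 0, 0, 0, 0))           # quaternion + qoffset
  wF(c(sp[1], 0, 0, orig[1]))       # srow_x
  wF(c(0, sp[2], 0, orig[2]))       # srow_y
  wF(c(0, 0, sp[3], orig[3]))       # srow_z
  wC("", 16)                         # intent_name
  wC("n+1", 4)                       # magic
  writeBin(raw(4), con)              # no extensions
  if (dt == "int32") {
    writeBin(as.integer(vx), con, size = 4, endian = "little")
  } else {
    writeBin(as.numeric(vx), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_nifti <- function(path) {
  con <- gzfile(path, "rb")          # reads plain files too
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 348)
  stop_if_not(length(hdr) == 348, "truncated NIfTI header in %s", path)
  rI <- function(off, size, n = 1, signed = TRUE)
    readBin(hdr[(off + 1):length(hdr)], "integer", n = n, size = size,
            endian = "little", signed = signed)
  rF <- function(off, n = 1)
    readBin(hdr[(off + 1):length(hdr)], "double", n = n, size = 4,
            endian = "little")
  stop_if_not(rI(0, 4) == 348, "not a little-endian NIfTI-1 file: %s", path)
  dims <- rI(40, 2, n = 8)
  stop_if_not(dims[1] >= 3, "expected a 3D volume in %s", path)
  nd <- dims[2:4]                    # (nx, ny, nz)
  datatype <- rI(70, 2)
  pixdim <- rF(76, 8)
  vox_offset <- rF(108)
  scl_slope <- rF(112); scl_inter <- rF(116)
  srow <- c(rF(280, 4), rF(296, 4), rF(312, 4))
  origin <- srow[c(4, 8, 12)]
  # skip to data
  readBin(con, "raw", n = max(0, round(vox_offset) - 348))
  n <- prod(nd)
  vals <- switch(as.character(datatype),
    "2"  = as.numeric(readBin(con, "integer", n = n, size = 1, signed = FALSE)),
    "4"  = as.numeric(readBin(con, "integer", n = n, size = 2,
                              endian = "little")),
    "8"  = as.numeric(readBin(con, "integer", n = n, size = 4,
                              endian = "little")),
    "16" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "64" = readBin(con, "double", n = n, size = 8, endian = "little"),
    stop(sprintf("unsupported NIfTI datatype %d in %s", datatype, path)))
  stop_if_not(length(vals) == n, "truncated NIfTI data in %s", path)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  arr <- aperm(array(vals, dim = nd), c(3, 2, 1))   # back to (z, y, x)
  list(values = arr,
       spacing_mm = rev(pixdim[2:4]),
       origin_mm = rev(origin))
}
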