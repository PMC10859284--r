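## Minimal NIfTI-1 single-file (.nii, uncompressed) reader/writer.
##
## Only the subset of the format the pipeline needs: 3D volumes, little- or
## big-endian, datatypes uint8/int16/int32/uint16/float32/float64, no
## extensions, scl_slope/scl_inter applied on read. Orientation is carried as
## the raw sform rows; the pipeline never resamples, it requires GM and atlas
## volumes to share a grid.

.nifti_dtypes <- list(
  "2"   = list(what = "integer", size = 1L, signed = FALSE, name = "uint8"),
  "4"   = list(what = "integer", size = 2L, signed = TRUE,  name = "int16"),
  "8"   = list(what = "integer", size = 4L, signed = TRUE,  name = "int32"),
  "16"  = list(what = "double",  size = 4L, signed = TRUE,  name = "float32"),
  "64"  = list(what = "double",  size = 8L, signed = TRUE,  name = "float64"),
  "512" = list(what = "integer", size = 2L, signed = FALSE, name = "uint16")
)

#' Gray-matter density volume
#'
#' A registered 3D grid of gray-matter density values in `[0, 1]`, together
#' with voxel dimensions (mm). GM and atlas volumes used together must share
#' the same grid shape.
#'
#' @param data numeric 3D array.
#' @param pixdim voxel dimensions in mm, length 3.
#' @return an object of class `gm_volume`.
#' @export
gm_volume <- function(data, pixdim = c(2, 2, 2)) {
  mn_assert(is.array(data) && length(dim(data)) == 3,
            "gm volume data must be a 3D array")
  structure(list(data = data, pixdim = as.double(pixdim)),
            class = "gm_volume")
}

#' Integer-labeled parcellation atlas volume
#'
#' @param data integer 3D array; 0 = background, labels `1..n_roi`.
#' @param pixdim voxel dimensions in mm, length 3.
#' @return an object of class `atlas_volume`.
#' @export
atlas_volume <- function(data, pixdim = c(2, 2, 2)) {
  mn_assert(is.array(data) && length(dim(data)) == 3,
            "atlas volume data must be a 3D array")
  mn_assert(all(is.finite(data)) && all(data >= 0) && all(data == round(data)),
            "atlas labels must be nonnegative integers")
  storage.mode(data) <- "integer"
  structure(list(data = data, pixdim = as.double(pixdim)),
            class = "atlas_volume")
}

#' @export
print.gm_volume <- function(x, ...) {
  cat("<gm_volume> grid", paste(dim(x$data), collapse = "x"),
      " voxel", paste(x$pixdim, collapse = "x"), "mm\n")
  invisible(x)
}

#' @export
print.atlas_volume <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$data))), 0L)
  cat("<atlas_volume> grid", paste(dim(x$data), collapse = "x"),
      " ", length(labs), "ROIs\n")
  invisible(x)
}

#' Write a 3D volume to a NIfTI-1 file
#'
#' @param vol a `gm_volume`, `atlas_volume`, or bare 3D array.
#' @param path output file path (`.nii`, uncompressed).
#' @param datatype `"float32"`, `"float64"`, or `"int32"`; atlas volumes
#'   default to `"int32"`, others to `"float32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = NULL) {
  if (is.array(vol)) vol <- list(data = vol, pixdim = c(2, 2, 2))
  data <- vol$data
  mn_assert(length(dim(data)) == 3, "write_nifti supports 3D volumes only")
  if (is.null(datatype))
    datatype <- if (inherits(vol, "atlas_volume")) "int32" else "float32"
  code <- switch(datatype, float32 = 16L, float64 = 64L, int32 = 8L,
                 mn_stop(paste0("unsupported datatype: ", datatype)))
  bitpix <- switch(datatype, float32 = 32L, float64 = 64L, int32 = 32L)
  dm <- dim(data)
  pd <- vol$pixdim %||% c(2, 2, 2)

  con <- file(path, "wb")
  on.exit(close(con))
  wI <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  wF <- function(x) writeBin(as.double(x), con, size = 4L, endian = "little")
  wC <- function(s, len) {
    raw <- charToRaw(s)
    writeBin(c(raw, raw(len - length(raw))), con)
  }
  wI(348L, 4)                      # sizeof_hdr
  wC("", 10); wC("", 18)           # data_type, db_name
  wI(0L, 4); wI(0L, 2); wC("r", 1); wC("", 1)  # extents, session_error, regular, dim_info
  wI(c(3L, dm, 1L, 1L, 1L, 1L), 2) # dim[8]
  wF(c(0, 0, 0)); wI(0L, 2)        # intent_p1..3, intent_code
  wI(code, 2); wI(bitpix, 2); wI(0L, 2)  # datatype, bitpix, slice_start
  wF(c(1, pd, 1, 1, 1, 1))         # pixdim[8] (qfac = 1)
  wF(352); wF(1); wF(0)            # vox_offset, scl_slope, scl_inter
  wI(0L, 2); wC("", 1); wC("", 1)  # slice_end, slice_code, xyzt_units
  wF(c(0, 0, 0, 0))                # cal_max, cal_min, slice_duration, toffset
  wI(c(0L, 0L), 4)                 # glmax, glmin
  wC("morphnet synthetic volume", 80)
  wC("", 24)                       # aux_file
  wI(0L, 2); wI(1L, 2)             # qform_code = 0, sform_code = 1
  wF(c(0, 0, 0)); wF(c(0, 0, 0))   # quatern_b..d, qoffset_x..z
  wF(c(pd[1], 0, 0, 0)); wF(c(0, pd[2], 0, 0)); wF(c(0, 0, pd[3], 0))
  wC("", 16)                       # intent_name
  writeBin(c(charToRaw("n+1"), as.raw(0)), con)  # magic
  writeBin(raw(4), con)            # no extensions
  if (code == 8L) {
    wI(as.vector(data), 4)
  } else {
    writeBin(as.double(as.vector(data)), con,
             size = if (code == 16L) 4L else 8L, endian = "little")
  }
  invisible(path)
}

## Parse the 348-byte header + data of an uncompressed .nii file.
read_nifti <- function(path) {
  mn_assert(file.exists(path), paste0("file not found: ", path),
            class = "mn_io_error")
  con <- file(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (sz != 348L) {
    sz_big <- readBin(writeBin(sz, raw(), size = 4L, endian = "little"),
                      "integer", 1, size = 4, endian = "big")
    mn_assert(sz_big == 348L, "not a NIfTI-1 file (bad sizeof_hdr)",
              class = "mn_io_error")
    endian <- "big"
  }
  rI <- function(n, size) readBin(con, "integer", n, size = size,
                                  endian = endian)
  rF <- function(n, size = 4) readBin(con, "double", n, size = size,
                                      endian = endian)
  seek(con, 40)
  dm <- rI(8, 2)
  ndim <- dm[1]
  rF(3); rI(1, 2)
  datatype <- rI(1, 2); rI(1, 2); rI(1, 2)
  pixdim <- rF(8)
  vox_offset <- rF(1)
  scl_slope <- rF(1); scl_inter <- rF(1)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 3))
  mn_assert(magic %in% c("n+1", "ni1"), "not a NIfTI-1 file (bad magic)",
            class = "mn_io_error")
  spec <- .nifti_dtypes[[as.character(datatype)]]
  if (is.null(spec))
    mn_stop(paste0("unsupported NIfTI datatype code: ", datatype),
            class = "mn_io_error")
  shape <- dm[2:(ndim + 1)]
  n <- prod(shape)
  seek(con, vox_offset)
  vals <- readBin(con, spec$what, n, size = spec$size, signed = spec$signed,
                  endian = endian)
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = shape), ndim = ndim,
       pixdim = pixdim[2:(1 + max(ndim, 3))], datatype = spec$name)
}

#' Read a gray-matter or atlas volume from a NIfTI-1 file
#'
#' Atlas volumes are validated to carry nonnegative integer labels; both kinds
#' must be 3D.
#'
#' @param path path to an uncompressed `.nii` file.
#' @param type `"gm"` or `"atlas"`.
#' @return a [gm_volume()] or [atlas_volume()].
#' @export
read_volume <- function(path, type = c("gm", "atlas")) {
  type <- match.arg(type)
  raw <- read_nifti(path)
  if (raw$ndim != 3)
    mn_stop(paste0("expected a 3D volume, got ", raw$ndim, "D: ", path),
            class = "mn_io_error")
  if (type == "atlas") {
    if (!all(raw$data >= 0) || !all(raw$data == round(raw$data)))
      mn_stop(paste0("atlas volume has non-integer or negative labels: ", path),
              class = "mn_io_error")
    atlas_volume(array(as.integer(round(raw$data)), dim(raw$data)),
                 pixdim = raw$pixdim[1:3])
  } else {
    gm_volume(raw$data, pixdim = raw$pixdim[1:3])
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
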