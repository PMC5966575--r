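# Minimal NIfTI-1 reader/writer (single-file .nii / .nii.gz).
# Only what a label volume needs: dims, datatype, pixdim, sform/qform.
# No R package for NIfTI is available in the target environment, so the
# format is handled here directly; the header layout follows the NIfTI-1
# standard (348-byte header, data at vox_offset).

.nifti_datatypes <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),
  `4`   = list(what = "integer", size = 2L, signed = TRUE),
  `8`   = list(what = "integer", size = 4L, signed = TRUE),
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),
  `256` = list(what = "integer", size = 1L, signed = TRUE),
  `512` = list(what = "integer", size = 2L, signed = FALSE)
)

.read_nifti1 <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  raw_hdr <- readBin(con, "raw", n = 348L)
  if (length(raw_hdr) < 348L)
    stop("not a NIfTI-1 file (truncated header): ", path)
  endian <- "little"
  szh <- readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian)
  if (szh != 348L) {
    endian <- "big"
    szh <- readBin(raw_hdr[1:4], "integer", size = 4L, endian = endian)
    if (szh != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(raw_hdr[345:347])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path)
  rd <- function(off, what, n, size) {
    readBin(raw_hdr[(off + 1L):(off + n * size)], what,
            n = n, size = size, endian = endian)
  }
  dims <- rd(40L, "integer", 8L, 2L)
  ndim <- dims[1]
  datatype <- rd(70L, "integer", 1L, 2L)
  pixdim <- rd(76L, "numeric", 8L, 4L)
  vox_offset <- rd(108L, "numeric", 1L, 4L)
  scl_slope <- rd(112L, "numeric", 1L, 4L)
  scl_inter <- rd(116L, "numeric", 1L, 4L)
  qform_code <- rd(252L, "integer", 1L, 2L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  quat <- rd(256L, "numeric", 3L, 4L)
  qoffset <- rd(268L, "numeric", 3L, 4L)
  srow <- rbind(rd(280L, "numeric", 4L, 4L),
                rd(296L, "numeric", 4L, 4L),
                rd(312L, "numeric", 4L, 4L))

  if (ndim != 3L) {
    extra <- if (ndim > 3L) dims[seq(5L, 1L + ndim)] else integer()
    if (ndim < 3L || any(extra > 1L))
      stop("expected a 3-D image, got ", ndim, "-D: ", path)
  }
  shape <- dims[2:4]

  dt <- .nifti_datatypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)
  nvox <- prod(shape)
  skip <- max(vox_offset, 348) - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  data <- readBin(con, dt$what, n = nvox, size = dt$size,
                  signed = dt$signed, endian = endian)
  if (length(data) < nvox) stop("truncated NIfTI data: ", path)
  if (!is.na(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0))
    data <- data * scl_slope + scl_inter
  data <- array(as.double(data), dim = shape)

  affine <- NULL
  if (sform_code > 0L) {
    affine <- rbind(srow, c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    b <- quat[1]; c <- quat[2]; d <- quat[3]
    a2 <- 1 - b^2 - c^2 - d^2
    a <- sqrt(max(a2, 0))
    R <- rbind(
      c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d),     2 * (b * d + a * c)),
      c(2 * (b * c + a * d),   a^2 + c^2 - b^2 - d^2,   2 * (c * d - a * b)),
      c(2 * (b * d - a * c),   2 * (c * d + a * b),     a^2 + d^2 - b^2 - c^2))
    qfac <- if (is.na(pixdim[1]) || pixdim[1] >= 0) 1 else -1
    sp <- abs(pixdim[2:4])
    sp[sp == 0] <- 1
    R <- R %*% diag(c(sp[1], sp[2], sp[3] * qfac))
    affine <- rbind(cbind(R, qoffset), c(0, 0, 0, 1))
  } else {
    sp <- abs(pixdim[2:4])
    sp[sp == 0] <- 1
    affine <- rbind(cbind(diag(sp), c(0, 0, 0)), c(0, 0, 0, 1))
  }
  list(data = data, affine = affine)
}

.write_nifti1 <- function(data, affine, path) {
  stopifnot(length(dim(data)) == 3L)
  shape <- dim(data)
  vals <- as.vector(data)
  integral <- all(is.finite(vals)) && all(vals == round(vals)) &&
    max(abs(vals)) < 2^31 - 1
  if (integral) {
    datatype <- 8L; bitpix <- 32L; what <- "integer"; size <- 4L
    vals <- as.integer(round(vals))
  } else {
    datatype <- 64L; bitpix <- 64L; what <- "numeric"; size <- 8L
  }
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))

  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size_, what_ = "integer")
    writeBin(if (what_ == "integer") as.integer(x) else as.double(x),
             con, size = size_, endian = "little")
  w(348L, 4L)                                  # sizeof_hdr
  writeBin(raw(36L), con)                      # data_type..dim_info
  w(c(3L, shape, 1L, 1L, 1L, 1L), 2L)          # dim[8]
  writeBin(raw(14L), con)                      # intent_p1..intent_code
  w(datatype, 2L)                              # datatype
  w(bitpix, 2L)                                # bitpix
  w(0L, 2L)                                    # slice_start
  w(c(1, spacing, 1, 1, 1, 1), 4L, "numeric")  # pixdim[8]
  w(352, 4L, "numeric")                        # vox_offset
  w(1, 4L, "numeric")                          # scl_slope
  w(0, 4L, "numeric")                          # scl_inter
  writeBin(raw(4L), con)                       # slice_end, slice_code, xyzt_units
  w(c(0, 0, 0, 0), 4L, "numeric")              # cal_max, cal_min, slice_duration, toffset
  w(c(0L, 0L), 4L)                             # glmax, glmin
  writeBin(raw(80L + 24L), con)                # descrip, aux_file
  w(0L, 2L)                                    # qform_code
  w(1L, 2L)                                    # sform_code
  w(rep(0, 6), 4L, "numeric")                  # quatern_b..qoffset_z
  w(affine[1, ], 4L, "numeric")                # srow_x
  w(affine[2, ], 4L, "numeric")                # srow_y
  w(affine[3, ], 4L, "numeric")                # srow_z
  writeBin(raw(16L), con)                      # intent_name
  writeBin(charToRaw("n+1"), con); writeBin(raw(1L), con)  # magic
  writeBin(raw(4L), con)                       # extension flag
  writeBin(if (what == "integer") as.integer(vals) else as.double(vals),
           con, size = size, endian = "little")
  invisible(path)
}
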