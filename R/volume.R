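#' Label volume: a 3-D voxel grid with world-coordinate metadata
#'
#' The basic voxel container of the toolkit.  `data` holds one integer label
#' per voxel, `affine` is the 4x4 homogeneous voxel-to-world map (millimetres)
#' and `spacing` is derived from the Euclidean norms of the affine's first
#' three columns.  Voxel indices are 0-based and refer to voxel *centers*.
#'
#' @param data 3-D numeric array of integer labels.
#' @param spacing length-3 positive numeric, mm per voxel.  Ignored when
#'   `affine` is supplied.
#' @param affine optional 4x4 voxel-to-world matrix; defaults to
#'   `diag(spacing)` with a zero origin.
#' @return An object of class `label_volume` with fields `data`, `spacing`
#'   and `affine`.
#' @examples
#' vol <- label_volume(array(0L, c(5, 5, 5)))
#' vol$spacing
#' @export
label_volume <- function(data, spacing = c(1, 1, 1), affine = NULL) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (is.null(affine)) {
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("`spacing` must be 3 strictly positive values")
    affine <- diag(c(spacing, 1))
  }
  affine <- unname(as.matrix(affine))
  if (!identical(dim(affine), c(4L, 4L)))
    stop("`affine` must be a 4x4 matrix")
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps)
    stop("the affine's upper-left 3x3 block must be nonsingular")
  spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(data = data, spacing = spacing, affine = affine),
            class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  labs <- sort(unique(as.vector(x$data)))
  cat("  labels: ", paste(utils::head(labs, 10), collapse = ", "),
      if (length(labs) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a 3-D NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (`.nii` or `.nii.gz`).  The affine is
#' taken from the sform when present, else from the qform, else from
#' `pixdim`; spacing is derived from the affine column norms.
#'
#' @param path path to a readable NIfTI-1 file.
#' @return A [label_volume()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  nii <- .read_nifti1(path)
  label_volume(nii$data, affine = nii$affine)
}

#' Write a volume to NIfTI-1
#'
#' Integer-valued data are stored as int32, anything else as float64.
#' The affine is written as the sform (code 1).
#'
#' @param vol a [label_volume()].
#' @param path output path; `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  .write_nifti1(vol$data, vol$affine, path)
}

#' Threshold one label to a binary mask
#'
#' @param vol a [label_volume()].
#' @param label the label value to extract.
#' @return A binary [label_volume()] (`data` in \{0, 1\}) on the same grid.
#'   An absent label yields an all-zero mask with a warning.
#' @export
binarize <- function(vol, label) {
  stopifnot(inherits(vol, "label_volume"))
  mask <- array(as.integer(vol$data == label), dim = dim(vol$data))
  if (!any(mask == 1L))
    warning("label ", label, " not present; returning an empty mask")
  label_volume(mask, affine = vol$affine)
}

#' Voxel-index to world-coordinate conversion
#'
#' Indices are 0-based and may be fractional; a voxel's coordinate refers to
#' its center.  `world_to_voxel` is the exact inverse.
#'
#' @param vol a [label_volume()].
#' @param ijk numeric length-3 vector or N x 3 matrix of voxel indices.
#' @return Positions in world mm, same shape as the input.
#' @export
voxel_to_world <- function(vol, ijk) {
  stopifnot(inherits(vol, "label_volume"))
  pts <- if (is.matrix(ijk)) ijk else matrix(ijk, ncol = 3)
  out <- cbind(pts, 1) %*% t(vol$affine)
  out <- out[, 1:3, drop = FALSE]
  if (is.matrix(ijk)) out else drop(out)
}

#' @rdname voxel_to_world
#' @param xyz numeric length-3 vector or N x 3 matrix of world positions (mm).
#' @export
world_to_voxel <- function(vol, xyz) {
  stopifnot(inherits(vol, "label_volume"))
  pts <- if (is.matrix(xyz)) xyz else matrix(xyz, ncol = 3)
  out <- cbind(pts, 1) %*% t(solve(vol$affine))
  out <- out[, 1:3, drop = FALSE]
  if (is.matrix(xyz)) out else drop(out)
}

# volume of one voxel in mm^3
.voxel_volume <- function(vol) abs(det(vol$affine[1:3, 1:3]))

# foreground voxel count of a binary volume
.n_foreground <- function(vol) sum(vol$data != 0)

# physical volume V(A) in mm^3 of the foreground
.mask_volume <- function(vol) .n_foreground(vol) * .voxel_volume(vol)

#' Connected components of a binary volume
#'
#' @param vol a binary [label_volume()].
#' @param connectivity 6 (face) or 26 (face+edge+corner, the default
#'   foreground convention).
#' @return A [label_volume()] whose data holds component labels 1..k
#'   (0 = background), with attribute `n_components`.
#' @export
volume_components <- function(vol, connectivity = 26) {
  stopifnot(inherits(vol, "label_volume"), connectivity %in% c(6, 26))
  lab <- .label_components(as.logical(vol$data != 0), dim(vol$data),
                           as.integer(connectivity))
  n <- attr(lab, "n_components")
  out <- label_volume(array(as.integer(lab), dim(vol$data)),
                      affine = vol$affine)
  attr(out, "n_components") <- n
  out
}

# number of 26-connected foreground components (plain integer)
.n_components_vol <- function(vol, connectivity = 26) {
  attr(volume_components(vol, connectivity), "n_components")
}
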