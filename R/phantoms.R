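# Seeded synthetic phantoms: subcortical-like binary masks on a voxel grid.
# Three shape families stand in for the structures the pipeline targets:
# smooth convex blobs (putamen/pallidus-like ellipsoids), curved elongated
# shapes (caudate/hippocampus-like bent tubes), and a two-lobe shape joined
# by a thin bridge (lateral-ventricle-like).  Noise corruption emulates the
# failure modes of automated segmentation: boundary voxel flips, interior
# holes and small disconnected components.

#' Phantom shape specification
#'
#' @param shape `"ellipsoid"`, `"bent_tube"` or `"dumbbell_bridge"`.
#' @param size_params shape-specific dimensions in mm; `NULL` for the
#'   defaults below.  Ellipsoid: `radii` (3).  Bent tube: `arc_radius`,
#'   `tube_radius`, `arc_deg`.  Dumbbell: `lobe_radii` (3),
#'   `lobe_offset` (center-to-center half-distance), `bridge_radius`.
#' @param grid_shape voxel grid dimensions.
#' @param spacing mm per voxel (3-vector).
#' @param seed integer seed (used by population/noise derivations).
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("ellipsoid", "bent_tube",
                                   "dumbbell_bridge"),
                         size_params = NULL,
                         grid_shape = c(48L, 48L, 48L),
                         spacing = c(1, 1, 1), seed = 1L) {
  shape <- match.arg(shape)
  defaults <- switch(shape,
    ellipsoid = list(radii = c(12, 8, 6)),
    bent_tube = list(arc_radius = 12, tube_radius = 4, arc_deg = 150),
    dumbbell_bridge = list(lobe_radii = c(6, 5.5, 5), lobe_offset = 11,
                           bridge_radius = 1.2))
  size_params <- utils::modifyList(defaults, as.list(size_params %||% list()))
  structure(list(shape = shape, size_params = size_params,
                 grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing), seed = as.integer(seed)),
            class = "phantom_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# implicit inside-test for a spec, evaluated at shape-centered points (mm);
# returns a logical vector
.phantom_inside <- function(spec, pts) {
  p <- spec$size_params
  switch(spec$shape,
    ellipsoid = {
      rowSums(sweep(pts, 2, p$radii, `/`)^2) <= 1
    },
    bent_tube = {
      # tube of radius r around a circular arc in the xy-plane
      half <- p$arc_deg / 2 * pi / 180
      phi <- pmin(pmax(atan2(pts[, 2], pts[, 1]), -half), half)
      cx <- p$arc_radius * cos(phi)
      cy <- p$arc_radius * sin(phi)
      (pts[, 1] - cx)^2 + (pts[, 2] - cy)^2 + pts[, 3]^2 <= p$tube_radius^2
    },
    dumbbell_bridge = {
      r <- p$lobe_radii
      d <- p$lobe_offset
      lobe1 <- (pts[, 1] + d)^2 / r[1]^2 + pts[, 2]^2 / r[2]^2 +
        pts[, 3]^2 / r[3]^2 <= 1
      lobe2 <- (pts[, 1] - d)^2 / r[1]^2 + pts[, 2]^2 / r[2]^2 +
        pts[, 3]^2 / r[3]^2 <= 1
      bridge <- abs(pts[, 1]) <= d &
        pts[, 2]^2 + pts[, 3]^2 <= p$bridge_radius^2
      lobe1 | lobe2 | bridge
    })
}

# mm extent (bounding half-widths) of a shape, for the fit check
.phantom_extent <- function(spec) {
  p <- spec$size_params
  switch(spec$shape,
    ellipsoid = p$radii,
    bent_tube = rep(p$arc_radius + p$tube_radius, 3),
    dumbbell_bridge = c(p$lobe_offset + p$lobe_radii[1],
                        max(p$lobe_radii[2], p$bridge_radius),
                        max(p$lobe_radii[3], p$bridge_radius)))
}

# world coordinates (mm) of all voxel centers, grid centered at the origin
.grid_points_centered <- function(grid_shape, spacing) {
  ctr <- (grid_shape - 1) / 2 * spacing
  g <- expand.grid(i = seq_len(grid_shape[1]) - 1,
                   j = seq_len(grid_shape[2]) - 1,
                   k = seq_len(grid_shape[3]) - 1)
  sweep(as.matrix(g) * rep(spacing, each = nrow(g)), 2, ctr)
}

#' Generate a phantom binary mask
#'
#' Analytic implicit fill of the requested shape, centered in the grid; the
#' result is single-component by construction and fully reproducible.
#'
#' @param spec a [phantom_spec()].
#' @return A binary [label_volume()] (the noise-free ground truth).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ext <- .phantom_extent(spec)
  half_grid <- (spec$grid_shape - 1) / 2 * spec$spacing
  if (any(ext > half_grid - 3 * spec$spacing))
    stop("shape does not fit in the grid with a 3-voxel margin")
  pts <- .grid_points_centered(spec$grid_shape, spec$spacing)
  inside <- .phantom_inside(spec, pts)
  mask <- label_volume(array(as.integer(inside), spec$grid_shape),
                       spacing = spec$spacing)
  if (.n_foreground(mask) == 0) stop("generated mask is empty")
  mask
}

#' Segmentation-noise specification
#'
#' @param boundary_flip_rate probability in [0, 1] of flipping each voxel in
#'   the one-voxel band around the true boundary.
#' @param n_holes number of interior spherical holes to carve.
#' @param hole_radius_mm hole radius, mm.
#' @param n_spurious_components number of small disconnected foreground
#'   blobs to add away from the structure.
#' @param spurious_radius_mm radius of the spurious blobs, mm.
#' @param seed integer seed; corruption is fully reproducible.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(boundary_flip_rate = 0, n_holes = 0L,
                       hole_radius_mm = 1.5, n_spurious_components = 0L,
                       spurious_radius_mm = 1.5, seed = 1L) {
  stopifnot(boundary_flip_rate >= 0, boundary_flip_rate <= 1)
  structure(list(boundary_flip_rate = boundary_flip_rate,
                 n_holes = as.integer(n_holes),
                 hole_radius_mm = hole_radius_mm,
                 n_spurious_components = as.integer(n_spurious_components),
                 spurious_radius_mm = spurious_radius_mm,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

# set a sphere of given mm radius around voxel index ctr (0-based) to value
.paint_sphere <- function(data, ctr, radius_mm, spacing, value) {
  d <- dim(data)
  r_vox <- ceiling(radius_mm / spacing)
  rng <- lapply(1:3, function(a)
    max(0, ctr[a] - r_vox[a]):min(d[a] - 1, ctr[a] + r_vox[a]))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  dist2 <- rowSums((sweep(g, 2, ctr) * rep(spacing, each = nrow(g)))^2)
  sel <- g[dist2 <= radius_mm^2, , drop = FALSE] + 1
  data[sel] <- value
  data
}

#' Corrupt a mask with segmentation-like noise
#'
#' Flips voxels in the one-voxel boundary band at the given rate, carves
#' interior spherical holes, and adds small disconnected foreground
#' components placed disjointly from the (dilated) structure.  Seeded and
#' reproducible; a zero-noise spec returns the input unchanged.
#'
#' @param mask a binary [label_volume()].
#' @param noise a [noise_spec()].
#' @return The corrupted binary [label_volume()].
#' @export
corrupt_mask <- function(mask, noise) {
  stopifnot(inherits(mask, "label_volume"), inherits(noise, "noise_spec"))
  if (noise$boundary_flip_rate == 0 && noise$n_holes == 0 &&
      noise$n_spurious_components == 0)
    return(mask)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(noise$seed)
  d <- dim(mask$data)
  m <- mask$data != 0
  dil <- array(.binary_morph(as.logical(m), d, 26L, 1L), d)
  ero <- array(.binary_morph(as.logical(m), d, 26L, 0L), d)

  if (noise$boundary_flip_rate > 0) {
    band <- which(dil & !ero)
    flip <- band[stats::runif(length(band)) < noise$boundary_flip_rate]
    m[flip] <- !m[flip]
  }
  if (noise$n_holes > 0) {
    interior <- which(ero)
    if (length(interior) > 0) {
      ctrs <- sample(interior, min(noise$n_holes, length(interior)))
      for (c0 in ctrs) {
        ijk <- c((c0 - 1) %% d[1],
                 ((c0 - 1) %/% d[1]) %% d[2],
                 (c0 - 1) %/% (d[1] * d[2]))
        m <- .paint_sphere(m, ijk, noise$hole_radius_mm, mask$spacing, FALSE)
      }
    }
  }
  if (noise$n_spurious_components > 0) {
    keepout <- array(.binary_morph(as.logical(dil), d, 26L, 1L), d)
    r_vox <- ceiling(noise$spurious_radius_mm / mask$spacing) + 1
    placed <- 0L
    for (try in seq_len(200L)) {
      if (placed >= noise$n_spurious_components) break
      ijk <- floor(c(stats::runif(1, r_vox[1], d[1] - r_vox[1]),
                     stats::runif(1, r_vox[2], d[2] - r_vox[2]),
                     stats::runif(1, r_vox[3], d[3] - r_vox[3])))
      probe <- .paint_sphere(array(FALSE, d), ijk,
                             noise$spurious_radius_mm + mask$spacing[1],
                             mask$spacing, TRUE)
      if (any(probe & (keepout | m))) next
      m <- m | probe
      # extend the keep-out zone so later blobs stay disjoint
      keepout <- keepout | array(.binary_morph(as.logical(probe), d, 26L, 1L), d)
      placed <- placed + 1L
    }
    if (placed < noise$n_spurious_components)
      warning("could only place ", placed, " of ",
              noise$n_spurious_components, " spurious components")
  }
  label_volume(array(as.integer(m), d), affine = mask$affine)
}

# low-order direction-dependent radial modulation basis (l = 1, 2 harmonics)
.radial_basis <- function(u) {
  cbind(u[, 1], u[, 2], u[, 3],
        u[, 1] * u[, 2], u[, 2] * u[, 3], u[, 1] * u[, 3],
        u[, 1]^2 - u[, 2]^2, 3 * u[, 3]^2 - 1)
}

#' Sample a population of phantom masks
#'
#' Each member is the base shape under a small random rigid motion plus a
#' smooth random radial modulation (low-order spherical-harmonic-like
#' direction field scaled by `variation`), re-voxelized on the same grid.
#' Members violating single-connectivity are resampled.  All randomness
#' derives from `seed` via one `sample.int` split.
#'
#' @param spec a [phantom_spec()].
#' @param n number of members (>= 1).
#' @param variation standard deviation of the relative radial modulation
#'   (0 = rigid-moved copies only).
#' @param seed integer seed.
#' @return A list of `n` binary [label_volume()] masks; each carries its
#'   member seed as attribute `seed`.
#' @export
sample_population <- function(spec, n, variation = 0.05, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), n >= 1, variation >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  member_seeds <- sample.int(2^31 - 2, n)
  pts <- .grid_points_centered(spec$grid_shape, spec$spacing)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- member_seeds[i]
    for (attempt in 1:20) {
      set.seed(s + attempt - 1L)
      # small random rigid motion: rotation about a uniform axis + shift
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      ang <- stats::rnorm(1, 0, 0.06)
      K <- rbind(c(0, -ax[3], ax[2]), c(ax[3], 0, -ax[1]),
                 c(-ax[2], ax[1], 0))
      R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
      tr <- stats::rnorm(3, 0, 1)
      co <- stats::rnorm(8, 0, variation / sqrt(8))
      rel <- sweep(pts, 2, tr) %*% R  # = R^T (x - t)
      rn <- sqrt(rowSums(rel^2))
      scale <- if (variation > 0) {
        u <- rel / pmax(rn, 1e-9)
        pmax(1 + as.numeric(.radial_basis(u) %*% co), 0.2)
      } else rep(1, nrow(rel))
      inside <- .phantom_inside(spec, rel / scale)
      mask <- label_volume(array(as.integer(inside), spec$grid_shape),
                           spacing = spec$spacing)
      if (.n_foreground(mask) > 0 && .n_components_vol(mask) == 1L) break
    }
    attr(mask, "seed") <- s
    out[[i]] <- mask
  }
  out
}
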