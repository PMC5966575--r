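# Evaluation metrics: overlap (DSC), volume agreement (AVD, PCC), surface
# smoothness (Geometric Laplacian), IQR outlier QC, Welch t-test, CAP score.

.check_same_grid <- function(A, B) {
  if (!identical(dim(A$data), dim(B$data)) ||
      max(abs(A$affine - B$affine)) > 1e-9)
    stop("volumes are not on the same grid (dim/affine mismatch)")
}

#' Dice similarity coefficient of two binary segmentations
#'
#' `DSC(A, B) = 2 V(A intersect B) / (V(A) + V(B))`, with V the physical
#' volume (foreground voxel count times voxel volume).  Two empty masks are
#' defined to have DSC 1 (with a warning).
#'
#' @param A,B binary [label_volume()] objects on the same grid.
#' @return DSC in [0, 1].
#' @export
dsc <- function(A, B) {
  stopifnot(inherits(A, "label_volume"), inherits(B, "label_volume"))
  .check_same_grid(A, B)
  a <- A$data != 0; b <- B$data != 0
  va <- sum(a); vb <- sum(b)
  if (va + vb == 0) {
    warning("both masks empty; DSC defined as 1")
    return(1)
  }
  2 * sum(a & b) / (va + vb)
}

#' Absolute volume difference of two binary segmentations
#'
#' `AVD(A, B) = |V(A) - V(B)| / ((V(A) + V(B)) / 2)`, in [0, 2].  Only the
#' volumes enter; overlap is not needed.  Two empty masks give 0 (with a
#' warning).
#'
#' @param A,B binary [label_volume()] objects on the same grid.
#' @return AVD in [0, 2].
#' @export
avd <- function(A, B) {
  stopifnot(inherits(A, "label_volume"), inherits(B, "label_volume"))
  .check_same_grid(A, B)
  va <- .mask_volume(A); vb <- .mask_volume(B)
  if (va + vb == 0) {
    warning("both masks empty; AVD defined as 0")
    return(0)
  }
  abs(va - vb) / ((va + vb) / 2)
}

#' Pearson product-moment correlation of paired volume measurements
#'
#' @param x,y numeric vectors of equal length >= 3 with non-zero variance.
#' @return The correlation coefficient in [-1, 1].
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("`x` and `y` must have equal length >= 3")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

# inverse-distance-weighted 1-ring sums for every vertex:
# returns list(num = N x 3, den = N, deg = N)
.gl_ring_sums <- function(mesh) {
  v <- mesh$vertices
  e <- .mesh_edges(mesh)
  l <- sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
  if (any(l == 0))
    stop("degenerate (zero-length) edge; clean the mesh first")
  w <- 1 / l
  n <- nrow(v)
  num <- matrix(0, n, 3)
  den <- numeric(n)
  deg <- integer(n)
  for (side in 1:2) {
    from <- e[, side]; to <- e[, 3 - side]
    acc <- rowsum(v[to, , drop = FALSE] * w, from)
    ids <- as.integer(rownames(acc))
    num[ids, ] <- num[ids, ] + acc
    dacc <- rowsum(w, from)
    den[ids] <- den[ids] + dacc[, 1]
    deg[ids] <- deg[ids] + tabulate(from, n)[ids]
  }
  list(num = num, den = den, deg = deg)
}

#' Geometric Laplacian vector at one vertex
#'
#' `GL(v) = v - (sum_i l_i^-1 v_i) / (sum_i l_i^-1)` over the edge-connected
#' 1-ring neighbors `v_i` at Euclidean distances `l_i`: the offset of the
#' vertex from the inverse-distance-weighted centroid of its ring.  A local
#' roughness measure — the larger its norm, the rougher the surface at `v`.
#'
#' @param mesh a clean [tri_mesh()].
#' @param v 1-based vertex index.
#' @return The GL 3-vector (mm).
#' @export
gl_vertex <- function(mesh, v) {
  stopifnot(inherits(mesh, "tri_mesh"), v >= 1, v <= nrow(mesh$vertices))
  sums <- .gl_ring_sums(mesh)
  if (sums$deg[v] == 0) stop("isolated vertex has no 1-ring")
  mesh$vertices[v, ] - sums$num[v, ] / sums$den[v]
}

#' Geometric Laplacian of a surface
#'
#' The sum (not the mean) of the Euclidean norms of all vertex-wise
#' [gl_vertex()] vectors.  Invariant under rigid motion; scales linearly
#' under uniform scaling.
#'
#' @param mesh a clean [tri_mesh()] with no isolated vertices.
#' @return Non-negative roughness score.
#' @export
gl_surface <- function(mesh) {
  stopifnot(inherits(mesh, "tri_mesh"))
  sums <- .gl_ring_sums(mesh)
  if (any(sums$deg == 0)) stop("isolated vertex has no 1-ring")
  gl <- mesh$vertices - sums$num / sums$den
  sum(sqrt(rowSums(gl^2)))
}

#' Interquartile-range outlier analysis
#'
#' Quantiles use linear interpolation of order statistics (R type 7).
#' `rule = "as_printed"` flags values outside
#' `[Q1 - 1.5 IQR, Q1 + 1.5 IQR]` (the upper bound anchored at Q1);
#' `rule = "tukey"` uses the standard `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.
#' Flagged values lie strictly outside the bounds.
#'
#' @param values numeric vector, length >= 4.
#' @param rule `"as_printed"` (default) or `"tukey"`.
#' @return A list of class `outlier_report` with `q1`, `q3`, `lower`,
#'   `upper`, `outlier_indices` and `rule`.
#' @export
outlier_analysis <- function(values, rule = c("as_printed", "tukey")) {
  rule <- match.arg(rule)
  if (length(values) < 4) stop("need at least 4 values for outlier analysis")
  q <- unname(stats::quantile(values, c(0.25, 0.75), type = 7))
  iqr <- q[2] - q[1]
  lower <- q[1] - 1.5 * iqr
  upper <- if (rule == "as_printed") q[1] + 1.5 * iqr else q[2] + 1.5 * iqr
  structure(list(q1 = q[1], q3 = q[2], lower = lower, upper = upper,
                 outlier_indices = which(values < lower | values > upper),
                 rule = rule),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("<outlier_report> rule=", x$rule, " Q1=", signif(x$q1, 6), " Q3=",
      signif(x$q3, 6), " bounds=[", signif(x$lower, 6), ", ",
      signif(x$upper, 6), "]\n  outliers: ",
      if (length(x$outlier_indices)) paste(x$outlier_indices, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Welch two-sample t-test
#'
#' Two-sided, unequal-variance form.  When both samples are degenerate
#' (zero variance) with equal means the test is defined as t = 0, p = 1.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return A list with `t` and `p`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) return(list(t = 0, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), p = unname(ht$p.value))
}

#' CAG-Age Product (CAP) score and disease-burden subgroup
#'
#' `CAP = age x (CAG - 33.66)`; subgroups: CAP < 290 low-HD,
#' 290 <= CAP <= 368 mid-HD (both boundaries inclusive), CAP > 368 high-HD.
#'
#' @param age_years age at study entry, years (> 0).
#' @param cag CAG repeat length (integer).
#' @return A list with `cap` and `group`
#'   (`"low-HD"`, `"mid-HD"` or `"high-HD"`).
#' @export
cap_score <- function(age_years, cag) {
  stopifnot(age_years > 0)
  cap <- age_years * (cag - 33.66)
  group <- if (cap < 290) "low-HD" else if (cap <= 368) "mid-HD" else "high-HD"
  list(cap = cap, group = group)
}
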