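#' Canonical seed frame from a voxel grid
#'
#' Principal-component canonicalization: the principal axes of the occupied
#' voxel centers, ordered by decreasing spread, become x (length), y (width)
#' and z (thickness), with the origin at the centroid. Axis signs are fixed
#' deterministically (third central moment along each axis made
#' non-negative, near-zero skewness falling back to a positive largest
#' component; handedness restored by flipping the least-skewed axis).
#'
#' @param grid a [voxel_grid()] with occupied voxels.
#' @return list with `rotation` (3x3, rows = canonical axes; canonical
#'   coordinates are `rotation %*% (x - center)`) and `center`.
#' @export
canonical_frame <- function(grid) {
  X <- voxel_centers(grid, "occupied")
  if (!nrow(X)) sh_stop("grid has no occupied voxel", "seedhull_empty_hull")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  ev <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  A <- t(ev$vectors)                 # rows = axes, decreasing spread
  Y <- Xc %*% t(A)
  skews <- colMeans(Y^3)
  flip <- rep(1, 3)
  for (a in 1:3) {
    if (abs(skews[a]) > 1e-9) {
      if (skews[a] < 0) flip[a] <- -1
    } else if (A[a, which.max(abs(A[a, ]))] < 0) flip[a] <- -1
  }
  A <- A * flip
  if (det(A) < 0) {
    a0 <- which.min(abs(skews))
    A[a0, ] <- -A[a0, ]
  }
  list(rotation = A, center = as.numeric(ctr))
}

# Occupied voxel centers expressed in a canonical frame.
canonical_points <- function(grid, frame = canonical_frame(grid)) {
  X <- voxel_centers(grid, "occupied")
  sweep(X, 2, frame$center) %*% t(frame$rotation)
}

#' Axial extents (length, width, thickness) in the canonical frame
#'
#' Per-axis `max - min` over occupied voxel extents (voxels extend half a
#' spacing beyond their centers, so one spacing is added to the center
#' range); L from x, W from y, D from z.
#'
#' @param grid a [voxel_grid()].
#' @param frame optional precomputed [canonical_frame()].
#' @return named numeric `c(L, W, D)` in mm.
#' @export
extents <- function(grid, frame = canonical_frame(grid)) {
  Y <- canonical_points(grid, frame)
  e <- apply(Y, 2, function(v) diff(range(v))) + grid$spacing
  stats::setNames(e, c("L", "W", "D"))
}

#' Surface area by Heron's formula over mesh triangles
#'
#' \eqn{S = \sum_i \sqrt{l(l-a_i)(l-b_i)(l-c_i)}} with `l` the semiperimeter
#' of triangle i. Degenerate triangles contribute zero.
#'
#' @param mesh a `triangle_mesh`.
#' @return surface area in mm^2.
#' @export
mesh_area <- function(mesh) {
  V <- mesh$vertices; F_ <- mesh$faces
  if (!nrow(F_)) return(0)
  d <- function(i, j) sqrt(rowSums((V[F_[, i], , drop = FALSE] -
                                    V[F_[, j], , drop = FALSE])^2))
  a <- d(1, 2); b <- d(2, 3); cc <- d(3, 1)
  l <- (a + b + cc) / 2
  sum(sqrt(pmax(l * (l - a) * (l - b) * (l - cc), 0)))
}

#' @rdname mesh_area
#' @export
surface_area <- mesh_area

#' Cross-section area profile along a canonical axis
#'
#' Bins occupied voxels into `n` equal slabs along the chosen canonical axis;
#' each slab's cross-section area is its voxel volume divided by the slab
#' thickness. `n` defaults to the voxel count along the axis, i.e. one slab
#' per voxel layer.
#'
#' @param grid a [voxel_grid()].
#' @param axis 1 = length (x), 2 = width (y), 3 = thickness (z).
#' @param n number of slabs (>= 2).
#' @param frame optional precomputed [canonical_frame()].
#' @return object of class `slice_profile`: `areas` (mm^2), `positions`
#'   (slab centers, mm), `axis`, `n`, `extent` (mm).
#' @export
slice_profile <- function(grid, axis = 1, n = NULL,
                          frame = canonical_frame(grid)) {
  Y <- canonical_points(grid, frame)
  x <- Y[, axis]
  rng <- range(x)
  if (is.null(n)) n <- max(2L, ceiling(diff(rng) / grid$spacing) + 1L)
  if (n < 2) sh_stop("need at least 2 slices", "seedhull_insufficient_slices")
  br <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n + 1)
  h <- br[2] - br[1]
  bin <- findInterval(x, br, rightmost.closed = TRUE)
  counts <- tabulate(bin, n)
  structure(list(areas = counts * grid$spacing^3 / h,
                 positions = (br[-1] + br[-(n + 1)]) / 2,
                 axis = axis, n = n, extent = diff(rng) + grid$spacing),
            class = "slice_profile")
}

#' Volume by trapezoidal integration of slice areas
#'
#' \eqn{V = h \sum_i (A_i + A_{i+1})/2} over equally spaced cross-section
#' areas spanning the length extent. Exact for constant profiles (cylinder);
#' second-order accurate for smooth ones.
#'
#' @param profile a [slice_profile()] or plain numeric vector of areas.
#' @param length_extent extent spanned by the profile, mm; defaults to the
#'   profile's recorded extent.
#' @return volume in mm^3.
#' @export
volume_slices <- function(profile, length_extent = NULL) {
  areas <- if (inherits(profile, "slice_profile")) profile$areas else as.numeric(profile)
  if (length(areas) < 2)
    sh_stop("need at least 2 slice areas", "seedhull_insufficient_slices")
  if (is.null(length_extent)) {
    if (!inherits(profile, "slice_profile"))
      sh_stop("length_extent required for a bare area vector", "seedhull_insufficient_slices")
    length_extent <- profile$extent
  }
  h <- length_extent / (length(areas) - 1)
  h * sum((areas[-1] + areas[-length(areas)]) / 2)
}

#' Maximum projection area (shadow along the thickness axis)
#'
#' Area of the orthographic shadow of the occupancy onto the canonical x-y
#' (length-width) plane: the number of occupied (x, y) columns times the
#' voxel footprint.
#'
#' @param grid a [voxel_grid()].
#' @param frame optional precomputed [canonical_frame()].
#' @return area in mm^2; attribute `"mask"` carries the shadow raster used
#'   (for the roundness outline), with attributes `u0`, `v0`, `spacing`.
#' @export
max_projection_area <- function(grid, frame = canonical_frame(grid)) {
  sh <- shadow_mask(grid, frame, axes = c(1, 2))
  a <- sum(sh$mask) * grid$spacing^2
  attr(a, "mask") <- sh$mask
  a
}

# Binary shadow raster of canonical points onto a pair of axes.
shadow_mask <- function(grid, frame, axes = c(1, 2), points = NULL) {
  Y <- if (is.null(points)) canonical_points(grid, frame) else points
  s <- grid$spacing
  i <- floor(Y[, axes[1]] / s)
  j <- floor(Y[, axes[2]] / s)
  i <- i - min(i) + 2L; j <- j - min(j) + 2L
  mask <- matrix(0L, max(j) + 2L, max(i) + 2L)   # rows = second axis
  mask[cbind(j, i)] <- 1L
  list(mask = mask, spacing = s)
}

#' Cardioid-derived area: maximum transverse cross-section
#'
#' The largest cross-section area over slices perpendicular to the length
#' axis (the width-thickness plane). For creased grains this outline is the
#' heart-shaped curve; removing a ventral groove strictly reduces it.
#'
#' @param grid a [voxel_grid()].
#' @param frame optional precomputed [canonical_frame()].
#' @return area in mm^2.
#' @export
cardioid_area <- function(grid, frame = canonical_frame(grid)) {
  prof <- slice_profile(grid, axis = 1, frame = frame)
  max(prof$areas)
}

#' J index: cardioid area normalized by the width-thickness rectangle
#'
#' `J = A_C / (W * D)`, dimensionless in (0, 1]; pi/4 for an elliptical
#' cross-section inscribed in its bounding rectangle.
#'
#' @param A_C cardioid-derived area, mm^2.
#' @param W,D seed width and thickness, mm (> 0).
#' @return J index.
#' @export
j_index <- function(A_C, W, D) {
  if (W <= 0 || D <= 0) sh_stop("W and D must be positive", "seedhull_division_by_zero")
  A_C / (W * D)
}

#' Roundness of a closed outline
#'
#' The perimeter is the sum of closed-polygon edge lengths
#' \eqn{P = \sum_j \sqrt{(x_j - x_{j+1})^2 + (y_j - y_{j+1})^2}} (wrapping
#' around), normalized to the isoperimetric ratio `R = 4 pi A / P^2`, which
#' is 1 for a circle and < 1 otherwise.
#'
#' @param outline m x 2 closed polygon (m >= 3), e.g. from
#'   [silhouette_contour()].
#' @return roundness in (0, 1].
#' @export
roundness <- function(outline) {
  p <- as.matrix(outline)
  if (nrow(p) < 3)
    sh_stop("outline needs at least 3 vertices", "seedhull_degenerate_outline")
  P <- polygon_perimeter(p)
  A <- abs(polygon_area(p))
  if (P <= 0 || A <= 0)
    sh_stop("outline has zero perimeter or area", "seedhull_degenerate_outline")
  4 * pi * A / P^2
}

#' Measure all nine traits of a reconstructed seed
#'
#' Composes the trait extractors in the canonical frame: length, width,
#' thickness (axial extents), surface area (Heron over the mesh), volume
#' (trapezoidal slice integration along the length axis), maximum projection
#' area (shadow along thickness), roundness of the shadow outline,
#' cardioid-derived area (max transverse section) and the J index.
#'
#' @param grid a [voxel_grid()] from [carve()].
#' @param mesh optional matching `triangle_mesh`; extracted from the grid
#'   when missing.
#' @return object of class `seed_traits`: named list with `L`, `W`, `D`,
#'   `S`, `V`, `A`, `R`, `A_C`, `J` plus `frame`.
#' @export
measure_all <- function(grid, mesh = NULL) {
  frame <- canonical_frame(grid)
  if (is.null(mesh)) mesh <- mesh_from_grid(grid)
  e <- extents(grid, frame)
  S <- mesh_area(mesh)
  prof <- slice_profile(grid, axis = 1, frame = frame)
  V <- volume_slices(prof)
  A <- max_projection_area(grid, frame)
  A_C <- cardioid_area(grid, frame)
  J <- j_index(A_C, e[["W"]], e[["D"]])
  outline <- silhouette_contour(attr(A, "mask"))
  R <- roundness(outline * grid$spacing)
  structure(list(L = e[["L"]], W = e[["W"]], D = e[["D"]], S = S, V = V,
                 A = as.numeric(A), R = R, A_C = A_C, J = J, frame = frame),
            class = "seed_traits")
}

#' @export
print.seed_traits <- function(x, ...) {
  cat("seed traits:\n")
  cat(sprintf("  L = %.3f mm, W = %.3f mm, D = %.3f mm\n", x$L, x$W, x$D))
  cat(sprintf("  S = %.3f mm^2, V = %.3f mm^3\n", x$S, x$V))
  cat(sprintf("  A = %.3f mm^2, A_C = %.3f mm^2\n", x$A, x$A_C))
  cat(sprintf("  R = %.4f, J = %.4f\n", x$R, x$J))
  invisible(x)
}

#' @export
as.data.frame.seed_traits <- function(x, ...) {
  data.frame(L = x$L, W = x$W, D = x$D, S = x$S, V = x$V, A = x$A,
             R = x$R, A_C = x$A_C, J = x$J)
}
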