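#' Voxel grid container
#'
#' Regular isotropic 3D lattice with per-voxel states 0 = outside,
#' 1 = surface (occupied with at least one face-adjacent outside voxel),
#' 2 = inside (occupied, all six face neighbors occupied). Voxel (i, j, k)
#' (1-based) has its center at `origin + (c(i, j, k) - 0.5) * spacing` in the
#' carving (world) frame.
#'
#' @param origin corner of the grid, mm (3-vector).
#' @param spacing isotropic voxel edge length, mm (> 0).
#' @param dims integer 3-vector (nx, ny, nz).
#' @param state optional integer array of states.
#' @return object of class `voxel_grid`.
#' @export
voxel_grid <- function(origin, spacing, dims, state = NULL) {
  stopifnot(spacing > 0, length(dims) == 3, all(dims >= 1))
  dims <- as.integer(dims)
  if (is.null(state)) state <- array(0L, dims)
  stopifnot(all(dim(state) == dims))
  structure(list(origin = as.numeric(origin), spacing = spacing,
                 dims = dims, state = state),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  occ <- sum(x$state > 0)
  cat(sprintf("voxel grid %dx%dx%d, spacing %.5f mm, %d occupied (%d surface, %d inside)\n",
              x$dims[1], x$dims[2], x$dims[3], x$spacing,
              occ, sum(x$state == 1L), sum(x$state == 2L)))
  invisible(x)
}

#' Voxel center coordinates of occupied (or all) voxels
#' @param grid a [voxel_grid()].
#' @param which `"occupied"`, `"surface"`, `"inside"` or `"all"`.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_centers <- function(grid, which = c("occupied", "surface", "inside", "all")) {
  which <- match.arg(which)
  sel <- switch(which,
                occupied = grid$state > 0L,
                surface = grid$state == 1L,
                inside = grid$state == 2L,
                all = array(TRUE, grid$dims))
  idx <- which(sel, arr.ind = TRUE)
  sweep((idx - 0.5) * grid$spacing, 2, -grid$origin)
}

#' Total occupied volume from the voxel count
#' @param grid a [voxel_grid()].
#' @return volume in mm^3 (`count * spacing^3`).
#' @export
voxel_volume <- function(grid) sum(grid$state > 0L) * grid$spacing^3

#' Carve the visual hull of a seed from silhouettes
#'
#' Shape-from-silhouette: a voxel is occupied iff its center projects inside
#' the silhouette in *every* view (nearest-pixel lookup of the binary mask);
#' centers projecting outside any image are outside. Occupied voxels are then
#' partitioned into surface (>= 1 face-adjacent outside neighbor; the grid
#' boundary counts as outside) and inside. The visual hull always contains
#' the imaged object, so the carved volume is an upper bound that tightens
#' as views are added.
#'
#' @param masks list of 0/1 silhouette matrices (one per view, same size).
#' @param projections matching list of [build_projection()] matrices mapping
#'   the carving frame to each view's pixels.
#' @param origin,spacing,dims grid specification; when any is `NULL` the grid
#'   is auto-sized (see [auto_grid_spec()]) with `resolution` voxels along
#'   the largest extent.
#' @param resolution default cube resolution for auto-sizing (128, matching
#'   the reference pipeline).
#' @return a [voxel_grid()]. Error class `seedhull_empty_hull` when nothing
#'   survives; an empty silhouette forces this (with a warning first).
#' @export
carve <- function(masks, projections, origin = NULL, spacing = NULL,
                  dims = NULL, resolution = 128) {
  stopifnot(length(masks) == length(projections), length(masks) >= 2)
  if (any(vapply(masks, function(m) !any(m > 0), logical(1)))) {
    sh_warn("at least one silhouette is empty; hull is empty",
            "seedhull_empty_silhouette")
    sh_stop("empty silhouette makes the visual hull empty", "seedhull_empty_hull")
  }
  if (is.null(origin) || is.null(spacing) || is.null(dims)) {
    gs <- auto_grid_spec(masks, projections, resolution)
    origin <- gs$origin; spacing <- gs$spacing; dims <- gs$dims
  }
  dims <- as.integer(dims)
  n <- prod(dims)
  occ_idx <- seq_len(n)          # linear indices of still-occupied voxels
  for (v in seq_along(masks)) {
    if (!length(occ_idx)) break
    P <- as_P(projections[[v]])
    m <- masks[[v]]
    ai <- arrayInd(occ_idx, dims)
    X <- sweep((ai - 0.5) * spacing, 2, -origin)
    h <- cbind(X, 1) %*% t(P)
    u <- round(h[, 1] / h[, 3]); vv <- round(h[, 2] / h[, 3])
    ok <- h[, 3] > 0 & u >= 1 & u <= ncol(m) & vv >= 1 & vv <= nrow(m)
    ok[ok] <- m[cbind(vv[ok], u[ok])] > 0
    occ_idx <- occ_idx[ok]
  }
  if (!length(occ_idx))
    sh_stop("no voxel projects inside all silhouettes", "seedhull_empty_hull")
  occ <- array(FALSE, dims)
  occ[occ_idx] <- TRUE
  voxel_grid(origin, spacing, dims, classify_states(occ))
}

# Partition an occupancy array into surface (1) / inside (2) states.
classify_states <- function(occ) {
  dims <- dim(occ)
  all_n <- array(TRUE, dims)
  shift_occ <- function(dlt) {
    out <- array(FALSE, dims)
    src <- lapply(1:3, function(a) {
      i <- seq_len(dims[a]) + dlt[a]
      i[i < 1 | i > dims[a]] <- NA
      i
    })
    valid <- lapply(src, function(i) !is.na(i))
    out_idx <- lapply(1:3, function(a) which(valid[[a]]))
    out[out_idx[[1]], out_idx[[2]], out_idx[[3]]] <-
      occ[src[[1]][valid[[1]]], src[[2]][valid[[2]]], src[[3]][valid[[3]]]]
    out
  }
  for (a in 1:3) for (s in c(-1L, 1L)) {
    d <- integer(3); d[a] <- s
    all_n <- all_n & shift_occ(d)
  }
  state <- array(0L, dims)
  state[occ & !all_n] <- 1L   # surface
  state[occ & all_n] <- 2L    # inside
  state
}

#' Auto-size a carving grid from back-projected silhouette extents
#'
#' Estimates the seed's bounding box in the carving frame from the pixel
#' extents of each silhouette scaled by the depth of the frame origin (the
#' rotation-axis point), adds a 5% margin, and centers a cubic grid with
#' `resolution` voxels along the largest extent.
#'
#' @inheritParams carve
#' @return list with `origin`, `spacing`, `dims`.
#' @export
auto_grid_spec <- function(masks, projections, resolution = 128, margin = 0.05) {
  rad <- 0; zmin <- Inf; zmax <- -Inf
  for (v in seq_along(masks)) {
    pr <- projections[[v]]
    m <- masks[[v]]
    fg <- which(m > 0, arr.ind = TRUE)
    if (!nrow(fg)) next
    uv0 <- project_points(pr, c(0, 0, 0))
    depth <- attr(uv0, "depth")
    mmpx_u <- depth / pr$K[1, 1]
    mmpx_v <- depth / pr$K[2, 2]
    du <- (fg[, 2] - uv0[1]) * mmpx_u
    dv <- (fg[, 1] - uv0[2]) * mmpx_v
    rad <- max(rad, abs(du))
    zmin <- min(zmin, min(dv)); zmax <- max(zmax, max(dv))
  }
  # carving frame: z along the rotation axis; image v maps (approximately)
  # to -z and u to lateral distance from the axis
  half_xy <- rad * (1 + margin) + 1e-9
  zr <- c(-zmax, -zmin) * (1 + margin)
  ext <- c(2 * half_xy, 2 * half_xy, diff(range(zr)))
  spacing <- max(ext) / resolution
  dims <- pmax(8L, as.integer(ceiling(ext / spacing)) + 2L)
  origin <- c(-dims[1] / 2 * spacing, -dims[2] / 2 * spacing,
              mean(range(zr)) - dims[3] / 2 * spacing)
  list(origin = origin, spacing = spacing, dims = dims)
}
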