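#' Parametric seed solid with an optional ventral crease
#'
#' Synthetic stand-in for a wheat grain: a superellipsoid
#' \eqn{|x/a|^p + |y/b|^p + |z/c|^p \le 1} (p = 2 gives an ellipsoid) from
#' which a cylindrical groove along the length (x) axis may be subtracted,
#' emulating the ventral crease that produces the heart-shaped transverse
#' section of real grains. The crease cylinder runs parallel to x at y = 0,
#' biting `crease_depth` mm into the +z face.
#'
#' The returned object carries a vectorized `inside(X)` predicate and a
#' reference volume: closed-form \eqn{8abc\,\Gamma(1+1/p)^3/\Gamma(1+3/p)}
#' for the uncreased solid, minus a high-resolution numeric integral of the
#' grooved-out material.
#'
#' @param a,b,c semi-axes in mm, `a >= b >= c > 0` (length, width, thickness).
#' @param exponent superellipsoid exponent p (>= 1); 2 = ellipsoid.
#' @param crease_depth depth of the groove below the +z surface, mm
#'   (0 = none; must be < c).
#' @param crease_width full width of the groove, mm (default `2 * crease_depth`).
#' @param pose optional [rigid_pose()] placing the solid in the world frame
#'   (`X_world = R X_solid + T`); identity when `NULL`.
#' @return object of class `seed_solid` with elements `inside` (function of an
#'   n x 3 world-coordinate matrix returning logicals), `reference_volume`
#'   (mm^3), `bound_radius` (mm, world-frame bounding-sphere radius about
#'   `center`), `center`, and the spec fields.
#' @export
#' @examples
#' s <- make_seed_solid(3.3, 1.6, 1.4)
#' abs(s$reference_volume - 4 / 3 * pi * 3.3 * 1.6 * 1.4) < 1e-3
make_seed_solid <- function(a, b, c, exponent = 2, crease_depth = 0,
                            crease_width = 2 * crease_depth, pose = NULL) {
  if (!(a >= b && b >= c && c > 0))
    sh_stop("semi-axes must satisfy a >= b >= c > 0", "seedhull_invalid_spec")
  if (exponent < 1) sh_stop("exponent must be >= 1", "seedhull_invalid_spec")
  if (crease_depth < 0 || crease_depth >= c)
    sh_stop("crease_depth must be in [0, c)", "seedhull_invalid_spec")
  if (crease_depth > 0 && crease_width <= 0)
    sh_stop("crease_width must be positive", "seedhull_invalid_spec")
  p <- exponent
  rc <- crease_width / 2
  z0 <- if (crease_depth > 0) c - crease_depth + rc else NA_real_

  inside_local <- function(X) {
    v <- abs(X[, 1] / a)^p + abs(X[, 2] / b)^p + abs(X[, 3] / c)^p <= 1
    if (crease_depth > 0)
      v <- v & !(X[, 2]^2 + (X[, 3] - z0)^2 <= rc^2)
    v
  }
  inside <- if (is.null(pose)) {
    function(X) inside_local(rbind_points(X))
  } else {
    function(X) {
      X <- rbind_points(X)
      inside_local(sweep(X, 2, pose$T) %*% pose$R)  # R^T (X - T), row form
    }
  }

  v_full <- 8 * a * b * c * gamma(1 + 1 / p)^3 / gamma(1 + 3 / p)
  v_crease <- if (crease_depth > 0) .crease_volume(a, b, c, p, rc, z0) else 0

  center <- if (is.null(pose)) c(0, 0, 0) else as.numeric(pose$T)
  structure(list(inside = inside, reference_volume = v_full - v_crease,
                 a = a, b = b, c = c, exponent = p,
                 crease_depth = crease_depth, crease_width = crease_width,
                 pose = pose, center = center,
                 bound_radius = sqrt(a^2 + b^2 + c^2)),
            class = "seed_solid")
}

# Volume of (superellipsoid intersect crease cylinder) by slice-wise 2D
# midpoint quadrature restricted to the cylinder cross-section.
.crease_volume <- function(a, b, c, p, rc, z0, nx = 240, nyz = 120) {
  xs <- (seq_len(nx) - 0.5) / nx * a          # symmetric in x, integrate half
  ys <- seq(-rc, rc, length.out = nyz)
  zs <- seq(z0 - rc, min(z0 + rc, c), length.out = nyz)
  dy <- ys[2] - ys[1]; dz <- zs[2] - zs[1]
  g <- expand.grid(y = ys, z = zs)
  in_cyl <- g$y^2 + (g$z - z0)^2 <= rc^2
  gy <- abs(g$y / b)^p; gz <- abs(g$z / c)^p
  areas <- vapply(xs, function(x) {
    sum(in_cyl & (gy + gz <= 1 - (x / a)^p)) * dy * dz
  }, numeric(1))
  2 * sum(areas) * (a / nx)
}

#' @export
print.seed_solid <- function(x, ...) {
  cat(sprintf("seed solid: semi-axes (%.3f, %.3f, %.3f) mm, exponent %.2f, crease %.3f x %.3f mm, V_ref %.4f mm^3\n",
              x$a, x$b, x$c, x$exponent, x$crease_depth, x$crease_width,
              x$reference_volume))
  invisible(x)
}

#' Render binary silhouettes of a solid under known projection matrices
#'
#' Ray-marches the solid's inside predicate along the camera ray through every
#' candidate pixel (restricted to the projected bounding sphere): a pixel is
#' foreground iff its ray intersects the solid. Boundary accuracy is about
#' one pixel for the default step count.
#'
#' @param solid a [make_seed_solid()] object (any object with `inside`,
#'   `center`, `bound_radius` works).
#' @param projections list of [build_projection()] matrices.
#' @param image_size `c(height, width)` in pixels.
#' @param n_steps ray-march samples across the bounding sphere.
#' @return list of integer 0/1 matrices (`height x width`), one per view.
#' @export
render_silhouettes <- function(solid, projections, image_size = c(280, 320),
                               n_steps = 96) {
  h <- image_size[1]; w <- image_size[2]
  lapply(seq_along(projections), function(vi) {
    pr <- projections[[vi]]
    K <- pr$K; R <- pr$pose$R; T_ <- pr$pose$T
    C <- as.numeric(-crossprod(R, T_))          # camera center, world
    uv0 <- project_points(pr, solid$center)
    depth <- attr(uv0, "depth")
    if (!is.finite(depth) || depth <= solid$bound_radius)
      sh_stop("solid not in front of the camera", "seedhull_out_of_frustum")
    prad <- solid$bound_radius * sqrt(K[1, 1] * K[2, 2]) / depth * 1.2 + 2
    if (uv0[1] + prad < 1 || uv0[1] - prad > w ||
        uv0[2] + prad < 1 || uv0[2] - prad > h)
      sh_stop("solid projects outside the image", "seedhull_out_of_frustum")
    us <- max(1L, floor(uv0[1] - prad)):min(w, ceiling(uv0[1] + prad))
    vs <- max(1L, floor(uv0[2] - prad)):min(h, ceiling(uv0[2] + prad))
    g <- expand.grid(u = us, v = vs)
    dirs <- solve(K, t(cbind(g$u, g$v, 1)))     # camera-frame ray directions
    dirs <- crossprod(R, dirs)                  # world frame
    dirs <- t(dirs) / sqrt(colSums(dirs^2))    # n x 3 unit
    dc <- sqrt(sum((solid$center - C)^2))
    ts <- seq(dc - solid$bound_radius, dc + solid$bound_radius,
              length.out = n_steps)
    hit <- rep(FALSE, nrow(g))
    for (t_ in ts) {
      idx <- which(!hit)
      if (!length(idx)) break
      Xw <- sweep(dirs[idx, , drop = FALSE] * t_, 2, -C)
      hit[idx] <- solid$inside(Xw)
    }
    mask <- matrix(0L, h, w)
    mask[cbind(g$v, g$u)] <- as.integer(hit)
    if (any(mask[1, ] > 0) || any(mask[h, ] > 0) ||
        any(mask[, 1] > 0) || any(mask[, w] > 0))
      sh_warn(sprintf("silhouette touches the image border in view %d; carving will truncate the hull", vi),
              "seedhull_clipped_silhouette")
    attr(mask, "view_index") <- vi - 1L
    mask
  })
}

#' Render an anti-aliased checkerboard image with ground-truth corners
#'
#' Intersects each pixel's camera ray with the board plane (z_w = 0) and
#' colors it by the checker parity, supersampled for anti-aliasing. The board
#' carries `rows x cols` interior corners at `pitch` spacing (so
#' `(rows+1) x (cols+1)` squares); pixels off the board see a mid-gray
#' background.
#'
#' @param board a [board_spec()].
#' @param pose board pose (board frame -> camera), a [rigid_pose()].
#' @param intr [intrinsics()].
#' @param image_size `c(height, width)` pixels.
#' @param supersample linear supersampling factor per pixel.
#' @param tones grayscale values `c(dark, light, background)`.
#' @return list with `image` (height x width matrix in [0, 1]) and `corners`
#'   (rows*cols x 2 ground-truth pixel coordinates, canonical row-major
#'   board order).
#' @export
render_checkerboard <- function(board, pose, intr, image_size = c(360, 360),
                                supersample = 3, tones = c(0.12, 0.88, 0.5)) {
  h <- image_size[1]; w <- image_size[2]
  pr <- build_projection(intr, pose)
  W <- board_world_points(board)
  uv <- project_points(pr, W)
  if (any(attr(uv, "depth") <= 0))
    sh_stop("board is behind the camera", "seedhull_out_of_frustum")
  if (any(uv[, 1] < 1 | uv[, 1] > w | uv[, 2] < 1 | uv[, 2] > h))
    sh_stop("board corners project outside the image", "seedhull_out_of_frustum")
  K <- pr$K; R <- pose$R; T_ <- pose$T
  C <- as.numeric(-crossprod(R, T_))
  ss <- supersample
  off <- (seq_len(ss) - (ss + 1) / 2) / ss
  img <- matrix(0, h, w)
  px <- expand.grid(u = seq_len(w), v = seq_len(h))
  acc <- numeric(nrow(px))
  p <- board$pitch
  xr <- c(-p, board$cols * p); yr <- c(-p, board$rows * p)
  for (du in off) for (dv in off) {
    dirs <- solve(K, t(cbind(px$u + du, px$v + dv, 1)))
    dirs <- crossprod(R, dirs)                  # world-frame directions
    tt <- -C[3] / dirs[3, ]
    x <- C[1] + tt * dirs[1, ]
    y <- C[2] + tt * dirs[2, ]
    on <- tt > 0 & x >= xr[1] & x <= xr[2] & y >= yr[1] & y <= yr[2]
    parity <- (floor(x / p) + floor(y / p)) %% 2
    val <- ifelse(on, ifelse(parity == 0, tones[1], tones[2]), tones[3])
    acc <- acc + val
  }
  img[cbind(px$v, px$u)] <- acc / (ss * ss)
  list(image = img, corners = uv[, 1:2, drop = FALSE])
}

#' Germplasm simulation specification
#'
#' Defines a multi-variety trait simulation: per-variety, per-trait Gaussian
#' means and SDs, parent/offspring roles, and per-offspring variance shifts
#' used by the genetic-variation-factor analysis (offspring trait variance is
#' `(Var(P1) + Var(P2)) * (1 + shift)`).
#'
#' @param varieties data.frame with columns `variety`, `group`, `role`
#'   (`"parent"` or `"offspring"`).
#' @param means,sds numeric matrices, one row per variety, one column per
#'   trait (`sds >= 0`).
#' @param n_per_variety seeds drawn per variety (>= 2).
#' @return object of class `germplasm_sim_spec`.
#' @seealso [default_germplasm_spec()], [simulate_germplasm()]
#' @export
germplasm_sim_spec <- function(varieties, means, sds, n_per_variety = 30) {
  means <- as.matrix(means); sds <- as.matrix(sds)
  if (nrow(varieties) != nrow(means) || !all(dim(means) == dim(sds)))
    sh_stop("varieties, means, sds must agree in size", "seedhull_invalid_spec")
  if (any(sds < 0)) sh_stop("sds must be non-negative", "seedhull_invalid_spec")
  if (n_per_variety < 2) sh_stop("need >= 2 seeds per variety", "seedhull_invalid_spec")
  if (is.null(colnames(means))) colnames(means) <- paste0("trait", seq_len(ncol(means)))
  colnames(sds) <- colnames(means)
  structure(list(varieties = varieties, means = means, sds = sds,
                 n_per_variety = as.integer(n_per_variety)),
            class = "germplasm_sim_spec")
}

#' Nine reference trait names
#' @return character vector: L, W, D, S, V, A, R, A_C, J.
#' @export
trait_names <- function() c("L", "W", "D", "S", "V", "A", "R", "A_C", "J")

# Pooled study-scale trait means and SDs used to parameterize the default
# simulation (mm / mm^2 / mm^3 / dimensionless).
.trait_means <- c(L = 6.67, W = 3.23, D = 2.83, S = 52.36, V = 28.77,
                  A = 16.45, R = 0.61, A_C = 7.29, J = 0.79)
.trait_sds <- c(L = 0.44, W = 0.31, D = 0.24, S = 7.54, V = 6.45,
                A = 2.41, R = 0.04, A_C = 1.24, J = 0.03)

#' Default germplasm simulation: 2 parents + 13 offspring, 30 seeds each
#'
#' Emulates the reference study design: 15 varieties (parents P1, P2; a first
#' offspring batch of 6 and a second of 7), 30 seeds per variety, nine traits.
#' Pooled means and dispersions are set to the study-scale values (e.g. mean
#' volume 28.77 mm^3 with pooled SD 6.45 mm^3, i.e. a pooled phenotypic CV of
#' ~22%). The pooled SD decomposes into a between-variety component (0.6 of
#' the pooled SD, as fixed deterministic variety offsets) and within-variety
#' components: parents get SD `w * pooled`, each offspring the
#' GVF-generating variance `(Var(P1)+Var(P2)) * (1 + shift)`, and `w` is
#' solved so the pooled variance recomposes to the target. The default
#' shifts make variety F1 decisively the most divergent (shift 1.0 vs at
#' most 0.12 elsewhere -- roughly an order of magnitude, so the designed
#' ranking is statistically unambiguous at 30 seeds per variety), giving the
#' GVF ranking a designed ground truth at realistic GVF magnitudes of a few
#' percent (the divergent variety lands near the top of the observed range).
#'
#' @param n_per_variety seeds per variety.
#' @param var_shift optional length-13 vector of offspring variance shifts.
#' @return a [germplasm_sim_spec()].
#' @export
default_germplasm_spec <- function(n_per_variety = 30, var_shift = NULL) {
  vs <- data.frame(
    variety = c("P1", "P2", paste0("F", 1:13)),
    group = c("parent", "parent", rep("batch1", 6), rep("batch2", 7)),
    role = c("parent", "parent", rep("offspring", 13)),
    stringsAsFactors = FALSE)
  nt <- length(.trait_means)
  q <- stats::qnorm(stats::ppoints(15))
  q <- q / stats::sd(q)
  means <- outer(rep(1, 15), .trait_means) + outer(q, 0.6 * .trait_sds)
  colnames(means) <- names(.trait_means)
  rownames(means) <- vs$variety
  if (is.null(var_shift))
    var_shift <- c(1.0, seq(0.02, 0.12, length.out = 12))
  stopifnot(length(var_shift) == 13)
  # parent within-SD fraction w solved so the pooled variance recomposes to
  # the target: between^2 + (2 w^2 / 15) (1 + sum(1 + shift)) = 1
  w <- sqrt((1 - 0.6^2) * 15 / (2 * (1 + sum(1 + var_shift))))
  sds <- outer(rep(1, 15), w * .trait_sds)
  parent_var <- sds[1, ]^2 + sds[2, ]^2
  for (i in 1:13)
    sds[2 + i, ] <- sqrt(parent_var * (1 + var_shift[i]))
  dimnames(sds) <- dimnames(means)
  spec <- germplasm_sim_spec(vs, means, sds, n_per_variety)
  spec$var_shift <- stats::setNames(var_shift, vs$variety[-(1:2)])
  spec
}

#' Simulate a germplasm trait table
#'
#' Draws independent Gaussian trait values per seed according to the spec.
#' Fully deterministic given `seed`; the global RNG state is restored on exit.
#'
#' @param spec a [germplasm_sim_spec()].
#' @param seed integer random seed.
#' @return `trait_table` data.frame: `seed_id`, `variety`, `group`, `role`,
#'   then one column per trait.
#' @export
#' @examples
#' tab <- simulate_germplasm(default_germplasm_spec(), seed = 1)
#' nrow(tab)  # 450
simulate_germplasm <- function(spec, seed = 1) {
  if (!inherits(spec, "germplasm_sim_spec"))
    sh_stop("spec must be a germplasm_sim_spec", "seedhull_invalid_spec")
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  n <- spec$n_per_variety
  nt <- ncol(spec$means)
  rows <- lapply(seq_len(nrow(spec$varieties)), function(i) {
    vals <- matrix(stats::rnorm(n * nt, mean = rep(spec$means[i, ], each = n),
                                sd = rep(spec$sds[i, ], each = n)), n, nt)
    colnames(vals) <- colnames(spec$means)
    data.frame(seed_id = paste0(spec$varieties$variety[i], "_", seq_len(n)),
               variety = spec$varieties$variety[i],
               group = spec$varieties$group[i],
               role = spec$varieties$role[i],
               vals, stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trait_table", "data.frame")
  out
}
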