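#' Detect checkerboard corners with subpixel refinement
#'
#' Interior checkerboard corners are saddle points of the (slightly blurred)
#' intensity surface: the local pattern is antisymmetric under 180-degree
#' rotation about the corner, so the saddle of the blurred image coincides
#' with the true corner. Detection proceeds by (1) Gaussian blur, (2) a
#' saddle response `Ixy^2 - Ixx * Iyy` from finite-difference Hessians,
#' (3) non-maximum suppression, (4) subpixel refinement by solving for the
#' stationary point of a local quadratic fit to the blurred intensity, and
#' (5) recovery of the grid topology and canonical row-major ordering (origin
#' at the corner nearest the image top-left).
#'
#' @param image numeric matrix (height x width), any grayscale range.
#' @param board a [board_spec()].
#' @param sigma blur scale in pixels (default 2: heavier blur averages more
#'   rendering/sensor noise while the saddle location is pinned by the
#'   corner's point symmetry).
#' @return (rows*cols) x 2 matrix of subpixel `(u, v)` pixel coordinates in
#'   canonical order. Errors: condition class `seedhull_no_board_found` when
#'   too few saddle points survive, `seedhull_ambiguous_ordering` when the
#'   grid topology cannot be recovered.
#' @export
detect_corners <- function(image, board, sigma = 2) {
  im <- as.matrix(image)
  if (diff(range(im)) < 1e-8)
    sh_stop("image is constant; no corners present", "seedhull_no_board_found")
  n_need <- board$rows * board$cols
  B <- gauss_blur(im, sigma)
  Ixx <- shift_mat(B, 0, 1) + shift_mat(B, 0, -1) - 2 * B
  Iyy <- shift_mat(B, 1, 0) + shift_mat(B, -1, 0) - 2 * B
  Ixy <- (shift_mat(B, 1, 1) + shift_mat(B, -1, -1) -
          shift_mat(B, 1, -1) - shift_mat(B, -1, 1)) / 4
  resp <- Ixy^2 - Ixx * Iyy
  m <- ceiling(3 * sigma) + 2
  resp[c(seq_len(m), nrow(resp) - seq_len(m) + 1L), ] <- -Inf
  resp[, c(seq_len(m), ncol(resp) - seq_len(m) + 1L)] <- -Inf
  # 3x3 non-maximum suppression
  is_max <- resp > 0
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & resp >= shift_mat(resp, dr, dc, fill = -Inf)
  }
  idx <- which(is_max)
  if (length(idx) < n_need)
    sh_stop(sprintf("found %d saddle candidates, need %d", length(idx), n_need),
            "seedhull_no_board_found")
  vals <- resp[idx]
  ord <- order(vals, decreasing = TRUE)
  idx <- idx[ord][seq_len(min(length(idx), 3L * n_need))]
  rc <- cbind((idx - 1L) %% nrow(resp) + 1L, (idx - 1L) %/% nrow(resp) + 1L)
  # checkerboard corners have alternating dark/light quadrants: on a small
  # sampling ring the 2nd angular harmonic dominates (board-edge or outline
  # saddles carry a dominant 1st harmonic instead)
  keep <- apply(rc, 1, function(p) ring_harmonic_ok(B, p[2], p[1]))
  rc <- rc[keep, , drop = FALSE]
  pts <- t(apply(rc, 1, function(p) refine_saddle(B, p[1], p[2])))
  # refinement can converge from two adjacent response peaks to one corner;
  # keep the strongest representative within a 2 px radius
  sel <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!sel[i]) next
    d2 <- (pts[, 1] - pts[i, 1])^2 + (pts[, 2] - pts[i, 2])^2
    dup <- which(sel & d2 < 4)
    sel[setdiff(dup, i)] <- FALSE      # earlier rows have higher response
  }
  pts <- pts[sel, , drop = FALSE]
  if (nrow(pts) < n_need)
    sh_stop(sprintf("only %d checkerboard-like corners, need %d", nrow(pts), n_need),
            "seedhull_no_board_found")
  pts <- pts[seq_len(n_need), , drop = FALSE]
  order_corner_grid(pts, board$rows, board$cols)
}

# Separable Gaussian blur with replicated borders.
gauss_blur <- function(im, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  acc <- matrix(0, nrow(im), ncol(im))
  for (i in seq_along(k)) acc <- acc + k[i] * shift_mat(im, (-r:r)[i], 0)
  out <- matrix(0, nrow(im), ncol(im))
  for (i in seq_along(k)) out <- out + k[i] * shift_mat(acc, 0, (-r:r)[i])
  out
}

# Shift a matrix by (dr, dc), replicating (or filling) borders.
shift_mat <- function(m, dr, dc, fill = NULL) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) - dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) - dc, 1L), nc)
  out <- m[ri, ci, drop = FALSE]
  if (!is.null(fill)) {
    if (dr > 0) out[seq_len(min(dr, nr)), ] <- fill
    if (dr < 0) out[nr - seq_len(min(-dr, nr)) + 1L, ] <- fill
    if (dc > 0) out[, seq_len(min(dc, nc))] <- fill
    if (dc < 0) out[, nc - seq_len(min(-dc, nc)) + 1L] <- fill
  }
  out
}

# Bilinear sample of a matrix at continuous (u = col, v = row) positions.
bilinear_sample <- function(m, u, v) {
  u <- pmin(pmax(u, 1), ncol(m) - 1e-9)
  v <- pmin(pmax(v, 1), nrow(m) - 1e-9)
  c0 <- floor(u); r0 <- floor(v)
  fu <- u - c0; fv <- v - r0
  m[cbind(r0, c0)] * (1 - fu) * (1 - fv) +
    m[cbind(r0, c0 + 1)] * fu * (1 - fv) +
    m[cbind(r0 + 1, c0)] * (1 - fu) * fv +
    m[cbind(r0 + 1, c0 + 1)] * fu * fv
}

# Second-angular-harmonic dominance test, passed if any sampling ring radius
# shows the alternating-quadrant signature (perspective can weaken one ring).
ring_harmonic_ok <- function(B, u, v, radii = c(3, 4, 6), n = 16) {
  th <- (seq_len(n) - 1) * 2 * pi / n
  for (radius in radii) {
    s <- bilinear_sample(B, u + radius * cos(th), v + radius * sin(th))
    f <- s - mean(s)
    a1 <- Mod(sum(f * exp(-1i * th)))
    a2 <- Mod(sum(f * exp(-2i * th)))
    if (a2 > 1.2 * a1) return(TRUE)
  }
  FALSE
}

# Subpixel saddle: stationary point of a quadratic fit to the blurred
# intensity in a (2w+1)^2 window, iterated twice.
refine_saddle <- function(B, row0, col0, w = 2L) {
  u <- col0; v <- row0
  for (it in 1:2) {
    r0 <- round(v); c0 <- round(u)
    if (r0 - w < 1 || r0 + w > nrow(B) || c0 - w < 1 || c0 + w > ncol(B)) break
    win <- B[(r0 - w):(r0 + w), (c0 - w):(c0 + w)]
    g <- expand.grid(y = -w:w, x = -w:w)
    X <- cbind(1, g$x, g$y, g$x^2, g$x * g$y, g$y^2)
    cf <- qr.solve(X, as.numeric(win))
    H <- matrix(c(2 * cf[4], cf[5], cf[5], 2 * cf[6]), 2, 2)
    if (abs(det(H)) < 1e-12) break
    s <- -solve(H, cf[2:3])
    if (max(abs(s)) > w) break
    u <- c0 + s[1]; v <- r0 + s[2]
  }
  c(u, v)
}

# --- grid topology recovery ------------------------------------------------

# Homography from 4 point correspondences (or more, least squares DLT).
homography_dlt <- function(src, dst) {
  n <- nrow(src)
  # Hartley normalization
  norm_pts <- function(p) {
    mu <- colMeans(p)
    sc <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, mu)^2)))
    T_ <- matrix(c(sc, 0, 0, 0, sc, 0, -sc * mu[1], -sc * mu[2], 1), 3, 3)
    list(p = cbind(p, 1) %*% t(T_), T = T_)
  }
  a <- norm_pts(src); b <- norm_pts(dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    X <- a$p[i, ]; x <- b$p[i, 1]; y <- b$p[i, 2]
    A[2 * i - 1, ] <- c(-X, 0, 0, 0, x * X)
    A[2 * i, ] <- c(0, 0, 0, -X, y * X)
  }
  h <- svd(A, nu = 0, nv = 9)$v[, 9]
  H <- solve(b$T) %*% matrix(h, 3, 3, byrow = TRUE) %*% a$T
  H / H[3, 3]
}

apply_homography <- function(H, p) {
  q <- cbind(p, 1) %*% t(H)
  q[, 1:2, drop = FALSE] / q[, 3]
}

# Recover the row-major canonical ordering of a perspective grid of points.
order_corner_grid <- function(pts, rows, cols) {
  n <- rows * cols
  if (nrow(pts) != n)
    sh_stop("wrong number of candidate corners", "seedhull_ambiguous_ordering")
  hull <- grDevices::chull(pts)            # clockwise indices
  hp <- pts[hull, , drop = FALSE]
  nh <- nrow(hp)
  if (nh < 4) sh_stop("degenerate hull", "seedhull_ambiguous_ordering")
  # exterior turn angle at each hull vertex; grid corners turn sharply
  turn <- vapply(seq_len(nh), function(i) {
    a <- hp[(i - 2) %% nh + 1, ]; b <- hp[i, ]; cc <- hp[i %% nh + 1, ]
    v1 <- b - a; v2 <- cc - b
    acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
  }, numeric(1))
  corn_i <- sort(order(turn, decreasing = TRUE)[1:4])
  corners4 <- hp[corn_i, , drop = FALSE]   # in hull (cyclic) order
  grid4 <- cbind(c(0, cols - 1, cols - 1, 0), c(0, 0, rows - 1, rows - 1))
  assign_try <- function(c4) {
    H <- homography_dlt(grid4, c4)
    gc <- apply_homography(solve(H), pts)
    gi <- round(gc)
    ok <- max(abs(gc - gi)) < 0.3 &&
      all(gi[, 1] >= 0 & gi[, 1] < cols & gi[, 2] >= 0 & gi[, 2] < rows) &&
      !anyDuplicated(gi[, 1] + gi[, 2] * cols)
    if (ok) gi else NULL
  }
  gi <- NULL
  for (rot in 0:3) {
    c4 <- corners4[(seq_len(4) + rot - 1) %% 4 + 1, , drop = FALSE]
    gi <- assign_try(c4)
    if (!is.null(gi)) break
    gi <- assign_try(c4[4:1, , drop = FALSE])
    if (!is.null(gi)) break
  }
  if (is.null(gi))
    sh_stop("could not recover grid topology", "seedhull_ambiguous_ordering")
  canonicalize_grid(pts, gi, rows, cols)
}

#' Align corner orderings across a rotation sequence
#'
#' The per-view canonical ordering (origin nearest the image top-left) can
#' flip between views as the board rotates, which would scramble corner
#' identities along their trajectories. Starting from the first view, each
#' subsequent corner set is relabeled by the dihedral grid symmetry that
#' minimizes the total pixel displacement to the previous (aligned) view --
#' consecutive turntable steps move corners only slightly, so the match is
#' unambiguous.
#'
#' @param corner_sets list of canonical (rows*cols) x 2 corner matrices.
#' @param board a [board_spec()].
#' @return list of corner matrices with consistent corner identities.
#' @export
align_corner_orderings <- function(corner_sets, board) {
  rows <- board$rows; cols <- board$cols
  perms <- grid_dihedral_perms(rows, cols)
  out <- corner_sets
  for (k in seq_along(out)[-1]) {
    ref <- out[[k - 1]]
    cur <- out[[k]]
    costs <- vapply(perms, function(p)
      sum((cur[p, ] - ref)^2), numeric(1))
    out[[k]] <- cur[perms[[which.min(costs)]], , drop = FALSE]
  }
  out
}

# Row-major index permutations of the grid's dihedral symmetries
# (4 for rectangular, 8 for square boards).
grid_dihedral_perms <- function(rows, cols) {
  g <- expand.grid(j = 0:(cols - 1), i = 0:(rows - 1))
  idx <- function(i, j) i * cols + j + 1L
  perms <- list()
  for (swap in c(FALSE, if (rows == cols) TRUE)) {
    for (flipj in c(FALSE, TRUE)) for (flipi in c(FALSE, TRUE)) {
      j <- if (swap) g$i else g$j
      i <- if (swap) g$j else g$i
      if (flipj) j <- cols - 1 - j
      if (flipi) i <- rows - 1 - i
      perms[[length(perms) + 1L]] <- idx(i, j)
    }
  }
  perms
}

# Apply the dihedral relabeling that puts the origin corner nearest the image
# top-left and (for square grids) makes columns the more horizontal axis.
canonicalize_grid <- function(pts, gi, rows, cols) {
  best <- NULL; best_score <- Inf
  for (swap in c(FALSE, if (rows == cols) TRUE)) {
    for (flipj in c(FALSE, TRUE)) for (flipi in c(FALSE, TRUE)) {
      j <- if (swap) gi[, 2] else gi[, 1]
      i <- if (swap) gi[, 1] else gi[, 2]
      if (flipj) j <- cols - 1 - j
      if (flipi) i <- rows - 1 - i
      origin <- pts[which(j == 0 & i == 0), ]
      uend <- pts[which(j == cols - 1 & i == 0), ]
      vend <- pts[which(j == 0 & i == rows - 1), ]
      if (rows == cols) {
        # columns run along the more horizontal grid axis
        if (abs(uend[1] - origin[1]) < abs(vend[1] - origin[1])) next
      }
      score <- origin[1]^2 + origin[2]^2
      if (score < best_score) {
        best_score <- score
        ord <- order(i * cols + j)
        best <- pts[ord, , drop = FALSE]
      }
    }
  }
  if (is.null(best))
    sh_stop("no canonical orientation found", "seedhull_ambiguous_ordering")
  colnames(best) <- c("u", "v")
  best
}
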