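#' Binarize a grayscale seed image
#'
#' Thresholds a grayscale image into a seed silhouette. With
#' `threshold = "auto"` a bimodal-histogram (Otsu) threshold is used and the
#' polarity is chosen so the smaller-area class is foreground (the seed
#' occupies a minority of the frame on this rig); with a numeric threshold,
#' pixels strictly greater than the threshold are foreground. Optional
#' morphological cleanup fills holes and keeps the largest connected
#' component, which voxel carving requires.
#'
#' @param image numeric matrix (height x width).
#' @param threshold numeric cut or `"auto"`.
#' @param clean fill holes and keep the largest component.
#' @return integer 0/1 mask of the same size. Error class
#'   `seedhull_degenerate_histogram` for a constant image.
#' @export
binarize <- function(image, threshold = "auto", clean = TRUE) {
  im <- as.matrix(image)
  if (diff(range(im)) < 1e-12)
    sh_stop("image is constant; cannot threshold", "seedhull_degenerate_histogram")
  if (identical(threshold, "auto")) {
    thr <- otsu_threshold(im)
    mask <- im > thr
    if (mean(mask) > 0.5) mask <- !mask
  } else {
    mask <- im > threshold
  }
  mask <- matrix(as.integer(mask), nrow(im), ncol(im))
  if (clean && any(mask > 0)) mask <- clean_mask(mask)
  mask
}

# Otsu's threshold on a 256-bin histogram of the normalized range.
otsu_threshold <- function(im) {
  r <- range(im)
  x <- (im - r[1]) / (r[2] - r[1])
  h <- tabulate(pmin(floor(x * 256) + 1L, 256L), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256) - 0.5))
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + (k / 256) * (r[2] - r[1])
}

# Fill holes and keep the largest 4-connected component.
clean_mask <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) > 1) {
    sizes <- tabulate(lab[lab > 0])
    mask <- matrix(as.integer(lab == which.max(sizes)), nrow(mask), ncol(mask))
  }
  filled <- EBImage::fillHull(mask)
  matrix(as.integer(filled > 0), nrow(mask), ncol(mask))
}

#' Remove the suction-nozzle background from silhouette masks
#'
#' The seed hangs from a suction nozzle that enters the frame from one image
#' edge (top by default) as a near-constant-width bar. Scanning row by row
#' from that edge, the intersection row is the first row whose white-pixel
#' count changes by at least `change_fraction` relative to the previous row
#' (the seed widens abruptly where it meets the nozzle). Rows on the nozzle
#' side of the intersection are cleared; the seed component beyond it is
#' untouched. When no such row exists (no nozzle reaching the edge, or an
#' all-foreground mask) the mask is returned unchanged with a warning of
#' class `seedhull_no_intersection` and attribute `nozzle_found = FALSE`.
#'
#' With `consensus = TRUE`, masks are treated as aligned views of one seed
#' and the median per-view intersection row is applied to every view.
#'
#' @param masks a single 0/1 mask or a list of per-view masks.
#' @param change_fraction relative row-to-row change that marks the
#'   nozzle/seed intersection (default 0.30).
#' @param edge image edge the nozzle enters from (`"top"` or `"bottom"`).
#' @param consensus apply the median intersection row across views.
#' @return mask or list of masks with attributes `nozzle_boundary_row`
#'   (NA when not found) and `nozzle_found`.
#' @export
remove_nozzle <- function(masks, change_fraction = 0.30, edge = c("top", "bottom"),
                          consensus = FALSE) {
  edge <- match.arg(edge)
  single <- !is.list(masks)
  if (single) masks <- list(masks)
  rows_found <- vapply(masks, function(m)
    find_nozzle_row(m, change_fraction, edge), numeric(1))
  if (consensus && any(!is.na(rows_found)))
    rows_found[] <- stats::median(rows_found, na.rm = TRUE)
  out <- lapply(seq_along(masks), function(i) {
    m <- masks[[i]]
    r <- rows_found[i]
    if (is.na(r)) {
      sh_warn("no nozzle/seed intersection row found; mask unchanged",
              "seedhull_no_intersection")
      attr(m, "nozzle_boundary_row") <- NA_integer_
      attr(m, "nozzle_found") <- FALSE
      return(m)
    }
    if (edge == "top") m[seq_len(r - 1), ] <- 0L else m[(r + 1):nrow(m), ] <- 0L
    attr(m, "nozzle_boundary_row") <- as.integer(r)
    attr(m, "nozzle_found") <- TRUE
    m
  })
  if (single) out[[1]] else out
}

find_nozzle_row <- function(mask, change_fraction, edge) {
  counts <- rowSums(mask > 0)
  if (edge == "bottom") counts <- rev(counts)
  if (counts[1] == 0) return(NA_real_)      # nothing touches the nozzle edge
  for (r in 2:length(counts)) {
    prev <- counts[r - 1]
    if (abs(counts[r] - prev) >= change_fraction * max(prev, 1)) {
      rr <- if (edge == "bottom") length(counts) - r + 1 else r
      return(rr)
    }
  }
  NA_real_
}

#' Subpixel outer contour of the largest silhouette component
#'
#' Traces the boundary of the largest connected foreground component by
#' marching squares at iso-level 0.5 (vertices at pixel-edge midpoints on a
#' binary mask), then applies a light cyclic moving-average smoothing that
#' suppresses the half-pixel staircase so perimeters of smooth shapes are
#' accurate to a couple of percent. The polygon is closed (last vertex
#' connects to the first) and oriented counter-clockwise (positive shoelace
#' area, v treated as the y coordinate).
#'
#' @param mask 0/1 matrix.
#' @param smooth_iterations cyclic `(1, 2, 1)/4` smoothing passes.
#' @return m x 2 matrix of `(u, v)` vertices with attributes `perimeter` and
#'   `area`. Error class `seedhull_empty_mask` on an empty mask.
#' @export
silhouette_contour <- function(mask, smooth_iterations = 3) {
  if (!any(mask > 0)) sh_stop("mask has no foreground", "seedhull_empty_mask")
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  comp <- matrix(as.numeric(lab == which.max(sizes)), nrow(mask), ncol(mask))
  loops <- marching_squares(comp, iso = 0.5)
  areas <- vapply(loops, function(L) abs(polygon_area(L)), numeric(1))
  poly <- loops[[which.max(areas)]]
  for (k in seq_len(smooth_iterations)) {
    nm <- nrow(poly)
    if (nm < 5) break
    up <- poly[c(2:nm, 1), , drop = FALSE]
    dn <- poly[c(nm, 1:(nm - 1)), , drop = FALSE]
    poly <- (dn + 2 * poly + up) / 4
  }
  if (polygon_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  colnames(poly) <- c("u", "v")
  attr(poly, "perimeter") <- polygon_perimeter(poly)
  attr(poly, "area") <- abs(polygon_area(poly))
  poly
}

# Shoelace signed area of a closed polygon (rows = vertices, open storage).
polygon_area <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
}

# Closed-polygon perimeter: sum of edge lengths with wraparound.
polygon_perimeter <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  sum(sqrt((p[, 1] - p[i2, 1])^2 + (p[, 2] - p[i2, 2])^2))
}

# --- marching squares ------------------------------------------------------

# Iso-contours of a 2D field sampled at (u = col, v = row) integer positions.
# Returns a list of closed loops (m x 2, columns u, v). The field is padded
# with `pad_value` so boundary-touching regions close. Ambiguous cells
# (diagonal pattern) are resolved by never connecting the >= iso corners,
# a rule that depends only on the cell so adjacent cells always agree.
marching_squares <- function(field, iso = 0.5, pad_value = 0) {
  f <- rbind(pad_value, cbind(pad_value, field, pad_value), pad_value)
  nr <- nrow(f); nc <- ncol(f)
  inside <- f >= iso
  # cell (r, c) has corners (r,c), (r,c+1), (r+1,c+1), (r+1,c)
  a <- inside[-nr, -nc]; b <- inside[-nr, -1]
  cc <- inside[-1, -1]; d <- inside[-1, -nc]
  config <- a + 2L * b + 4L * cc + 8L * d
  cells <- which(config != 0L & config != 15L, arr.ind = TRUE)
  if (!nrow(cells)) sh_stop("no contour found", "seedhull_empty_mask")
  # edge keys: horizontal edge between (r,c)-(r,c+1) -> "h:r:c";
  # vertical edge between (r,c)-(r+1,c) -> "v:r:c". Crossing positions by
  # linear interpolation of the field.
  interp <- function(v1, v2) (iso - v1) / (v2 - v1)
  env <- new.env()
  env$from <- character(0); env$to <- character(0); env$pts <- list()
  add_seg <- function(k1, p1, k2, p2) {
    env$from <- c(env$from, k1); env$to <- c(env$to, k2)
    env$pts[[length(env$pts) + 1L]] <- rbind(p1, p2)
  }
  for (i in seq_len(nrow(cells))) {
    r <- cells[i, 1]; c0 <- cells[i, 2]
    vals <- c(f[r, c0], f[r, c0 + 1], f[r + 1, c0 + 1], f[r + 1, c0])
    ins <- vals >= iso
    # crossing point + key per cell edge 1..4 (top, right, bottom, left)
    ek <- pk <- vector("list", 4)
    if (ins[1] != ins[2]) {
      t_ <- interp(vals[1], vals[2])
      ek[[1]] <- paste0("h:", r, ":", c0); pk[[1]] <- c(c0 + t_, r)
    }
    if (ins[2] != ins[3]) {
      t_ <- interp(vals[2], vals[3])
      ek[[2]] <- paste0("v:", r, ":", c0 + 1); pk[[2]] <- c(c0 + 1, r + t_)
    }
    if (ins[4] != ins[3]) {
      t_ <- interp(vals[4], vals[3])
      ek[[3]] <- paste0("h:", r + 1, ":", c0); pk[[3]] <- c(c0 + t_, r + 1)
    }
    if (ins[1] != ins[4]) {
      t_ <- interp(vals[1], vals[4])
      ek[[4]] <- paste0("v:", r, ":", c0); pk[[4]] <- c(c0, r + t_)
    }
    segs <- ms_cell_segments(ins)
    for (s in segs) add_seg(ek[[s[1]]], pk[[s[1]]], ek[[s[2]]], pk[[s[2]]])
  }
  # chain directed segments into loops
  nxt <- match(env$to, env$from)
  used <- rep(FALSE, length(env$from))
  loops <- list()
  for (s0 in seq_along(env$from)) {
    if (used[s0]) next
    path <- integer(0); s <- s0
    repeat {
      used[s] <- TRUE
      path <- c(path, s)
      s <- nxt[s]
      if (is.na(s) || used[s]) break
    }
    pts <- do.call(rbind, lapply(path, function(k) env$pts[[k]][1, , drop = FALSE]))
    # shift coordinates back for the padding (subtract 1)
    loops[[length(loops) + 1L]] <- pts - 1
  }
  loops
}

# Directed segments (tail edge -> head edge, cell edges 1=top 2=right
# 3=bottom 4=left) for a marching-squares cell, inside region on the left
# when v points down and loops are traversed so shoelace area over (u, v)
# is positive for outer boundaries.
ms_cell_segments <- function(ins) {
  code <- sum(c(1L, 2L, 4L, 8L)[ins])
  # single inside corner k: segment edge k -> edge k-1 (cyclic); complements
  # reversed; adjacent pairs bridge; diagonals kept as two corner segments.
  switch(code + 1L,
    list(),                       # 0
    list(c(1, 4)),                # 1: corner 1 (top-left)
    list(c(2, 1)),                # 2: corner 2 (top-right)
    list(c(2, 4)),                # 3: top pair
    list(c(3, 2)),                # 4: corner 3 (bottom-right)
    list(c(1, 4), c(3, 2)),       # 5: diagonal 1+3, kept separated
    list(c(3, 1)),                # 6: right pair
    list(c(3, 4)),                # 7: all but bottom-left
    list(c(4, 3)),                # 8: corner 4 (bottom-left)
    list(c(1, 3)),                # 9: left pair
    list(c(2, 1), c(4, 3)),       # 10: diagonal 2+4, kept separated
    list(c(2, 3)),                # 11: all but bottom-right
    list(c(4, 2)),                # 12: bottom pair
    list(c(1, 2)),                # 13: all but top-right
    list(c(4, 1)),                # 14: all but top-left
    list())                       # 15
}
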