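#' Read a grayscale image (PNG or TIFF)
#'
#' 8/16-bit PNG or TIFF via EBImage; multi-channel images are averaged to
#' grayscale. Returned as a height x width matrix in [0, 1] with pixel
#' (u, v) at `[v, u]`.
#'
#' @param path image file.
#' @return numeric matrix.
#' @export
read_gray_image <- function(path) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
  t(a)   # EBImage stores [x, y]; transpose to [row = v, col = u]
}

#' Write a binary mask as an 8-bit PNG (0/255)
#' @param mask 0/1 matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  EBImage::writeImage(EBImage::Image(t(mask > 0) * 1), path)
  invisible(path)
}

#' Write a mesh as ASCII PLY
#' @param mesh a `triangle_mesh`.
#' @param path output `.ply` file.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(mesh$vertices, trim = TRUE, digits = 8), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, mesh$faces - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a mesh as Wavefront OBJ
#' @param mesh a `triangle_mesh`.
#' @param path output `.obj` file.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.8g %.8g %.8g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' Save a rig calibration as JSON
#'
#' Serializes intrinsics, per-view poses, the rotation axis and the virtual
#' projection matrices (row-major 12-number arrays) with residual
#' diagnostics.
#'
#' @param calib a `rig_calibration` from [calibrate_rig()].
#' @param path output `.json` file.
#' @export
write_calibration <- function(calib, path) {
  doc <- list(
    intrinsics = calib$intrinsics[c("alpha_u", "alpha_v", "skew", "u0", "v0")],
    board = unclass(calib$board),
    poses = lapply(calib$poses, function(p)
      list(R = as.numeric(t(p$R)), T = p$T)),
    axis = list(point = calib$axis$point, direction = calib$axis$direction,
                eigenvalues = calib$axis$eigenvalues,
                n_centers = calib$axis$n_centers),
    step_deg = calib$step_deg, n_views = calib$n_views,
    projections = lapply(calib$projections, function(p) as.numeric(t(p$P))),
    rms_reprojection_error = calib$rms_reprojection_error)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a rig calibration saved by [write_calibration()]
#' @param path `.json` file.
#' @return `rig_calibration`-like list with `intrinsics`, `axis`,
#'   `projections` (list of `projection_matrix`), `step_deg`, `n_views`.
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  intr <- intrinsics(alpha_u = doc$intrinsics$alpha_u,
                     alpha_v = doc$intrinsics$alpha_v,
                     skew = doc$intrinsics$skew,
                     u0 = doc$intrinsics$u0, v0 = doc$intrinsics$v0)
  axis <- list(point = doc$axis$point, direction = doc$axis$direction)
  plist <- doc$projections
  if (is.matrix(plist)) plist <- lapply(seq_len(nrow(plist)), function(i) plist[i, ])
  projections <- lapply(plist, function(v) {
    P <- matrix(as.numeric(v), 3, 4, byrow = TRUE)
    dec <- decompose_projection(P)
    build_projection(dec$intrinsics, dec$pose)
  })
  structure(list(intrinsics = intr, axis = axis, projections = projections,
                 step_deg = doc$step_deg, n_views = doc$n_views,
                 rms_reprojection_error = doc$rms_reprojection_error),
            class = "rig_calibration")
}

#' Write a traits table as CSV
#' @param df data.frame (one row per seed).
#' @param path output `.csv`.
#' @export
write_traits_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a traits CSV (schema: seed_id, variety, group, optional role, traits)
#' @param path `.csv` file.
#' @param require_traits validate that the nine trait columns are present.
#' @return `trait_table` data.frame.
#' @export
read_traits_csv <- function(path, require_traits = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("seed_id", "variety", "group")
  miss <- setdiff(need, names(df))
  if (length(miss))
    sh_stop(paste("traits CSV missing column(s):", paste(miss, collapse = ", ")),
            "seedhull_schema_error")
  if (require_traits) {
    miss_tr <- setdiff(trait_names(), names(df))
    if (length(miss_tr))
      sh_stop(paste("traits CSV missing trait column(s):",
                    paste(miss_tr, collapse = ", ")), "seedhull_schema_error")
    bad <- names(which(vapply(trait_names(), function(tr)
      any(!is.finite(df[[tr]])), logical(1))))
    if (length(bad))
      sh_stop(paste("non-finite trait values in column(s):",
                    paste(bad, collapse = ", ")), "seedhull_schema_error")
  }
  class(df) <- c("trait_table", "data.frame")
  df
}
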