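#' Run configuration for the reconstruction / statistics pipelines
#'
#' Collects paths and parameters with rig defaults (9 x 9 corner board at
#' 0.5 mm pitch, 9-degree steps, 40 views, 128^3 grid). Accepts a YAML or
#' JSON file via [read_run_config()], or build it directly.
#'
#' @param images_dir directory of seed image directories (one per seed) or
#'   mask directories.
#' @param calibration path to a calibration JSON ([write_calibration()]).
#' @param output_dir where meshes / CSVs are written.
#' @param board a [board_spec()].
#' @param step_deg,n_views turntable step and view count.
#' @param resolution carving grid resolution.
#' @param threshold binarization threshold (`"auto"` or numeric).
#' @param change_fraction nozzle-removal row-change fraction.
#' @param nozzle_edge image edge the nozzle enters from.
#' @param traits_csv,design_csv inputs for the statistics stage.
#' @param seed RNG seed for stochastic steps (k-means restarts).
#' @return object of class `run_config`.
#' @export
run_config <- function(images_dir = NULL, calibration = NULL,
                       output_dir = ".", board = board_spec(),
                       step_deg = 9, n_views = 40, resolution = 128,
                       threshold = "auto", change_fraction = 0.3,
                       nozzle_edge = "top", traits_csv = NULL,
                       design_csv = NULL, seed = 1) {
  stopifnot(step_deg * n_views <= 360 + 1e-6)
  structure(list(images_dir = images_dir, calibration = calibration,
                 output_dir = output_dir, board = board, step_deg = step_deg,
                 n_views = n_views, resolution = resolution,
                 threshold = threshold, change_fraction = change_fraction,
                 nozzle_edge = nozzle_edge, traits_csv = traits_csv,
                 design_csv = design_csv, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path `.yaml`/`.yml` or `.json` file of `run_config` fields.
#' @return `run_config`.
#' @export
read_run_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      sh_stop("yaml package required for YAML configs", "seedhull_schema_error")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(vals$board)) vals$board <- do.call(board_spec, as.list(vals$board))
  do.call(run_config, vals)
}

#' Reconstruct every seed in a directory and measure traits
#'
#' For each seed subdirectory of `config$images_dir` (images named
#' `<prefix>_<viewindex>.png`, 0-based), runs binarization, nozzle removal,
#' visual-hull carving against the calibration's virtual views, marching
#' cubes, and the nine-trait measurement; writes one PLY mesh per seed and a
#' combined traits CSV. Errors are re-thrown with the failing stage and seed
#' in the message.
#'
#' @param config a [run_config()] with `images_dir` and `calibration` set.
#' @return data.frame of traits (also written to
#'   `<output_dir>/traits.csv`), invisibly; attribute `report` carries
#'   per-stage timings and warnings.
#' @export
run_reconstruction <- function(config) {
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    r <- tryCatch(force(expr), error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
    list(value = r, elapsed = proc.time()[3] - t0)
  }
  if (is.null(config$calibration) || !file.exists(config$calibration))
    stop("[stage calibration] calibration file not found: ",
         config$calibration %||% "<missing>", call. = FALSE)
  calib <- stage("calibration", read_calibration(config$calibration))$value
  if (is.null(config$images_dir) || !dir.exists(config$images_dir))
    stop("[stage images] image directory not found: ",
         config$images_dir %||% "<missing>", call. = FALSE)
  seed_dirs <- list.dirs(config$images_dir, recursive = FALSE)
  if (!length(seed_dirs)) seed_dirs <- config$images_dir
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list()
  rows <- lapply(seed_dirs, function(sd) {
    sid <- basename(sd)
    files <- list.files(sd, pattern = "\\.(png|tif|tiff)$", full.names = TRUE)
    idx <- as.integer(sub(".*_(\\d+)\\.(png|tif|tiff)$", "\\1", files))
    files <- files[order(idx)]
    if (!length(files)) stop(sprintf("[stage images] no images for seed %s", sid),
                             call. = FALSE)
    s1 <- stage("silhouette", {
      masks <- lapply(files, function(f)
        binarize(read_gray_image(f), threshold = config$threshold))
      remove_nozzle(masks, change_fraction = config$change_fraction,
                    edge = config$nozzle_edge)
    })
    s2 <- stage("carve", carve(s1$value,
                               calib$projections[seq_along(s1$value)],
                               resolution = config$resolution))
    s3 <- stage("mesh", mesh_from_grid(s2$value))
    s4 <- stage("traits", measure_all(s2$value, s3$value))
    write_ply(s3$value, file.path(config$output_dir, paste0(sid, ".ply")))
    report[[sid]] <<- vapply(list(s1, s2, s3, s4), `[[`, numeric(1), "elapsed")
    cbind(data.frame(seed_id = sid, variety = NA_character_,
                     group = NA_character_, stringsAsFactors = FALSE),
          as.data.frame(s4$value))
  })
  out <- do.call(rbind, rows)
  write_traits_csv(out, file.path(config$output_dir, "traits.csv"))
  attr(out, "report") <- report
  invisible(out)
}

#' Run the germplasm statistics stage
#'
#' Reads a traits CSV and a design CSV (`variety`, `group`,
#' `role` in parent/offspring), joins them, and writes the three result
#' tables: pooled trait summary (mean/min/max/SD/PCV), nested ANOVA, and
#' the GVF matrix with the offspring ranking by average GVF. With a single
#' variety the ANOVA and GVF stages are skipped with a notice.
#'
#' @param config a [run_config()] with `traits_csv` (and optionally
#'   `design_csv`) set.
#' @return list with `summary`, `anova`, `gvf` (NULL where skipped),
#'   invisibly; CSVs written under `config$output_dir`.
#' @export
run_stats <- function(config) {
  tab <- read_traits_csv(config$traits_csv)
  if (!is.null(config$design_csv)) {
    des <- utils::read.csv(config$design_csv, stringsAsFactors = FALSE)
    need <- c("variety", "group", "role")
    miss <- setdiff(need, names(des))
    if (length(miss))
      sh_stop(paste("design CSV missing column(s):", paste(miss, collapse = ", ")),
              "seedhull_schema_error")
    tab$group <- des$group[match(tab$variety, des$variety)]
    tab$role <- des$role[match(tab$variety, des$variety)]
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  smry <- summarize_traits(tab)
  utils::write.csv(smry, file.path(config$output_dir, "summary.csv"),
                   row.names = FALSE)
  nvar <- length(unique(tab$variety))
  anova_res <- NULL; gvf_res <- NULL
  if (nvar >= 2 && length(unique(tab$group)) >= 2) {
    anova_res <- tryCatch(nested_anova(tab), seedhull_error = function(e) {
      message("ANOVA skipped: ", conditionMessage(e)); NULL
    })
    if (!is.null(anova_res))
      utils::write.csv(anova_res, file.path(config$output_dir, "anova.csv"),
                       row.names = FALSE)
  } else message("ANOVA skipped: fewer than 2 varieties or groups")
  if ("role" %in% names(tab) && sum(tab$role == "parent") > 0) {
    gvf_res <- tryCatch(gvf_table(tab), seedhull_error = function(e) {
      message("GVF skipped: ", conditionMessage(e)); NULL
    })
    if (!is.null(gvf_res)) {
      gm <- data.frame(trait = rownames(gvf_res$gvf), gvf_res$gvf,
                       check.names = FALSE)
      utils::write.csv(gm, file.path(config$output_dir, "gvf.csv"),
                       row.names = FALSE)
      utils::write.csv(data.frame(variety = names(gvf_res$average),
                                  average_gvf = gvf_res$average,
                                  rank = match(names(gvf_res$average),
                                               gvf_res$ranking)),
                       file.path(config$output_dir, "gvf_ranking.csv"),
                       row.names = FALSE)
    }
  }
  invisible(list(summary = smry, anova = anova_res, gvf = gvf_res))
}
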