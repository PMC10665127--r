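#' Phenotypic coefficient of variation (PCV)
#'
#' `100 * SD / mean` of a trait across seeds of a germplasm, the standard
#' relative-dispersion measure for comparing trait variability across scales.
#' The sample SD (n - 1 denominator) is used, the usual convention for
#' summary tables.
#'
#' @param values numeric vector (length >= 2, nonzero mean).
#' @return PCV in percent.
#' @export
#' @examples
#' pcv(c(1, 3))  # 70.71
pcv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2)
    sh_stop("need at least 2 values", "seedhull_too_few_values")
  m <- mean(values)
  if (abs(m) < .Machine$double.eps)
    sh_stop("mean is zero; PCV undefined", "seedhull_zero_mean")
  100 * stats::sd(values) / m
}

#' PCV from printed summary moments
#' @param mean_,sd_ summary mean and SD of a trait.
#' @return `100 * sd_ / mean_`.
#' @export
pcv_from_moments <- function(mean_, sd_) 100 * sd_ / mean_

#' Summary statistics table for a germplasm trait table
#'
#' Mean, min, max, SD and PCV per trait, pooled over all seeds or per
#' variety, with traits ranked by descending PCV.
#'
#' @param table a `trait_table` (data.frame with trait columns plus
#'   `variety` labels).
#' @param scope `"pooled"` or `"per-variety"`.
#' @param traits trait column names (default [trait_names()] intersected
#'   with the table).
#' @return data.frame of class `summary_stats` with columns `scope`,
#'   `trait`, `mean`, `min`, `max`, `sd`, `pcv`, `pcv_rank`.
#' @export
summarize_traits <- function(table, scope = c("pooled", "per-variety"),
                             traits = NULL) {
  scope <- match.arg(scope)
  if (is.null(traits)) traits <- intersect(trait_names(), names(table))
  if (!length(traits)) sh_stop("no trait columns found", "seedhull_invalid_spec")
  one <- function(df, label) {
    rows <- lapply(traits, function(tr) {
      v <- df[[tr]]
      data.frame(scope = label, trait = tr, mean = mean(v), min = min(v),
                 max = max(v), sd = stats::sd(v), pcv = pcv(v),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$pcv_rank <- rank(-out$pcv, ties.method = "first")
    out
  }
  res <- if (scope == "pooled") one(table, "pooled")
         else do.call(rbind, lapply(split(table, table$variety), function(d)
           one(d, d$variety[1])))
  rownames(res) <- NULL
  class(res) <- c("summary_stats", "data.frame")
  res
}

#' Two-level nested analysis of variance
#'
#' Decomposes each trait's variation into among germplasm groups, within
#' groups (varieties nested in groups) and residual (seeds within
#' varieties), from definitional sums of squares:
#' \deqn{SS_{among} = \sum_g n_g(\bar y_g - \bar y)^2,\quad
#'       SS_{within} = \sum_v n_v(\bar y_v - \bar y_{g(v)})^2,\quad
#'       SS_{error} = \sum_i (y_i - \bar y_{v(i)})^2}
#' which partition the total sum of squares exactly. Both F ratios use the
#' residual mean square in the denominator; significance is flagged at
#' P < 0.01.
#'
#' @param table a `trait_table` with `group` and `variety` columns.
#' @param traits trait columns to analyze.
#' @return data.frame of class `anova_result`: per trait, mean squares
#'   (`ms_among`, `ms_within`, `ms_error`), `f_among`, `f_within`, degrees
#'   of freedom, P values and significance flags. Constant tables yield
#'   zero mean squares and `NaN` F ratios with `degenerate = TRUE`.
#' @export
nested_anova <- function(table, traits = NULL) {
  if (is.null(traits)) traits <- intersect(trait_names(), names(table))
  g <- as.character(table$group)
  v <- as.character(table$variety)
  if (length(unique(g)) < 2)
    sh_stop("need >= 2 germplasm groups", "seedhull_insufficient_replication")
  tab_gv <- table(g, v)
  if (any(rowSums(tab_gv > 0) < 2))
    sh_stop("need >= 2 varieties per group", "seedhull_insufficient_replication")
  if (any(tab_gv[tab_gv > 0] < 2))
    sh_stop("need >= 2 seeds per variety", "seedhull_insufficient_replication")
  a <- length(unique(g))
  b_tot <- length(unique(paste(g, v)))
  N <- nrow(table)
  rows <- lapply(traits, function(tr) {
    y <- table[[tr]]
    gm <- mean(y)
    mg <- tapply(y, g, mean); ng <- tapply(y, g, length)
    key <- paste(g, v)
    mv <- tapply(y, key, mean); nv <- tapply(y, key, length)
    gv_group <- tapply(g, key, `[`, 1)
    ss_among <- sum(ng * (mg - gm)^2)
    ss_within <- sum(nv * (mv - mg[gv_group])^2)
    ss_error <- sum((y - mv[key])^2)
    df_among <- a - 1
    df_within <- b_tot - a
    df_error <- N - b_tot
    ms <- c(ss_among / df_among, ss_within / df_within, ss_error / df_error)
    f_among <- ms[1] / ms[3]
    f_within <- ms[2] / ms[3]
    degen <- ms[3] == 0
    p_among <- if (degen) NaN else stats::pf(f_among, df_among, df_error, lower.tail = FALSE)
    p_within <- if (degen) NaN else stats::pf(f_within, df_within, df_error, lower.tail = FALSE)
    data.frame(trait = tr, ss_among = ss_among, ss_within = ss_within,
               ss_error = ss_error, ss_total = sum((y - gm)^2),
               df_among = df_among, df_within = df_within, df_error = df_error,
               ms_among = ms[1], ms_within = ms[2], ms_error = ms[3],
               f_among = f_among, f_within = f_within,
               p_among = p_among, p_within = p_within,
               sig_among = !degen && is.finite(p_among) && p_among < 0.01,
               sig_within = !degen && is.finite(p_within) && p_within < 0.01,
               degenerate = degen, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Genetic variation factor (GVF) for one trait
#'
#' Compares the combined parental variance with an offspring variety's
#' variance, normalized by the summed parental means:
#' \deqn{GVF = 100 \cdot \frac{\sqrt{|D(P_1) + D(P_2) - D(F_i)|}}{E(P_1) + E(P_2)}}
#' where `D` is the population variance (1/N denominator; the parents are
#' independent samples so the variance of their sum is the sum of
#' variances) and `E` the expectation. Under an unchanged environment the
#' environmental variance cancels in the difference, so the factor tracks
#' the genetic component of the parent-to-offspring variance change; the
#' absolute value guards the square root against sampling noise.
#'
#' @param p1,p2 parent trait vectors (length >= 2 each).
#' @param f_i offspring trait vector (length >= 2).
#' @return GVF in percent.
#' @export
#' @examples
#' gvf(c(9, 10, 11), c(19, 20, 21), c(15, 15, 15))  # 3.85
gvf <- function(p1, p2, f_i) {
  for (v in list(p1, p2, f_i))
    if (length(v) < 2) sh_stop("each sample needs >= 2 values", "seedhull_too_few_values")
  pvar <- function(x) mean((x - mean(x))^2)
  denom <- mean(p1) + mean(p2)
  if (abs(denom) < .Machine$double.eps)
    sh_stop("summed parent mean is zero", "seedhull_zero_parent_mean")
  100 * sqrt(abs(pvar(p1) + pvar(p2) - pvar(f_i))) / denom
}

#' GVF matrix across traits and offspring varieties
#'
#' Computes the per-trait GVF of every offspring variety against the two
#' parents, the per-variety average over traits, and the descending ranking
#' of offspring varieties by average GVF.
#'
#' @param table a `trait_table`.
#' @param parent_labels length-2 character vector of parent variety labels;
#'   default: varieties with `role == "parent"`.
#' @param offspring_labels offspring variety labels; default: all others.
#' @param traits trait columns.
#' @return object of class `gvf_result`: `gvf` (traits x offspring matrix,
#'   percent), `average` (named vector), `ranking` (labels, descending
#'   average GVF).
#' @export
gvf_table <- function(table, parent_labels = NULL, offspring_labels = NULL,
                      traits = NULL) {
  if (is.null(traits)) traits <- intersect(trait_names(), names(table))
  if (is.null(parent_labels) && "role" %in% names(table))
    parent_labels <- unique(table$variety[table$role == "parent"])
  if (length(parent_labels) != 2 ||
      !all(parent_labels %in% table$variety))
    sh_stop("exactly 2 parent varieties must be present", "seedhull_missing_parent")
  if (is.null(offspring_labels))
    offspring_labels <- setdiff(unique(table$variety), parent_labels)
  if (!length(offspring_labels))
    sh_stop("no offspring varieties", "seedhull_missing_parent")
  p1 <- table[table$variety == parent_labels[1], , drop = FALSE]
  p2 <- table[table$variety == parent_labels[2], , drop = FALSE]
  M <- vapply(offspring_labels, function(off) {
    fo <- table[table$variety == off, , drop = FALSE]
    vapply(traits, function(tr) gvf(p1[[tr]], p2[[tr]], fo[[tr]]), numeric(1))
  }, numeric(length(traits)))
  M <- matrix(M, nrow = length(traits),
              dimnames = list(traits, offspring_labels))
  avg <- colMeans(M)
  structure(list(gvf = M, average = avg,
                 ranking = names(sort(avg, decreasing = TRUE)),
                 parents = parent_labels),
            class = "gvf_result")
}

#' @export
print.gvf_result <- function(x, ...) {
  cat(sprintf("GVF (%%) vs parents %s, %s:\n", x$parents[1], x$parents[2]))
  print(round(x$gvf, 2))
  cat("average:\n"); print(round(x$average, 2))
  cat("ranking (descending):", paste(x$ranking, collapse = ", "), "\n")
  invisible(x)
}

#' Cluster seeds by traits and score against known groups
#'
#' Standardizes the trait columns, clusters with k-means, hierarchical
#' (Ward) or DBSCAN, and reports the precision against the true group
#' labels after the optimal cluster-to-group matching (maximum over label
#' permutations, so relabeling clusters never changes the score). This is
#' evaluation plumbing for the germplasm analysis, not an inferential step.
#'
#' @param table a `trait_table` with a `group` column (ground truth).
#' @param method `"kmeans"`, `"hierarchical"` or `"dbscan"`.
#' @param k number of clusters (ignored by dbscan).
#' @param traits trait columns.
#' @param eps,min_pts DBSCAN neighborhood radius (in standardized units) and
#'   core-point threshold.
#' @param seed RNG seed for k-means restarts.
#' @return list with `labels` (integer clusters), `precision`, `method`.
#' @export
cluster_and_score <- function(table, method = c("kmeans", "hierarchical", "dbscan"),
                              k = 2, traits = NULL, eps = 2.0, min_pts = 5,
                              seed = 1) {
  method <- match.arg(method)
  if (is.null(traits)) traits <- intersect(trait_names(), names(table))
  X <- scale(as.matrix(table[, traits, drop = FALSE]))
  X[!is.finite(X)] <- 0
  if (nrow(unique(X)) < k)
    sh_stop("fewer distinct points than clusters", "seedhull_degenerate_clustering")
  labels <- switch(method,
    kmeans = {
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
      }
      set.seed(seed)
      stats::kmeans(X, centers = k, nstart = 10)$cluster
    },
    hierarchical = stats::cutree(stats::hclust(stats::dist(X), method = "ward.D2"), k),
    dbscan = dbscan_simple(X, eps = eps, min_pts = min_pts))
  if (length(unique(labels[labels > 0])) < k)
    sh_stop("clustering returned fewer than k nonempty clusters",
            "seedhull_degenerate_clustering")
  truth <- as.integer(factor(table$group))
  list(labels = labels, precision = matched_precision(labels, truth),
       method = method)
}

# Best achievable accuracy over all assignments of cluster ids to true group
# ids (exhaustive over permutations; cluster counts here are small).
matched_precision <- function(labels, truth) {
  cl <- sort(unique(labels))
  gr <- sort(unique(truth))
  if (length(cl) > 7) sh_stop("too many clusters for exhaustive matching",
                              "seedhull_degenerate_clustering")
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  # pad group ids so every cluster can map somewhere
  targets <- rep(gr, length.out = max(length(cl), length(gr)))
  best <- 0
  for (p in perms(seq_along(targets))) {
    map <- targets[p][seq_along(cl)]
    pred <- map[match(labels, cl)]
    best <- max(best, mean(pred == truth, na.rm = TRUE))
  }
  best
}

# Minimal DBSCAN (Euclidean): labels > 0 are clusters, 0 is noise.
dbscan_simple <- function(X, eps = 1.0, min_pts = 5) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  neigh <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(neigh, length, integer(1)) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      for (q in neigh[[j]]) {
        if (labels[q] == 0L) {
          labels[q] <- cl
          if (core[q]) queue <- c(queue, q)
        }
      }
    }
  }
  labels
}
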