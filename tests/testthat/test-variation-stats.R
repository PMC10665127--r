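test_that("pcv matches hand computations and is scale invariant", {
  expect_equal(pcv(c(1, 3)), 70.71068, tolerance = 1e-5)
  expect_equal(pcv(rep(4.2, 10)), 0)
  set.seed(1)
  x <- rlnorm(50)
  expect_equal(pcv(3.7 * x), pcv(x), tolerance = 1e-12)
  expect_error(pcv(5), class = "seedhull_too_few_values")
  expect_error(pcv(c(-1, 1)), class = "seedhull_zero_mean")
})

test_that("summaries recover generator parameters and document duplication", {
  spec <- default_germplasm_spec()
  tab <- simulate_germplasm(spec, seed = 42)
  sm <- summarize_traits(tab)
  # pooled means within 2 standard errors of the design means
  for (tr in c("L", "V", "J")) {
    mu <- mean(spec$means[, tr])
    se <- sd(tab[[tr]]) / sqrt(nrow(tab))
    expect_lt(abs(sm$mean[sm$trait == tr] - mu), 3 * se)
  }
  expect_true(all(sm$min <= sm$mean & sm$mean <= sm$max))
  # single-variety per-variety scope gives one block
  one <- summarize_traits(tab[tab$variety == "P1", ], scope = "per-variety")
  expect_equal(unique(one$scope), "P1")
  # duplicating every row keeps means; the n-1 SD shrinks slightly
  dup <- rbind(tab, tab)
  class(dup) <- class(tab)
  sm2 <- summarize_traits(dup)
  expect_equal(sm2$mean, sm$mean, tolerance = 1e-12)
  n <- nrow(tab)
  expect_equal(sm2$sd, sm$sd * sqrt((2 * n - 2) / (2 * n - 1)), tolerance = 1e-9)
})

test_that("nested ANOVA equals the definitional oracle on a tiny table", {
  tiny <- data.frame(
    group = rep(c("g1", "g2"), each = 6),
    variety = rep(c("a", "b", "c", "d"), each = 3),
    V = c(5.1, 4.9, 5.3, 6.2, 6.0, 6.4, 7.7, 8.1, 7.9, 9.0, 9.4, 8.8))
  res <- nested_anova(tiny, traits = "V")
  y <- tiny$V
  gm <- mean(y)
  mg <- tapply(y, tiny$group, mean)
  mv <- tapply(y, tiny$variety, mean)
  ss_among_o <- sum(6 * (mg - gm)^2)
  ss_within_o <- sum(3 * (mv - mg[c("g1", "g1", "g2", "g2")])^2)
  ss_error_o <- sum((y - mv[tiny$variety])^2)
  expect_equal(res$ss_among, ss_among_o, tolerance = 1e-10)
  expect_equal(res$ss_within, ss_within_o, tolerance = 1e-10)
  expect_equal(res$ss_error, ss_error_o, tolerance = 1e-10)
  expect_equal(res$f_among, (ss_among_o / 1) / (ss_error_o / 8), tolerance = 1e-10)
  # independent cross-check through stats::aov
  av <- summary(aov(V ~ group + group:variety, data = tiny))[[1]]
  expect_equal(unname(av[["Sum Sq"]]),
               c(res$ss_among, res$ss_within, res$ss_error), tolerance = 1e-8)
})

test_that("ANOVA sum-of-squares partition holds on random tables", {
  set.seed(7)
  for (i in 1:5) {
    tab <- simulate_germplasm(default_germplasm_spec(n_per_variety = 8),
                              seed = i)
    tab <- tab[tab$role == "offspring", ]
    res <- nested_anova(tab)
    expect_lt(max(abs(res$ss_total -
                        (res$ss_among + res$ss_within + res$ss_error))), 1e-9)
  }
})

test_that("constant observations give zero mean squares and flagged NaN F", {
  tab <- data.frame(group = rep(c("g1", "g2"), each = 4),
                    variety = rep(c("a", "b", "c", "d"), each = 2),
                    V = rep(5, 8))
  res <- nested_anova(tab, traits = "V")
  expect_equal(res$ms_among, 0)
  expect_true(is.nan(res$f_among))
  expect_true(res$degenerate)
  expect_error(nested_anova(data.frame(group = "g", variety = "a", V = 1:4),
                            traits = "V"),
               class = "seedhull_insufficient_replication")
})

test_that("expected mean squares emerge from a balanced variance-component design", {
  # groups N(0, 4), varieties N(0, 1), error N(0, 1), n = 30 per variety
  set.seed(31)
  a <- 2; b <- 3; n <- 30
  ms <- replicate(200, {
    ge <- rnorm(a, 0, 2)
    ve <- rnorm(a * b, 0, 1)
    df <- data.frame(group = rep(seq_len(a), each = b * n),
                     variety = rep(seq_len(a * b), each = n))
    df$V <- ge[df$group] + ve[df$variety] + rnorm(nrow(df))
    r <- nested_anova(df, traits = "V")
    c(r$ms_among, r$ms_within, r$ms_error)
  })
  avg <- rowMeans(ms)
  # EMS: sigma2 + n sigma2_v + b n sigma2_g ; sigma2 + n sigma2_v ; sigma2
  expect_equal(avg[1], 1 + n * 1 + b * n * 4, tolerance = 0.25)
  expect_equal(avg[2], 1 + n * 1, tolerance = 0.1)
  expect_equal(avg[3], 1, tolerance = 0.05)
})

test_that("gvf matches the stated convention and its invariances", {
  expect_equal(gvf(c(9, 10, 11), c(19, 20, 21), c(15, 15, 15)), 3.849002,
               tolerance = 1e-5)
  # offspring variance equal to the summed parent variance -> 0
  p1 <- c(1, 2, 3); p2 <- c(4, 5, 6)
  f <- sqrt(2) * (p1 - 2) + 10   # pop var = 2*2/3 = VarP1+VarP2
  # the square root amplifies float error, so "zero" is ~1e-6 here
  expect_lt(gvf(p1, p2, f), 1e-4)
  # common scaling leaves gvf unchanged
  expect_lt(abs(gvf(3 * p1, 3 * p2, 3 * f) - gvf(p1, p2, f)), 1e-4)
  set.seed(2); x1 <- rnorm(20, 10); x2 <- rnorm(20, 20); xf <- rnorm(20, 15, 2)
  expect_equal(gvf(2 * x1, 2 * x2, 2 * xf), gvf(x1, x2, xf), tolerance = 1e-9)
  expect_error(gvf(c(1), c(1, 2), c(1, 2)), class = "seedhull_too_few_values")
  expect_error(gvf(c(-1, 1), c(-1, 1), c(0, 0)),
               class = "seedhull_zero_parent_mean")
})

test_that("gvf estimates track a designed 5% truth at n = 30", {
  # design: parents sd s, offspring var 2 s^2 (1 + shift); truth
  # 100 * s * sqrt(2 * shift) / (mu1 + mu2) = 5
  mu <- c(10, 20); s <- 1.5
  shift <- (5 * (mu[1] + mu[2]) / (100 * s))^2 / 2
  set.seed(12)
  est <- replicate(500, {
    gvf(rnorm(30, mu[1], s), rnorm(30, mu[2], s),
        rnorm(30, 15, s * sqrt(2 * (1 + shift))))
  })
  expect_lt(abs(mean(est) - 5), 1)
})

test_that("gvf_table ranks the designed divergent variety first", {
  tab <- simulate_germplasm(default_germplasm_spec(), seed = 3)
  res <- gvf_table(tab)
  expect_equal(dim(res$gvf), c(9, 13))
  expect_equal(res$ranking[1], "F1")
  expect_equal(res$average, colMeans(res$gvf), tolerance = 1e-12)
  # single offspring: 9 x 1 matrix, average = mean of entries
  res1 <- gvf_table(tab, offspring_labels = "F3")
  expect_equal(dim(res1$gvf), c(9, 1))
  expect_equal(unname(res1$average), mean(res1$gvf), tolerance = 1e-12)
  # offspring built to match the parents' combined variance -> near zero
  p1 <- tab[tab$variety == "P1", ]; p2 <- tab[tab$variety == "P2", ]
  syn <- p1
  pv <- function(x) mean((x - mean(x))^2)
  for (tr in trait_names()) {
    z <- (p1[[tr]] - mean(p1[[tr]])) / sqrt(pv(p1[[tr]]))
    syn[[tr]] <- mean(p1[[tr]]) + z * sqrt(pv(p1[[tr]]) + pv(p2[[tr]]))
  }
  syn$variety <- "SYN"; syn$role <- "offspring"
  res2 <- gvf_table(rbind(tab, syn))
  expect_lt(res2$average[["SYN"]], 0.5)
  expect_error(gvf_table(tab[tab$role == "offspring", ]),
               class = "seedhull_missing_parent")
})

test_that("clustering separates designed blobs and scoring is label invariant", {
  set.seed(5)
  n <- 60
  mk <- function(center) matrix(rnorm(n * 9, center, 0.3), n, 9)
  X <- rbind(mk(0), mk(4))
  tab <- data.frame(group = rep(c("A", "B"), each = n), X)
  names(tab)[-1] <- trait_names()
  for (m in c("kmeans", "hierarchical")) {
    cs <- cluster_and_score(tab, m, k = 2)
    expect_equal(cs$precision, 1.0)
  }
  cd <- cluster_and_score(tab, "dbscan", eps = 2, min_pts = 5)
  expect_equal(cd$precision, 1.0)
  # flipping cluster ids leaves the matched precision unchanged
  labs <- cluster_and_score(tab, "kmeans", k = 2)$labels
  truth <- as.integer(factor(tab$group))
  expect_equal(seedhull:::matched_precision(labs, truth),
               seedhull:::matched_precision(3 - labs, truth))
  # identical points cannot be clustered
  same <- tab; same[trait_names()] <- 1
  expect_error(cluster_and_score(same, "kmeans", k = 2),
               class = "seedhull_degenerate_clustering")
})
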