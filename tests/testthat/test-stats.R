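# Validation statistics, 1-D k-means, ANOVA + Tukey HSD compact letters.

test_that("perfect agreement gives r = 1, RMSE = 0, t = 0, p = 1", {
  v <- c(3.1, 4.5, 2.2, 6.6, 5.0)
  rep <- validate_trait(v, v)
  expect_equal(rep$pearson_r, 1)
  expect_equal(rep$rmse, 0)
  expect_equal(rep$t_stat, 0)
  expect_equal(rep$p_paired, 1)
  expect_equal(rep$detection_frequency_pct, 100)
})

test_that("63 successes of 70 attempts is a 90.0% detection frequency", {
  rep <- validate_trait(rnorm(63), rnorm(63), attempts = 70)
  expect_equal(rep$detection_frequency_pct, 90.0, tolerance = 1e-12)
})

test_that("Pearson and paired t agree with the stats:: oracles to 1e-10", {
  measured <- c(1, 2, 3, 4, 5); predicted <- c(2, 4, 5, 7, 8)
  rep <- validate_trait(measured, predicted)
  ct <- stats::cor.test(measured, predicted)
  tt <- stats::t.test(measured, predicted, paired = TRUE)
  expect_equal(rep$pearson_r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(rep$p_pearson, ct$p.value, tolerance = 1e-10)
  expect_equal(rep$t_stat, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(rep$p_paired, tt$p.value, tolerance = 1e-10)
  expect_equal(rep$r_squared, rep$pearson_r^2, tolerance = 1e-12)
  expect_equal(rep$rmse, sqrt(mean((measured - predicted)^2)), tolerance = 1e-12)
})

test_that("too few pairs raise spt_insufficient_pairs", {
  expect_error(validate_trait(c(1, 2), c(1, 2)), class = "spt_insufficient_pairs")
})

test_that("three well-separated triplets form pure clusters labelled large to small", {
  cl <- kmeans_clusters(c(1, 1, 1, 5, 5, 5, 9, 9, 9), k = 3, seed = 1)
  expect_equal(cl$cluster_means, c(9, 5, 1))
  expect_equal(cl$assignments, c(3, 3, 3, 2, 2, 2, 1, 1, 1))
  expect_equal(cl$sizes, c(3, 3, 3))
})

test_that("cluster assignments are invariant to input permutation and seed-stable", {
  set.seed(77)
  v <- c(rnorm(20, 2, 0.3), rnorm(20, 8, 0.3), rnorm(20, 15, 0.3))
  cl1 <- kmeans_clusters(v, k = 3, seed = 42)
  perm <- sample(length(v))
  cl2 <- kmeans_clusters(v[perm], k = 3, seed = 42)
  expect_equal(cl2$assignments, cl1$assignments[perm])
  cl3 <- kmeans_clusters(v, k = 3, seed = 42)
  expect_identical(cl1$assignments, cl3$assignments)
})

test_that("k-means matches the exhaustive 1-D DP optimum on separated mixtures", {
  agree <- sapply(1:20, function(i) {
    v <- local({
      set.seed(500 + i)
      c(rnorm(15, 0, 0.5), rnorm(15, 5, 0.5), rnorm(15, 10, 0.5))
    })
    cl <- kmeans_clusters(v, k = 3, seed = i)
    all(cl$assignments == dp_kmeans_1d(v, 3))
  })
  expect_gte(mean(agree), 0.95)
})

test_that("n < k raises spt_too_few_samples", {
  expect_error(kmeans_clusters(c(1, 2), k = 3), class = "spt_too_few_samples")
})

test_that("two identical groups give F = 0 and a shared letter", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  res <- anova_tukey(g)
  expect_equal(res$F, 0)
  expect_equal(unname(res$letters), c("a", "a"))
})

test_that("clearly separated groups get p < 0.05 and distinct letters", {
  set.seed(13)
  g <- list(lo = rnorm(20, 0, 1), hi = rnorm(20, 10, 1))
  res <- anova_tukey(g)
  expect_lt(res$p, 0.05)
  expect_false(res$letters[["lo"]] == res$letters[["hi"]])
})

test_that("ANOVA F matches the aov() oracle on textbook values", {
  g <- list(g1 = c(6, 8, 4, 5, 3, 4),
            g2 = c(8, 12, 9, 11, 6, 8),
            g3 = c(13, 9, 11, 8, 7, 12))
  res <- anova_tukey(g)
  df <- data.frame(y = unlist(g), grp = rep(names(g), lengths(g)))
  ref <- anova(stats::lm(y ~ grp, data = df))
  expect_equal(res$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(res$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
  thsd <- stats::TukeyHSD(stats::aov(y ~ grp, data = df))$grp
  expect_equal(sort(res$tukey$p_adj), sort(unname(thsd[, "p adj"])), tolerance = 1e-8)
})

test_that("letters are consistent with pairwise Tukey significance", {
  set.seed(99)
  for (rep_i in 1:6) {
    k <- sample(3:5, 1)
    g <- lapply(seq_len(k), function(j) rnorm(8, mean = sample(0:6, 1)))
    names(g) <- paste0("g", seq_len(k))
    res <- anova_tukey(g)
    share <- function(i, j)
      length(intersect(strsplit(res$letters[[i]], "")[[1]],
                       strsplit(res$letters[[j]], "")[[1]])) > 0
    pair_p <- function(i, j) {
      r <- res$tukey
      hit <- (r$group1 == names(g)[i] & r$group2 == names(g)[j]) |
             (r$group1 == names(g)[j] & r$group2 == names(g)[i])
      r$p_adj[hit]
    }
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (pair_p(i, j) < 0.05) expect_false(share(i, j))
      else expect_true(share(i, j))
    }
  }
})

test_that("zero total variance raises spt_degenerate_groups", {
  expect_error(anova_tukey(list(a = c(2, 2), b = c(2, 2))),
               class = "spt_degenerate_groups")
})
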