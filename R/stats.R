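#' Validation and field-analysis statistics
#'
#' The statistics used to validate the tool against conventional
#' measurements (Pearson correlation, RMSE, paired t-tests, detection
#' frequency) and to analyse field data (1-D k-means size clustering,
#' one-way ANOVA with Tukey HSD and compact letter displays).  All tests
#' are two-sided; closed-form formulas are used throughout so results are
#' reproducible to machine precision.
#'
#' @name spt_stats
NULL

#' Compare measured (conventional) and predicted (tool) values for a trait
#'
#' @param measured,predicted paired finite numeric vectors of equal length
#'   `n >= 3` (successful measurement attempts only)
#' @param attempts total number of measurement attempts (`>= n`); misses
#'   feed the detection frequency
#' @param trait optional trait id for the report
#' @return object of class `validation_report`: `n`, `pearson_r` with
#'   two-sided `p_pearson` (t transform), `r_squared = r^2`, `rmse` (trait
#'   units), paired `t_stat` / `p_paired`, and `detection_frequency_pct =
#'   100 n / attempts`
#' @export
validate_trait <- function(measured, predicted, attempts = length(measured),
                           trait = NA_character_) {
  stopifnot(length(measured) == length(predicted),
            all(is.finite(measured)), all(is.finite(predicted)))
  n <- length(measured)
  if (n < 3) err_insufficient_pairs(n)
  stopifnot(attempts >= n)
  mx <- mean(measured); my <- mean(predicted)
  sxx <- sum((measured - mx)^2); syy <- sum((predicted - my)^2)
  sxy <- sum((measured - mx) * (predicted - my))
  r <- if (sxx > 0 && syy > 0) sxy / sqrt(sxx * syy) else NA_real_
  if (is.finite(r)) {
    r <- max(-1, min(1, r))
    if (abs(r) < 1) {
      t_r <- r * sqrt((n - 2) / (1 - r^2))
      p_r <- 2 * stats::pt(-abs(t_r), n - 2)
    } else p_r <- 0
  } else p_r <- NA_real_
  d <- measured - predicted
  sd_d <- stats::sd(d)
  if (sd_d > 0) {
    t_stat <- mean(d) / (sd_d / sqrt(n))
    p_paired <- 2 * stats::pt(-abs(t_stat), n - 1)
  } else { t_stat <- 0; p_paired <- 1 }
  structure(list(trait = trait, n = n,
                 pearson_r = r, p_pearson = p_r, r_squared = r^2,
                 rmse = sqrt(mean(d^2)),
                 bias = mean(d),
                 t_stat = t_stat, p_paired = p_paired,
                 detection_frequency_pct = 100 * n / attempts),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation%s: n=%d  r=%.3f (p=%.3g)  RMSE=%.3g  t=%.3f (p=%.3g)  freq=%.1f%%\n",
              if (is.na(x$trait)) "" else paste0(" [", x$trait, "]"),
              x$n, x$pearson_r, x$p_pearson, x$rmse, x$t_stat, x$p_paired,
              x$detection_frequency_pct))
  invisible(x)
}

#' One-dimensional k-means size clustering
#'
#' Lloyd's algorithm with k-means++ initialisation run on the *sorted*
#' values, which makes the result invariant to input order; the fixed seed
#' drives the k-means++ draws.  Clusters are relabelled by descending mean
#' so that cluster 1 always holds the largest sizes.
#'
#' @param values numeric vector, `length(values) >= k`
#' @param k number of clusters; defaults to 3 (large / medium / small)
#' @param seed integer seed for the k-means++ initialisation
#' @param max_iter Lloyd iteration cap
#' @return object of class `cluster_result`: `k`, `assignments` (integer
#'   per input value, 1 = largest cluster), `cluster_means` (descending),
#'   `sizes`, `withinss`
#' @export
kmeans_clusters <- function(values, k = 3, seed = 1L, max_iter = 200) {
  stopifnot(all(is.finite(values)), k >= 2)
  n <- length(values)
  if (n < k) err_too_few_samples(n, k)
  x <- sort(values)
  centers <- with_seed(seed, {
    cen <- x[sample.int(n, 1)]
    while (length(cen) < k) {
      d2 <- vapply(x, function(v) min((v - cen)^2), numeric(1))
      if (sum(d2) == 0) cen <- c(cen, x[sample.int(n, 1)])
      else cen <- c(cen, x[sample.int(n, 1, prob = d2)])
    }
    cen
  })
  assign_to <- function(cen, v) {
    D <- abs(outer(v, cen, "-"))
    max.col(-D, ties.method = "first")
  }
  for (it in seq_len(max_iter)) {
    a <- assign_to(centers, x)
    newc <- vapply(seq_len(k), function(j)
      if (any(a == j)) mean(x[a == j]) else centers[j], numeric(1))
    if (max(abs(newc - centers)) < 1e-12) { centers <- newc; break }
    centers <- newc
  }
  ord <- order(centers, decreasing = TRUE)
  centers <- centers[ord]
  assignments <- assign_to(centers, values)   # original order, relabelled
  sizes <- tabulate(assignments, nbins = k)
  wss <- sum((values - centers[assignments])^2)
  structure(list(k = k, assignments = assignments,
                 cluster_means = centers, sizes = sizes, withinss = wss),
            class = "cluster_result")
}

#' One-way ANOVA with Tukey HSD and a compact letter display
#'
#' @param groups list of numeric vectors (>= 2 groups, each with >= 2
#'   observations); names are used as group labels
#' @param alpha significance level for the letter display
#' @return list with `F`, `p`, `df` (c(between, within)), `means` (in input
#'   order), `tukey` (pairwise data.frame: groups, difference, q statistic,
#'   adjusted p) and `letters` (character per group; groups sharing a
#'   letter are not significantly different at `alpha`)
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  stopifnot(is.list(groups), length(groups) >= 2)
  k <- length(groups)
  ns <- lengths(groups)
  stopifnot(all(ns >= 2))
  if (is.null(names(groups))) names(groups) <- paste0("group", seq_len(k))
  all_v <- unlist(groups, use.names = FALSE)
  N <- length(all_v)
  gm <- mean(all_v)
  if (sum((all_v - gm)^2) <= 0) err_degenerate_groups()
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- k - 1; df2 <- N - k
  msb <- ssb / df1
  msw <- ssw / df2
  if (msw > 0) {
    Fstat <- msb / msw
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  } else { Fstat <- if (ssb > 0) Inf else 0; p <- if (ssb > 0) 0 else 1 }
  pairs <- utils::combn(k, 2)
  tuk <- data.frame(group1 = names(groups)[pairs[1, ]],
                    group2 = names(groups)[pairs[2, ]],
                    diff = means[pairs[1, ]] - means[pairs[2, ]])
  if (msw > 0) {
    se <- sqrt(msw / 2 * (1 / ns[pairs[1, ]] + 1 / ns[pairs[2, ]]))
    tuk$q <- abs(tuk$diff) / se
    tuk$p_adj <- stats::ptukey(tuk$q, nmeans = k, df = df2, lower.tail = FALSE)
  } else {
    tuk$q <- ifelse(tuk$diff == 0, 0, Inf)
    tuk$p_adj <- ifelse(tuk$diff == 0, 1, 0)
  }
  sig <- matrix(FALSE, k, k)
  sig[t(pairs)] <- tuk$p_adj < alpha
  sig <- sig | t(sig)
  letters <- cld_insert_absorb(means, sig)
  list(F = Fstat, p = p, df = c(between = df1, within = df2),
       means = means, tukey = tuk, letters = letters)
}

# Compact letter display via the insert-and-absorb algorithm: start with
# one letter covering all groups, split it for every significant pair,
# absorb redundant (subset) letters, then assign letters in order of the
# highest group mean they cover.
cld_insert_absorb <- function(means, sig) {
  k <- length(means)
  cols <- list(seq_len(k))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (!sig[i, j]) next
    for (ci in seq_along(cols)) {
      cc <- cols[[ci]]
      if (all(c(i, j) %in% cc)) {
        cols[[ci]] <- setdiff(cc, i)
        cols[[length(cols) + 1L]] <- setdiff(cc, j)
      }
    }
    # absorb: drop columns that are subsets of another column
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a != b && keep[a] && keep[b] && all(cols[[a]] %in% cols[[b]]) &&
          (length(cols[[a]]) < length(cols[[b]]) || a > b))
        keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  ord <- order(vapply(cols, function(cc) max(means[cc]), numeric(1)),
               decreasing = TRUE)
  cols <- cols[ord]
  lab <- rep("", k)
  for (ci in seq_along(cols)) {
    lt <- letters[(ci - 1) %% 26 + 1]
    if (ci > 26) lt <- paste0(lt, (ci - 1) %/% 26)
    for (g in cols[[ci]]) lab[g] <- paste0(lab[g], lt)
  }
  names(lab) <- names(means)
  lab
}
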