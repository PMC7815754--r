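make_labeled_dist <- function(n, seed, labels) {
  d <- withr::with_seed(seed, {
    m <- matrix(runif(n * n), n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
    m
  })
  list(d = d,
       labels = if (is.null(labels)) NULL
                else stats::setNames(labels, rownames(d)))
}

test_that("PERMANOVA p-value equals exhaustive enumeration for n = 6", {
  f <- make_labeled_dist(6, seed = 2, labels = rep(c("g1", "g2"), each = 3))
  res <- permanova(f$d, f$labels, n_perm = 999, seed = 1)
  expect_true(res$exhaustive)

  # independent oracle: enumerate the 20 distinct 3|3 splits directly
  d2 <- f$d^2
  sstot <- sum(d2[upper.tri(d2)]) / 6
  fstat <- function(g1) {
    g2 <- setdiff(1:6, g1)
    ssw <- sum(d2[g1, g1][upper.tri(diag(3))]) / 3 +
      sum(d2[g2, g2][upper.tri(diag(3))]) / 3
    ((sstot - ssw) / 1) / (ssw / 4)
  }
  splits <- utils::combn(6, 3, simplify = FALSE)
  f_all <- vapply(splits, fstat, numeric(1))
  f_obs <- fstat(1:3)
  expect_equal(res$pseudo_F, f_obs, tolerance = 1e-12)
  expect_equal(res$p_value, mean(f_all >= f_obs - 1e-12), tolerance = 1e-12)
})

test_that("PERMANOVA is invariant to sample order and rejects degenerate input", {
  f <- make_labeled_dist(12, seed = 5, labels = rep(c("a", "b", "c"), each = 4))
  r1 <- permanova(f$d, f$labels, n_perm = 199, seed = 3)
  perm <- withr::with_seed(4, sample(rownames(f$d)))
  r2 <- permanova(f$d[perm, perm], f$labels[perm], n_perm = 199, seed = 3)
  expect_equal(r1$pseudo_F, r2$pseudo_F, tolerance = 1e-12)
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_error(permanova(z, c("a", "a", "b", "b")), "degenerate")
})

test_that("PERMANOVA pseudo-F matches vegan::adonis2 on a one-factor design", {
  tab <- random_table(20, 12, seed = 8)
  d <- beta_distance(tab, "bray_curtis")
  labels <- rep(c("g1", "g2", "g3"), each = 4)
  res <- permanova(d, stats::setNames(labels, colnames(tab)), n_perm = 99,
                   seed = 1)
  ad <- vegan::adonis2(stats::as.dist(d) ~ g, data = data.frame(g = labels),
                       permutations = 5)
  expect_equal(res$pseudo_F, ad$F[1], tolerance = 1e-10)
})

test_that("Mantel r and p match closed form, vegan and exhaustive enumeration", {
  f <- make_labeled_dist(4, seed = 11, labels = NULL)
  g <- make_labeled_dist(4, seed = 12, labels = NULL)
  res <- mantel(f$d, g$d, n_perm = 999, seed = 1)
  expect_true(res$exhaustive)
  # oracle: all 4! = 24 permutations
  lower <- function(m) m[lower.tri(m)]
  perms <- expand.grid(rep(list(1:4), 4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  r_obs <- stats::cor(lower(f$d), lower(g$d))
  r_all <- apply(perms, 1, function(o) {
    o <- as.integer(o)
    stats::cor(lower(f$d[o, o]), lower(g$d))
  })
  expect_equal(res$statistic, r_obs, tolerance = 1e-12)
  expect_equal(res$p_value, mean(r_all >= r_obs - 1e-12), tolerance = 1e-12)
  expect_equal(nrow(perms), 24)

  # self-correlation and vegan cross-check on a larger instance
  h <- make_labeled_dist(10, seed = 13, labels = NULL)$d
  k <- make_labeled_dist(10, seed = 14, labels = NULL)$d
  expect_equal(mantel(h, h, n_perm = 99, seed = 1)$statistic, 1)
  vg <- vegan::mantel(stats::as.dist(h), stats::as.dist(k), permutations = 5)
  expect_equal(mantel(h, k, n_perm = 99, seed = 1)$statistic, vg$statistic,
               tolerance = 1e-10)
  # invariance under a common reordering
  o <- withr::with_seed(3, sample(rownames(h)))
  expect_equal(mantel(h[o, o], k[o, o], n_perm = 99, seed = 1)$statistic,
               mantel(h, k, n_perm = 99, seed = 1)$statistic, tolerance = 1e-12)
})

test_that("partial Mantel follows its algebraic identities", {
  a <- make_labeled_dist(12, seed = 21, labels = NULL)$d
  b <- make_labeled_dist(12, seed = 22, labels = NULL)$d
  c_ <- make_labeled_dist(12, seed = 23, labels = NULL)$d
  lower <- function(m) m[lower.tri(m)]
  # b = c makes the partial correlation 0 by construction
  expect_equal(partial_mantel(a, b, b, n_perm = 49, seed = 1)$statistic, 0,
               tolerance = 1e-12)
  # agreement with the residual-regression formulation
  va <- lower(a); vb <- lower(b); vc <- lower(c_)
  ra <- stats::resid(stats::lm(va ~ vc))
  rb <- stats::resid(stats::lm(vb ~ vc))
  expect_equal(partial_mantel(a, b, c_, n_perm = 49, seed = 1)$statistic,
               stats::cor(ra, rb), tolerance = 1e-10)
})

test_that("ANOVA with LSD produces textbook F and sensible letters", {
  # two-group equal-n closed form
  g1 <- c(1, 2, 3, 4); g2 <- c(3, 4, 5, 6)
  res <- anova_lsd(c(g1, g2), rep(c("a", "b"), each = 4))
  n <- 4; sp2 <- (stats::var(g1) + stats::var(g2)) / 2
  f_expected <- n * (mean(g1) - mean(g2))^2 / (2 * sp2)
  expect_equal(res$anova$F, f_expected, tolerance = 1e-10)

  # identical distributions share a letter
  same <- anova_lsd(rep(c(1, 2, 3), 3), rep(c("x", "y", "z"), each = 3))
  expect_equal(length(unique(same$means$letters)), 1)

  # overwhelming separation gets distinct letters
  vals <- withr::with_seed(1, c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1)))
  far <- anova_lsd(vals, rep(c("lo", "hi"), each = 5))
  expect_setequal(far$means$letters, c("a", "b"))
  expect_error(anova_lsd(c(1, 2, 3), c("a", "a", "b")), "2 observations")
})

test_that("hierarchical partitioning obeys its decomposition identities", {
  # single factor: independent contribution equals the marginal R^2
  df <- withr::with_seed(31, {
    stage <- factor(rep(c("S1", "S2", "S3"), each = 8))
    tibble::tibble(sample_id = sprintf("s%02d", 1:24),
                   pd = as.numeric(stage) + rnorm(24, 0, 0.3))
  })
  meta1 <- tibble::tibble(sample_id = df$sample_id,
                          stage = rep(c("S1", "S2", "S3"), each = 8))
  vp1 <- variance_partition(df, meta1, response = "pd", factors = "stage")
  expect_equal(vp1$independent, vp1$r2_marginal, tolerance = 1e-12)

  # two orthogonal balanced factors: independent = marginal
  meta2 <- tibble::tibble(sample_id = df$sample_id,
                          stage = rep(c("S1", "S2", "S3"), each = 8),
                          food = rep(rep(c("live", "dry"), each = 4), 3))
  resp <- withr::with_seed(32, tibble::tibble(
    sample_id = df$sample_id,
    pd = as.numeric(factor(meta2$stage)) + 2 * (meta2$food == "dry") +
      rnorm(24, 0, 0.2)))
  vp2 <- variance_partition(resp, meta2, response = "pd",
                            factors = c("stage", "food"))
  expect_equal(vp2$independent, vp2$r2_marginal, tolerance = 1e-10)

  # four factors: independent contributions sum to the full-model R^2
  st <- tiny_study(seed = 6, n_otus = 80, depth = 500, replicates = 2,
                   dph = c(12L, 20L, 42L, 98L))
  tab <- st$table
  alpha <- alpha_diversity(tab, st$tree)
  gut <- st$metadata[st$metadata$habitat == "gut", ]
  vp4 <- variance_partition(alpha[alpha$sample_id %in% gut$sample_id, ], gut,
                            response = "shannon")
  expect_equal(sum(vp4$independent), attr(vp4, "r2_full"), tolerance = 1e-8)
  expect_equal(sum(vp4$independent_pct), 100, tolerance = 1e-8)
})
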