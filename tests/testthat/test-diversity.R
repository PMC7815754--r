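test_that("alpha diversity matches closed forms on the worked example", {
  tree <- example_tree()
  m <- cbind(even4 = c(5L, 5L, 5L, 5L), ab = c(5L, 5L, 0L, 0L),
             solo = c(9L, 0L, 0L, 0L))
  rownames(m) <- c("A", "B", "C", "D")
  a <- alpha_diversity(otu_table(m), tree)
  expect_equal(a$shannon[a$sample_id == "even4"], log(4), tolerance = 1e-12)
  expect_equal(a$shannon[a$sample_id == "solo"], 0)
  expect_equal(a$richness, c(4L, 2L, 1L), ignore_attr = TRUE)
  # root-inclusive Faith PD: {A,B} spans A:1 + B:1 + stem:1 = 3
  expect_equal(a$pd[a$sample_id == "ab"], 3)
  # full tip set spans the whole tree
  expect_equal(a$pd[a$sample_id == "even4"], sum(tree$edge.length))
})

test_that("alpha diversity errors name OTUs missing from the tree", {
  m <- matrix(c(1L, 1L), 2, 1, dimnames = list(c("A", "ZZZ"), "s1"))
  expect_error(alpha_diversity(otu_table(m), example_tree()), "ZZZ")
})

test_that("Shannon is bounded by log richness with equality at evenness", {
  tab <- random_table(25, 12, seed = 31)
  tree <- random_tree_for(tab, seed = 31)
  a <- alpha_diversity(tab, tree)
  expect_true(all(a$shannon <= log(a$richness) + 1e-12))
  expect_true(all(a$shannon >= 0))
  expect_true(all(a$pd[a$richness >= 1] > 0))
})

test_that("beta distances match their formulas and a double-loop oracle", {
  m <- cbind(x = c(10L, 0L, 10L), y = c(0L, 10L, 10L))
  rownames(m) <- c("o1", "o2", "o3")
  bc <- beta_distance(otu_table(m), "bray_curtis")
  expect_equal(bc["x", "y"], 0.5)
  jm <- cbind(a = c(1L, 0L, 1L), b = c(0L, 1L, 1L))
  rownames(jm) <- c("o1", "o2", "o3")
  jc <- beta_distance(otu_table(jm), "jaccard")
  expect_equal(jc["a", "b"], 1 - 1 / 3, tolerance = 1e-12)

  tab <- random_table(10, 10, seed = 77)
  d <- beta_distance(tab, "bray_curtis")
  expect_equal(diag(d), rep(0, 10), ignore_attr = TRUE)
  cnt <- unclass(tab)
  for (pair in list(c(1, 2), c(3, 9), c(5, 10))) {
    i <- pair[1]; j <- pair[2]
    expect_equal(d[i, j],
                 sum(abs(cnt[, i] - cnt[, j])) / sum(cnt[, i] + cnt[, j]),
                 tolerance = 1e-12)
  }
  dj <- beta_distance(tab, "jaccard")
  pa <- cnt > 0
  expect_equal(dj[1, 2],
               1 - sum(pa[, 1] & pa[, 2]) / sum(pa[, 1] | pa[, 2]),
               tolerance = 1e-12)
})

test_that("shared-OTU fractions behave at the degenerate limits", {
  same <- cbind(A = c(TRUE, TRUE), B = c(TRUE, TRUE), C = c(TRUE, TRUE))
  s <- shared_otu_fractions(same)
  expect_equal(s$fraction[s$members == "A+B+C"], 1)
  expect_equal(attr(s, "unique_fraction"), 0)
  disjoint <- cbind(A = c(TRUE, FALSE), B = c(FALSE, TRUE), C = c(FALSE, FALSE))
  s2 <- shared_otu_fractions(disjoint)
  expect_equal(s2$fraction[s2$members == "A+B+C"], 0)
  expect_equal(attr(s2, "unique_fraction"), 1)
})

test_that("Rao quadratic entropy matches closed forms and symmetries", {
  expect_equal(rao_quadratic_entropy(1, matrix(0, 1, 1)), 0)
  d2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(rao_quadratic_entropy(c(0.5, 0.5), d2), 0.5)
  # species-neutral d makes Rao equal Gini-Simpson
  p <- withr::with_seed(3, { v <- runif(15); v / sum(v) })
  dn <- 1 - diag(15)
  expect_equal(rao_quadratic_entropy(p, dn), 1 - sum(p^2), tolerance = 1e-12)
  # invariance under a common permutation
  perm <- withr::with_seed(4, sample(15))
  dd <- withr::with_seed(5, { m <- matrix(runif(225), 15); m <- m + t(m); diag(m) <- 0; m })
  expect_equal(rao_quadratic_entropy(p[perm], dd[perm, perm]),
               rao_quadratic_entropy(p, dd), tolerance = 1e-12)
  expect_error(rao_quadratic_entropy(c(0.5, 0.5), matrix(0, 3, 3)), "mismatch")
})

test_that("the Rao partition is additive, non-negative and exact at degeneracy", {
  st <- tiny_study(seed = 5, n_otus = 60, depth = 400)
  part <- partition_diversity(st$table, st$metadata)
  expect_equal(part$gamma_ecosystem,
               part$alpha_local + part$beta_intra_habitats +
                 part$beta_inter_habitats, tolerance = 1e-10)
  expect_equal(part$frac_alpha + part$frac_beta_intra + part$frac_beta_inter,
               1, tolerance = 1e-10)
  expect_true(all(c(part$alpha_local, part$beta_intra_habitats,
                    part$beta_inter_habitats) >= -1e-12))
  # random tables: additivity and non-negativity with the correction on
  for (seed in c(11, 12, 13)) {
    tab <- random_table(20, 8, seed = seed)
    meta <- tibble::tibble(sample_id = colnames(tab),
                           habitat = rep(c("water", "gut"), each = 4),
                           tank = "T1", cage = NA, hatch_env = NA,
                           rear_env = "A", dph = 12, stage = "S1",
                           transition = FALSE, food = NA)
    p <- partition_diversity(tab, meta)
    expect_equal(p$gamma_ecosystem,
                 p$alpha_local + p$beta_intra_habitats + p$beta_inter_habitats,
                 tolerance = 1e-10)
    expect_true(all(c(p$beta_intra_habitats, p$beta_inter_habitats) >= -1e-10))
  }
  # identical samples: all turnover components vanish
  one <- matrix(c(3L, 2L, 1L), 3, 4, dimnames = list(c("a", "b", "c"),
                                                     paste0("s", 1:4)))
  meta1 <- tibble::tibble(sample_id = paste0("s", 1:4),
                          habitat = rep(c("water", "gut"), each = 2),
                          tank = "T1", cage = NA, hatch_env = NA,
                          rear_env = "A", dph = 12, stage = "S1",
                          transition = FALSE, food = NA)
  p1 <- partition_diversity(otu_table(one), meta1)
  expect_equal(p1$beta_intra_habitats, 0, tolerance = 1e-10)
  expect_equal(p1$beta_inter_habitats, 0, tolerance = 1e-10)
  expect_equal(p1$gamma_ecosystem, p1$alpha_local, tolerance = 1e-10)
  # a scope missing one habitat errors
  expect_error(partition_diversity(otu_table(one), within(as.data.frame(meta1),
               habitat <- "gut")), "lacks habitat")
})
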