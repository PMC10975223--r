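test_that("two-sided Fisher reproduces the published 2x2 p-values at 3 dp", {
  # molecular response vs trough-threshold attainment tables
  cases <- list(
    list(tab = matrix(c(16, 11, 9, 2), 2, byrow = TRUE), p = 0.268),
    list(tab = matrix(c(10, 17, 5, 6), 2, byrow = TRUE), p = 0.722),
    list(tab = matrix(c(6, 4, 19, 9), 2, byrow = TRUE), p = 0.709),
    list(tab = matrix(c(5, 5, 10, 18), 2, byrow = TRUE), p = 0.473))
  for (cs in cases)
    expect_equal(round(fisher_exact_two_sided(cs$tab), 3), cs$p)
  expect_equal(fisher_exact_two_sided(matrix(c(1, 0, 0, 1), 2)), 1.0)
})

test_that("Fisher agrees with the reference implementation on random tables", {
  set.seed(21)
  for (i in 1:40) {
    tab <- random_table(2, 2, sample(4:60, 1))
    expect_equal(fisher_exact_two_sided(tab),
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
})

test_that("Freeman-Halton reduces to Fisher on 2x2 and matches brute force", {
  set.seed(22)
  for (i in 1:25) {
    tab <- random_table(2, 2, sample(4:40, 1))
    expect_equal(freeman_halton_exact(tab), fisher_exact_two_sided(tab),
                 tolerance = 1e-12)
  }
  # independent label-assignment enumeration for all-shape tables, N <= 12
  for (i in 1:12) {
    nr <- sample(2:3, 1); nc <- sample(2:3, 1)
    tab <- random_table(nr, nc, sample((nr * nc):12, 1))
    expect_equal(freeman_halton_exact(tab), brute_force_exact_p(tab),
                 tolerance = 1e-10)
  }
})

test_that("exact r x c p-values for the published dose-group tables are stable", {
  # Values under the point-probability convention, frozen after verification
  # against the brute-force oracle; the corresponding Pearson p-values are
  # computed alongside because published crosstab output may mix conventions.
  att107 <- matrix(c(8, 1, 14, 3, 5, 7), 3, byrow = TRUE)
  att213 <- matrix(c(4, 5, 6, 11, 0, 12), 3, byrow = TRUE)
  mr3dose <- matrix(c(3, 6, 12, 5, 10, 2), 3, byrow = TRUE)
  dmrdose <- matrix(c(2, 7, 6, 11, 7, 5), 3, byrow = TRUE)
  expect_equal(round(freeman_halton_exact(att107), 4), 0.0328)
  expect_equal(round(freeman_halton_exact(att213), 4), 0.0226)
  expect_equal(round(freeman_halton_exact(mr3dose), 4), 0.0591)
  expect_equal(round(freeman_halton_exact(dmrdose), 4), 0.2457)
  expect_equal(round(pearson_chi2(att107)$p, 3), 0.024)
  expect_equal(round(pearson_chi2(att213)$p, 3), 0.038)
})

test_that("exact p-values are invariant to permutation and transposition", {
  set.seed(23)
  for (i in 1:10) {
    tab <- random_table(3, 2, sample(8:20, 1))
    p <- freeman_halton_exact(tab)
    expect_equal(freeman_halton_exact(tab[sample(3), sample(2)]), p,
                 tolerance = 1e-12)
    expect_equal(freeman_halton_exact(t(tab)), p, tolerance = 1e-12)
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("Pearson chi-squared follows the textbook formula", {
  expect_equal(pearson_chi2(matrix(2, 2, 2)),
               list(statistic = 0, df = 1, p = 1))
  tab <- matrix(c(8, 1, 14, 3, 5, 7), 3, byrow = TRUE)
  res <- pearson_chi2(tab)
  expect_equal(res$statistic, 7.486, tolerance = 1e-3)
  expect_equal(res$df, 2)
  ref <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  # symmetry under simultaneous row and column permutation
  expect_equal(pearson_chi2(tab[c(3, 1, 2), c(2, 1)])$statistic,
               res$statistic, tolerance = 1e-12)
  # Yates correction agrees with the reference on 2x2
  t22 <- matrix(c(16, 11, 9, 2), 2, byrow = TRUE)
  expect_equal(pearson_chi2(t22, correct = TRUE)$statistic,
               unname(suppressWarnings(stats::chisq.test(t22))$statistic),
               tolerance = 1e-12)
})

test_that("degenerate tables and runaway enumerations are rejected", {
  expect_error(fisher_exact_two_sided(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "degenerate")
  expect_error(freeman_halton_exact(matrix(c(5, 0, 7, 0), 2)), "degenerate")
  expect_error(pearson_chi2(matrix(c(1, -1, 2, 2), 2)), "non-negative")
  expect_error(freeman_halton_exact(matrix(25, 4, 4), guard = 1000),
               "guard")
})

test_that("group-comparison wrappers behave under exchangeable input", {
  x <- c(1, 2, 3, 4, 5); y <- c(1, 2, 3, 4, 5)
  mw <- compare_continuous_groups(c(x, y), rep(c("a", "b"), each = 5),
                                  "mann_whitney")
  expect_equal(mw$statistic, 5 * 5 / 2)
  expect_gte(mw$p, 0.99)
  sp <- compare_continuous_groups(1:8, (1:8)^3, "spearman")
  expect_equal(sp$statistic, 1)
  expect_error(compare_continuous_groups(rep(1, 5), 1:5, "spearman"),
               "constant")
  tt <- compare_continuous_groups(c(x, y + 10), rep(c("a", "b"), each = 5),
                                  "t_test")
  expect_lt(tt$p, 0.01)
  set.seed(4)
  v <- rnorm(30); g <- rep(c("a", "b", "c"), each = 10)
  kw <- compare_continuous_groups(v, g, "kruskal_wallis_bonferroni")
  expect_length(kw$pairwise, 3)
  expect_true(all(kw$pairwise <= 1))
  expect_equal(kw$statistic, unname(stats::kruskal.test(v, factor(g))$statistic))
  expect_error(compare_continuous_groups(v[1:11], c(rep("a", 10), "b"),
                                         "mann_whitney"), "at least 2")
})
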