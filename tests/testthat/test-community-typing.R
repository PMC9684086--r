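mk_tab <- function(..., taxa) {
  m <- rbind(...)
  colnames(m) <- taxa
  rownames(m) <- paste0("S", seq_len(nrow(m)))
  abundance_table(m)
}

test_that("dominance typing applies the inclusive 50% rule and tie-breaks", {
  tab <- mk_tab(c(0.6, 0.4, 0), c(0.49, 0.48, 0.03), c(0.5, 0.5, 0),
                taxa = c("s__Lactobacillus_crispatus", "s__Lactobacillus_iners",
                         "s__Gardnerella_vaginalis"))
  ty <- assign_types(tab)
  expect_identical(ty$type,
                   c("Lactobacillus_crispatus", "diverse", "Lactobacillus_crispatus"))
  expect_equal(ty$dominant_fraction, c(0.6, 0.49, 0.5))

  # exact-threshold tie between two labels -> lexicographically first
  tab2 <- mk_tab(c(0.5, 0.5), taxa = c("s__Zeta_b", "s__Alpha_a"))
  expect_identical(assign_types(tab2)$type, "Alpha_a")

  # invariant to column order and to absent taxa
  perm <- unclass(tab)[, c(3, 1, 2)]
  expect_identical(assign_types(abundance_table(perm))$type, ty$type)
  wide <- cbind(unclass(tab), "s__Extra_sp" = 0)
  expect_identical(assign_types(abundance_table(wide))$type, ty$type)
})

test_that("all-zero samples are labelled diverse with a warning", {
  m <- matrix(c(0.7, 0.3, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("S1", "S2"), c("s__A_a", "s__B_b")))
  expect_warning(ty <- assign_types(abundance_table(m)), "all-zero")
  expect_identical(ty$type[2], "diverse")
  expect_identical(ty$dominant_fraction[2], 0)
})

test_that("centroid ordering matches a brute-force linkage oracle", {
  # identical samples merge at height zero and sit adjacent
  m <- mk_tab(c(0.5, 0.5), c(0.9, 0.1), c(0.5, 0.5),
              taxa = c("s__A_a", "s__B_b"))
  co <- cluster_order(m)
  expect_equal(min(co$height), 0)
  pos <- match(c(1, 3), co$order)
  expect_equal(abs(diff(pos)), 1)

  expect_identical(cluster_order(m[1, , drop = FALSE])$order, 1L)

  x <- unclass(random_abund(10, 6, seed = 7))
  got <- sort(cluster_order(x)$height)
  expect_equal(got, centroid_linkage_oracle(x), tolerance = 1e-9)
})

test_that("type-covariate LR test separates, stays uniform under the null", {
  groups <- rep(c("a", "b"), each = 10)
  sep <- type_covariate_test(groups, rep(c(0, 5), each = 10))
  expect_lt(sep$overall_p, 1e-12)
  expect_lt(sep$pairwise["a", "b"], 1e-12)

  expect_equal(type_covariate_test(groups, rep(1, 20))$overall_p, 1)

  # null calibration: permuted labels give roughly uniform P
  ps <- withr_seed(42, replicate(500, {
    type_covariate_test(sample(rep(c("a", "b", "c"), each = 15)), rnorm(45))$overall_p
  }))
  expect_equal(mean(ps), 0.5, tolerance = 0.05)

  # affine invariance of the overall P
  y <- withr_seed(5, rnorm(30))
  g <- rep(c("a", "b", "c"), 10)
  expect_equal(type_covariate_test(g, y)$overall_p,
               type_covariate_test(g, 100 + 7 * y)$overall_p)
})

test_that("two-group LR chi-square agrees with the F test asymptotically", {
  y <- withr_seed(8, rnorm(2000))
  g <- rep(c("a", "b"), 1000)
  lr_p <- type_covariate_test(g, y)$overall_p
  f_p <- anova(lm(y ~ g))[["Pr(>F)"]][1]
  expect_equal(lr_p, f_p, tolerance = 1e-3)
})

test_that("small groups are excluded and group floor enforced", {
  g <- c(rep("a", 10), rep("b", 10), rep("c", 2))
  y <- seq_along(g)
  expect_message(res <- type_covariate_test(g, y, min_group = 3), "excluding")
  expect_equal(res$n_groups, 2)
  expect_error(suppressMessages(
    type_covariate_test(c(rep("a", 10), "b"), seq_len(11))), "at least 2 groups")
})

test_that("fisher co-occurrence matches the enumeration oracle", {
  bal <- fisher_cooccurrence(table = rbind(c(50, 50), c(50, 50)))
  expect_equal(bal$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(bal$p_two_sided, 1)

  tab <- rbind(c(5, 1), c(2, 8))
  r <- fisher_cooccurrence(table = tab)
  expect_equal(r$p_two_sided, fisher_p_oracle(tab), tolerance = 1e-10)
  expect_equal(r$odds_ratio, fisher_or_oracle(tab), tolerance = 1e-6)

  sep <- fisher_cooccurrence(table = rbind(c(10, 0), c(0, 10)))
  expect_equal(sep$p_two_sided, fisher_p_oracle(rbind(c(10, 0), c(0, 10))),
               tolerance = 1e-12)
  expect_identical(sep$odds_ratio, Inf)

  dg <- fisher_cooccurrence(rep(1, 20), rbinom(20, 1, 0.5))
  expect_true(dg$degenerate)
  expect_equal(dg$p_two_sided, 1)
  expect_true(is.nan(dg$odds_ratio))
})

test_that("fisher P is invariant to vector swap and joint relabeling", {
  a <- withr_seed(3, rbinom(60, 1, 0.4))
  b <- withr_seed(4, rbinom(60, 1, 0.6))
  p1 <- fisher_cooccurrence(a, b)$p_two_sided
  expect_equal(fisher_cooccurrence(b, a)$p_two_sided, p1)
  expect_equal(fisher_cooccurrence(1 - a, 1 - b)$p_two_sided, p1)
})

test_that("rank-sum comparison is exact at small n and calibrated at large n", {
  expect_equal(ranksum_compare(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(ranksum_compare(1:5, 6:10), 2 / choose(10, 5))

  # agrees with the reference implementation where both are exact
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(0.4, 6.0, 7.2, 8.8, 9.1)
  expect_equal(ranksum_compare(x, y),
               wilcox.test(x, y, exact = TRUE)$p.value)

  ps <- withr_seed(11, replicate(500, ranksum_compare(rnorm(30), rnorm(30))))
  expect_equal(mean(ps), 0.5, tolerance = 0.06)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)

  expect_error(ranksum_compare(numeric(0), 1:3), "nonempty")
})
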