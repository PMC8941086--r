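test_that("exact binomial tail matches closed forms", {
  r <- binomial_vs_base_rate(0, 21, 0.15, tail = "less")
  expect_equal(r$p, 0.85^21, tolerance = 1e-12)
  expect_equal(round(r$p, 3), 0.033)
  expect_equal(binomial_vs_base_rate(8, 8, 0.5, tail = "greater")$p, 0.5^8)
  # k/n == p0: either tail gives p >= 0.5
  expect_gte(binomial_vs_base_rate(5, 10, 0.5, "greater")$p, 0.5)
  expect_gte(binomial_vs_base_rate(5, 10, 0.5, "less")$p, 0.5)
  # auto tail follows the observed direction
  expect_identical(binomial_vs_base_rate(1, 20, 0.3)$tail, "less")
  expect_identical(binomial_vs_base_rate(15, 20, 0.3)$tail, "greater")
  # monotone: for fixed n, p0, greater-tail p non-increasing in k
  ps <- vapply(0:10, function(k)
    binomial_vs_base_rate(k, 10, 0.4, "greater")$p, 0)
  expect_true(all(diff(ps) <= 1e-15))
  expect_error(binomial_vs_base_rate(1, 10, 0), "base rate")
  expect_error(binomial_vs_base_rate(1, 10, 1), "base rate")
})

test_that("one-vs-rest chi-square reproduces reference statistics", {
  expect_equal(round(chi_square_one_vs_rest(0, 21, 19, 112)$chi_square, 2),
               4.16)
  # printed counts give 8.4247 (prints as 8.43 in the source table)
  expect_equal(chi_square_one_vs_rest(18, 87, 1, 46)$chi_square,
               8.424663, tolerance = 1e-6)
  expect_equal(round(chi_square_one_vs_rest(6, 21, 8, 112)$chi_square, 2),
               8.62)
  expect_equal(chi_square_one_vs_rest(10, 20, 10, 20)$chi_square, 0)
  # symmetric in group/rest
  a <- chi_square_one_vs_rest(5, 30, 12, 40)
  b <- chi_square_one_vs_rest(12, 40, 5, 30)
  expect_equal(a$chi_square, b$chi_square)
  expect_error(chi_square_one_vs_rest(0, 10, 0, 20), "zero margin")
  # oracle: stats::chisq.test without correction, random tables
  set.seed(17)
  for (i in 1:10) {
    ng <- sample(5:40, 1); nr <- sample(5:40, 1)
    kg <- sample(1:(ng - 1), 1); kr <- sample(1:(nr - 1), 1)
    mine <- chi_square_one_vs_rest(kg, ng, kr, nr)
    ref <- suppressWarnings(
      chisq.test(matrix(c(kg, ng - kg, kr, nr - kr), 2, byrow = TRUE),
                 correct = FALSE))
    expect_equal(mine$chi_square, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("Kruskal-Wallis H matches hand computation and stats oracle", {
  expect_equal(kruskal_wallis(list(1:3, 4:6))$H, 27 / 7, tolerance = 1e-12)
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0,
               tolerance = 1e-12)
  expect_equal(kruskal_wallis(list(5, c(5, 5), c(5, 5, 5)))$H, 0)
  expect_true(is.finite(kruskal_wallis(list(1, 2, 3))$H))
  set.seed(23)
  gs <- list(rnorm(8), rnorm(5, 1), round(rnorm(7), 1))
  mine <- kruskal_wallis(gs)
  ref <- kruskal.test(gs)
  expect_equal(mine$H, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
})

test_that("phenotype report reproduces the reference table statistics", {
  ref <- synthetic_reference_corpus()
  rep <- suppressMessages(phenotype_report(ref$corpus, ref$magset))
  row <- function(ch, g) rep[rep$characteristic == ch & rep$group == g, ]

  dep1 <- row("DEP", "1")
  expect_equal(dep1$pct, 0)
  expect_equal(dep1$base_rate_pct, 15.0)
  expect_equal(round(dep1$chi_square, 2), 4.16)
  expect_true(dep1$sig_vs_base_rate)          # p = 0.033 < 0.05
  expect_true(dep1$sig_between_mags)          # p = 0.041

  dep2 <- row("DEP", "2")
  expect_equal(dep2$pct, 20.7)
  expect_equal(round(dep2$p_chi_square, 3), 0.004)
  expect_false(dep2$sig_vs_base_rate)         # p = 0.123-ish, n.s.

  pos1 <- row("valence_positive", "1")
  expect_equal(pos1$pct, 28.6)
  expect_equal(round(pos1$chi_square, 2), 8.62)
  expect_equal(round(pos1$p_binomial, 3), 0.028)

  kw <- attr(rep, "kruskal")$pct_boys
  expect_true(!is.null(kw) && kw$H >= 0)
})

test_that("phenotype report handles degenerate groupings", {
  ref <- synthetic_reference_corpus()
  all_in_one <- prune_small_groups(
    setNames(rep(1L, length(ref$labels)), names(ref$labels)), 10)
  rep1 <- suppressMessages(phenotype_report(ref$corpus, all_in_one))
  expect_true(all(is.na(rep1$chi_square)))    # no rest group: degenerate
  # uniform characteristic: no between-MAG flags
  expect_false(any(rep1$sig_between_mags))
})

test_that("label enrichment matches the binomial z formula", {
  g <- cube_grid(10)
  n_half <- floor(g$n_mask_voxels / 2)
  cluster <- c(rep(TRUE, n_half), rep(FALSE, g$n_mask_voxels - n_half))
  centres <- voxel_to_world(g, which(g$mask, arr.ind = TRUE) - 1L)
  set.seed(41)
  # label "conc" 5x concentrated in the cluster; "flat" at base rate
  pick <- function(n, inside) {
    pool <- if (inside) seq_len(n_half) else (n_half + 1):g$n_mask_voxels
    centres[sample(pool, n, TRUE), , drop = FALSE]
  }
  db <- rbind(
    data.frame(pick(80, TRUE), label = "conc"),
    data.frame(pick(16, FALSE), label = "conc"),
    data.frame(pick(50, TRUE), label = "flat"),
    data.frame(pick(50, FALSE), label = "flat"),
    data.frame(pick(500, TRUE), label = "other"),   # anchors p_mask near 0.5
    data.frame(pick(500, FALSE), label = "other"))
  res <- label_enrichment(cluster, db, g)
  p_mask <- (80 + 50 + 500) / nrow(db)
  z_conc <- (80 - 96 * p_mask) / sqrt(96 * p_mask * (1 - p_mask))
  expect_equal(res$z[res$label == "conc"], z_conc, tolerance = 1e-9)
  expect_true(res$significant[res$label == "conc"])
  expect_false(res$significant[res$label == "flat"])
  expect_lt(abs(res$z[res$label == "flat"]), 2)
  expect_error(label_enrichment(cluster, db[0, ], g), "empty")
  expect_error(label_enrichment(rep(FALSE, g$n_mask_voxels), db, g), "empty")
})
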