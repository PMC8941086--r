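test_that("spearman_similarity matches hand-computed rank correlations", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
  s <- spearman_similarity(m)
  expect_equal(s$rho["a", "a"], 1)
  expect_equal(s$rho["a", "b"], 0.8)         # 1 - 6*2 / (4*15)
  expect_equal(s$rho["a", "c"], -1)
  expect_equal(s$rho, t(s$rho))
  # oracle: base R cor with spearman on a random matrix with ties
  set.seed(5)
  r <- matrix(sample(0:3, 60, TRUE), nrow = 4)
  expect_equal(spearman_similarity(r)$rho,
               unname(cor(t(r), method = "spearman")),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(spearman_similarity(rbind(c(1, 1, 1), c(1, 2, 3))), "constant")
})

test_that("average-linkage tree matches hand-computed merges on blocks", {
  # two perfectly correlated pairs, cross-pair rho 0
  rho <- diag(4)
  rho[1, 2] <- rho[2, 1] <- 1
  rho[3, 4] <- rho[4, 3] <- 1
  ids <- c("a", "b", "c", "d")
  dimnames(rho) <- list(ids, ids)
  tree <- hierarchical_cluster(list(ids = ids, rho = rho))
  sol <- cut_tree(tree, 2)
  expect_identical(unname(sol$labels[c("a", "b")]),
                   rep(sol$labels[["a"]], 2))
  expect_identical(unname(sol$labels[c("c", "d")]),
                   rep(sol$labels[["c"]], 2))
  expect_false(sol$labels[["a"]] == sol$labels[["c"]])

  # 6 items, 3 planted blocks: heights match hand-computed average linkage
  rho6 <- matrix(0.1, 6, 6)
  for (b in list(1:2, 3:4, 5:6)) rho6[b, b] <- 0.9
  diag(rho6) <- 1
  ids6 <- letters[1:6]
  dimnames(rho6) <- list(ids6, ids6)
  t6 <- hierarchical_cluster(list(ids = ids6, rho = rho6))
  expect_equal(t6$height, c(0.1, 0.1, 0.1, 0.9, 0.9), tolerance = 1e-12)
  s3 <- cut_tree(t6, 3)
  expect_equal(adjusted_rand(s3$labels, rep(1:3, each = 2)), 1)
  # K = e gives singletons
  expect_identical(sort(unname(cut_tree(t6, 6)$labels)), 1:6)
  expect_error(cut_tree(t6, 7), "out of range")
})

test_that("tree agrees with stats::hclust average linkage on random data", {
  set.seed(42)
  m <- matrix(rnorm(12 * 30), nrow = 12,
              dimnames = list(sprintf("e%02d", 1:12), NULL))
  sim <- spearman_similarity(m)
  tree <- hierarchical_cluster(sim)
  ref <- stats::hclust(stats::as.dist(1 - sim$rho), method = "average")
  expect_equal(tree$height, ref$height, tolerance = 1e-12)
  for (K in c(2, 4, 7))
    expect_equal(adjusted_rand(cut_tree(tree, K)$labels,
                               stats::cutree(ref, K)), 1)
})

test_that("clustering is invariant to experiment input order", {
  set.seed(9)
  m <- matrix(rnorm(10 * 40), nrow = 10,
              dimnames = list(sprintf("e%02d", 1:10), NULL))
  perm <- sample(10)
  solA <- cut_tree(hierarchical_cluster(spearman_similarity(m)), 3)
  solB <- cut_tree(hierarchical_cluster(spearman_similarity(m[perm, ])), 3)
  expect_equal(adjusted_rand(solA$labels, solB$labels), 1)
  # similarity itself is invariant to voxel (column) permutation
  sim1 <- spearman_similarity(m)
  sim2 <- spearman_similarity(m[, sample(ncol(m))])
  expect_equal(sim1$rho, sim2$rho, tolerance = 1e-12)
})

test_that("silhouette and CH behave per definitions and conventions", {
  x <- c(0, 0.1, 5, 5.1)
  d <- as.matrix(dist(x))
  lab <- c(1, 1, 2, 2)
  expect_equal(silhouette_index(lab, d), 0.979998, tolerance = 1e-5)
  # singleton silhouette defined as 0
  expect_equal(silhouette_index(c(1, 2, 2), as.matrix(dist(c(0, 5, 5.2)))),
               mean(c(0, (5 - 0.2) / 5, (5.2 - 0.2) / 5.2)), tolerance = 1e-12)
  # identical points in one cluster: degenerate but defined
  expect_true(is.finite(silhouette_index(c(1, 1, 2, 2),
                                         as.matrix(dist(c(1, 1, 1, 1))))))
  set.seed(3)
  feats <- rbind(matrix(rnorm(20, 0), 10), matrix(rnorm(20, 8), 10))
  good <- rep(1:2, each = 10)
  expect_gt(calinski_harabasz(good, feats),
            calinski_harabasz(sample(good), feats))
})

test_that("aRI and VI match closed forms and are mutually consistent", {
  expect_equal(adjusted_rand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(variation_of_information(c(1, 1, 2, 2), c(2, 2, 1, 1)), 0)
  # {AB|CD} vs {AC|BD}: VI = 2 ln 2, aRI = -0.5 by the contingency formula
  a <- c(1, 1, 2, 2); b <- c(1, 2, 1, 2)
  expect_equal(variation_of_information(a, b), 2 * log(2), tolerance = 1e-12)
  expect_equal(adjusted_rand(a, b), -0.5, tolerance = 1e-12)
  expect_error(adjusted_rand(setNames(a, letters[1:4]),
                             setNames(b, letters[5:8])), "item")
  # property: VI == 0 iff aRI == 1, over random partitions
  set.seed(21)
  for (i in 1:20) {
    p1 <- sample(1:3, 8, TRUE)
    p2 <- if (i %% 2) p1[c(2, 1, 3:8)] else sample(1:3, 8, TRUE)
    vi0 <- variation_of_information(p1, p2) < 1e-12
    ari1 <- abs(adjusted_rand(p1, p2) - 1) < 1e-12
    expect_identical(vi0, ari1)
  }
})

test_that("subsample stability is reproducible and degenerate-safe", {
  set.seed(14)
  m <- rbind(matrix(rnorm(5 * 30, 0), 5), matrix(rnorm(5 * 30, 3), 5),
             matrix(rnorm(5 * 30, -3), 5))
  rownames(m) <- sprintf("e%02d", 1:15)
  # fraction = 1: identical metrics across iterations, aRI vs full = 1
  r1 <- subsample_stability(m, K_range = 2:4, fraction = 1, n_iter = 3,
                            seed = 1)
  expect_equal(r1$ari_subsample, rep(1, 3))
  r2 <- subsample_stability(m, K_range = 2:4, fraction = 1, n_iter = 1,
                            seed = 99)
  expect_equal(r1$silhouette, r2$silhouette)
  # seed-fixed bit-identical rerun
  a <- subsample_stability(m, K_range = 2:5, fraction = 0.8, n_iter = 10,
                           seed = 7)
  b <- subsample_stability(m, K_range = 2:5, fraction = 0.8, n_iter = 10,
                           seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("planted 3-block structure is most stable at K = 3", {
  set.seed(31)
  # groups differ in WHICH columns are elevated (rank-visible structure)
  m <- matrix(rnorm(24 * 60), nrow = 24)
  for (b in 1:3)
    m[(b - 1) * 8 + 1:8, (b - 1) * 20 + 1:20] <-
      m[(b - 1) * 8 + 1:8, (b - 1) * 20 + 1:20] + 4
  rownames(m) <- sprintf("e%02d", 1:24)
  rep <- subsample_stability(m, K_range = 2:6, fraction = 0.9, n_iter = 50,
                             seed = 2)
  expect_gt(rep$ari_subsample[rep$K == 3], rep$ari_subsample[rep$K == 5])
  expect_equal(rep$K[which.max(rep$silhouette)], 3)
})

test_that("select_k applies the majority rule with CH monotonicity guard", {
  rep_all4 <- data.frame(K = 2:6, silhouette = c(1, 2, 5, 3, 1) / 10,
                         ch = c(5, 8, 9, 7, 6),
                         ari_subsample = c(0.2, 0.4, 0.9, 0.5, 0.3),
                         vi_subsample = 0,
                         ari_consecutive = NA,
                         vi_consecutive = c(NA, 2, 0.1, 1, 2))
  expect_equal(as.integer(select_k(rep_all4)), 4L)

  # reference scenario: silhouette peak 8, aRI tied peaks {3, 8} (argmax
  # tie resolves to 3), VI change smallest at 8, CH monotone (excluded)
  K <- 2:15
  repc <- data.frame(
    K = K,
    silhouette = ifelse(K == 8, 0.5, 0.2),
    ch = as.numeric(K),                       # monotone -> excluded
    ari_subsample = ifelse(K %in% c(3, 8), 0.9, 0.4),
    vi_subsample = 0.5,
    ari_consecutive = NA,
    vi_consecutive = c(NA, ifelse(K[-1] == 8, 0.01, 0.6)))
  expect_message(k <- select_k(repc), "monotone")
  expect_equal(as.integer(k), 8L)
  votes <- attr(k, "votes")
  expect_false("ch" %in% names(votes))

  expect_equal(as.integer(select_k(repc, override = 5)), 5L)
  expect_error(select_k(repc[0, ]), "empty")
})

test_that("small groups are pruned by the outlier rule", {
  sizes <- c(21, 87, 13, 12, 8, 3, 2, 1)
  labels <- setNames(rep(seq_along(sizes), sizes),
                     sprintf("e%03d", seq_len(sum(sizes))))
  ms <- prune_small_groups(labels, min_size = 10)
  expect_length(ms$retained, 4)
  expect_length(ms$excluded, 4)
  expect_identical(sum(lengths(ms$retained)), 133L)
  expect_equal(ms$retained_fraction, 133 / 147, tolerance = 1e-12)
  expect_identical(unname(sort(lengths(ms$retained), decreasing = TRUE)),
                   c(87L, 21L, 13L, 12L))
  # min_size 1: nothing pruned
  expect_length(prune_small_groups(labels, 1)$excluded, 0)
  expect_error(prune_small_groups(setNames(rep(1:2, each = 5),
                                           letters[1:10]), 10),
               "nothing retained")
})

test_that("planted 3-group corpora are recovered at K = 3 (aRI >= 0.9)", {
  g <- recovery_grid()
  hits <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    syn <- generate_corpus(recovery_spec(seed = 100 + i), g)
    m <- ma_matrix(syn$corpus, g)
    sol <- cut_tree(hierarchical_cluster(spearman_similarity(m)), 3)
    if (adjusted_rand(sol$labels, syn$true_labels) >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
})
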