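make_const_map <- function(grid, value) voxel_map(grid, rep(value, grid$n_mask_voxels))

test_that("ALE union follows the closed form", {
  g <- cube_grid(5)
  one <- make_const_map(g, 0.3)
  expect_equal(ale_union(list(one))$ale$values, one$values)
  two <- ale_union(list(make_const_map(g, 0.5), make_const_map(g, 0.5)))
  expect_equal(unique(two$ale$values), 0.75)
  ten <- ale_union(rep(list(make_const_map(g, 0.1)), 10))
  expect_equal(unique(ten$ale$values), 1 - 0.9^10, tolerance = 1e-12)
  expect_error(ale_union(list(make_const_map(g, 0.1),
                              make_const_map(cube_grid(6), 0.1))),
               "different grids")
})

test_that("union bound and monotonicity hold on random MA stacks", {
  g <- cube_grid(4)
  set.seed(8)
  maps <- lapply(1:5, function(i) voxel_map(g, runif(g$n_mask_voxels, 0, 0.3)))
  ale5 <- ale_union(maps)$ale$values
  for (m in maps) expect_true(all(ale5 >= m$values - 1e-15))
  expect_true(all(ale5 <= Reduce(`+`, lapply(maps, `[[`, "values")) + 1e-15))
  ale4 <- ale_union(maps[1:4])$ale$values
  expect_true(all(ale5 >= ale4 - 1e-15))     # adding an experiment never lowers
})

test_that("analytic voxel p equals exhaustive enumeration on a tiny mask", {
  g <- cube_grid(7)                           # 343 voxels <= 1000
  expect_lte(g$n_mask_voxels, 1000L)
  exps <- list(
    experiment_record("s", "a", rbind(c(0, 0, 0), c(4, 2, 0)), n_cases = 12),
    experiment_record("s", "b", c(-2, 2, 2), n_cases = 25))
  ma_maps <- lapply(exps, build_ma_map, grid = g)
  ale <- ale_union(ma_maps)
  vp <- suppressWarnings(voxel_pvalues(ale, ma_maps, method = "histogram"))
  expect_false(vp$null$binned)                # tiny support stayed exact

  # oracle: the per-experiment relocation null is each experiment's
  # empirical MA distribution over the mask; enumerate the joint tail by
  # exact convolution of tabulated values, independent of the package's
  # sparse-union implementation
  enum_tail <- function(obs) {
    dists <- lapply(ma_maps, function(m) {
      tab <- table(m$voxmap$values)
      list(v = as.numeric(names(tab)), p = as.numeric(tab) / sum(tab))
    })
    grids <- expand.grid(i = seq_along(dists[[1]]$v),
                         j = seq_along(dists[[2]]$v))
    u <- 1 - (1 - dists[[1]]$v[grids$i]) * (1 - dists[[2]]$v[grids$j])
    pr <- dists[[1]]$p[grids$i] * dists[[2]]$p[grids$j]
    sum(pr[u >= obs - 1e-12])
  }
  probes <- c(which.max(ale$ale$values), 1L, 57L, 200L)
  for (pos in probes)
    expect_equal(vp$p$values[pos], enum_tail(ale$ale$values[pos]),
                 tolerance = 1e-10)
  # a voxel where every MA is 0 has p = 1
  zero_pos <- which(ma_maps[[1]]$voxmap$values == 0 &
                      ma_maps[[2]]$voxmap$values == 0)[1]
  if (!is.na(zero_pos)) expect_equal(vp$p$values[zero_pos], 1)
})

test_that("histogram and permutation voxel nulls agree within MC error", {
  g <- small_ellipsoid()
  syn <- generate_corpus(recovery_spec(seed = 55), g)
  exps <- syn$corpus$experiments[1:6]
  ma_maps <- lapply(exps, build_ma_map, grid = g)
  ale <- ale_union(ma_maps)
  hp <- voxel_pvalues(ale, ma_maps, method = "histogram")
  n_perm <- 400
  pp <- voxel_pvalues(ale, ma_maps, method = "permutation",
                      n_permutations = n_perm, seed = 3, experiments = exps)
  # agreement is asserted in the tail region where the cluster-forming
  # threshold operates; in the mid-range the two pooled nulls deviate
  # because the mask is spatially heterogeneous (documented property)
  set.seed(77)
  tail_region <- which(hp$p$values < 0.05 & ale$ale$values > 0)
  probes <- sample(tail_region, 20)
  for (pos in probes) {
    p1 <- hp$p$values[pos]
    p2 <- pp$p$values[pos]
    se <- sqrt(max(p1 * (1 - p1), 1 / n_perm) / n_perm)
    expect_lt(abs(p1 - p2), 3 * se + 2 / n_perm)
  }
})

test_that("permute_foci preserves structure and redraws uniformly", {
  g <- cube_grid(5)                           # 125 voxels
  corp <- corpus(list(
    experiment_record("s", "a", matrix(rnorm(21), ncol = 3), 15),
    experiment_record("s", "b", matrix(rnorm(9), ncol = 3), 22)))
  p1 <- permute_foci(corp, g, seed = 4)
  expect_identical(vapply(p1$experiments, function(e) nrow(e$foci), 0L),
                   c(a = 7L, b = 3L))
  expect_identical(p1$experiments[["a"]]$n_cases, 15L)
  mpos <- mask_positions(g)
  for (e in p1$experiments) {
    vox <- world_to_voxel(g, e$foci)
    expect_true(all(in_volume(g, vox)))
    expect_true(all(mpos[ijk_to_lin(g, vox)] > 0))
  }
  expect_identical(permute_foci(corp, g, seed = 4)$experiments[["a"]]$foci,
                   p1$experiments[["a"]]$foci)

  # uniformity: 10,000 redrawn foci, chi-square GOF p > 0.001
  big <- corpus(list(experiment_record("s", "big",
                                       matrix(0, nrow = 10000, ncol = 3), 10)))
  drawn <- permute_foci(big, g, seed = 9)$experiments[["big"]]$foci
  counts <- tabulate(mpos[ijk_to_lin(g, world_to_voxel(g, drawn))],
                     g$n_mask_voxels)
  gof <- chisq.test(counts)
  expect_gt(gof$p.value, 0.001)
})

test_that("cluster extraction respects threshold and connectivity", {
  g <- cube_grid(9)
  p <- rep(1, g$n_mask_voxels)
  expect_length(cluster_extract(voxel_map(g, p)), 0)

  # single 3x3x3 block
  vol <- array(1, g$shape)
  vol[3:5, 3:5, 3:5] <- 0
  p1 <- voxel_map(g, vol[g$mask_lin])
  cl <- cluster_extract(p1, alpha_voxel = 0.001)
  expect_length(cl, 1)
  expect_identical(cl[[1]]$size_voxels, 27L)
  expect_equal(cl[[1]]$size_mm3, 216)

  # two 2x2x2 blocks touching only at a corner
  vol2 <- array(1, g$shape)
  vol2[1:2, 1:2, 1:2] <- 0
  vol2[3:4, 3:4, 3:4] <- 0
  p2 <- voxel_map(g, vol2[g$mask_lin])
  expect_length(cluster_extract(p2, connectivity = 26), 1)
  expect_length(cluster_extract(p2, connectivity = 6), 2)
})

test_that("cluster-level FWE retains by the null quantile rule", {
  nm <- structure(list(max_cluster_size_null = c(rep(5L, 220), rep(40L, 30)),
                       n_permutations = 250L, cutoff = 0.1,
                       connectivity = 26L, seed = 1), class = "null_model")
  small <- list(cluster_id = 1L, mask_positions = 1:3, size_voxels = 3L,
                size_mm3 = 24)
  big <- list(cluster_id = 2L, mask_positions = 1:100, size_voxels = 100L,
              size_mm3 = 800)
  kept <- cluster_fwe(list(small, big), nm, alpha_cluster = 0.05)
  expect_length(kept, 1)
  expect_identical(kept[[1]]$size_voxels, 100L)
  expect_equal(kept[[1]]$p_fwe, 1 / 251)
  nm_small <- nm; nm_small$max_cluster_size_null <- rep(1L, 50)
  expect_warning(cluster_fwe(list(big), nm_small), "100 permutations")
})

test_that("peak table orders clusters and resolves ties deterministically", {
  g <- cube_grid(7)
  vals <- rep(0, g$n_mask_voxels)
  mpos <- mask_positions(g)
  at <- function(xyz) mpos[ijk_to_lin(g, world_to_voxel(g, xyz))]
  b1 <- c(at(c(0, 0, 0)), at(c(2, 0, 0)), at(c(0, 2, 0)))
  b2 <- c(at(c(-4, -4, -4)), at(c(-4, -4, -2)))
  vals[b1] <- c(0.5, 0.5, 0.2)                # tied peak within cluster 1
  vals[b2] <- c(0.4, 0.3)
  ale <- structure(list(grid = g, ale = voxel_map(g, vals),
                        experiment_ids = "x"), class = "ale_map")
  recs <- list(list(cluster_id = 1L, mask_positions = b1, size_voxels = 3L,
                    size_mm3 = 24, p_fwe = 0.01),
               list(cluster_id = 2L, mask_positions = b2, size_voxels = 2L,
                    size_mm3 = 16, p_fwe = 0.02))
  tab <- peak_table(recs, ale)
  expect_identical(tab$cluster, 1:2)
  expect_true(all(diff(tab$size_mm3) <= 0))
  expect_equal(tab$peak_ale[1], 0.5)
  expect_equal(unlist(tab[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
  expect_equal(peak_table(list(), ale)$cluster, integer(0))
})

test_that("ale_analysis is seed-deterministic end to end", {
  g <- small_ellipsoid()
  syn <- generate_corpus(recovery_spec(seed = 12), g)
  exps <- syn$corpus$experiments[1:8]
  r1 <- ale_analysis(exps, g, n_permutations = 120, seed = 5)
  r2 <- ale_analysis(exps, g, n_permutations = 120, seed = 5)
  expect_identical(r1$peaks, r2$peaks)
  expect_identical(r1$null_model$max_cluster_size_null,
                   r2$null_model$max_cluster_size_null)
  # ALE map dominates every contributing MA map
  ma <- ma_matrix(corpus(exps), g)
  expect_true(all(r1$ale$ale$values >= apply(ma, 2, max) - 1e-12))
})
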