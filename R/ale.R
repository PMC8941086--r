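# ALE meta-analysis within a group of experiments.
#
# The ALE score at a voxel is the union 1 - prod(1 - MA_i) of the
# experiments' modeled-activation values: the probability that at least one
# experiment truly activates there, under independence.  Voxel-level p comes
# either from an analytic null (union convolution of the per-experiment MA
# histograms under spatial independence) or from foci-shuffling
# permutations; cluster-level FWE is always permutation-based via the
# max-cluster-size null.

same_grid <- function(a, b) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) < 1e-8
}

ma_values_list <- function(ma_maps) {
  lapply(ma_maps, function(m) {
    if (inherits(m, "ma_map")) m$voxmap$values
    else if (inherits(m, "voxel_map")) m$values
    else as.double(m)
  })
}

#' Voxel-wise ALE union of MA maps
#'
#' @param ma_maps list of `ma_map`s (or `voxel_map`s) on a shared grid.
#' @return an `ale_map`: list with `grid`, `ale` ([voxel_map()]) and
#'   `experiment_ids`.
#' @export
ale_union <- function(ma_maps) {
  if (length(ma_maps) < 1L) stop("need >= 1 MA map")
  grids <- lapply(ma_maps, function(m)
    if (inherits(m, "ma_map")) m$voxmap$grid else m$grid)
  grid <- grids[[1]]
  for (g in grids[-1])
    if (!same_grid(grid, g)) stop("MA maps are on different grids")
  vals <- ma_values_list(ma_maps)
  one_minus <- rep(1, grid$n_mask_voxels)
  for (v in vals) one_minus <- one_minus * (1 - v)
  ids <- vapply(ma_maps, function(m)
    if (inherits(m, "ma_map")) m$experiment_id else NA_character_, "")
  structure(list(grid = grid, ale = voxel_map(grid, 1 - one_minus),
                 experiment_ids = ids),
            class = "ale_map")
}

# ---- analytic (histogram) voxel null --------------------------------------

# Sparse null distribution over ALE values: exact (value, prob) support as
# long as it stays below `exact_cap`, after which the support is collapsed
# to bins of width `bin_width` (left-edge representative values).  On tiny
# problems this is exact, which the enumeration oracle tests rely on.
union_null_distribution <- function(ma_values, bin_width = 1e-5,
                                    exact_cap = 131072) {
  agg <- function(v, p) {
    o <- order(v)
    v <- v[o]; p <- p[o]
    grp <- cumsum(c(TRUE, diff(v) > 1e-15))
    list(v = v[!duplicated(grp)], p = as.vector(rowsum(p, grp)))
  }
  collapse <- function(v, p) {
    idx <- floor(v / bin_width + 1e-9)
    agg(idx * bin_width, p)
  }
  null <- list(v = 0, p = 1)
  binned <- FALSE
  for (x in ma_values) {
    if (length(x) > 4096) {
      # dense-bin the experiment histogram in O(V): equal-mass voxels
      idx <- as.integer(floor(x / bin_width + 1e-9))
      cnt <- tabulate(idx + 1L)
      occ <- which(cnt > 0)
      ex <- list(v = (occ - 1) * bin_width, p = cnt[occ] / length(x))
      binned <- TRUE
    } else {
      ex <- agg(x, rep(1 / length(x), length(x)))
    }
    if (!binned && length(null$v) * length(ex$v) <= 4e6) {
      u <- outer(null$v, ex$v, function(a, b) a + b - a * b)
      pr <- outer(null$p, ex$p)
      cand <- agg(as.vector(u), as.vector(pr))
      if (length(cand$v) > exact_cap) {
        cand <- collapse(cand$v, cand$p)
        binned <- TRUE
      }
      null <- cand
    } else {
      binned <- TRUE
      null <- cpp_union_convolve(null$v, null$p, ex$v, ex$p, bin_width)
    }
  }
  structure(list(values = null$v, probs = null$p, binned = binned,
                 bin_width = bin_width), class = "ale_null_dist")
}

# right-tail P(null >= obs); when the null support is binned the observed
# values are quantized identically so tails are compared in bin space
null_tail_p <- function(null, obs) {
  tail_from <- rev(cumsum(rev(null$probs)))
  if (null$binned) obs <- floor(obs / null$bin_width + 1e-9) * null$bin_width
  idx <- findInterval(obs - 1e-12, null$values) + 1L
  p <- rep(0, length(obs))
  inside <- idx <= length(null$values)
  p[inside] <- tail_from[idx[inside]]
  pmin(pmax(p, 0), 1)
}

# smallest ALE value whose right-tail null probability is < alpha
ale_cutoff <- function(null, alpha) {
  tail_from <- rev(cumsum(rev(null$probs)))
  i <- which(tail_from < alpha)
  if (!length(i)) return(Inf)
  null$values[min(i)]
}

#' Voxel-wise p-values for an ALE map
#'
#' `method = "histogram"`: analytic null from the union convolution of the
#' per-experiment MA-value histograms under spatial independence (fast,
#' deterministic).  `method = "permutation"`: empirical null pooled over
#' in-mask ALE values of foci-shuffled pseudo-datasets.  Both are right-tail
#' `P(null ALE >= observed)`.
#'
#' @param ale an [ale_union()] result.
#' @param ma_maps the contributing MA maps (histogram method).
#' @param method `"histogram"` or `"permutation"`.
#' @param n_permutations,seed permutation settings (permutation method).
#' @param experiments list of [experiment_record()]s matching `ma_maps`
#'   (needed to rebuild kernels for the permutation method).
#' @param spec [kernel_spec()] used to build the MA maps.
#' @param bin_width histogram resolution on the ALE axis (default 1e-5).
#' @return list with `p` (a [voxel_map()]) and `null` (the null object).
#' @export
voxel_pvalues <- function(ale, ma_maps, method = c("histogram", "permutation"),
                          n_permutations = 1000, seed = 1,
                          experiments = NULL, spec = kernel_spec(),
                          bin_width = 1e-5) {
  method <- match.arg(method)
  grid <- ale$grid
  if (method == "histogram") {
    if (length(ma_maps) < 2L)
      warning("analytic voxel null from fewer than 2 experiments is degenerate")
    null <- union_null_distribution(ma_values_list(ma_maps),
                                    bin_width = bin_width)
    p <- null_tail_p(null, ale$ale$values)
  } else {
    if (is.null(experiments))
      stop("permutation method needs the experiment records")
    prep <- permutation_inputs(experiments, grid, spec)
    nbins <- as.integer(ceiling(1 / bin_width))
    set.seed(seed)
    res <- cpp_ale_permutation(as.integer(n_permutations), prep$n_foci,
                               prep$kern_off, prep$kern_val, grid$shape,
                               mask_positions(grid),
                               as.integer(grid$mask_lin - 1L),
                               2.0, 26L, nbins, bin_width)
    counts <- res$hist
    probs <- counts / sum(counts)
    keep <- probs > 0
    null <- structure(list(values = (which(keep) - 1L) * bin_width,
                           probs = probs[keep], binned = TRUE,
                           bin_width = bin_width), class = "ale_null_dist")
    p <- null_tail_p(null, ale$ale$values)
  }
  list(p = voxel_map(grid, p), null = null)
}

# kernels + focus counts for the C++ permutation loop
permutation_inputs <- function(experiments, grid, spec) {
  kern_cache <- new.env(parent = emptyenv())
  kern_off <- vector("list", length(experiments))
  kern_val <- vector("list", length(experiments))
  n_foci <- integer(length(experiments))
  for (i in seq_along(experiments)) {
    e <- experiments[[i]]
    n <- if (spec$sample_size == "cases") e$n_cases
         else e$n_cases + e$n_controls
    key <- as.character(n)
    if (is.null(kern_cache[[key]]))
      kern_cache[[key]] <- build_kernel(kernel_fwhm(n, spec), grid, spec)
    kern_off[[i]] <- kern_cache[[key]]$offsets
    kern_val[[i]] <- kern_cache[[key]]$values
    n_foci[i] <- nrow(e$foci)
  }
  list(kern_off = kern_off, kern_val = kern_val, n_foci = n_foci)
}

#' Shuffle foci across experiments (permutation pseudo-corpus)
#'
#' Each experiment keeps its focus count (and hence its kernel width via its
#' unchanged metadata); focus locations are redrawn uniformly from in-mask
#' voxel centres.
#'
#' @param corp a `corpus`.
#' @param grid a [brain_grid()].
#' @param seed RNG seed.
#' @return a pseudo-`corpus`.
#' @export
permute_foci <- function(corp, grid, seed = 1) {
  set.seed(seed)
  centres <- voxel_to_world(grid, which(grid$mask, arr.ind = TRUE) - 1L)
  recs <- lapply(corp$experiments, function(e) {
    k <- nrow(e$foci)
    e$foci <- centres[sample.int(nrow(centres), k, replace = TRUE), ,
                      drop = FALSE]
    e
  })
  corpus(recs, provenance = paste0(corp$provenance, "; permuted seed=", seed))
}

#' Max-cluster-size permutation null
#'
#' Builds the null distribution of the maximum suprathreshold cluster size
#' over foci-shuffled pseudo-datasets, thresholded at the same ALE cutoff as
#' the observed analysis.
#'
#' @param experiments list of [experiment_record()]s.
#' @param grid a [brain_grid()].
#' @param spec a [kernel_spec()].
#' @param cutoff ALE cluster-forming cutoff (from the observed voxel null at
#'   `alpha_voxel`).
#' @param n_permutations number of pseudo-datasets (reference setting 5000).
#' @param connectivity 6, 18 or 26 (default).
#' @param seed RNG seed.
#' @return a `null_model`: list with `max_cluster_size_null`,
#'   `n_permutations`, `cutoff`, `connectivity`, `seed`.
#' @export
cluster_size_null <- function(experiments, grid, spec, cutoff,
                              n_permutations = 5000, connectivity = 26,
                              seed = 1) {
  stopifnot(connectivity %in% c(6, 18, 26))
  prep <- permutation_inputs(experiments, grid, spec)
  set.seed(seed)
  res <- cpp_ale_permutation(as.integer(n_permutations), prep$n_foci,
                             prep$kern_off, prep$kern_val, grid$shape,
                             mask_positions(grid),
                             as.integer(grid$mask_lin - 1L),
                             cutoff, as.integer(connectivity), 0L, 1e-5)
  structure(list(max_cluster_size_null = as.integer(res$max_size),
                 n_permutations = as.integer(n_permutations),
                 cutoff = cutoff, connectivity = as.integer(connectivity),
                 seed = seed),
            class = "null_model")
}

#' Extract suprathreshold candidate clusters
#'
#' Connected components of `{p < alpha_voxel}` under the configured voxel
#' connectivity.
#'
#' @param p_map a [voxel_map()] of voxel-wise p-values.
#' @param alpha_voxel cluster-forming threshold (default 0.001).
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners, default).
#' @return list of candidate clusters, each with `cluster_id`,
#'   `mask_positions`, `size_voxels`, `size_mm3`; may be empty.
#' @export
cluster_extract <- function(p_map, alpha_voxel = 0.001, connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  grid <- p_map$grid
  supra_pos <- which(p_map$values < alpha_voxel)
  if (!length(supra_pos)) return(list())
  lin0 <- as.integer(grid$mask_lin[supra_pos] - 1L)
  labels <- cpp_label_components(lin0, grid$shape, as.integer(connectivity))
  out <- lapply(sort(unique(labels)), function(l) {
    pos <- supra_pos[labels == l]
    list(cluster_id = l, mask_positions = pos,
         size_voxels = length(pos),
         size_mm3 = length(pos) * grid$voxel_volume_mm3)
  })
  # stable ids ordered by size, largest first
  out <- out[order(-vapply(out, `[[`, 0L, "size_voxels"))]
  for (i in seq_along(out)) out[[i]]$cluster_id <- i
  out
}

#' Cluster-level family-wise error filtering
#'
#' A candidate is retained iff its size exceeds the `(1 - alpha_cluster)`
#' empirical quantile of the max-cluster-size null; its p-value uses the
#' add-one permutation convention `(1 + #{null >= size}) / (1 + n_perm)`.
#'
#' @param candidates output of [cluster_extract()].
#' @param null_model a [cluster_size_null()] result.
#' @param alpha_cluster cluster-level FWE threshold (default 0.05).
#' @return list of significant cluster records (possibly empty), each
#'   augmented with `p_fwe`.
#' @export
cluster_fwe <- function(candidates, null_model, alpha_cluster = 0.05) {
  nulls <- null_model$max_cluster_size_null
  if (length(nulls) < 100)
    warning("fewer than 100 permutations: unstable cluster-size quantile")
  q <- quantile(nulls, 1 - alpha_cluster, type = 1, names = FALSE)
  keep <- list()
  for (cand in candidates) {
    p <- (1 + sum(nulls >= cand$size_voxels)) / (1 + length(nulls))
    if (cand$size_voxels > q) {
      cand$p_fwe <- p
      keep[[length(keep) + 1L]] <- cand
    }
  }
  keep
}

#' Peak table of significant clusters
#'
#' One row per cluster: size (mm3), peak MNI coordinate (in-cluster voxel
#' with maximal ALE; ties resolve to the smallest x, then y, then z) and the
#' peak ALE value, ordered by size descending.
#'
#' @param records significant clusters from [cluster_fwe()].
#' @param ale an [ale_union()] result on the same grid.
#' @return data.frame with columns `cluster`, `size_mm3`, `size_voxels`,
#'   `x`, `y`, `z`, `peak_ale`, `p_fwe`.
#' @export
peak_table <- function(records, ale) {
  grid <- ale$grid
  if (!length(records))
    return(data.frame(cluster = integer(), size_mm3 = numeric(),
                      size_voxels = integer(), x = numeric(), y = numeric(),
                      z = numeric(), peak_ale = numeric(), p_fwe = numeric()))
  rows <- lapply(records, function(r) {
    pos <- r$mask_positions
    vals <- ale$ale$values[pos]
    best <- pos[vals == max(vals)]
    ijk <- arrayInd(grid$mask_lin[best], grid$shape)
    # smallest-coordinate tie-break in world space
    w <- voxel_to_world(grid, ijk - 1L)
    w <- w[order(w[, 1], w[, 2], w[, 3]), , drop = FALSE]
    data.frame(cluster = r$cluster_id, size_mm3 = r$size_mm3,
               size_voxels = r$size_voxels,
               x = w[1, 1], y = w[1, 2], z = w[1, 3],
               peak_ale = max(vals),
               p_fwe = if (is.null(r$p_fwe)) NA_real_ else r$p_fwe)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$size_mm3), , drop = FALSE]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Full ALE analysis of one experiment group
#'
#' Convenience wrapper running the whole chain: MA maps, ALE union, voxel
#' null and p-values, candidate clusters, permutation max-cluster-size null
#' and cluster-level FWE filtering.
#'
#' @param experiments list of [experiment_record()]s (one MAG).
#' @param grid a [brain_grid()].
#' @param spec a [kernel_spec()].
#' @param alpha_voxel cluster-forming threshold (default 0.001).
#' @param alpha_cluster cluster-level FWE threshold (default 0.05).
#' @param n_permutations permutations for the cluster-size null (default
#'   5000, the reference setting).
#' @param connectivity 6, 18 or 26 (default).
#' @param voxel_null `"histogram"` (analytic, default) or `"permutation"`.
#' @param seed RNG seed for the permutation stages.
#' @return an `ale_result`: list with `ale`, `p`, `null`, `candidates`,
#'   `significant`, `peaks`, `null_model` and the settings.
#' @export
ale_analysis <- function(experiments, grid, spec = kernel_spec(),
                         alpha_voxel = 0.001, alpha_cluster = 0.05,
                         n_permutations = 5000, connectivity = 26,
                         voxel_null = c("histogram", "permutation"),
                         seed = 1) {
  voxel_null <- match.arg(voxel_null)
  if (inherits(experiments, "corpus")) experiments <- experiments$experiments
  ma_maps <- lapply(experiments, build_ma_map, grid = grid, spec = spec)
  ale <- ale_union(ma_maps)
  vp <- voxel_pvalues(ale, ma_maps, method = voxel_null,
                      n_permutations = n_permutations, seed = seed + 1L,
                      experiments = experiments, spec = spec)
  cutoff <- ale_cutoff(vp$null, alpha_voxel)
  candidates <- cluster_extract(vp$p, alpha_voxel, connectivity)
  nm <- cluster_size_null(experiments, grid, spec, cutoff,
                          n_permutations = n_permutations,
                          connectivity = connectivity, seed = seed)
  significant <- cluster_fwe(candidates, nm, alpha_cluster)
  structure(list(ale = ale, p = vp$p, null = vp$null,
                 candidates = candidates, significant = significant,
                 peaks = peak_table(significant, ale), null_model = nm,
                 settings = list(alpha_voxel = alpha_voxel,
                                 alpha_cluster = alpha_cluster,
                                 n_permutations = n_permutations,
                                 connectivity = connectivity,
                                 voxel_null = voxel_null, seed = seed)),
            class = "ale_result")
}

#' @export
print.ale_result <- function(x, ...) {
  cat("ale_result:", length(x$ale$experiment_ids), "experiments,",
      length(x$candidates), "candidate cluster(s),",
      length(x$significant), "significant at pFWE <",
      x$settings$alpha_cluster, "\n")
  invisible(x)
}
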