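# Correlation-matrix-based hierarchical clustering (CMHC) of MA maps.
#
# Experiments are compared by Spearman rank correlation of their flattened
# MA maps; agglomerative clustering uses correlation distance (1 - rho) with
# average linkage.  K is selected over a range (default 2-15) by a majority
# vote of silhouette, adjusted Rand index and variation-of-information
# criteria computed under 90%-subsample resampling; groups smaller than 10
# experiments are excluded as outliers before meta-analysis.

#' Spearman similarity matrix between MA maps
#'
#' Pairwise Spearman rank correlation (average ranks for ties -- the mass of
#' zero voxels outside all kernels produces heavy ties) between the rows of
#' the experiment-by-voxel MA matrix.
#'
#' @param ma_mat experiment x voxel matrix (>= 2 rows, rownames = IDs).
#' @return a `similarity_matrix`: list with `ids` and `rho` (symmetric,
#'   unit diagonal).
#' @export
spearman_similarity <- function(ma_mat) {
  if (nrow(ma_mat) < 2L) stop("need >= 2 experiments")
  constant <- which(apply(ma_mat, 1, function(r) diff(range(r)) == 0))
  if (length(constant))
    stop("constant MA row(s), Spearman undefined: ",
         paste(rownames(ma_mat)[constant], collapse = ", "))
  ranks <- t(apply(ma_mat, 1, rank))          # average ranks for ties
  ranks <- ranks - rowMeans(ranks)
  norms <- sqrt(rowSums(ranks^2))
  rho <- tcrossprod(ranks / norms)
  rho <- (rho + t(rho)) / 2                   # enforce exact symmetry
  rho[rho > 1] <- 1
  rho[rho < -1] <- -1
  diag(rho) <- 1
  ids <- rownames(ma_mat)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(ma_mat)))
  dimnames(rho) <- list(ids, ids)
  structure(list(ids = ids, rho = rho), class = "similarity_matrix")
}

#' Average-linkage hierarchical clustering on correlation distance
#'
#' Agglomerates on `d = 1 - rho` with average (UPGMA) linkage.  Ties in the
#' merge distance (within 1e-12) are broken deterministically: each cluster
#' is keyed by the lexicographically smallest experiment ID among its
#' members, and the candidate pair with the smallest `(min key, max key)` is
#' merged.  The result is an `hclust`-compatible tree.
#'
#' @param similarity a [spearman_similarity()] result (or any object with
#'   `ids` and a symmetric `rho`).
#' @return an object of classes `mag_tree` and `hclust`.
#' @export
hierarchical_cluster <- function(similarity) {
  rho <- similarity$rho
  ids <- similarity$ids
  e <- length(ids)
  if (e < 2L) stop("need >= 2 experiments to cluster")
  d <- 1 - rho
  diag(d) <- Inf
  key <- ids                                   # per-cluster lexicographic key
  code <- -seq_len(e)                          # hclust codes: -i singleton
  size <- rep(1L, e)
  active <- rep(TRUE, e)
  merge <- matrix(0L, e - 1L, 2L)
  height <- numeric(e - 1L)

  for (step in seq_len(e - 1L)) {
    dmin <- min(d[active, active])
    cand <- which(d <= dmin + 1e-12 & outer(active, active, `&`),
                  arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    k1 <- pmin(key[cand[, 1]], key[cand[, 2]])
    k2 <- pmax(key[cand[, 1]], key[cand[, 2]])
    pick <- order(k1, k2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    height[step] <- d[i, j]
    merge[step, ] <- sort(c(code[i], code[j]))
    # average-linkage update into slot i
    others <- which(active & seq_len(e) != i & seq_len(e) != j)
    if (length(others)) {
      dn <- (size[i] * d[i, others] + size[j] * d[j, others]) /
        (size[i] + size[j])
      d[i, others] <- dn
      d[others, i] <- dn
    }
    size[i] <- size[i] + size[j]
    key[i] <- min(key[i], key[j])
    code[i] <- step
    active[j] <- FALSE
    d[j, ] <- Inf
    d[, j] <- Inf
  }
  height <- cummax(height)                     # guard FP monotonicity
  tree <- structure(list(merge = merge, height = height,
                         order = tree_order(merge), labels = ids,
                         method = "average",
                         dist.method = "1 - spearman rho",
                         call = match.call()),
                    class = c("mag_tree", "hclust"))
  tree
}

# leaf order for plotting, by recursive traversal of the merge table
tree_order <- function(merge) {
  n <- nrow(merge) + 1L
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Cut the tree into K groups
#'
#' @param tree a [hierarchical_cluster()] result.
#' @param K number of groups, `2 <= K <= e` (K = e gives singletons).
#' @return a `cluster_solution`: list with `K`, `labels` (named integer
#'   vector) and the `tree`.
#' @export
cut_tree <- function(tree, K) {
  e <- length(tree$labels)
  if (K < 1L || K > e) stop("K out of range [1, ", e, "]: ", K)
  labels <- stats::cutree(tree, k = K)
  structure(list(K = as.integer(K), labels = labels, tree = tree),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("cluster_solution: K =", x$K, "| sizes:",
      paste(sort(tabulate(x$labels), decreasing = TRUE), collapse = ", "),
      "\n")
  invisible(x)
}

#' Subsample stability analysis over a range of K
#'
#' For `n_iter` without-replacement subsamples of fraction `fraction`, the
#' subsample is re-clustered and, at each K: mean silhouette (on the 1 - rho
#' distance), Calinski-Harabasz (on the MA feature rows), and the adjusted
#' Rand index / variation of information between the subsample solution and
#' the full-data solution restricted to the subsample.  Consecutive-K aRI /
#' VI between full-data solutions are reported alongside (computed once on
#' the full data).
#'
#' @param ma_mat experiment x voxel MA matrix.
#' @param K_range integers, default `2:15`.
#' @param fraction subsample fraction in (0, 1], default 0.9.
#' @param n_iter number of subsample iterations (the reference analysis used
#'   5000; tests use far fewer).
#' @param seed RNG seed for reproducibility.
#' @return a `stability_report`: data.frame with one row per K and columns
#'   `silhouette`, `ch`, `ari_subsample`, `vi_subsample`,
#'   `ari_consecutive`, `vi_consecutive`; attributes record the settings.
#' @export
subsample_stability <- function(ma_mat, K_range = 2:15, fraction = 0.9,
                                n_iter = 100, seed = 1) {
  stopifnot(n_iter >= 1, fraction > 0, fraction <= 1)
  e <- nrow(ma_mat)
  K_range <- K_range[K_range >= 2 & K_range <= e]
  if (!length(K_range)) stop("empty K range after clipping to corpus size")
  sim <- spearman_similarity(ma_mat)
  full_tree <- hierarchical_cluster(sim)
  full_labels <- lapply(K_range, function(K) cut_tree(full_tree, K)$labels)
  names(full_labels) <- K_range

  nk <- length(K_range)
  acc <- matrix(0, nk, 4,
                dimnames = list(K_range, c("silhouette", "ch",
                                           "ari_subsample", "vi_subsample")))
  used <- 0L
  m <- max(2L, round(fraction * e))
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    idx <- sort(sample.int(e, m))
    if (m < max(K_range)) {
      message("iteration ", it, " skipped: subsample smaller than max K")
      next
    }
    sub_rho <- sim$rho[idx, idx]
    sub_sim <- structure(list(ids = sim$ids[idx], rho = sub_rho),
                         class = "similarity_matrix")
    sub_tree <- hierarchical_cluster(sub_sim)
    sub_d <- 1 - sub_rho
    sub_feat <- ma_mat[idx, , drop = FALSE]
    for (ki in seq_len(nk)) {
      lab <- cut_tree(sub_tree, K_range[ki])$labels
      ref <- full_labels[[ki]][idx]
      acc[ki, ] <- acc[ki, ] +
        c(silhouette_index(lab, sub_d),
          calinski_harabasz(lab, sub_feat),
          adjusted_rand(lab, ref),
          variation_of_information(lab, ref))
    }
    used <- used + 1L
  }
  if (used == 0L) stop("no usable subsample iterations")
  out <- as.data.frame(acc / used)
  out$K <- K_range
  out$ari_consecutive <- NA_real_
  out$vi_consecutive <- NA_real_
  for (ki in seq_len(nk)[-1]) {
    out$ari_consecutive[ki] <- adjusted_rand(full_labels[[ki - 1]],
                                             full_labels[[ki]])
    out$vi_consecutive[ki] <- variation_of_information(full_labels[[ki - 1]],
                                                       full_labels[[ki]])
  }
  out <- out[, c("K", "silhouette", "ch", "ari_subsample", "vi_subsample",
                 "ari_consecutive", "vi_consecutive")]
  structure(out, class = c("stability_report", "data.frame"),
            n_iter = used, fraction = fraction, seed = seed)
}

#' Select the number of groups from a stability report
#'
#' Mechanical majority rule over per-metric optima: silhouette argmax, aRI
#' (subsample mean) argmax, and the K at which the consecutive-K variation
#' of information change is smallest.  Calinski-Harabasz joins the vote only
#' when it is not monotone over the K range (a monotone CH carries no
#' optimum and is logged as excluded).  Vote ties resolve to the smaller K;
#' `override` bypasses the rule entirely (investigator judgment).
#'
#' @param report a [subsample_stability()] report.
#' @param override optional K to force.
#' @return selected K (integer) with attribute `votes`.
#' @export
select_k <- function(report, override = NULL) {
  if (nrow(report) == 0L) stop("empty stability report")
  if (!is.null(override)) {
    if (!override %in% report$K) stop("override K not in report range")
    return(structure(as.integer(override), votes = c(override = override)))
  }
  K <- report$K
  votes <- c(silhouette = K[which.max(report$silhouette)],
             ari = K[which.max(report$ari_subsample)])
  vi_ok <- which(!is.na(report$vi_consecutive))
  if (length(vi_ok))
    votes["vi"] <- K[vi_ok[which.min(report$vi_consecutive[vi_ok])]]
  ch <- report$ch
  monotone <- all(diff(ch) >= 0) || all(diff(ch) <= 0)
  if (monotone) {
    message("Calinski-Harabasz is monotone over the K range; ",
            "excluded from the vote")
  } else {
    votes["ch"] <- K[which.max(ch)]
  }
  counts <- table(votes)
  winners <- as.integer(names(counts)[counts == max(counts)])
  structure(min(winners), votes = votes)
}

#' Prune groups below the minimum size
#'
#' Groups with fewer than `min_size` experiments are considered outliers
#' (a single experiment could drive a meta-analysis on them) and moved to
#' the excluded set; retained groups keep their original group IDs.
#'
#' @param solution a [cut_tree()] solution, or a named label vector.
#' @param min_size minimum experiments per retained group (default 10).
#' @return a `mag_set`: list with `retained` (group id -> experiment IDs),
#'   `excluded` (with reasons), `labels` (retained labels only) and
#'   `retained_fraction`.
#' @export
prune_small_groups <- function(solution, min_size = 10) {
  labels <- if (inherits(solution, "cluster_solution")) solution$labels
            else solution
  if (is.null(names(labels)))
    names(labels) <- as.character(seq_along(labels))
  groups <- split(names(labels), labels)
  sizes <- lengths(groups)
  keep <- sizes >= min_size
  if (!any(keep))
    stop("all groups smaller than min_size = ", min_size, "; nothing retained")
  retained <- groups[keep]
  excluded <- lapply(names(groups)[!keep], function(g) {
    list(group = g, ids = groups[[g]],
         reason = sprintf("size %d < min_size %d", sizes[[g]], min_size))
  })
  kept_labels <- labels[names(labels) %in% unlist(retained, use.names = FALSE)]
  structure(list(retained = retained, excluded = excluded,
                 labels = kept_labels,
                 retained_fraction = sum(sizes[keep]) / length(labels)),
            class = "mag_set")
}

#' @export
print.mag_set <- function(x, ...) {
  cat("mag_set:", length(x$retained), "retained group(s) (",
      paste(lengths(x$retained), collapse = ", "), "experiments ),",
      length(x$excluded), "excluded;",
      sprintf("%.1f%% of experiments retained\n", 100 * x$retained_fraction))
  invisible(x)
}
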