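# Partition-comparison and cluster-quality metrics used for K selection.

align_partitions <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    if (length(common) == 0L) stop("partitions share no items")
    if (length(common) != length(a) || length(common) != length(b))
      stop("partitions are over different item sets")
    list(a = a[common], b = b[common])
  } else {
    if (length(a) != length(b))
      stop("partitions are over different item sets")
    list(a = a, b = b)
  }
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model;
#' 1 iff the partitions are identical up to relabelling.
#'
#' @param labels_a,labels_b label vectors over the same items (aligned by
#'   names when both are named).
#' @return scalar aRI (<= 1).
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  p <- align_partitions(labels_a, labels_b)
  tab <- table(p$a, p$b)
  n <- sum(tab)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < 1e-15) return(1)  # both trivial partitions
  (sum_ij - expected) / (max_index - expected)
}

#' Variation of information between two partitions (nats)
#'
#' `VI = H(A) + H(B) - 2 I(A, B)`; zero iff the partitions are identical up
#' to relabelling.
#'
#' @inheritParams adjusted_rand
#' @return scalar VI >= 0, in nats.
#' @export
variation_of_information <- function(labels_a, labels_b) {
  p <- align_partitions(labels_a, labels_b)
  tab <- table(p$a, p$b) / length(p$a)
  pa <- rowSums(tab)
  pb <- colSums(tab)
  ent <- function(q) -sum(q[q > 0] * log(q[q > 0]))
  mi <- sum(tab[tab > 0] *
              log(tab[tab > 0] / outer(pa, pb)[as.matrix(tab) > 0]))
  max(0, ent(pa) + ent(pb) - 2 * mi)
}

#' Mean silhouette index of a cluster solution
#'
#' Computed on an arbitrary distance matrix (here 1 - Spearman rho).  The
#' silhouette of a singleton cluster is defined as 0 (documented
#' convention).
#'
#' @param labels cluster labels (>= 2 clusters).
#' @param distances square distance matrix in the same item order.
#' @return mean silhouette in `[-1, 1]`.
#' @export
silhouette_index <- function(labels, distances) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("silhouette needs >= 2 clusters")
  n <- length(labels)
  stopifnot(nrow(distances) == n)
  sizes <- tabulate(labels, k)
  # mean distance from each item to each cluster
  sums <- rowsum(distances, labels)           # k x n: column = item
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- labels[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- sums[ci, i] / (sizes[ci] - 1)
    b <- min((sums[, i] / sizes)[-ci])
    denom <- max(a, b)
    s[i] <- if (denom > 0) (b - a) / denom else 0
  }
  mean(s)
}

#' Calinski-Harabasz score of a cluster solution
#'
#' Between- over within-cluster dispersion in the feature space (here the
#' MA matrix rows), scaled by degrees of freedom.
#'
#' @param labels cluster labels (>= 2 clusters, each nonempty).
#' @param features item x feature numeric matrix.
#' @return nonnegative CH score (Inf when within-dispersion is 0).
#' @export
calinski_harabasz <- function(labels, features) {
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop("Calinski-Harabasz needs >= 2 clusters")
  n <- nrow(features)
  centroid <- colMeans(features)
  wss <- 0
  bss <- 0
  for (g in seq_len(k)) {
    sub <- features[labels == g, , drop = FALSE]
    cg <- colMeans(sub)
    wss <- wss + sum(sweep(sub, 2, cg)^2)
    bss <- bss + nrow(sub) * sum((cg - centroid)^2)
  }
  if (wss == 0) return(Inf)
  (bss / (k - 1)) / (wss / (n - k))
}
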