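# Over/under-representation statistics across MAGs.
#
# Two denominators coexist by design: one-tailed exact binomial tests
# compare a MAG's prevalence of a characteristic with its base rate over
# the FULL corpus (all experiments, including unclustered outliers), while
# one-vs-rest chi-squares compare a MAG against the other RETAINED MAGs
# only.  This dual convention is what reproduces the published statistics.

#' One-tailed exact binomial test against a base rate
#'
#' @param k observed successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param p0 base rate, strictly inside (0, 1).
#' @param tail `"less"` (P(X <= k)), `"greater"` (P(X >= k)) or `"auto"`
#'   (direction chosen by the sign of `k/n - p0`).
#' @return a `binomial_result`: list with `k`, `n`, `p0`, `tail`, `p`.
#' @export
binomial_vs_base_rate <- function(k, n, p0, tail = c("auto", "greater",
                                                     "less")) {
  tail <- match.arg(tail)
  stopifnot(n >= 1, k >= 0, k <= n)
  if (p0 <= 0 || p0 >= 1) stop("base rate p0 must be strictly inside (0, 1)")
  if (tail == "auto") tail <- if (k / n < p0) "less" else "greater"
  p <- if (tail == "less") pbinom(k, n, p0)
       else pbinom(k - 1, n, p0, lower.tail = FALSE)
  structure(list(k = k, n = n, p0 = p0, tail = tail, p = p),
            class = "binomial_result")
}

#' One-vs-rest Pearson chi-square on a 2x2 table
#'
#' Tests whether a characteristic's frequency in one group differs from its
#' frequency in all other groups combined; no continuity correction, df = 1,
#' right-tail p.
#'
#' @param count_in_group,size_group characteristic count and total in the
#'   group of interest.
#' @param count_in_rest,size_rest same for the pooled remaining groups.
#' @return a `contingency_result`: list with `observed` (2x2), `expected`,
#'   `chi_square`, `df`, `p`.
#' @export
chi_square_one_vs_rest <- function(count_in_group, size_group,
                                   count_in_rest, size_rest) {
  stopifnot(count_in_group >= 0, count_in_rest >= 0,
            count_in_group <= size_group, count_in_rest <= size_rest,
            size_group >= 1, size_rest >= 1)
  obs <- matrix(c(count_in_group, size_group - count_in_group,
                  count_in_rest, size_rest - count_in_rest),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("group", "rest"), c("yes", "no")))
  if (any(rowSums(obs) == 0) || any(colSums(obs) == 0))
    stop("degenerate 2x2 table: zero margin")
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  x2 <- sum((obs - expected)^2 / expected)
  structure(list(observed = obs, expected = expected, chi_square = x2,
                 df = 1L, p = pchisq(x2, 1, lower.tail = FALSE)),
            class = "contingency_result")
}

#' Kruskal-Wallis rank test across groups
#'
#' Standard rank-based H with tie correction and the chi-square
#' approximation for p.  When all values are identical (tie correction
#' denominator 0) H is defined as 0.
#'
#' @param groups list of numeric vectors (>= 2 groups, each nonempty).
#' @return list with `H`, `df`, `p`, `n`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) == 0L)) stop("each group must be nonempty")
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rsums <- tapply(r, g, sum)
  h <- 12 / (n * (n + 1)) * sum(rsums^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h <- if (correction <= 0) 0 else h / correction
  df <- length(groups) - 1L
  list(H = h, df = df, p = pchisq(h, df, lower.tail = FALSE), n = n)
}

# NA-aware characteristic flags per experiment (unknowns stay NA and are
# excluded pairwise from the tests that use them)
phenotype_flags <- function(e) {
  c(setNames(DIAGNOSES == e$diagnosis, DIAGNOSES),
    setNames(TASK_DOMAINS %in% e$task_domain, paste0("task_", TASK_DOMAINS)),
    setNames(c("positive", "negative", "both") == e$valence,
             c("valence_positive", "valence_negative", "valence_both")),
    medication_naive = e$medication_naive,
    mixed_sex = if (is.na(e$pct_boys)) NA
                else e$pct_boys > 0 && e$pct_boys < 100)
}

#' Phenotype over/under-representation report across MAGs
#'
#' For each characteristic and each retained MAG: count, percent, one-tailed
#' exact binomial p against the base rate over the full corpus, and a
#' one-vs-rest chi-square over the retained experiments only.  `pct_boys`
#' is additionally compared across MAGs with a Kruskal-Wallis test.
#' Characteristics absent from the whole corpus are skipped with a message.
#'
#' @param corp the full `corpus` (base-rate denominator).
#' @param magset a [prune_small_groups()] result (retained groupings).
#' @param alpha flag threshold for the `sig_*` columns (default 0.05,
#'   unadjusted as in the source convention).
#' @param p_adjust optional multiple-testing adjustment method passed to
#'   [stats::p.adjust()] applied per test family; default `"none"`.
#' @return data.frame (one row per characteristic x MAG) with columns
#'   `characteristic`, `group`, `k`, `n`, `pct`, `base_rate_pct`,
#'   `p_binomial`, `sig_vs_base_rate`, `chi_square`, `p_chi_square`,
#'   `sig_between_mags`; Kruskal-Wallis results are attached as attribute
#'   `kruskal`.
#' @export
phenotype_report <- function(corp, magset, alpha = 0.05, p_adjust = "none") {
  flags <- vapply(corp$experiments, phenotype_flags,
                  phenotype_flags(corp$experiments[[1]]))
  all_ids <- corpus_ids(corp)
  groups <- magset$retained
  retained_ids <- unlist(groups, use.names = FALSE)
  rows <- list()
  for (ch in rownames(flags)) {
    v <- flags[ch, ]
    n_total <- sum(!is.na(v))
    k_total <- sum(v, na.rm = TRUE)
    if (k_total == 0) {
      message("characteristic ", ch, " absent from corpus; skipped")
      next
    }
    p0 <- k_total / n_total
    for (g in names(groups)) {
      vg <- v[groups[[g]]]
      vr <- v[setdiff(retained_ids, groups[[g]])]
      k <- sum(vg, na.rm = TRUE); n <- sum(!is.na(vg))
      kr <- sum(vr, na.rm = TRUE); nr <- sum(!is.na(vr))
      pb <- if (n >= 1 && p0 > 0 && p0 < 1)
        binomial_vs_base_rate(k, n, p0)$p else NA_real_
      x2 <- tryCatch(chi_square_one_vs_rest(k, n, kr, nr),
                     error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        characteristic = ch, group = g, k = k, n = n,
        pct = round(100 * k / n, 1), base_rate_pct = round(100 * p0, 1),
        p_binomial = pb,
        chi_square = if (is.null(x2)) NA_real_ else x2$chi_square,
        p_chi_square = if (is.null(x2)) NA_real_ else x2$p)
    }
  }
  out <- do.call(rbind, rows)
  out$p_binomial <- stats::p.adjust(out$p_binomial, method = p_adjust)
  out$p_chi_square <- stats::p.adjust(out$p_chi_square, method = p_adjust)
  out$sig_vs_base_rate <- !is.na(out$p_binomial) & out$p_binomial < alpha
  out$sig_between_mags <- !is.na(out$p_chi_square) & out$p_chi_square < alpha

  pct_boys <- vapply(corp$experiments, `[[`, 0, "pct_boys")
  kw <- tryCatch(
    kruskal_wallis(lapply(groups, function(ids) pct_boys[ids])),
    error = function(e) NULL)
  attr(out, "kruskal") <- list(pct_boys = kw)
  rownames(out) <- NULL
  out
}

#' Behavioural-label enrichment of a cluster mask
#'
#' Generic functional characterization: given a database of foci tagged
#' with behavioural-domain labels, tests whether each label's foci
#' concentrate inside a cluster mask.  With `p_mask` the fraction of all
#' database foci falling in the mask, a label with `n` foci has expectation
#' `n * p_mask` inside and `z = (obs - exp) / sqrt(exp * (1 - p_mask))`
#' (binomial-approximation z, a transparent stand-in for proprietary
#' plugins).  Significance at `z >= z_threshold` (default 3, i.e. p < 0.05
#' Bonferroni-corrected at typical label counts).
#'
#' @param cluster_mask logical vector over the grid's mask voxels (or a
#'   vector of mask positions).
#' @param labeled_foci_db data.frame with columns `x`, `y`, `z` (MNI mm)
#'   and `label`.
#' @param grid a [brain_grid()].
#' @param z_threshold significance threshold on z (default 3).
#' @return data.frame with `label`, `observed`, `expected`, `z`,
#'   `significant`, sorted by decreasing z.
#' @export
label_enrichment <- function(cluster_mask, labeled_foci_db, grid,
                             z_threshold = 3) {
  if (nrow(labeled_foci_db) == 0L) stop("empty labeled-foci database")
  if (is.logical(cluster_mask)) {
    stopifnot(length(cluster_mask) == grid$n_mask_voxels)
    pos <- which(cluster_mask)
  } else pos <- as.integer(cluster_mask)
  if (!length(pos)) stop("empty cluster mask")
  in_cluster <- logical(grid$n_mask_voxels)
  in_cluster[pos] <- TRUE

  vox <- world_to_voxel(grid, as.matrix(labeled_foci_db[, c("x", "y", "z")]))
  ok <- in_volume(grid, vox)
  mpos <- mask_positions(grid)
  focus_pos <- rep(0L, nrow(vox))
  focus_pos[ok] <- mpos[ijk_to_lin(grid, vox[ok, , drop = FALSE])]
  inside <- focus_pos > 0 & in_cluster[pmax(focus_pos, 1L)]

  p_mask <- mean(inside)
  if (p_mask == 0 || p_mask == 1)
    stop("degenerate mask fraction p_mask = ", p_mask)
  labels <- as.character(labeled_foci_db$label)
  out <- do.call(rbind, lapply(unique(labels), function(l) {
    sel <- labels == l
    n <- sum(sel)
    obs <- sum(inside[sel])
    expct <- n * p_mask
    z <- (obs - expct) / sqrt(expct * (1 - p_mask))
    data.frame(label = l, observed = obs, expected = expct, z = z)
  }))
  out$significant <- out$z >= z_threshold
  out[order(-out$z), , drop = FALSE]
}
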