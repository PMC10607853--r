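#' Bray-Curtis dissimilarity matrix
#'
#' `BC(i, j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)`, computed on the
#' counts as given (no internal renormalization; rarefy first if depths
#' differ).
#'
#' @param x a [community_table()] or a samples-by-taxa numeric matrix.
#' @return symmetric matrix in `[0, 1]` with zero diagonal, `metric`
#'   attribute `"bray_curtis"`.
#' @export
bray_curtis <- function(x) {
  counts <- if (inherits(x, "community_table")) x$counts else as.matrix(x)
  if (sum(rowSums(counts) == 0) >= 2)
    stop("Bray-Curtis undefined for a pair of all-zero samples")
  d <- as.matrix(vegan::vegdist(counts, method = "bray"))
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Weighted UniFrac distance matrix
#'
#' For each branch `b` with length `l_b`, let `A_b` and `B_b` be the
#' fractions of each sample's reads descending from `b`; the raw weighted
#' UniFrac distance is `sum_b l_b |A_b - B_b|` and the normalized variant
#' (the default, bounded in `[0, 1]`) divides by `sum_b l_b (A_b + B_b)`.
#'
#' @param x a [community_table()]; all taxa must be tips of `tree`.
#' @param tree rooted `phylo` with branch lengths.
#' @param normalized return the normalized variant (default `TRUE`).
#' @return symmetric matrix with zero diagonal, `metric` attribute
#'   `"weighted_unifrac"`.
#' @export
weighted_unifrac <- function(x, tree, normalized = TRUE) {
  stopifnot(inherits(x, "community_table"), inherits(tree, "phylo"))
  taxa <- colnames(x$counts)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa missing from tree: ", paste(head(missing, 5), collapse = ", "))
  rel <- rel_abund(x$counts)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  S <- nrow(rel)

  # accumulate, for every node, each sample's read fraction below it
  W <- matrix(0, nrow = nnode, ncol = S)
  W[match(taxa, tree$tip.label), ] <- t(rel)
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    W[po$edge[e, 1], ] <- W[po$edge[e, 1], ] + W[po$edge[e, 2], ]
  }
  len <- po$edge.length
  A <- W[po$edge[, 2], , drop = FALSE]   # per-branch descendant fractions

  d <- matrix(0, S, S, dimnames = list(rownames(rel), rownames(rel)))
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      num <- sum(len * abs(A[, i] - A[, j]))
      d[i, j] <- d[j, i] <-
        if (normalized) num / sum(len * (A[, i] + A[, j])) else num
    }
  }
  attr(d, "metric") <- "weighted_unifrac"
  d
}

#' Principal coordinate analysis (classical MDS)
#'
#' Gower double-centering of the squared distances followed by an
#' eigendecomposition. Coordinates are returned for the positive
#' eigenvalues; negative eigenvalues are reported but excluded from the
#' proportion-explained denominator.
#'
#' @param d symmetric distance matrix (at least 3 samples).
#' @param k number of axes to return (default: all positive-eigenvalue
#'   axes).
#' @return list with `points` (samples x axes), `eigenvalues` (all, in
#'   decreasing order), `proportion` (per returned axis, computed over the
#'   positive eigenvalues).
#' @export
pcoa <- function(d, k = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 samples")
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  b <- ctr %*% a %*% ctr
  eg <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- eg$values > max(eg$values, 0) * 1e-9
  npos <- sum(pos)
  k <- min(k %||% npos, npos)
  pts <- if (k > 0) {
    sweep(eg$vectors[, seq_len(k), drop = FALSE], 2,
          sqrt(eg$values[seq_len(k)]), `*`)
  } else matrix(0, n, 0)
  rownames(pts) <- rownames(d)
  if (k > 0) colnames(pts) <- paste0("PCo", seq_len(k))
  list(points = pts,
       eigenvalues = eg$values,
       proportion = if (npos > 0) eg$values[seq_len(k)] / sum(eg$values[pos])
                    else numeric(0))
}

permanova_stat <- function(d2, groups) {
  n <- length(groups)
  a <- nlevels(groups)
  ss_t <- sum(d2[upper.tri(d2)]) / n
  ss_w <- 0
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    sub <- d2[idx, idx, drop = FALSE]
    ss_w <- ss_w + sum(sub[upper.tri(sub)]) / length(idx)
  }
  ss_a <- ss_t - ss_w
  list(f = (ss_a / (a - 1)) / (ss_w / (n - a)), r2 = ss_a / ss_t)
}

#' One-way PERMANOVA from a distance matrix
#'
#' Permutational multivariate analysis of variance (Anderson): pseudo-F from
#' the partition of the sum of squared distances, `R2 = SS_between /
#' SS_total`, and a permutation p-value that counts the observed statistic,
#' `p = (1 + #{F_perm >= F_obs}) / (1 + n_permutations)`.
#'
#' @param d symmetric distance matrix.
#' @param groups group label per sample (>= 2 groups, each with >= 2
#'   samples).
#' @param n_permutations number of label permutations (>= 99).
#' @param seed integer seed for the permutation stream.
#' @return list with `f`, `r_squared`, `p_value`, `n_permutations`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL) {
  d <- as.matrix(d)
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("every group needs at least 2 samples")
  if (n_permutations < 99) stop("need at least 99 permutations")
  d2 <- d^2
  obs <- permanova_stat(d2, groups)
  exceed <- with_seed_opt(seed, {
    sum(vapply(seq_len(n_permutations), function(i) {
      permanova_stat(d2, sample(groups))$f >= obs$f
    }, logical(1)))
  })
  list(f = obs$f, r_squared = obs$r2,
       p_value = (1 + exceed) / (1 + n_permutations),
       n_permutations = n_permutations)
}

#' Within-group pairwise similarities
#'
#' Similarity is `1 - dissimilarity` for every pair of samples belonging to
#' the same group (the "inter-individual similarity within each gradient
#' level").
#'
#' @param d symmetric dissimilarity matrix.
#' @param groups group label per sample.
#' @return data.frame with `group`, `sample_a`, `sample_b`, `similarity`.
#' @export
within_group_similarity <- function(d, groups) {
  d <- as.matrix(d)
  groups <- as.character(groups)
  out <- list()
  for (lev in unique(groups)) {
    idx <- which(groups == lev)
    if (length(idx) < 2) next
    pr <- t(combn(idx, 2))
    out[[lev]] <- data.frame(group = lev,
                             sample_a = rownames(d)[pr[, 1]],
                             sample_b = rownames(d)[pr[, 2]],
                             similarity = 1 - d[pr],
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Distance-decay of community similarity with elevation
#'
#' OLS regression of pairwise similarity (`1 - dissimilarity`) on pairwise
#' altitude separation `|delta altitude|`, over all sample pairs.
#'
#' @param d symmetric dissimilarity matrix.
#' @param altitudes altitude per sample, aligned with `d`.
#' @return a [gradient_regression()] fit (slope, R2, p, n).
#' @export
distance_decay <- function(d, altitudes) {
  d <- as.matrix(d)
  if (length(altitudes) != nrow(d)) stop("altitudes must match samples")
  if (length(unique(altitudes)) == 1) stop("all altitudes equal")
  pr <- t(combn(nrow(d), 2))
  gradient_regression(1 - d[pr], abs(altitudes[pr[, 1]] - altitudes[pr[, 2]]))
}
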