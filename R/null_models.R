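#' Patristic distance matrix over the taxa of a table
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param taxa taxon ids; must all be tips of `tree`.
#' @return symmetric matrix of tip-to-tip path lengths.
#' @export
patristic_distances <- function(tree, taxa = tree$tip.label) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa missing from tree: ", paste(head(missing, 5), collapse = ", "))
  d <- stats::cophenetic(tree)
  d[taxa, taxa]
}

as_dist_matrix <- function(dist, taxa) {
  if (inherits(dist, "phylo")) dist <- patristic_distances(dist, taxa)
  dist
}

mntd_idx <- function(w, idx, D, abundance_weighted) {
  sub <- D[idx, idx, drop = FALSE]
  diag(sub) <- Inf
  nn <- row_mins(sub)
  if (abundance_weighted) sum(w * nn) else mean(nn)
}

#' Mean nearest taxon distance of one community
#'
#' For every taxon present, the patristic distance to its nearest
#' co-occurring taxon; averaged either equally (unweighted) or by relative
#' abundance (weighted).
#'
#' @param counts named count (or abundance) vector; names are taxon ids.
#' @param tree a `phylo` object, or a precomputed patristic distance matrix
#'   whose dimnames cover the taxa.
#' @param abundance_weighted weight each taxon's nearest-neighbour distance
#'   by its relative abundance.
#' @return non-negative scalar in branch-length units.
#' @export
mntd <- function(counts, tree, abundance_weighted = FALSE) {
  idx <- which(counts > 0)
  if (length(idx) < 2) stop("need at least 2 taxa present")
  D <- as_dist_matrix(tree, names(counts))
  ids <- names(counts)[idx]
  sub <- D[ids, ids]
  diag(sub) <- Inf
  nn <- row_mins(sub)
  if (abundance_weighted) sum(counts[idx] / sum(counts[idx]) * nn) else mean(nn)
}

#' Standardized effect size of MNTD (SES.MNTD)
#'
#' Null model: shuffle taxon labels across the pool of taxa in the table
#' (the "taxa labels" randomization), recompute MNTD for every sample each
#' draw, and standardize: `SES = (obs - null mean) / null SD`. Negative
#' values indicate phylogenetic clustering, positive values overdispersion;
#' |SES| > 2 is the conventional significance rule.
#'
#' @param x a [community_table()].
#' @param tree `phylo` or patristic distance matrix over the table's taxa.
#' @param n_null number of null draws (>= 99; default 999).
#' @param seed integer seed.
#' @param abundance_weighted weighted MNTD (default `TRUE`).
#' @return data.frame per sample: `sample_id`, `observed`, `null_mean`,
#'   `null_sd`, `ses`, `n_null`. Samples whose null SD is 0 (e.g. a sample
#'   containing the whole taxon pool, which every label shuffle leaves
#'   unchanged) get `ses = NA`.
#' @export
ses_mntd <- function(x, tree, n_null = 999, seed = NULL,
                     abundance_weighted = TRUE) {
  stopifnot(inherits(x, "community_table"))
  if (n_null < 99) stop("n_null must be at least 99")
  counts <- x$counts
  D <- as_dist_matrix(tree, colnames(counts))
  D <- D[colnames(counts), colnames(counts)]
  nt <- ncol(counts)
  pres <- lapply(seq_len(nrow(counts)), function(s) which(counts[s, ] > 0))
  wts <- lapply(seq_len(nrow(counts)), function(s) {
    v <- counts[s, pres[[s]]]
    v / sum(v)
  })
  if (any(lengths(pres) < 2)) stop("every sample needs at least 2 taxa present")

  obs <- vapply(seq_along(pres), function(s)
    mntd_idx(wts[[s]], pres[[s]], D, abundance_weighted), numeric(1))

  nulls <- with_seed_opt(seed, {
    vapply(seq_len(n_null), function(r) {
      perm <- sample.int(nt)
      vapply(seq_along(pres), function(s)
        mntd_idx(wts[[s]], perm[pres[[s]]], D, abundance_weighted),
        numeric(1))
    }, numeric(length(pres)))
  })
  nulls <- matrix(nulls, nrow = length(pres))
  mu <- rowMeans(nulls)
  sdev <- apply(nulls, 1, sd)
  ses <- ifelse(sdev > 0, (obs - mu) / sdev, NA_real_)
  data.frame(sample_id = rownames(counts), observed = obs, null_mean = mu,
             null_sd = sdev, ses = ses, n_null = n_null,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Between-sample mean nearest taxon distance (beta-MNTD)
#'
#' For each taxon in sample a, the nearest patristic distance to any taxon
#' in sample b (0 if shared), averaged with abundance weights by default;
#' symmetrized as the mean of the two directions.
#'
#' @param a,b named count vectors over the same taxon set.
#' @param tree `phylo` or patristic distance matrix.
#' @param abundance_weighted weight by relative abundance (default `TRUE`).
#' @return non-negative scalar, symmetric in `a`, `b`.
#' @export
beta_mntd <- function(a, b, tree, abundance_weighted = TRUE) {
  if (sum(a > 0) == 0 || sum(b > 0) == 0) stop("empty sample")
  D <- as_dist_matrix(tree, names(a))
  ia <- which(a > 0); ib <- which(b > 0)
  na <- names(a)[ia]; nb <- names(b)[ib]
  d_ab <- row_mins(D[na, nb, drop = FALSE])  # per taxon of a, nearest in b
  d_ba <- row_mins(D[nb, na, drop = FALSE])
  if (abundance_weighted) {
    wa <- a[ia] / sum(a[ia]); wb <- b[ib] / sum(b[ib])
    (sum(wa * d_ab) + sum(wb * d_ba)) / 2
  } else (mean(d_ab) + mean(d_ba)) / 2
}

# All pairwise beta-MNTD values for weight matrix W (samples x taxa, rows
# normalized) with presence index list `pres`, under distance matrix D.
bmntd_matrix <- function(W, pres, D) {
  S <- length(pres)
  nt <- ncol(W)
  M <- matrix(0, nrow = nt, ncol = S)  # M[t, s] = min_{j in s} D[t, j]
  for (s in seq_len(S)) {
    sub <- D[, pres[[s]], drop = FALSE]
    M[, s] <- row_mins(sub)
  }
  P <- W %*% M   # P[a, b] = sum_i w_ai min_{j in b} D_ij
  (P + t(P)) / 2
}

#' Pairwise beta-NTI matrix
#'
#' `betaNTI(a, b) = (observed betaMNTD - null mean) / null SD`, where the
#' null shuffles taxon labels across the table's taxon pool and recomputes
#' beta-MNTD for all pairs on each draw. |betaNTI| > 2 signals selection
#' (variable if > +2, homogeneous if < -2).
#'
#' @param x a [community_table()].
#' @param tree `phylo` or patristic distance matrix over the table's taxa.
#' @param n_null number of null draws (>= 99; default 999).
#' @param seed integer seed.
#' @param abundance_weighted weighted beta-MNTD (default `TRUE`).
#' @return list of class `beta_nti` with matrices `bmntd` (observed),
#'   `bnti`, `null_mean`, `null_sd`; diagonals are `NA`, as are entries with
#'   zero null SD.
#' @export
beta_nti <- function(x, tree, n_null = 999, seed = NULL,
                     abundance_weighted = TRUE) {
  stopifnot(inherits(x, "community_table"))
  if (n_null < 99) stop("n_null must be at least 99")
  counts <- x$counts
  D <- as_dist_matrix(tree, colnames(counts))
  D <- D[colnames(counts), colnames(counts)]
  dimnames(D) <- NULL
  nt <- ncol(counts)
  S <- nrow(counts)
  pres <- lapply(seq_len(S), function(s) which(counts[s, ] > 0))
  W <- if (abundance_weighted) counts / rowSums(counts)
       else (counts > 0) / rowSums(counts > 0)

  obs <- bmntd_matrix(W, pres, D)
  sum1 <- matrix(0, S, S)
  sum2 <- matrix(0, S, S)
  with_seed_opt(seed, {
    for (r in seq_len(n_null)) {
      perm <- sample.int(nt)
      Wp <- W
      Wp[, perm] <- W
      presp <- lapply(pres, function(i) perm[i])
      nm <- bmntd_matrix(Wp, presp, D)
      sum1 <- sum1 + nm
      sum2 <- sum2 + nm^2
    }
  })
  mu <- sum1 / n_null
  vr <- pmax(sum2 / n_null - mu^2, 0) * n_null / (n_null - 1)
  sdev <- sqrt(vr)
  bnti <- ifelse(sdev > 0, (obs - mu) / sdev, NA_real_)
  diag(bnti) <- NA_real_
  diag(obs) <- NA_real_
  ids <- rownames(counts)
  dimnames(bnti) <- dimnames(obs) <- dimnames(mu) <- dimnames(sdev) <-
    list(ids, ids)
  structure(list(bmntd = obs, bnti = bnti, null_mean = mu, null_sd = sdev,
                 n_null = n_null),
            class = "beta_nti")
}

#' Bray-Curtis-based Raup-Crick null (RC_bray)
#'
#' For each sample pair, both communities are repeatedly reassembled from
#' the regional pool at their observed richness and read total: taxa are
#' drawn without replacement with probability proportional to their
#' occurrence frequency across samples, given one read each, and the
#' remaining reads are allocated multinomially in proportion to regional
#' relative abundance (the Stegen-style probabilistic null). The index is
#' `RC = (#{BC_null < BC_obs} + 0.5 #{BC_null = BC_obs}) / n_null`,
#' rescaled to `[-1, 1]` as `2 RC - 1`. `RC > 0.95` with |betaNTI| < 2
#' signals dispersal limitation, `RC < -0.95` homogenizing dispersal.
#'
#' @param x a [community_table()]; the regional pool is the table's taxa.
#' @param n_null number of null assemblies per pair (>= 99; default 999).
#' @param seed integer seed.
#' @param groups optional group label per sample; when given, only
#'   within-group pairs are computed (the regional pool and occurrence
#'   frequencies still come from the whole table) and between-group entries
#'   stay `NA`.
#' @return symmetric matrix in `[-1, 1]` with `NA` diagonal.
#' @export
raup_crick_bray <- function(x, n_null = 999, seed = NULL, groups = NULL) {
  stopifnot(inherits(x, "community_table"))
  if (n_null < 99) stop("n_null must be at least 99")
  counts <- x$counts
  if (any(rowSums(counts) == 0)) stop("sample with zero richness")
  S <- nrow(counts)
  nt <- ncol(counts)
  occ <- colMeans(counts > 0)          # occurrence frequency
  reg <- colSums(counts)               # regional abundance
  reg <- reg / sum(reg)
  rich <- rowSums(counts > 0)
  tot <- rowSums(counts)

  bc_pair <- function(u, v) sum(abs(u - v)) / sum(u + v)
  draw_comm <- function(richness, total) {
    chosen <- sample.int(nt, richness, prob = occ)
    ab <- numeric(nt)
    ab[chosen] <- 1
    if (total > richness) {
      extra <- rmultinom(1, total - richness, prob = reg[chosen])
      ab[chosen] <- ab[chosen] + extra
    }
    ab
  }

  if (!is.null(groups) && length(groups) != S)
    stop("groups must have one label per sample")
  rc <- matrix(NA_real_, S, S, dimnames = list(rownames(counts), rownames(counts)))
  with_seed_opt(seed, {
    for (i in seq_len(S - 1)) {
      for (j in (i + 1):S) {
        if (!is.null(groups) && groups[i] != groups[j]) next
        bc_obs <- bc_pair(counts[i, ], counts[j, ])
        less <- 0; equal <- 0
        for (r in seq_len(n_null)) {
          bc_null <- bc_pair(draw_comm(rich[i], tot[i]),
                             draw_comm(rich[j], tot[j]))
          if (bc_null < bc_obs) less <- less + 1
          else if (bc_null == bc_obs) equal <- equal + 1
        }
        rc[i, j] <- rc[j, i] <- 2 * (less + 0.5 * equal) / n_null - 1
      }
    }
  })
  rc
}

#' Classify a sample pair into one of five assembly processes
#'
#' Decision rule (strict inequalities, beta-NTI takes precedence):
#' `betaNTI > +2` variable selection; `betaNTI < -2` homogeneous selection;
#' otherwise `RC > +0.95` dispersal limitation, `RC < -0.95` homogenizing
#' dispersal, else drift. Vectorized; missing inputs yield `NA`
#' (unclassified).
#'
#' @param bnti beta-NTI value(s).
#' @param rc RC_bray value(s) in `[-1, 1]`.
#' @return character vector over
#'   `c("variable_selection", "homogeneous_selection",
#'   "dispersal_limitation", "homogenizing_dispersal", "drift")`.
#' @export
classify_pair <- function(bnti, rc) {
  out <- rep(NA_character_, length(bnti))
  ok <- is.finite(bnti) & is.finite(rc)
  out[ok & bnti > 2] <- "variable_selection"
  out[ok & bnti < -2] <- "homogeneous_selection"
  mid <- ok & abs(bnti) <= 2
  out[mid & rc > 0.95] <- "dispersal_limitation"
  out[mid & rc < -0.95] <- "homogenizing_dispersal"
  out[mid & abs(rc) <= 0.95] <- "drift"
  out
}

#' Full pairwise assembly analysis
#'
#' Computes beta-NTI and RC_bray on the table (regional pool and null
#' randomizations over the whole table's taxa) and classifies every sample
#' pair.
#'
#' @param x a [community_table()].
#' @param tree `phylo` or patristic distance matrix.
#' @param n_null null draws for both nulls.
#' @param seed integer seed (the RC null uses `seed + 1`).
#' @param abundance_weighted weighted beta-MNTD (default `TRUE`).
#' @return data.frame per unordered pair: `sample_a`, `sample_b`, `bmntd`,
#'   `bnti`, `rc`, `process`.
#' @export
assembly_pairs <- function(x, tree, n_null = 999, seed = NULL,
                           abundance_weighted = TRUE) {
  bn <- beta_nti(x, tree, n_null = n_null, seed = seed,
                 abundance_weighted = abundance_weighted)
  rc <- raup_crick_bray(x, n_null = n_null,
                        seed = if (is.null(seed)) NULL else seed + 1L)
  pr <- t(combn(nrow(x$counts), 2))
  ids <- rownames(x$counts)
  data.frame(sample_a = ids[pr[, 1]], sample_b = ids[pr[, 2]],
             bmntd = bn$bmntd[pr], bnti = bn$bnti[pr], rc = rc[pr],
             process = classify_pair(bn$bnti[pr], rc[pr]),
             stringsAsFactors = FALSE)
}

process_levels <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal", "drift")

#' Partition assembly processes by group
#'
#' Fractions of the five processes over the within-group sample pairs of
#' each group; the five fractions of a group sum to 1.
#'
#' @param pairs data.frame as returned by [assembly_pairs()] (needs columns
#'   `sample_a`, `sample_b`, `process`).
#' @param groups named character vector mapping sample id to group label.
#' @return data.frame: `group`, `n_pairs`, and one fraction column per
#'   process.
#' @export
partition_processes <- function(pairs, groups) {
  ga <- groups[pairs$sample_a]
  gb <- groups[pairs$sample_b]
  if (anyNA(ga) || anyNA(gb)) stop("groups must cover every sample in pairs")
  within <- pairs[ga == gb, , drop = FALSE]
  within$group <- ga[ga == gb]
  levs <- unique(groups)
  out <- lapply(levs, function(lev) {
    sub <- within[within$group == lev, , drop = FALSE]
    if (nrow(sub) == 0)
      stop("group with fewer than 2 samples: ", lev)
    fr <- table(factor(sub$process, levels = process_levels)) / nrow(sub)
    cbind(data.frame(group = lev, n_pairs = nrow(sub),
                     stringsAsFactors = FALSE),
          as.data.frame.matrix(t(as.matrix(fr))))
  })
  do.call(rbind, out)
}

#' Regress per-sample SES.MNTD on altitude
#'
#' @param ses data.frame from [ses_mntd()].
#' @param altitudes altitude per sample (aligned with `ses`).
#' @return a [gradient_regression()] fit.
#' @export
ses_vs_gradient <- function(ses, altitudes) {
  gradient_regression(ses$ses, altitudes)
}

#' Regress within-group beta-NTI on altitude
#'
#' Uses the within-group pairs (both samples at the same altitude) and
#' regresses their beta-NTI values on that altitude.
#'
#' @param pairs data.frame from [assembly_pairs()].
#' @param altitudes named numeric vector mapping sample id to altitude.
#' @return a [gradient_regression()] fit.
#' @export
bnti_vs_gradient <- function(pairs, altitudes) {
  aa <- altitudes[pairs$sample_a]
  ab <- altitudes[pairs$sample_b]
  keep <- is.finite(aa) & is.finite(ab) & aa == ab
  gradient_regression(pairs$bnti[keep], aa[keep])
}
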