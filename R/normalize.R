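#' Rarefy a community table to an even depth
#'
#' Subsamples each sample without replacement (hypergeometric draw) down to
#' `depth` reads, the convention used by QIIME-style pipelines when counts
#' are "normalized to the minimum number of sequences".
#'
#' @param x a [community_table()].
#' @param depth target reads per sample; defaults to the minimum sample sum.
#' @param seed integer seed for the subsampling draw (`NULL` uses the
#'   current RNG stream).
#' @param drop_shallow if `TRUE`, samples with fewer than `depth` reads are
#'   removed instead of raising an error.
#' @return a `community_table` in which every sample sums to exactly
#'   `depth`.
#' @export
rarefy <- function(x, depth = NULL, seed = NULL, drop_shallow = FALSE) {
  stopifnot(inherits(x, "community_table"))
  sums <- rowSums(x$counts)
  depth <- depth %||% min(sums)
  if (depth <= 0 || depth != round(depth)) stop("depth must be a positive integer")
  shallow <- sums < depth
  if (any(shallow)) {
    if (!drop_shallow)
      stop("depth exceeds the sum of sample(s): ",
           paste(head(rownames(x$counts)[shallow], 5), collapse = ", "),
           " (use drop_shallow = TRUE to remove them)")
    x <- subset_samples(x, !shallow)
  }
  counts <- x$counts
  nt <- ncol(counts)
  out <- with_seed_opt(seed, {
    t(apply(counts, 1, function(row) {
      pool <- rep.int(seq_len(nt), row)
      tabulate(sample(pool, depth), nbins = nt)
    }))
  })
  dimnames(out) <- dimnames(counts)
  community_table(out, x$metadata)
}

#' Good's coverage estimator
#'
#' Estimated fraction of reads belonging to observed taxa,
#' `1 - F1 / N`, where `F1` is the number of singleton taxa and `N` the
#' sample's read sum.
#'
#' @param x numeric count vector for one sample, or a [community_table()]
#'   (then a named per-sample vector is returned).
#' @return coverage in `[0, 1]`.
#' @examples
#' goods_coverage(c(1, 2, 3, 1))  # 1 - 2/7
#' @export
goods_coverage <- function(x) {
  if (inherits(x, "community_table"))
    return(apply(x$counts, 1, goods_coverage))
  if (sum(x) <= 0) stop("empty sample: coverage undefined")
  1 - sum(x == 1) / sum(x)
}

#' Filter taxa by prevalence
#'
#' Keeps taxa whose occurrence (count > 0) across samples strictly exceeds
#' `min_fraction` of the number of samples. The sample set is unchanged:
#' samples that end up with zero counts are retained (downstream distance
#' code is responsible for flagging them).
#'
#' @param x a [community_table()].
#' @param min_fraction prevalence threshold in `[0, 1)`; the comparison is
#'   strict (`>`), so with 10 samples and `min_fraction = 0.10` a taxon seen
#'   in exactly one sample is dropped.
#' @return a `community_table` with the retained taxa.
#' @export
filter_prevalence <- function(x, min_fraction = 0.10) {
  stopifnot(inherits(x, "community_table"))
  if (min_fraction < 0 || min_fraction >= 1)
    stop("min_fraction must be in [0, 1)")
  occ <- colMeans(x$counts > 0)
  replace_counts(x, x$counts[, occ > min_fraction, drop = FALSE])
}
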