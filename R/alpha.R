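#' Per-sample alpha diversity
#'
#' Computes, for every sample: observed richness, Shannon entropy
#' (`-sum p log p`, natural log by default), bias-corrected Chao1
#' (`S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, defined even when no doubletons
#' are present), and the Gini-Simpson index (`1 - sum p^2`).
#'
#' @param x a [community_table()] (typically rarefied first, so that
#'   richness estimates are comparable across samples).
#' @param log_base base of the Shannon logarithm (default `exp(1)`, nats).
#' @return data.frame with columns `sample_id`, `observed_richness`,
#'   `shannon`, `chao1`, `gini_simpson`.
#' @examples
#' \dontrun{alpha_diversity(rarefy(tab, seed = 1))}
#' @export
alpha_diversity <- function(x, log_base = exp(1)) {
  stopifnot(inherits(x, "community_table"))
  res <- t(apply(x$counts, 1, function(cts) {
    n <- sum(cts)
    if (n == 0) stop("empty sample")
    p <- cts[cts > 0] / n
    f1 <- sum(cts == 1)
    f2 <- sum(cts == 2)
    s_obs <- sum(cts > 0)
    c(observed_richness = s_obs,
      shannon = -sum(p * log(p, base = log_base)),
      chao1 = s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)),
      gini_simpson = 1 - sum(p^2))
  }))
  data.frame(sample_id = rownames(x$counts), res,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate a community table at a taxonomic rank
#'
#' Sums per-sample relative abundances within each group at `rank`, keeps
#' the `top_k` groups by mean relative abundance, and pools the rest into an
#' `"others"` bucket. Taxa without a lineage entry (or with an empty rank
#' string) are pooled as `"unclassified"`.
#'
#' @param x a [community_table()].
#' @param taxonomy data.frame with a `taxon_id` column and one column per
#'   rank (e.g. `kingdom` ... `genus`).
#' @param rank rank column to aggregate at.
#' @param top_k number of named groups to keep.
#' @return numeric matrix, samples x (top_k groups + `"others"`); rows sum
#'   to 1.
#' @export
aggregate_taxonomy <- function(x, taxonomy, rank, top_k = 5) {
  stopifnot(inherits(x, "community_table"))
  if (!rank %in% names(taxonomy)) stop("unknown rank: ", rank)
  lab <- taxonomy[[rank]][match(colnames(x$counts), taxonomy$taxon_id)]
  lab[is.na(lab) | !nzchar(lab)] <- "unclassified"
  rel <- rel_abund(x$counts)
  agg <- t(rowsum(t(rel), group = lab))            # samples x groups
  ord <- order(colMeans(agg), decreasing = TRUE)
  agg <- agg[, ord, drop = FALSE]
  top_k <- min(top_k, ncol(agg))
  keep <- agg[, seq_len(top_k), drop = FALSE]
  others <- if (ncol(agg) > top_k)
    rowSums(agg[, -seq_len(top_k), drop = FALSE]) else rep(0, nrow(agg))
  cbind(keep, others = others)
}

#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected H statistic with the chi-square approximation on k - 1
#' degrees of freedom. When every value is identical the statistic is
#' defined as 0 with p = 1.
#'
#' @param values numeric vector (e.g. per-sample relative abundance of one
#'   taxon).
#' @param groups group labels, same length as `values`.
#' @return list with `chi2`, `df`, `p_value`.
#' @export
kruskal_wallis_by_group <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(table(groups) == 0)) stop("empty group")
  if (length(values) < 5) stop("need total n >= 5")
  if (length(unique(values)) == 1)
    return(list(chi2 = 0, df = nlevels(groups) - 1L, p_value = 1))
  kt <- kruskal.test(values, groups)
  list(chi2 = unname(kt$statistic), df = unname(kt$parameter),
       p_value = kt$p.value)
}

#' Ordinary least-squares regression on a gradient
#'
#' Simple OLS of a per-sample quantity on altitude, with the usual two-sided
#' t-test on the slope.
#'
#' @param y response values.
#' @param x gradient values (e.g. altitude in m a.s.l.).
#' @return list of class `gradient_fit` with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`.
#' @export
gradient_regression <- function(y, x) {
  ok <- is.finite(y) & is.finite(x)
  y <- y[ok]; x <- x[ok]
  if (length(y) < 3) stop("need at least 3 observations")
  if (var(x) == 0) stop("zero variance in the gradient")
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fixtures trigger lm's perfect-fit warning
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = unname(sm$coefficients[2, 4]),
                 n = length(y)),
            class = "gradient_fit")
}

#' @export
print.gradient_fit <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): slope = %.6g, R2 = %.4f, p = %.4g\n",
              x$n, x$slope, x$r_squared, x$p_value))
  invisible(x)
}
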