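#' Per-taxon occurrence frequency and mean relative abundance
#'
#' The inputs of the Sloan neutral-model fit: `p_i` is the mean across
#' samples of the within-sample relative abundance, and `f_i` the fraction
#' of samples in which the taxon is detected (count > 0).
#'
#' @param x a [community_table()].
#' @param pooled if `TRUE`, compute `p_i` from pooled counts across samples
#'   instead of the mean of per-sample relative abundances.
#' @return data.frame with `taxon_id`, `p`, `f`.
#' @export
occurrence_abundance <- function(x, pooled = FALSE) {
  stopifnot(inherits(x, "community_table"))
  p <- if (pooled) {
    cs <- colSums(x$counts)
    cs / sum(cs)
  } else colMeans(rel_abund(x$counts))
  data.frame(taxon_id = colnames(x$counts), p = unname(p),
             f = unname(colMeans(x$counts > 0)),
             stringsAsFactors = FALSE)
}

sloan_pred <- function(p, Nm, d) 1 - pbeta(d, Nm * p, Nm * (1 - p))

wilson_interval <- function(p, n, level = 0.95) {
  z <- qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(center - half, 0), upper = pmin(center + half, 1))
}

#' Fit the Sloan neutral community model
#'
#' Predicted occurrence frequency for a taxon with metacommunity relative
#' abundance `p` is `F(p) = 1 - I_d(Nm p, Nm (1 - p))`, the upper tail at
#' the detection limit `d = 1/N` of the Beta stationary distribution of
#' local relative abundance. `Nm` is fitted by least squares of the observed
#' frequencies on `F(p)` (bounded one-parameter optimization), the migration
#' rate is `m = Nm / N` with `N` the mean sample read depth, and
#' `R2 = 1 - SSE/SST` (reported as-is, possibly negative). Taxa never
#' observed (`f = 0`) cannot contribute occurrence data and are excluded.
#' 95% bands around the prediction are Wilson score intervals at
#' `n = n_samples`.
#'
#' @param x a [community_table()] (at least 20 taxa with `p > 0`).
#' @param detection_limit override the detection limit `d` (default `1/N`).
#' @param ci_level confidence level of the prediction band.
#' @param pooled see [occurrence_abundance()].
#' @return object of class `sloan_fit`: list with `Nm`, `m`, `N`,
#'   `r_squared`, `detection_limit`, `n_samples`, `n_taxa`, and `taxa`
#'   (data.frame: `taxon_id`, `p`, `f`, `predicted`, `lower`, `upper`,
#'   `partition` in `above` / `neutral` / `below`).
#' @export
fit_sloan <- function(x, detection_limit = NULL, ci_level = 0.95,
                      pooled = FALSE) {
  stopifnot(inherits(x, "community_table"))
  N <- mean(rowSums(x$counts))
  d <- detection_limit %||% (1 / N)
  oa <- occurrence_abundance(x, pooled = pooled)
  oa <- oa[oa$f > 0 & oa$p > 0, , drop = FALSE]
  if (nrow(oa) < 20) stop("need at least 20 observed taxa to fit")
  if (all(oa$f == 1))
    warning("all occurrence frequencies are 1: fit is degenerate")

  sse <- function(log_nm) {
    pred <- sloan_pred(oa$p, exp(log_nm), d)
    sum((oa$f - pred)^2)
  }
  opt <- optimize(sse, interval = log(c(1e-3, 1e7)))
  Nm <- exp(opt$minimum)
  pred <- sloan_pred(oa$p, Nm, d)
  sst <- sum((oa$f - mean(oa$f))^2)
  r2 <- if (sst > 0) 1 - opt$objective / sst else NA_real_
  ci <- wilson_interval(pred, nrow(x$counts), ci_level)
  partition <- ifelse(oa$f > ci$upper, "above",
                      ifelse(oa$f < ci$lower, "below", "neutral"))
  taxa <- data.frame(oa, predicted = pred, lower = ci$lower,
                     upper = ci$upper, partition = partition,
                     stringsAsFactors = FALSE)
  structure(list(Nm = Nm, m = Nm / N, N = N, r_squared = r2,
                 detection_limit = d, n_samples = nrow(x$counts),
                 n_taxa = nrow(taxa), taxa = taxa),
            class = "sloan_fit")
}

#' @export
print.sloan_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral model fit: Nm = %.2f, m = %.4f, R2 = %.3f (%d taxa, %d samples)\n",
              x$Nm, x$m, x$r_squared, x$n_taxa, x$n_samples))
  tb <- table(factor(x$taxa$partition, levels = c("above", "neutral", "below")))
  cat("  partitions:", paste(names(tb), tb, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Neutral-model taxon partition labels
#'
#' @param fit a [fit_sloan()] result.
#' @return named character vector (`above` / `neutral` / `below`) per taxon.
#' @export
partition_taxa <- function(fit) {
  stopifnot(inherits(fit, "sloan_fit"))
  setNames(fit$taxa$partition, fit$taxa$taxon_id)
}

#' Fit the Sloan model within each sample group
#'
#' @param x a [community_table()].
#' @param by metadata columns defining the groups (default altitude and
#'   season, i.e. one fit per gradient level and season).
#' @param min_samples groups smaller than this are skipped with a warning.
#' @param ... passed to [fit_sloan()].
#' @return list with `fits` (named list of `sloan_fit`) and `summary`
#'   (data.frame: group, Nm, m, N, r_squared, taxon counts per partition).
#' @export
fit_by_group <- function(x, by = c("altitude", "season"), min_samples = 5,
                         ...) {
  stopifnot(inherits(x, "community_table"))
  grp <- sample_groups(x, by)
  fits <- list()
  for (lev in unique(grp)) {
    if (sum(grp == lev) < min_samples) {
      warning("group ", lev, " has fewer than ", min_samples,
              " samples: skipped")
      next
    }
    fits[[lev]] <- fit_sloan(subset_samples(x, grp == lev), ...)
  }
  summ <- do.call(rbind, lapply(names(fits), function(lev) {
    f <- fits[[lev]]
    tb <- table(factor(f$taxa$partition,
                       levels = c("above", "neutral", "below")))
    data.frame(group = lev, Nm = f$Nm, m = f$m, N = f$N,
               r_squared = f$r_squared, n_taxa = f$n_taxa,
               above = as.integer(tb["above"]),
               neutral = as.integer(tb["neutral"]),
               below = as.integer(tb["below"]),
               stringsAsFactors = FALSE)
  }))
  list(fits = fits, summary = summ)
}
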