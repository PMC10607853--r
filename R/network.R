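#' Pairwise Spearman correlations among taxa
#'
#' Tie-corrected Spearman r for every taxon pair (Pearson correlation of
#' mid-ranks across samples) with two-sided p-values from the t
#' approximation `t = r sqrt((n - 2) / (1 - r^2))`. By default taxa are
#' converted to per-sample relative abundances first; Spearman is computed
#' per taxon across samples, so this can change ranks relative to raw
#' counts.
#'
#' @param x a [community_table()] (prevalence-filter first, e.g.
#'   [filter_prevalence()] at 0.10) or a samples-by-taxa matrix.
#' @param use_relative correlate relative abundances (default) rather than
#'   raw counts.
#' @return list with matrices `r` and `p`; taxa constant across samples get
#'   `NA` rows/columns with a warning.
#' @export
spearman_matrix <- function(x, use_relative = TRUE) {
  m <- if (inherits(x, "community_table")) x$counts else as.matrix(x)
  n <- nrow(m)
  if (n < 5) stop("need at least 5 samples")
  if (use_relative) m <- rel_abund(m)
  constant <- apply(m, 2, function(v) length(unique(v)) == 1)
  if (any(constant))
    warning("taxa constant across samples excluded from correlations: ",
            paste(head(colnames(m)[constant], 5), collapse = ", "))
  rk <- apply(m, 2, rank)
  rk[, constant] <- NA_real_
  r <- suppressWarnings(cor(rk))
  r[!is.finite(r)] <- NA_real_
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  p[r == 1 | r == -1] <- 0
  diag(r) <- 1; diag(p) <- 0
  list(r = r, p = p, n_samples = n)
}

#' Build a Spearman co-occurrence network
#'
#' Edges are taxon pairs whose correlation passes both thresholds strictly:
#' `|r| > r_threshold` and `p < p_threshold` (no multiple-testing
#' correction, matching the conventional "robust correlation" rule). The
#' node set is the set of taxa with at least one passing edge, the way
#' network panels are usually reported.
#'
#' @param x a [community_table()] (prevalence-filtered) or matrix.
#' @param r_threshold correlation magnitude threshold (strict `>`).
#' @param p_threshold p-value threshold (strict `<`).
#' @param use_relative see [spearman_matrix()].
#' @param group_label optional label (e.g. `"3118.warm"`) carried on the
#'   network.
#' @return object of class `cooccurrence_network`: list with `nodes`
#'   (character), `edges` (data.frame `taxon_a`, `taxon_b`, `r`, `p`,
#'   `sign`), `group`, `n_samples`.
#' @export
build_network <- function(x, r_threshold = 0.5, p_threshold = 0.05,
                          use_relative = TRUE, group_label = NA_character_) {
  sp <- spearman_matrix(x, use_relative = use_relative)
  r <- sp$r; p <- sp$p
  ut <- upper.tri(r)
  pass <- ut & is.finite(r) & is.finite(p) &
    abs(r) > r_threshold & p < p_threshold
  idx <- which(pass, arr.ind = TRUE)
  edges <- data.frame(taxon_a = rownames(r)[idx[, 1]],
                      taxon_b = colnames(r)[idx[, 2]],
                      r = r[idx], p = p[idx],
                      sign = ifelse(r[idx] > 0, "positive", "negative"),
                      stringsAsFactors = FALSE)
  structure(list(nodes = sort(unique(c(edges$taxon_a, edges$taxon_b))),
                 edges = edges, group = group_label,
                 n_samples = sp$n_samples),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat("co-occurrence network", if (!is.na(x$group)) paste0("[", x$group, "]"),
      ":", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("taxon_a", "taxon_b")],
                                directed = FALSE,
                                vertices = net$nodes)
}

#' Topological statistics of a co-occurrence network
#'
#' Node/edge counts, positive and negative edge counts, their ratio
#' (reported as `NA` when there are no positive edges), mean degree, and
#' Newman modularity of the Louvain partition (resolution 1, fixed seed; the
#' default used by common network tools). Modularity is `NA` for an empty
#' edge set.
#'
#' @param net a [build_network()] result.
#' @param seed seed for the Louvain community detection.
#' @return data.frame (one row) with `group`, `n_nodes`, `n_edges`,
#'   `n_positive`, `n_negative`, `neg_pos_ratio`, `mean_degree`,
#'   `modularity`.
#' @export
topology <- function(net, seed = 1L) {
  stopifnot(inherits(net, "cooccurrence_network"))
  n_pos <- sum(net$edges$sign == "positive")
  n_neg <- sum(net$edges$sign == "negative")
  n_edges <- nrow(net$edges)
  n_nodes <- length(net$nodes)
  mod <- NA_real_
  if (n_edges > 0) {
    g <- as_igraph(net)
    cl <- with_seed_opt(seed, igraph::cluster_louvain(g, resolution = 1))
    mod <- igraph::modularity(g, igraph::membership(cl))
  }
  data.frame(group = net$group, n_nodes = n_nodes, n_edges = n_edges,
             n_positive = n_pos, n_negative = n_neg,
             neg_pos_ratio = if (n_pos > 0) n_neg / n_pos else NA_real_,
             mean_degree = if (n_nodes > 0) 2 * n_edges / n_nodes else NA_real_,
             modularity = mod, stringsAsFactors = FALSE)
}

#' Build one network per sample group
#'
#' Convenience wrapper: prevalence-filters and builds a network within each
#' altitude-by-season group, as in per-panel network figures.
#'
#' @param x a [community_table()].
#' @param by metadata columns defining the groups.
#' @param min_fraction prevalence threshold applied within each group.
#' @param ... passed to [build_network()].
#' @return named list of `cooccurrence_network` objects.
#' @export
networks_by_group <- function(x, by = c("altitude", "season"),
                              min_fraction = 0.10, ...) {
  stopifnot(inherits(x, "community_table"))
  grp <- sample_groups(x, by)
  out <- list()
  for (lev in unique(grp)) {
    sub <- subset_samples(x, grp == lev)
    sub <- filter_prevalence(sub, min_fraction)
    out[[lev]] <- build_network(sub, group_label = lev, ...)
  }
  out
}

#' Correlate topology metrics with the gradient
#'
#' Spearman correlation (with exact small-sample p-values where available
#' via [stats::cor.test()]) between each topology metric and altitude across
#' groups. Metrics constant across groups are flagged `NA`.
#'
#' @param stats_df row-bound [topology()] results (>= 4 groups).
#' @param altitudes altitude per row of `stats_df`.
#' @return data.frame with `metric`, `rho`, `p_value`.
#' @export
topology_vs_gradient <- function(stats_df, altitudes) {
  if (nrow(stats_df) < 4) stop("need at least 4 groups")
  metrics <- setdiff(names(stats_df), "group")
  out <- lapply(metrics, function(mt) {
    v <- stats_df[[mt]]
    ok <- is.finite(v) & is.finite(altitudes)
    if (sum(ok) < 4 || length(unique(v[ok])) == 1)
      return(data.frame(metric = mt, rho = NA_real_, p_value = NA_real_))
    ct <- suppressWarnings(cor.test(v[ok], altitudes[ok], method = "spearman"))
    data.frame(metric = mt, rho = unname(ct$estimate), p_value = ct$p.value)
  })
  do.call(rbind, out)
}

#' Export network edges as TSV
#'
#' @param net a [build_network()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  write.table(net$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a network as GraphML (Gephi-compatible)
#'
#' @param net a [build_network()] result (must have at least one edge).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::E(g)$r <- net$edges$r
  igraph::E(g)$sign <- net$edges$sign
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
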