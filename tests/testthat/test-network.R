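test_that("Spearman correlations match the hand-ranked formula", {
  m <- cbind(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5), z = 5:1)
  rownames(m) <- paste0("s", 1:5)
  sp <- spearman_matrix(m, use_relative = FALSE)
  expect_equal(sp$r["x", "y"], 0.8)            # 1 - 6*4/120
  expect_equal(sp$r["x", "z"], -1)             # perfectly anti-ranked
  expect_equal(diag(sp$r), setNames(rep(1, 3), colnames(m)))
  expect_equal(sp$p["x", "z"], 0)

  or <- spearman_brute(m[, "x"], m[, "y"])
  expect_equal(sp$p["x", "y"], or$p, tolerance = 1e-12)

  mc <- cbind(m, const = rep(1, 5))
  expect_warning(spc <- spearman_matrix(mc, use_relative = FALSE), "constant")
  expect_true(all(is.na(spc$r["const", c("x", "y", "z")])))
})

test_that("network edges require both thresholds strictly", {
  # 10 samples; construct taxa with known rank relations
  base <- c(3, 1, 4, 1, 5, 9, 2, 6, 8, 7)
  m <- cbind(t1 = base,
             t2 = base + withr::with_seed(1, rnorm(10, sd = 0.1)),  # r ~ 1
             t3 = -base,                                            # r = -1 with t1
             t4 = withr::with_seed(2, rnorm(10)))
  rownames(m) <- paste0("s", 1:10)
  net <- build_network(m, use_relative = FALSE)
  key <- paste(net$edges$taxon_a, net$edges$taxon_b)
  expect_true("t1 t2" %in% key)
  expect_true("t1 t3" %in% key)
  expect_equal(net$edges$sign[net$edges$taxon_a == "t1" &
                              net$edges$taxon_b == "t3"], "negative")

  # r = 0.49 with tiny p must not pass; r below threshold blocked even if
  # p passes (thresholds are a conjunction)
  net_hi <- build_network(m, r_threshold = 0.999, use_relative = FALSE)
  expect_true(!"t1 t2" %in% paste(net_hi$edges$taxon_a, net_hi$edges$taxon_b) ||
              abs(net_hi$edges$r[1]) > 0.999)

  # isolated taxa are not nodes
  expect_false("t4" %in% net$nodes)
})

test_that("edge set equals the brute-force double loop on random fixtures", {
  for (seed in 1:5) {
    rt <- random_table(10, 25, seed = 100 + seed, mu = 10)
    keep <- apply(rt$counts, 2, function(v) length(unique(v)) > 1)
    rel <- rt$counts[, keep] / rowSums(rt$counts)
    net <- suppressWarnings(build_network(rt))
    want <- character(0)
    cn <- colnames(rel)
    for (i in seq_len(ncol(rel) - 1)) for (j in (i + 1):ncol(rel)) {
      o <- spearman_brute(rel[, i], rel[, j])
      if (abs(o$r) > 0.5 && o$p < 0.05)
        want <- c(want, paste(sort(c(cn[i], cn[j])), collapse = " "))
    }
    got <- paste(net$edges$taxon_a, net$edges$taxon_b)
    expect_setequal(got, want)
  }
})

test_that("null (iid) taxa produce roughly the expected false-positive edges", {
  nt <- 150
  m <- withr::with_seed(7, matrix(rnorm(10 * nt), nrow = 10,
                                  dimnames = list(paste0("s", 1:10),
                                                  paste0("t", 1:nt))))
  net <- build_network(m, use_relative = FALSE)
  # Monte-Carlo estimate of the per-pair pass rate under independence
  pass <- withr::with_seed(8, {
    mean(vapply(seq_len(20000), function(i) {
      o <- spearman_brute(rnorm(10), rnorm(10))
      abs(o$r) > 0.5 && o$p < 0.05
    }, logical(1)))
  })
  expected <- pass * choose(nt, 2)
  expect_gt(nrow(net$edges), 0.5 * expected)
  expect_lt(nrow(net$edges), 2 * expected)
})

test_that("topology counts and modularity match hand values", {
  tri <- structure(list(
    nodes = c("a", "b", "c"),
    edges = data.frame(taxon_a = c("a", "a", "b"), taxon_b = c("b", "c", "c"),
                       r = c(0.9, 0.8, 0.7), p = c(0.01, 0.01, 0.01),
                       sign = "positive", stringsAsFactors = FALSE),
    group = "g", n_samples = 10), class = "cooccurrence_network")
  ts <- topology(tri, seed = 1)
  expect_equal(ts$n_nodes, 3)
  expect_equal(ts$n_edges, 3)
  expect_equal(ts$neg_pos_ratio, 0)
  expect_equal(ts$mean_degree, 2)

  # two disjoint 5-cliques: Louvain finds the cliques, Q = 0.5 exactly
  cl5 <- t(combn(5, 2))
  edges <- rbind(
    data.frame(taxon_a = paste0("x", cl5[, 1]), taxon_b = paste0("x", cl5[, 2])),
    data.frame(taxon_a = paste0("y", cl5[, 1]), taxon_b = paste0("y", cl5[, 2])))
  edges$r <- 0.9; edges$p <- 0.001; edges$sign <- "positive"
  two <- structure(list(nodes = sort(unique(c(edges$taxon_a, edges$taxon_b))),
                        edges = edges, group = "g", n_samples = 10),
                   class = "cooccurrence_network")
  ts2 <- topology(two, seed = 1)
  expect_equal(ts2$modularity, 0.5, tolerance = 1e-12)
  expect_true(is.na(topology(structure(list(nodes = character(0),
                                            edges = edges[0, ], group = "g",
                                            n_samples = 10),
                                       class = "cooccurrence_network"))$modularity))

  # ratio undefined (NA), not 0 or Inf, when no positive edges
  neg <- tri; neg$edges$sign <- "negative"
  expect_true(is.na(topology(neg)$neg_pos_ratio))
})

test_that("modularity equals the explicit Newman sum and is reproducible", {
  for (seed in 11:13) {
    rt <- random_table(12, 30, seed = seed, mu = 8)
    net <- suppressWarnings(build_network(rt))
    if (nrow(net$edges) == 0) next
    g <- igraph::graph_from_data_frame(net$edges[, 1:2], directed = FALSE,
                                       vertices = net$nodes)
    cl <- withr::with_seed(5L, igraph::cluster_louvain(g))
    memb <- setNames(as.vector(igraph::membership(cl)), net$nodes)
    expect_equal(igraph::modularity(g, igraph::membership(cl)),
                 modularity_brute(net$edges, memb), tolerance = 1e-10)
    expect_identical(topology(net, seed = 99)$modularity,
                     topology(net, seed = 99)$modularity)
  }
})

test_that("topology-gradient correlations use exact small-n p-values", {
  alts <- c(3118, 3363, 3550, 3945, 4343, 4761)
  stats_df <- data.frame(group = paste0("g", 1:6),
                         n_edges = c(60, 50, 40, 30, 20, 10),
                         n_nodes = rep(5, 6))
  tg <- topology_vs_gradient(stats_df, alts)
  expect_equal(tg$rho[tg$metric == "n_edges"], -1)
  # exact permutation p for rho = -1 at n = 6: 2 / 6!
  expect_equal(tg$p_value[tg$metric == "n_edges"], 2 / 720, tolerance = 1e-12)
  expect_true(is.na(tg$rho[tg$metric == "n_nodes"]))
  expect_error(topology_vs_gradient(stats_df[1:3, ], alts[1:3]), "at least 4")
})

test_that("per-group networks from a selection regime are power-sensitive", {
  sim <- simulate_study(assembly_scenario("variable_selection", n_taxa = 60,
                                          reads = 1000, samples_per_group = 10,
                                          seasons = "warm", seed = 77))
  nets10 <- suppressWarnings(networks_by_group(sim$table))
  # thin to 6 samples per group: fewer significant edges overall
  keep <- unlist(lapply(split(seq_len(120)[1:60],
                              sample_groups(sim$table)[1:60]), head, 6))
  thin <- subset_samples(sim$table, sort(keep))
  nets6 <- suppressWarnings(networks_by_group(thin))
  expect_gte(sum(vapply(nets10, function(n) nrow(n$edges), numeric(1))),
             sum(vapply(nets6, function(n) nrow(n$edges), numeric(1))))
})
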