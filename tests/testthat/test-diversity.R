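test_that("alpha indices match hand-derived values", {
  tab <- make_table(rbind(c(25L, 25L, 25L, 25L),
                          c(5L, 3L, 1L, 1L),
                          c(7L, 0L, 0L, 0L)))
  a <- alpha_diversity(tab)
  expect_equal(a$shannon[1], log(4))
  expect_equal(a$gini_simpson[1], 0.75)
  expect_equal(a$chao1[1], 4)
  expect_equal(a$chao1[2], 5.0)            # F1 = 2, F2 = 0, bias-corrected
  expect_equal(a[3, c("shannon", "gini_simpson", "chao1")],
               data.frame(shannon = 0, gini_simpson = 0, chao1 = 1, row.names = 3L))
  expect_true(all(a$chao1 >= a$observed_richness))
})

test_that("Bray-Curtis matches hand values and the brute-force oracle", {
  tab <- make_table(rbind(c(6L, 2L), c(2L, 2L), c(5L, 0L), c(0L, 5L)))
  d <- bray_curtis(tab)
  expect_equal(d[1, 2], 1 / 3)
  expect_equal(d[3, 4], 1)
  expect_equal(diag(d), setNames(rep(0, 4), rownames(tab$counts)))

  for (seed in 1:5) {
    rt <- random_table(sample(5:20, 1), sample(10:50, 1), seed = seed)
    expect_lt(max(abs(bray_curtis(rt) - bc_matrix_brute(rt$counts))), 1e-10)
  }
})

test_that("weighted UniFrac matches the per-branch oracle and phyloseq", {
  tr <- four_tip_tree()
  tab <- make_table(rbind(A_only = c(3L, 0L, 0L, 0L),
                          C_only = c(0L, 0L, 7L, 0L)))
  colnames(tab$counts) <- tr$tip.label
  raw <- weighted_unifrac(tab, tr, normalized = FALSE)
  expect_equal(raw[1, 2], 4.0)             # hand-summed branch terms
  expect_equal(weighted_unifrac(tab, tr)[1, 2], 1.0)

  for (seed in 6:10) {
    nt <- 10
    tr2 <- simulate_tree(nt, seed = seed)
    rt <- random_table(8, nt, seed = seed, taxon_ids = tr2$tip.label)
    wu <- weighted_unifrac(rt, tr2)
    expect_lt(max(abs(wu - wu_brute(rt$counts, tr2))), 1e-10)
    # column permutation invariance
    perm <- withr::with_seed(seed, sample(nt))
    rt_perm <- make_table(rt$counts[, perm], altitude = rt$metadata$altitude)
    expect_equal(weighted_unifrac(rt_perm, tr2), wu, tolerance = 1e-12)
  }

  # independent library oracle
  ps <- phyloseq::phyloseq(
    phyloseq::otu_table(random_table(6, 10, seed = 12,
                                     taxon_ids = simulate_tree(10, seed = 12)$tip.label)$counts,
                        taxa_are_rows = FALSE),
    phyloseq::phy_tree(simulate_tree(10, seed = 12)))
  rt <- random_table(6, 10, seed = 12,
                     taxon_ids = simulate_tree(10, seed = 12)$tip.label)
  wu_ps <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  expect_equal(unname(weighted_unifrac(rt, simulate_tree(10, seed = 12))),
               unname(wu_ps), tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(weighted_unifrac(make_table(rbind(c(1L, 1L), c(2L, 1L))), tr),
               "missing from tree")
})

test_that("PCoA recovers Euclidean configurations", {
  # points on a line: axis 1 carries everything, in input order
  d <- abs(outer(0:3, 0:3, "-"))
  dimnames(d) <- list(letters[1:4], letters[1:4])
  ord <- pcoa(d)
  expect_equal(ord$proportion[1], 1, tolerance = 1e-8)
  expect_equal(diff(ord$points[, 1]), rep(diff(ord$points[1:2, 1]), 3),
               tolerance = 1e-8, ignore_attr = TRUE)

  # distances reconstructed from coordinates for Euclidean input
  pts <- withr::with_seed(1, matrix(rnorm(20), 10, 2))
  d2 <- as.matrix(dist(pts))
  ord2 <- pcoa(d2)
  expect_lt(max(abs(as.matrix(dist(ord2$points)) - d2)), 1e-8)

  expect_error(pcoa(d[1:2, 1:2]), "at least 3")
})

test_that("PERMANOVA follows the Anderson conventions and matches vegan", {
  tab <- random_table(12, 20, seed = 20)
  grp <- rep(c("a", "b", "c"), each = 4)
  d <- bray_curtis(tab)
  pm <- permanova(d, grp, n_permutations = 199, seed = 1)

  df <- data.frame(grp = grp)
  ad <- vegan::adonis2(as.dist(d) ~ grp, data = df, permutations = 19)
  expect_equal(pm$f, ad$F[1], tolerance = 1e-10)
  expect_equal(pm$r_squared, ad$R2[1], tolerance = 1e-10)

  # F and R2 do not depend on the permutation count
  pm2 <- permanova(d, grp, n_permutations = 399, seed = 2)
  expect_equal(pm2$f, pm$f)
  expect_equal(pm2$r_squared, pm$r_squared)

  # perfect separation: p attains its permutation floor
  disj <- make_table(rbind(matrix(c(5L, 0L), 10, 2, byrow = TRUE),
                           matrix(c(0L, 5L), 10, 2, byrow = TRUE)))
  pmd <- permanova(bray_curtis(disj), rep(c("x", "y"), each = 10),
                   n_permutations = 99, seed = 3)
  expect_equal(pmd$p_value, 1 / 100)
  expect_error(permanova(d, c("a", rep("b", 11)), 99), "at least 2 samples")
})

test_that("within-group similarity is 1 - dissimilarity over within pairs", {
  tab <- make_table(rbind(c(5L, 0L), c(5L, 0L), c(0L, 4L), c(2L, 2L)))
  d <- bray_curtis(tab)
  ws <- within_group_similarity(d, c("g1", "g1", "g2", "g2"))
  expect_equal(ws$similarity[ws$group == "g1"], 1)
  expect_equal(ws$similarity[ws$group == "g2"],
               1 - d["s03", "s04"])
})

test_that("distance-decay recovers constructed and null relationships", {
  # exact linear fixture: similarity = 1 - dalt / 5000
  alts <- c(3118, 3363, 3550, 3945, 4343, 4761)
  n <- length(alts)
  d <- matrix(0, n, n, dimnames = list(paste0("s", 1:n), paste0("s", 1:n)))
  for (i in 1:n) for (j in 1:n) d[i, j] <- abs(alts[i] - alts[j]) / 5000
  dd <- distance_decay(d, alts)
  expect_equal(dd$slope, -1 / 5000, tolerance = 1e-12)
  expect_equal(dd$r_squared, 1, tolerance = 1e-12)

  # iid communities: slope centred on zero over 100 seeds
  slopes <- vapply(1:100, function(s) {
    rt <- random_table(10, 30, seed = 1000 + s)
    distance_decay(bray_curtis(rt),
                   withr::with_seed(2000 + s, runif(10, 3000, 5000)))$slope
  }, numeric(1))
  tt <- t.test(slopes)
  expect_gt(tt$p.value, 0.01)

  expect_error(distance_decay(d, rep(3118, n)), "all altitudes equal")
})

test_that("gradient regression handles exact, noisy, and degenerate input", {
  alt <- c(3118, 3363, 3550, 3945, 4343, 4761)
  fit <- gradient_regression(2 * alt + 5, alt)
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  expect_error(gradient_regression(1:5, rep(3118, 5)), "zero variance")
  expect_error(gradient_regression(1:2, 1:2), "at least 3")

  # 95% CI covers zero in >= 90/100 null replicates
  covered <- vapply(1:100, function(s) {
    ci <- withr::with_seed(s, {
      y <- rnorm(20)
      x <- runif(20, 3000, 5000)
      confint(lm(y ~ x))
    })
    ci[2, 1] < 0 && ci[2, 2] > 0
  }, logical(1))
  expect_gte(sum(covered), 90)
})

test_that("taxonomy aggregation produces closed relative abundances", {
  cts <- rbind(c(30L, 40L, 20L, 10L), c(10L, 10L, 40L, 40L))
  tab <- make_table(cts)
  taxm <- data.frame(taxon_id = colnames(tab$counts),
                     phylum = c("P1", "P1", "P2", "P3"),
                     stringsAsFactors = FALSE)
  agg <- aggregate_taxonomy(tab, taxm, "phylum", top_k = 2)
  expect_equal(rowSums(agg), c(s01 = 1, s02 = 1))
  expect_equal(unname(agg[1, "P1"]), 0.7)
  # top_k = number of groups -> empty "others"
  agg_all <- aggregate_taxonomy(tab, taxm, "phylum", top_k = 3)
  expect_equal(unname(agg_all[, "others"]), c(0, 0))
  expect_error(aggregate_taxonomy(tab, taxm, "order"), "unknown rank")
})

test_that("Kruskal-Wallis matches the hand-ranked oracle and null rate", {
  res <- kruskal_wallis_by_group(c(1, 2, 3, 10, 11, 12),
                                 rep(c("lo", "hi"), each = 3))
  expect_equal(res$chi2, 27 / 7, tolerance = 1e-10)   # hand-ranked H
  expect_equal(res$p_value, pchisq(27 / 7, 1, lower.tail = FALSE))

  same <- kruskal_wallis_by_group(rep(2, 6), rep(c("a", "b"), 3))
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)

  rej <- vapply(1:500, function(s) {
    withr::with_seed(s, kruskal_wallis_by_group(rnorm(15),
                                                rep(c("a", "b", "c"), 5))$p_value < 0.05)
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.10)
})
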