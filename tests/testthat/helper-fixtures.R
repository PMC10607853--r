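# fixtures built in code: small tables, trees, and random generators

four_tip_tree <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

make_md <- function(ids, altitude = 3118, season = "warm", site = "X") {
  data.frame(sample_id = ids, altitude = altitude, season = season,
             site = site, stringsAsFactors = FALSE)
}

make_table <- function(counts, altitude = NULL, season = "warm") {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("s%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("t%02d", seq_len(ncol(counts)))
  altitude <- altitude %||% rep(3118, nrow(counts))
  community_table(counts, make_md(rownames(counts), altitude, season))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random count table with no empty samples
random_table <- function(n_samples, n_taxa, seed, mu = 5, size = 0.5,
                         taxon_ids = NULL) {
  withr::with_seed(seed, {
    m <- matrix(rnbinom(n_samples * n_taxa, mu = mu, size = size),
                nrow = n_samples)
    empty <- rowSums(m) == 0
    m[empty, 1] <- 1L
    colnames(m) <- taxon_ids %||% sprintf("t%02d", seq_len(n_taxa))
    rownames(m) <- sprintf("s%02d", seq_len(n_samples))
    make_table(m, altitude = sample(c(3118, 3363, 3550, 3945), n_samples,
                                    replace = TRUE))
  })
}

process_levels5 <- c("variable_selection", "homogeneous_selection",
                     "dispersal_limitation", "homogenizing_dispersal", "drift")
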