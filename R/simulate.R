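#' Simulate an ultrametric Yule phylogeny
#'
#' Pure-birth tree with `n_tips` extant tips, relabelled `ASV_0001`,
#' `ASV_0002`, ... All phylogenetic null models in the package operate on
#' such trees (or on any rooted `phylo` with branch lengths).
#'
#' @param n_tips number of tips (at least 4).
#' @param birth_rate speciation rate of the pure-birth process.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return an `ape::phylo` object, rooted and ultrametric.
#' @export
simulate_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 4) stop("n_tips must be at least 4")
  tr <- with_seed_opt(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  tr$tip.label <- sprintf("ASV_%04d", seq_len(n_tips))
  tr
}

#' Simulate a lognormal metacommunity abundance profile
#'
#' Relative abundances are drawn i.i.d. lognormal(0, sigma^2) and
#' normalized; the lognormal species-abundance distribution is the standard
#' description of rank-abundance structure in microbial surveys.
#'
#' @param n_taxa number of taxa (at least 4).
#' @param sigma lognormal shape on the log scale; larger values give steeper
#'   rank-abundance curves (sigma = 0 degenerates to the uniform profile).
#' @param seed integer seed.
#' @param taxon_ids optional taxon labels (default `ASV_0001`...).
#' @return object of class `metacommunity`: list with `taxon_ids`, relative
#'   abundances `p` (summing to 1), and the generating parameters.
#' @export
simulate_metacommunity <- function(n_taxa, sigma = 2, seed = NULL,
                                   taxon_ids = NULL) {
  if (n_taxa < 4) stop("n_taxa must be at least 4")
  if (sigma < 0) stop("sigma must be non-negative")
  p <- with_seed_opt(seed, rlnorm(n_taxa, meanlog = 0, sdlog = sigma))
  p <- p / sum(p)
  structure(list(taxon_ids = taxon_ids %||% sprintf("ASV_%04d", seq_len(n_taxa)),
                 p = p, distribution = "lognormal", sigma = sigma),
            class = "metacommunity")
}

#' @export
print.metacommunity <- function(x, ...) {
  cat("metacommunity:", length(x$p), "taxa,", x$distribution,
      "(sigma =", x$sigma, ")\n")
  invisible(x)
}

default_md <- function(sample_ids, altitude, season, site) {
  data.frame(sample_id = sample_ids, altitude = altitude,
             season = season, site = site, stringsAsFactors = FALSE)
}

#' Simulate neutral local communities (Sloan stationary distribution)
#'
#' Each sample's composition is drawn from a Dirichlet with concentration
#' `N * m * p_i` and then `N` reads are drawn multinomially. The marginal
#' per-taxon relative abundance is therefore Beta(Nmp, Nm(1-p)) before read
#' sampling — exactly the stationary distribution assumed by the Sloan
#' neutral-model fit, which makes recovery of `m` a clean end-to-end test.
#'
#' @param meta a [simulate_metacommunity()] profile.
#' @param m migration rate in (0, 1]; smaller values give more drift
#'   (larger between-sample variance).
#' @param N reads per sample (>= 100).
#' @param n_samples number of samples (>= 5).
#' @param seed integer seed.
#' @param altitude,season,site metadata applied to every sample.
#' @param sample_ids optional sample labels.
#' @return a [community_table()]; every row sums to `N`, and taxa with zero
#'   total count are retained in the taxon set.
#' @export
simulate_neutral_samples <- function(meta, m, N, n_samples, seed = NULL,
                                     altitude = 3118, season = "warm",
                                     site = "sim", sample_ids = NULL) {
  stopifnot(inherits(meta, "metacommunity"))
  if (m <= 0 || m > 1) stop("m must be in (0, 1]")
  if (N < 100) stop("N must be at least 100")
  if (n_samples < 5) stop("n_samples must be at least 5")
  alpha <- N * m * meta$p
  counts <- with_seed_opt(seed, {
    t(vapply(seq_len(n_samples), function(i) {
      g <- rgamma(length(alpha), shape = alpha)
      if (sum(g) == 0) g[which.max(alpha)] <- 1  # underflow guard
      as.integer(rmultinom(1, N, prob = g / sum(g)))
    }, integer(length(alpha))))
  })
  rownames(counts) <- sample_ids %||% sprintf("N%03d", seq_len(n_samples))
  colnames(counts) <- meta$taxon_ids
  community_table(counts, default_md(rownames(counts), altitude, season, site))
}

#' Brownian-motion trait values on a tree
#'
#' @param tree `phylo` object.
#' @param rate Brownian rate (variance per unit branch length).
#' @param seed integer seed.
#' @return named numeric vector of tip trait values.
#' @export
simulate_traits <- function(tree, rate = 1, seed = NULL) {
  with_seed_opt(seed, ape::rTraitCont(tree, model = "BM", sigma = sqrt(rate)))
}

#' Simulate communities under environmental selection
#'
#' Each taxon carries a Brownian trait on the phylogeny; a sample whose
#' environment has optimum `optimum` draws its `reads` reads multinomially
#' with weights `w_i` proportional to `p_i * exp(-s * (trait_i - optimum)^2)`.
#' With `s = 0` this reduces to neutral multinomial sampling from the
#' metacommunity (no Dirichlet stage). Because the trait is phylogenetically
#' conserved, strong selection toward a shared optimum produces
#' phylogenetically clustered communities (negative SES.MNTD / beta-NTI).
#'
#' @param meta a [simulate_metacommunity()] profile.
#' @param traits named trait vector over `meta$taxon_ids`, as from
#'   [simulate_traits()].
#' @param s selection strength (>= 0).
#' @param optimum environmental optimum; scalar (shared by all samples) or a
#'   vector of length `n_samples`.
#' @param reads reads per sample.
#' @param n_samples number of samples (>= 5).
#' @param seed integer seed.
#' @param altitude,season,site metadata applied to every sample.
#' @param sample_ids optional sample labels.
#' @return a [community_table()].
#' @export
simulate_selected_samples <- function(meta, traits, s, optimum, reads,
                                      n_samples, seed = NULL,
                                      altitude = 3118, season = "warm",
                                      site = "sim", sample_ids = NULL) {
  stopifnot(inherits(meta, "metacommunity"))
  if (s < 0) stop("selection strength s must be non-negative")
  if (n_samples < 5) stop("n_samples must be at least 5")
  traits <- traits[meta$taxon_ids]
  if (anyNA(traits)) stop("traits missing for some taxa")
  optimum <- rep_len(optimum, n_samples)
  counts <- with_seed_opt(seed, {
    t(vapply(seq_len(n_samples), function(i) {
      lw <- log(meta$p) - s * (traits - optimum[i])^2
      w <- exp(lw - max(lw))
      as.integer(rmultinom(1, reads, prob = w / sum(w)))
    }, integer(length(meta$p))))
  })
  rownames(counts) <- sample_ids %||% sprintf("S%03d", seq_len(n_samples))
  colnames(counts) <- meta$taxon_ids
  community_table(counts, default_md(rownames(counts), altitude, season, site))
}

#' Describe a simulated study design
#'
#' Bundles the parameters of [simulate_study()]: the assembly regime, the
#' migration rate, read depth, richness, selection parameters, and the
#' altitude-by-season group design (defaults mirror a 6-altitude x 2-season
#' survey with ten samples per group).
#'
#' @param regime one of `"neutral_drift"`, `"homogeneous_selection"`,
#'   `"variable_selection"`, `"dispersal_limitation"`, `"mixed"` (`"mixed"`
#'   applies homogeneous selection whose strength increases linearly with
#'   altitude rank, from 0 at the lowest altitude).
#' @param m migration rate in (0, 1]; either a scalar or a vector named by
#'   season (e.g. `c(warm = 0.1, cold = 0.3)`).
#' @param reads reads per sample.
#' @param n_taxa metacommunity richness.
#' @param sigma lognormal shape of the metacommunity.
#' @param s selection strength for the selection regimes.
#' @param bm_rate Brownian rate of trait evolution.
#' @param altitudes altitude levels (m a.s.l.).
#' @param seasons subset of `c("warm", "cold")`.
#' @param samples_per_group samples per altitude-season group.
#' @param dispersal_keep fraction of metacommunity taxa available to each
#'   group under dispersal limitation.
#' @param m_dispersal migration rate used under dispersal limitation.
#' @param seed master seed.
#' @return list of class `assembly_scenario`.
#' @export
assembly_scenario <- function(regime = c("neutral_drift", "homogeneous_selection",
                                         "variable_selection",
                                         "dispersal_limitation", "mixed"),
                              m = 0.1, reads = 2000, n_taxa = 300, sigma = 2,
                              s = 10, bm_rate = 1,
                              altitudes = c(3118, 3363, 3550, 3945, 4343, 4761),
                              seasons = c("warm", "cold"),
                              samples_per_group = 10,
                              dispersal_keep = 0.6, m_dispersal = 0.02,
                              seed = 20230) {
  regime <- match.arg(regime)
  if (any(m <= 0 | m > 1)) stop("m must be in (0, 1]")
  if (regime %in% c("homogeneous_selection", "variable_selection") && s <= 0)
    stop("selection regimes require s > 0")
  seasons <- match.arg(seasons, c("warm", "cold"), several.ok = TRUE)
  structure(list(regime = regime, m = m, reads = reads, n_taxa = n_taxa,
                 sigma = sigma, s = s, bm_rate = bm_rate,
                 altitudes = altitudes, seasons = seasons,
                 samples_per_group = samples_per_group,
                 dispersal_keep = dispersal_keep, m_dispersal = m_dispersal,
                 seed = seed),
            class = "assembly_scenario")
}

m_for_season <- function(m, season) {
  if (length(m) > 1) {
    if (is.null(names(m)) || !season %in% names(m))
      stop("season-specific m must be named by season")
    unname(m[[season]])
  } else unname(m)
}

#' Simulate a full altitude-by-season study under a known assembly regime
#'
#' Generates one phylogeny, one metacommunity, Brownian traits, and a
#' community table covering every altitude-season group of the scenario.
#' The regime determines how each group is assembled:
#' \describe{
#'   \item{neutral_drift}{Dirichlet-multinomial sampling from the shared
#'     metacommunity with migration rate `m` (Sloan stationary model).}
#'   \item{homogeneous_selection}{Gaussian selection of strength `s` toward
#'     one optimum shared by all groups: the 90th-percentile tip trait, an
#'     upper-tail value whose neighbourhood is phylogenetically coherent, so
#'     the favoured taxa form a clade (a median optimum would select a
#'     phylogenetically scattered set and blur the clustering signature).}
#'   \item{variable_selection}{as above, but the optimum moves linearly in
#'     altitude rank between the 10% and 90% trait quantiles.}
#'   \item{dispersal_limitation}{each altitude group sees its own jackknifed
#'     subset (`dispersal_keep`) of the metacommunity, sampled with the
#'     small migration rate `m_dispersal`.}
#'   \item{mixed}{homogeneous selection with strength growing linearly in
#'     altitude rank from 0 (neutral) to `s`.}
#' }
#'
#' @param scenario an [assembly_scenario()].
#' @return list with `table` (a [community_table()]), `tree`,
#'   `metacommunity`, `traits`, and `truth` (the regime and parameters, for
#'   ground-truth tests).
#' @export
simulate_study <- function(scenario = assembly_scenario()) {
  stopifnot(inherits(scenario, "assembly_scenario"))
  sc <- scenario
  seed0 <- as.integer(sc$seed)
  tree <- simulate_tree(sc$n_taxa, birth_rate = 1, seed = seed0 + 1L)
  meta <- simulate_metacommunity(sc$n_taxa, sigma = sc$sigma, seed = seed0 + 2L,
                                 taxon_ids = tree$tip.label)
  traits <- simulate_traits(tree, rate = sc$bm_rate, seed = seed0 + 3L)

  ranks <- rank(sc$altitudes)
  n_ranks <- length(sc$altitudes)
  qs <- quantile(traits, c(0.1, 0.9), names = FALSE)
  opt_for_rank <- function(r) {
    if (n_ranks == 1) median(traits)
    else qs[1] + (r - 1) / (n_ranks - 1) * (qs[2] - qs[1])
  }

  tabs <- list()
  k <- 0L
  for (season in sc$seasons) {
    for (gi in seq_along(sc$altitudes)) {
      k <- k + 1L
      alt <- sc$altitudes[gi]
      gseed <- seed0 + 100L + k
      ids <- sprintf("A%d_%s_%02d", alt, season, seq_len(sc$samples_per_group))
      site <- paste0("site_", alt)
      tab <- switch(sc$regime,
        neutral_drift = simulate_neutral_samples(
          meta, m = m_for_season(sc$m, season), N = sc$reads,
          n_samples = sc$samples_per_group, seed = gseed,
          altitude = alt, season = season, site = site, sample_ids = ids),
        homogeneous_selection = simulate_selected_samples(
          meta, traits, s = sc$s, optimum = qs[2], reads = sc$reads,
          n_samples = sc$samples_per_group, seed = gseed,
          altitude = alt, season = season, site = site, sample_ids = ids),
        variable_selection = simulate_selected_samples(
          meta, traits, s = sc$s, optimum = opt_for_rank(ranks[gi]),
          reads = sc$reads, n_samples = sc$samples_per_group, seed = gseed,
          altitude = alt, season = season, site = site, sample_ids = ids),
        dispersal_limitation = {
          meta_g <- with_seed_opt(seed0 + 500L + gi, {
            keep <- sample(length(meta$p), round(sc$dispersal_keep * length(meta$p)))
            p <- meta$p
            p[-keep] <- 0
            m2 <- meta
            m2$p <- p / sum(p)
            m2
          })
          # zero-abundance taxa get Dirichlet weight 0 and stay in the taxon set
          simulate_neutral_samples(
            meta_g, m = sc$m_dispersal, N = sc$reads,
            n_samples = sc$samples_per_group, seed = gseed,
            altitude = alt, season = season, site = site, sample_ids = ids)
        },
        mixed = simulate_selected_samples(
          meta, traits, s = sc$s * (ranks[gi] - 1) / max(1, n_ranks - 1),
          optimum = qs[2], reads = sc$reads,
          n_samples = sc$samples_per_group, seed = gseed,
          altitude = alt, season = season, site = site, sample_ids = ids)
      )
      tabs[[k]] <- tab
    }
  }
  counts <- do.call(rbind, lapply(tabs, function(t) t$counts))
  md <- do.call(rbind, lapply(tabs, function(t) t$metadata))
  list(table = community_table(counts, md),
       tree = tree, metacommunity = meta, traits = traits,
       truth = list(regime = sc$regime, m = sc$m, reads = sc$reads,
                    n_taxa = sc$n_taxa, sigma = sc$sigma, s = sc$s,
                    bm_rate = sc$bm_rate, altitudes = sc$altitudes,
                    seasons = sc$seasons,
                    samples_per_group = sc$samples_per_group,
                    seed = sc$seed))
}
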