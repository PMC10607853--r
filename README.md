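# assemblyscope

Tools for asking, of a microbial community survey along an environmental
gradient, the ecologist's central question: **how much of community
structure is built by deterministic selection, and how much by dispersal
and chance?** The package was written for amplicon (ASV-level) surveys of
host-associated or environmental microbiomes sampled across gradient levels
(here, altitude bands crossed with season), and bundles the standard
community-assembly toolkit into one tested codebase:

- **Diversity**: Shannon, bias-corrected Chao1, Gini–Simpson; Bray–Curtis
  and weighted UniFrac distances; PCoA; one-way PERMANOVA; within-group
  similarity and distance–decay regressions along the gradient.
- **Co-occurrence networks**: per-group Spearman networks thresholded at
  |r| > 0.5 and p < 0.05 on prevalence-filtered taxa (> 10% of samples),
  with node/edge counts, positive:negative edge structure and Louvain
  modularity, plus Spearman correlations of each topology metric with the
  gradient.
- **Phylogenetic null models**: SES.MNTD per sample and beta-NTI per sample
  pair under taxa-label shuffling nulls; the Bray–Curtis Raup–Crick null
  (RC_bray); and the five-way partition of sample pairs into variable
  selection, homogeneous selection, dispersal limitation, homogenizing
  dispersal and drift:

  | betaNTI | RC_bray | process |
  |---|---|---|
  | > +2 | — | variable selection |
  | < −2 | — | homogeneous selection |
  | in [−2, +2] | > +0.95 | dispersal limitation |
  | in [−2, +2] | < −0.95 | homogenizing dispersal |
  | in [−2, +2] | in [−0.95, +0.95] | drift |

- **Sloan neutral model**: the occurrence-frequency curve
  `F(p) = 1 − I_{1/N}(Nm·p, Nm·(1−p))` fitted by least squares to per-taxon
  (mean relative abundance, occurrence frequency) data, yielding the
  migration rate `m`, the fit `R²`, and an above/neutral/below taxon
  partition against the 95% Wilson band.
- **Synthetic data**: a simulator that emits a full 6-altitude × 2-season
  study (Yule phylogeny, lognormal metacommunity, ~10 samples per group)
  under a *known* assembly regime — neutral drift (Dirichlet-multinomial,
  the Sloan stationary distribution), homogeneous/variable selection
  (Gaussian selection on Brownian traits), or dispersal limitation — so
  every downstream stage can be validated against ground truth.

## Worked example

Simulate a neutral-drift study and ask the package whether it can tell:

```r
library(assemblyscope)

sim <- simulate_study(assembly_scenario("neutral_drift", m = 0.1,
                                        reads = 2000, n_taxa = 120,
                                        samples_per_group = 8,
                                        seasons = "warm", seed = 42))
tab <- sim$table

alpha <- alpha_diversity(tab)
gradient_regression(alpha$shannon, tab$metadata$altitude)
#> OLS fit (n = 48): slope = 6.24925e-05, R2 = 0.1108, p = 0.02082

ses <- ses_mntd(tab, sim$tree, n_null = 199, seed = 42)
mean(abs(ses$ses) < 2, na.rm = TRUE)
#> [1] 1

pairs <- assembly_pairs(tab, sim$tree, n_null = 199, seed = 42)
grp <- setNames(sample_groups(tab, "altitude"), rownames(tab$counts))
partition_processes(pairs, grp)[1:3, c("group", "n_pairs", "drift")]
#>   group n_pairs     drift
#> 1  3118      28 0.9642857
#> 2  3363      28 1.0000000
#> 3  3550      28 1.0000000

fit_sloan(tab)
#> Sloan neutral model fit: Nm = 272.88, m = 0.1364, R2 = 0.969 (104 taxa, 48 samples)
#>   partitions: above = 15, neutral = 85, below = 4
```

Reading the output: every sample's SES.MNTD sits inside ±2 (no
phylogenetic signal of selection), drift is the modal process in every
altitude group, and the communities fit the neutral curve with R² ≈ 0.97 —
the analysis correctly reports a stochastically assembled system. The
fitted `m` (0.136) overshoots the generating value (0.1) by the known
detection-limit bias of the Sloan fit discussed in the methods vignette.
The weak positive Shannon–altitude slope is sampling noise under this
regime (p = 0.02 at face value; no multiplicity control).

## Command line

```sh
assemblyscope simulate --regime neutral_drift --m 0.1 --reads 2000 \
    --taxa 300 --samples-per-group 10 --seed 20230 --out-dir sim/
assemblyscope diversity  --counts sim/counts.tsv --metadata sim/metadata.tsv \
    --tree sim/tree.nwk --out-dir div/
assemblyscope network    --counts sim/counts.tsv --metadata sim/metadata.tsv --out-dir net/
assemblyscope nullmodels --counts sim/counts.tsv --metadata sim/metadata.tsv \
    --tree sim/tree.nwk --n-null 999 --out-dir null/
assemblyscope neutral    --counts sim/counts.tsv --metadata sim/metadata.tsv --out-dir fit/
```

All commands accept `--seed` (default 20230) and are byte-reproducible
under a fixed seed. The launcher script is installed at
`inst/scripts/assemblyscope`.

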