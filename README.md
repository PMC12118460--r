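# anthosphere

Community-assembly analysis for flower (anthosphere) and pollinator
microbiomes, built for 16S ASV count tables from cultivation surveys and
pollinator-exclusion experiments.

Flower microbiomes are short-lived, pollinator-visited communities whose
diversity and stability respond strongly to how intensively a crop is
managed. This package provides, in one tested toolbox, the statistics
such studies run:

* **Filtering and normalisation** of ASV tables: organellar removal,
  length filtering (> 260 bases), the 500-read sample floor, relative
  abundances, seeded rarefaction, genus aggregation.
* **Alpha diversity** — richness, inverse Simpson
  `1 / Σ p²`, analytic (hypergeometric) rarefaction curves — with
  Kruskal–Wallis + Dunn (Bonferroni) and exact Wilcoxon group tests.
* **Beta diversity** — Bray–Curtis `BC = 1 − Σ min(p_j, p_k)` on
  relative abundances, PCoA, **sequential (Type-I) PERMANOVA** with
  permutation p-values `p = (1 + #{F* ≥ F}) / (1 + n_perm)` (exact
  enumeration for tiny n), multivariate dispersion (PERMDISP) and
  distance-based RDA for numeric covariates such as cultivation area.
* **Core microbiome** by the occupancy–abundance elbow: taxa ranked by
  `o_i + p_i / max p`, cumulative Bray–Curtis similarity curve, core =
  last rank with ≥ 2% relative gain.
* **Sloan neutral model**: occupancy predicted from metacommunity
  abundance via `π ~ Beta(Nmp, Nm(1−p))`; migration parameter `m̂` by
  bounded least squares, generalised `R²` (can be negative), RMSE, and
  an above/neutral/below partition from Wilson 95% intervals.
* **Pollinator→flower transfer index**: per flower, the proportion of
  its ASVs with > 3 reads that also occur on foragers of the same
  environment; plus per-taxon Fisher prevalence contrasts.
* **Seeded Dirichlet-multinomial simulators** (`gen_neutral`,
  `gen_grouped`, `gen_flower_forager`, `gen_planted_core`, `gen_study`)
  whose ground truth (migration, effect sizes, planted cores, sharing
  fractions) validates every stage.
* A **configuration-driven pipeline** (`run_pipeline()` + a thin CLI in
  `inst/scripts/anthosphere-cli.R`) that writes a structured TSV/JSON
  report with a manifest and log.

## Worked example

Simulate a four-environment study with known ground truth (planted
migration wild 0.4 > open_field 0.2 > tunnel 0.08 > greenhouse 0.05,
planted transfer sharing 0.4, sub-500-read decoy samples), then run the
main analyses:

```r
library(anthosphere)

sim  <- gen_study(seed = 42)
filt <- filter_dataset(sim$table, min_reads = 500, drop_organellar = FALSE)
length(filt$report$low_depth_samples)   # 8 decoy samples removed

flowers <- sim$meta$sample_id[sim$meta$role == "flower" &
                              sim$meta$sample_id %in% sample_ids(filt$table)]
ftab <- subset_table(filt$table, samples = sample_ids(filt$table) %in% flowers)

head(alpha_diversity(ftab), 3)
#>    sample_id richness  simpson inverse_simpson
#>  wild_FL001       68 0.047098        21.23232
#>  wild_FL002       65 0.049360        20.25932
#>  wild_FL003       68 0.049420        20.23472

D <- bray_curtis(ftab)
permanova(D, sim$meta, terms = c("environment", "netted", "farmer"),
          n_perm = 999, seed = 42)
#> <permanova_table> 60 samples, 999 permutations
#>         term df       SS       R2       F     p
#>  environment  3 18.37335 0.835256 95.2990 0.001
#>       netted  1  0.06332 0.002879  0.9853 0.417
#>       farmer  3  0.21880 0.009947  1.1349 0.317
#>     Residual 52  3.34181 0.151919      NA    NA
#>        Total 59 21.99728 1.000000      NA    NA
```

The planted environment effect dominates (R² = 0.84, p = 0.001);
netting and farmer, which the generator left null, stay at noise level.
Dispersion, core detection and the neutral fit on the wild flowers:

```r
env <- setNames(sim$meta$environment[match(sample_ids(ftab),
                                           sim$meta$sample_id)],
                sample_ids(ftab))
dispersion(D, env)
#> <dispersion_result> center = spatial_median, F = 94.63, p = 6.55e-22
#> greenhouse open_field     tunnel       wild
#>     0.3430     0.1888     0.2419     0.1619

wild <- subset_table(ftab, samples = env == "wild")
core_by_elbow(wild)
#> <core_result> 13 core taxa of 159 (elbow at rank 13, threshold 0.02)

fit_neutral(wild, N = 500, seed = 42)
#> <neutral_fit> m = 0.6877, N = 500, R2 = 0.954, RMSE = 0.0727 (146 taxa, 15 samples)
#>   partition: above=16, below=1, neutral=129
```

The 13-taxon core contains the 10 planted core taxa; low-migration
environments (tunnel, greenhouse) yield smaller `m̂` in the same
ordering as planted. (`m̂` exceeds the planted 0.4 by the depth ratio:
the model depends on `N·m` only, and these samples were generated at
1000 reads then rarefied to N = 500 — see the methods vignette.)

```r
tr <- transfer_index(filt$table, sim$meta)   # planted sharing s = 0.4
tr$summary
#>  environment n_flowers mean_index min_index
#>   greenhouse        15     0.3637    0.2812
#>   open_field        15     0.3804    0.3095
#>       tunnel        15     0.3560    0.2667
#>         wild        15     0.3463    0.2727
```

The full pipeline over a YAML config:

```sh
Rscript inst/scripts/anthosphere-cli.R simulate --seed 5 --out sim/
Rscript inst/scripts/anthosphere-cli.R run --config config.yaml
```

writes `alpha.tsv`, `permanova.tsv`, `dispersion.tsv`,
`core_<env>.tsv`, `neutral_<env>.json`, `transfer.tsv`,
`prevalence.tsv`, a manifest and a log; identical config + seed gives
byte-identical outputs.

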