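---
title: "Methods: community assembly analysis of flower and pollinator microbiomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community assembly analysis of flower and pollinator microbiomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthosphere)
```

# Scope and data model

`anthosphere` analyses amplicon sequence variant (ASV) count tables from
flower (anthosphere) and pollinator microbiome surveys: which taxa make
up the recurring core of a flower community, how closely community
assembly follows neutral expectation, how cultivation factors structure
composition and spread, and how much of a flower's community is shared
with the pollinators foraging around it.

The central container is the `count_table`: taxa in rows, samples in
columns, integer read counts (or, after `to_relative()`, within-sample
proportions), with optional per-taxon taxonomy and representative
sequences. Sample metadata travels in a `sample_frame` with controlled
vocabularies for the sample `role` (flower, forager, hive_bee,
nurse_bee, pupa) and `environment` (wild, open_field, tunnel,
greenhouse); missing questionnaire fields stay `NA`, never zero.

## Quality filtering

`filter_dataset()` applies the filters customary for 16S flower
surveys, in a fixed order whose sequence matters:

1. organellar taxa are removed — any rank label matching
   "chloroplast" or "mitochondri", case-insensitively, which is robust
   to where different reference databases place those labels;
2. taxa whose representative sequence exceeds 260 bases are removed
   (off-target length for the V4 region);
3. samples whose *remaining* reads fall strictly below 500 are
   discarded — a flower sample dominated by chloroplast reads is
   correctly discarded only if organellar removal runs first;
4. taxa left without any reads are dropped.

A report of everything dropped is returned alongside the table, and the
pipeline writes it out, so filtering is auditable.

Rarefaction (`rarefy()`) subsamples each sample without replacement to
an exact common depth and is fully determined by its seed. All
stochastic operations in the package take an explicit seed; nothing
consumes global random state without restoring it.

Genus-level aggregation (`aggregate_by_rank()`) drops taxa unassigned
at the target rank rather than inventing an "unclassified" bin;
prevalence tests at genus level therefore speak only for classified
reads, and the exclusions are reported.

# Diversity

Alpha diversity is observed richness and the inverse Simpson index
$1/\sum_i p_i^2$, the effective number of equally abundant taxa.
Analytic rarefaction curves use the exact hypergeometric expectation
$E[S_d] = \sum_i [1 - \binom{T-x_i}{d}/\binom{T}{d}]$, evaluated in log
space; depths beyond a sample's total are reported missing, never
extrapolated.

Group comparisons are nonparametric, as is usual for these skewed
distributions: Kruskal–Wallis (tie-corrected midranks) with Dunn
pairwise z statistics and Bonferroni adjustment, or a two-group
Wilcoxon rank-sum test. The Wilcoxon test is exact (full enumeration)
for tie-free samples up to a combined n of 20, and the tie-corrected
normal approximation otherwise; two-sided throughout, since directional
hypotheses are rarely defensible a priori for diversity contrasts. Dunn
contrasts are always computed regardless of the omnibus p, leaving
gating to the caller. When every value is identical the tests return
p = 1 rather than failing.

# Beta diversity and ordination

Dissimilarity is Bray–Curtis on within-sample relative abundances:
$BC_{jk} = 1 - \sum_i \min(p_{ij}, p_{ik})$. Bray–Curtis is a
semimetric — triangle inequality violations are expected, and principal
coordinates of such matrices have negative eigenvalues. `pcoa()`
reports them rather than hiding them and returns coordinates for
positive axes only.

## Sequential PERMANOVA

`permanova()` partitions the total sum of squares of the Gower-centred
matrix $G = -\tfrac12 J D^{(2)} J$ over an *ordered* term list
(Type-I): each term's SS is the increment in $\mathrm{tr}(H_k G)$ over
nested hat matrices. Entry order is an analysis decision — enter the
most specific factors first and the most general (e.g. farmer) last, so
general factors absorb only variation not already explained. Pseudo-F
uses the residual mean square; significance comes from free permutation
of sample labels with

$$p = \frac{1 + \#\{F^* \ge F\}}{1 + n_{perm}},$$

ties counted with a $10^{-12}$ tolerance. With `exhaustive = TRUE` all
$n! - 1$ non-identity relabelings are enumerated (capped at $n = 8$)
and the p-value is exact; the unit tests verify exact agreement with an
independently coded enumeration oracle, and the decomposition itself is
cross-checked against `vegan::adonis2`. Numeric covariates enter as
single-degree-of-freedom linear regressors. Samples missing any term
value are dropped with a warning — imputation of questionnaire data is
out of scope. Defaults are 999 permutations; use more (e.g. 9999) for
publication-grade tables. Permutations are free (no strata).

## Dispersion and constrained ordination

Within-group spread ("variability of the microbiome") is analysed with
`vegan::betadisper`: distances to the group's spatial median (default;
centroid available, for which closed-form checks exist) in principal
coordinate space with the usual negative-eigenvalue correction,
followed by one-way ANOVA and Tukey contrasts. Groups of one sample are
excluded with a warning. The spatial median default follows common
practice; it is less sensitive to outlying samples than the centroid.

`dbrda_constrained()` wraps `vegan::capscale` for numeric constraints
such as cultivation surface area. Eigenvalues are rescaled to the
total-SS scale used by `pcoa()` so a constraint equal to the first
principal coordinate recovers exactly the first PCoA eigenvalue.

# Core detection by the occupancy–abundance elbow

Taxa are ranked by the joint score $o_i + p_i/\max_j p_j$ — occupancy
plus mean relative abundance rescaled to $[0,1]$, so neither axis
dominates; ties break by higher abundance, then taxon id. An
occupancy-only ranking is available by flag.

Walking down the ranking, `core_by_elbow()` tracks the cumulative
fraction of mean pairwise Bray–Curtis *similarity* explained by the top
$k$ taxa (each pair contributes its shared relative abundance mass over
the full-table shared mass, so the curve is non-decreasing and ends at
1). The core is the last rank whose relative gain
$(C_k - C_{k-1})/C_k$ still reaches the threshold, default 2%. The
last-rank ("final 2% gain") rule is deterministic and reproducible
across datasets of different richness, which is why it is the default
over curvature-based elbow variants; the threshold is configurable.

# The Sloan neutral model

Under neutral assembly with migration parameter $m$ and depth $N$ reads
per sample, a taxon with metacommunity relative abundance $p$ has local
latent abundance $\pi \sim \mathrm{Beta}(Nmp,\, Nm(1-p))$. Its expected
detection frequency (occupancy) is available in two conventions in
`neutral_occupancy()`:

* **multinomial** (default): the exact probability of observing at
  least one of $N$ multinomially drawn reads,
  $1 - B(Nmp, Nm(1-p)+N)/B(Nmp, Nm(1-p))$;
* **threshold**: the classical detection-limit approximation
  $1 - I(1/N;\, Nmp,\, Nm(1-p))$, which treats detection as certain
  above $d = 1/N$ and impossible below.

The threshold form is the one most published fits use. On count tables
that are genuinely multinomial samples — including every table this
package's own generator produces and, arguably, any rarefied real
table — it systematically overestimates $m$, because rare taxa below
the nominal limit are still detected occasionally and the optimiser
compensates. In our simulations the threshold fit shows median relative
error in $\hat m$ of 0.3–0.4 across $m \in [0.05, 0.5]$, while the
multinomial form stays under 0.05. The multinomial convention is
therefore the fitting default; the threshold form is retained for
comparability with published analyses. Fit quality ($R^2$, RMSE,
partition) is computed under whichever convention was fitted.

`fit_neutral()` rarefies to a common depth $N$ (default 500 reads, the
depth at which the detection limit is meaningful; shallower samples are
dropped with a warning), computes occupancy and mean relative abundance
*on the rarefied table* — detection limit and occupancy must refer to
the same depth — and estimates $m$ by bounded nonlinear least squares
on $(10^{-6}, 10]$ from a start of 0.1, with a golden-section fallback
on the same SSE objective if the port algorithm stalls. Reported are
the generalised $R^2 = 1 - SSE/SST$ (negative when the neutral curve
fits worse than a flat mean — a meaningful outcome indicating
non-neutral structure), $RMSE = \sqrt{SSE/(S-1)}$ over $S$ taxa
(the $S-1$ denominator follows the convention of widely used fitting
code; plain $S$ differs negligibly at realistic richness), and a
partition of taxa into `above` / `neutral` / `below` the Wilson 95%
interval around the predicted occupancy with the sample count as
trials.

One identifiability caveat: the model depends on $m$ and $N$ only
through the product $Nm$. If a table generated (or sequenced) at depth
$N_0$ is rarefied to $N < N_0$, the latent Beta concentration remains
$N_0 m$, and the fit at depth $N$ returns $\hat m \approx N_0 m / N$.
Comparisons of $\hat m$ across groups are meaningful when fitted at a
common depth, which is exactly what `fit_neutral()` enforces; absolute
values should be quoted together with $N$.

# Pollinator-to-flower transfer

The transfer index quantifies, per flower, the proportion of its
distinct ASVs with **more than 3 reads** that also occur (at least one
read) in any forager sample of the same environment. The read threshold
applies on the flower side only: it guards against counting
cross-contamination-level flower detections, while forager presence is
deliberately depth-free — the index is unchanged if forager libraries
are rescaled. Foragers are pooled per environment (union of presence).
Flowers with no eligible ASV are flagged undefined and excluded from
per-environment summaries (mean and minimum index), with a warning.

Prevalence contrasts between two groups (netted vs unnetted, flowers vs
foragers, cultivation types) use the exact two-sided Fisher test per
taxon at ASV or genus rank, with conditional-MLE odds ratios (0 and
infinity allowed at zero cells, no continuity correction) and
Benjamini–Hochberg adjusted p-values reported alongside the raw ones.

# Synthetic data with known truth

The generators exist so every stage can be validated against known
ground truth without downloading anything.

* `gen_neutral()` draws a log-normal metacommunity (sdlog 2, a
  realistically heavy-tailed rank-abundance curve), then per sample a
  composition from $\mathrm{Dirichlet}(Nm\,p)$ and counts from
  $\mathrm{Multinomial}(N, \cdot)$. Because the Dirichlet total equals
  $Nm$, each taxon's marginal abundance is exactly the Sloan stationary
  Beta — generator and fitter are counterparts, which is the package's
  central self-consistency property. A Dirichlet-multinomial stationary
  draw is used instead of forward birth–death simulation: it is exact
  in distribution and orders of magnitude faster.
* `gen_grouped()` adds compositional group effects by mixing weight
  $\epsilon$ toward independent group metacommunities and inflates
  within-group spread by dividing the Dirichlet concentration by a
  per-group dispersion multiplier.
* `gen_flower_forager()` emulates a two-environment pollinator
  exclusion experiment. Flowers default to strong drift ($m = 0.05$):
  flowers are ephemeral, weakly coupled habitats, and this also keeps
  their eligible ASV sets largely distinct. Foragers carry exactly
  $\mathrm{round}(s \cdot K)$ of the environment's $K$ eligible flower
  taxa — the planted sharing fraction is exact by construction, so the
  realised mean transfer index concentrates on $s$ — plus
  forager-specialist taxa absent from flowers (the analogue of
  gut-resident bee taxa).
* `gen_study()` assembles a four-environment study with planted
  per-environment migration (wild 0.4 > open_field 0.2 > tunnel 0.08 >
  greenhouse 0.05, mirroring the intuition that wild communities track
  the regional species pool most closely), a planted 10-taxon
  high-abundance core per environment, planted sharing, and sub-500-read
  decoy samples that downstream filtering must remove.

What the generators do **not** emulate: sequencing error and chimeras,
taxonomy misassignment, compositional correlations beyond the Dirichlet
(no true co-occurrence networks), cross-contamination between samples,
or variable amplification efficiency. Passing the validation suite
therefore demonstrates correctness of the statistics under the stated
sampling model, not robustness to upstream artefacts of real surveys.

# Validation design and problem sizes

The package's acceptance checks (also run by `scripts/acceptance.R`)
use these reference conditions, chosen to be realistic for desk-scale
validation: neutral recovery at $m \in \{0.05, 0.15, 0.5\}$ with 200
taxa, 50 samples, depth 500, 20 seeds per $m$; PERMANOVA null
calibration over 1000 label-independent simulations (two groups of 10);
dispersion power at a planted 2x multiplier over 200 simulations of
20+20 samples; core recovery over 100 simulations of a 10-taxon planted
core against 200 rare noise taxa; transfer recovery with planted
$s = 0.4$ over 30 flowers; 2000 Monte-Carlo draws against one analytic
rarefaction value; and 20-fixture sweeps of the exact Wilcoxon and
Fisher branches against full-enumeration oracles.

# Numerical choices and degenerate inputs

* Permutation tie tolerance $10^{-12}$; distance-matrix symmetry
  tolerance $10^{-12}$; relative-abundance column sums checked to
  $10^{-9}$; PCoA eigenvalue cutoffs relative at $10^{-9}$.
* Ranking ties: abundance, then lexicographic taxon id — deterministic
  output for identical input.
* All-zero samples are errors everywhere (they cannot be normalised);
  all-constant responses in group tests return p = 1; single-level
  model terms, all-samples-filtered tables, and missing taxonomy are
  errors naming the offending column, sample, or taxon.
* Exhaustive permutation enumeration is limited to $n \le 8$ ($8! =
  40320$ relabelings); beyond that, Monte-Carlo permutation p-values
  are the estimator of choice anyway.

# Limitations

* No phylogenetic diversity, UniFrac, or NMDS; no differential
  abundance models (export the tables and use the dedicated packages).
* Linear mixed-effects modelling of alpha diversity is deliberately out
  of scope; `alpha_diversity()` output is tidy precisely so such models
  can be fitted externally.
* The transfer index is presence overlap, not source attribution; it
  cannot distinguish flower-to-forager from forager-to-flower
  transport, nor shared environmental origin.
* The neutral fit assumes a single common depth; tables with widely
  varying library sizes must be rarefied (the function enforces this),
  which discards reads.
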