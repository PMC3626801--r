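---
title: "Methods: signed coexpression networks, module statistics, and cross-disease comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed coexpression networks, module statistics, and cross-disease comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexnet)
```

# The analysis model

`coexnet` implements a systems-level analysis of bulk transcriptomes built
around a signed weighted gene coexpression network. The pipeline takes a
probe- or gene-level log-intensity matrix with sample phenotypes, reduces it
to one row per gene, builds a network, groups genes into modules, summarizes
each module by an eigengene, and relates modules and single genes to
clinical variables — a continuous impairment score and a categorical group
design. A second, independent study of another disease can then be compared
gene-by-gene on impairment-correlated transcription.

## Signed adjacency

For each gene pair the Pearson correlation $r_{ij}$ is transformed to

$$a_{ij} = \left(\frac{r_{ij} + 1}{2}\right)^\beta, \qquad \beta = 12,$$

so $r = -1$ maps to adjacency 0 and $r = +1$ to 1: the sign of
coexpression is preserved rather than folded, which matters for small,
directionally coherent modules. $\beta = 12$ is the conventional
soft-threshold power for signed networks and is a fixed parameter here
(scale-free-fit selection is out of scope). Correlations use
pairwise-complete observations; genes whose correlations are undefined
after that must be removed first.

## Topological overlap and module detection

Node similarity uses the standard topological overlap applied to the signed
adjacency:

$$t_{ij} = \frac{\ell_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}},
\qquad \ell_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj},
\qquad k_i = \sum_{u \ne i} a_{iu}.$$

Genes are clustered by average linkage on $1 - t_{ij}$ and modules are cut
from the tree by a branch decomposition: every maximal subtree that merges
below `cut_height` (default 0.99 of the maximum merge height) and holds at
least `min_module_size` genes (default 30) becomes a module; everything
else is "grey". An optional `deep_split` flag further splits a branch when
it joins two sufficiently large, clearly tighter sub-branches (child merge
height below 0.9 of the join height). This is a deliberately transparent
reduction of adaptive dynamic tree cutting; module counts are sensitive to
both parameters, and the defaults are the package's documented choices, not
universal constants.

Module labels are color names assigned by decreasing module size in a fixed
palette order (turquoise, blue, brown, ...), so runs are comparable;
`match_labels()` transfers a reference run's labels onto another run by
best hypergeometric overlap (Bonferroni over reference modules, p < 0.05),
giving unmatched modules fresh labels.

## Eigengenes and module statistics

The module eigengene is the first principal component of the per-gene
z-scored module submatrix, scaled to unit variance and oriented so the mean
correlation with the module's genes is non-negative (the sign of a PC is
arbitrary; this convention makes trait-correlation signs reproducible).
Because genes are z-scored first, multiplying any gene by a positive
constant leaves the eigengene unchanged. kME (module membership) is the
correlation of any gene with an eigengene; kIN is the sum of a gene's
within-module adjacencies, and scaled kIN divides by the module maximum so
the top hub is exactly 1.0.

Module-trait association is the Pearson correlation of the eigengene with
the trait, with a two-sided t-distribution p-value reported raw — list
building downstream deliberately works at trend level (p < 0.05) without
multiplicity adjustment, and the tests verify the t-based p against a
permutation p. Group comparisons report both one-way ANOVA and
Kruskal-Wallis, since at the sample sizes typical of post-mortem brain
studies the parametric and rank answers can disagree; both are emitted and
neither is privileged.

## Module preservation

Preservation between a reference and a test dataset is a reduced
two-statistic permutation composite, computed on the genes common to both:

* **density** — mean intramodular adjacency in the test network; null:
  random gene sets of the same size drawn from the common genes.
* **connectivity** — Fisher z-transformed correlation between the module
  genes' kIN in the reference and in the test network; null: the gene
  correspondence between the two kIN vectors is permuted.

Each statistic yields $Z = (\mathrm{obs} - \mu_{perm})/\sigma_{perm}$ and
`Z_summary` is their mean. Two numerical choices deserve note. First, the
connectivity null permutes correspondence rather than drawing random gene
sets, because the random-set null is degenerate whenever the two datasets
are similar: any gene set then has kIN correlation exactly 1 and the null
variance collapses. Second, the Fisher z-transform (clipped at
$|r| = 1 - 10^{-12}$) keeps the statistic informative as the observed
correlation approaches 1; with the raw correlation, the observed value
saturates at 1 while the null SD scales as $1/\sqrt{n}$, capping Z near
$\sqrt{n}$ regardless of how strong preservation is. Both choices are
variance handling, not tuning: the same code path runs for self-
preservation (Z far above 10), genuine cross-dataset preservation, and
random gene sets (|Z| < 2).

## EASE enrichment

Gene-set enrichment uses the EASE score: a conservative variant of the
one-tailed Fisher exact test in which one gene is removed from the
category's list hits before computing the tail probability. Concretely,
with list hits $LH$, list total $LT$, population hits $PH$, population
total $PT$:

$$\mathrm{EASE} = P(X \ge LH - 1), \qquad
X \sim \mathrm{Hypergeom}(PH,\; PT - PH,\; LT - 1),$$

i.e. the jackknifed gene leaves both the hit count and the list. This
construction reproduces published EASE values to 3 significant figures
where the plain Fisher p (and the variant that decrements only the hit
cell) does not, and it sends any single-hit category to a score of exactly
1. Population totals are universe-specific: different annotation sources
annotate different fractions of an array, so enrichment is run per source
with that source's universe. Bonferroni multiplies by the number of
categories actually tested (those with at least one list hit). Gene
symbols are canonicalized once — uppercase, trimmed — before any set
operation.

## Cross-disease impairment genes

The two diseases are compared on the genes common to both studies. Per-gene
impairment correlations are oriented so positive always means "up with
impairment": the impairment score GCR (1-9, higher = worse) is used
directly; MMSE (0-30, lower = worse) is sign-flipped. A gene is a common
impairment gene when its oriented correlation exceeds +0.25 (or falls below
-0.25, strictly) in the second disease's dataset *and in both regions* of
the first. Hub comparison uses scaled kIN with a strict 0.70 cutoff,
required in the second disease plus at least one region of the first
(configurable to all regions); scaled kIN is non-negative, so the cutoff
applies within the up- and down-direction groups separately. Whether the
second study's correlations use all samples or cases only is exposed as a
sample filter; the default uses all samples with a non-missing score.

# The synthetic-data generator

Every downstream stage is validated against generated data with known
structure. The generative model is a latent-factor model chosen so that the
eigengene summary is exact by construction:

$$z_s \sim N(0,1), \qquad
f_{m,s} = \rho_m z_s + \sqrt{1 - \rho_m^2}\, e_{m,s}, \qquad
x_{g,s} = b + \delta_{m,\mathrm{grp}(s)} + \lambda_m f_{m,s} +
\varepsilon_{g,s},$$

with $z$ the per-sample impairment latent, $\rho_m$ the module's
`trait_effect` (population correlation of its factor with the trait),
$\lambda_m$ the `factor_loading`, $\delta$ per-group mean shifts in
expression units, $b = 7$ a baseline log-intensity, and
$\varepsilon \sim N(0, \mathrm{noise\_sd})$. Background genes are pure
noise. Trait scores are clipped linear transforms of $z$: GCR
$= 5 + 2z$ in [1, 9], MMSE $= 21 - 6z$ in [0, 30]; clipping at roughly
2 SD attenuates the planted correlation by well under the 0.05 recovery
tolerance. CPE is an independent clipped score. Presence calls are
independent Bernoulli draws — no probe-level chemistry is simulated — and
the multi-probe mode duplicates each gene with a constant per-probe offset,
exactly the structure the max-mean probe collapse resolves. Paired
two-disease designs regenerate a designated shared gene set as
$b + d\,a\,z + \sqrt{1-a^2}\,e$ with direction $d = \pm 1$ and magnitude
$a$, so the planted impairment correlation is $d \cdot a$ in both cohorts.

All randomness flows from the design seed through tagged substreams
(`substream_seed()`), so a design is one reproducible world. Default sizes
in the test suite mirror the scale of the motivating setting: ~20-60
samples split over four groups, modules of tens to low hundreds of genes,
noise SD 0.5 against loading 0.9 (within-module correlations ~0.75), and a
planted trait effect of 0.6.

What a green test does **not** establish: the generator draws Gaussian,
module-independent noise with equal variance, no batch structure, no
correlated background, and it plants modules that really are rank-one plus
noise. Real microarray data violate all of these; recovery on synthetic
data validates the machinery, not biological conclusions on any particular
dataset.

# Preprocessing decisions

Stage order is fixed: outlier arrays are flagged on the **un-normalized**
matrix by mean inter-array correlation (flag below mean − 2 SD; the SD
multiplier is exposed), then quantile normalization, then presence
filtering, then probe collapse. Two presence filters exist because they
serve different stages: drop rows absent in strictly more than 90% of
samples (general QC), and keep rows present in at least 6 samples (the
stricter pre-network filter). The outlier rule is a deterministic stand-in
for cluster-plus-RNA-quality review (RNA quality metadata is not part of a
matrix); the single-linkage dendrogram is returned for inspection. Probe
collapse keeps, per gene, the probe with the highest mean expression across
samples; exact ties break to the lexicographically smallest probe id so the
choice is stable under row reordering.

# Pipeline defaults

| parameter | default | meaning |
|---|---|---|
| `beta` | 12 | soft-threshold power, signed adjacency |
| `min_module_size` | 30 | smallest admissible module |
| `cut_height` | 0.99 | branch cut, fraction of max merge height |
| `max_absent_fraction` | 0.90 | strict absent-call removal threshold |
| `min_present_samples` | 6 | pre-network presence requirement |
| `r_top` | 0.75 | \|R\| cutoff for top gene tables |
| `de_alpha` | 0.05 | raw-p cutoff for enrichment gene lists |
| `impair_threshold` | 0.25 | cross-disease quadrant threshold |
| `hub_threshold` | 0.70 | scaled-kIN common-hub cutoff |
| `module_ad_alpha` | 2e-05 | module flagging for cross-disease enrichment |
| `sd_multiplier` | 2 | outlier flag, SDs below mean IAC |
| `n_permutations` | 200 | preservation permutations |

Each default is either a convention of the methods this package
reimplements or a documented package decision above; the pipeline log
records every value actually used, and unknown configuration keys are
errors so a typo cannot silently fall back to a default.

# Known limitations

* Dynamic tree cutting is a reduced branch decomposition, not the full
  adaptive algorithm; on weakly separated modules it will disagree with
  more sophisticated cutters, and module counts move with `cut_height`.
* Preservation is a two-statistic composite, not the full multi-statistic
  Z-summary machinery; it captures density and hub-pattern preservation
  only.
* Soft-threshold selection, block-wise approximations for very large
  arrays, consensus modules across regions, and eigengene networks are out
  of scope.
* The enrichment machinery ships no annotation databases; users supply GMT
  files, and population totals follow the supplied universe.

# Worked example

```{r example}
design <- synthetic_design(
  modules = list(
    module_spec("M1", 100, factor_loading = 0.9, trait_effect = 0.6),
    module_spec("M2", 80, factor_loading = 0.9),
    module_spec("M3", 60, factor_loading = 0.9, trait_effect = -0.4)),
  n_background_genes = 60,
  samples_per_group = c(A = 10, B = 10, C = 10, D = 10),
  noise_sd = 0.5, seed = 7)
study <- generate_study(design)

adj <- signed_adjacency(study$expression)
tom <- topological_overlap(adj)
modules <- cluster_and_cut(tom, min_module_size = 30)
table(modules$labels)

mes <- module_eigengenes(study$expression, modules)
module_trait_correlation(mes, study$phenotypes, "GCR")
```

The turquoise module (the largest, absorbing the planted M1) shows the
planted positive GCR correlation; the module without a trait effect does
not.
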