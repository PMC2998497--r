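---
title: "Determinants of protein evolutionary rates in PPI networks: methods and design"
author: "ppiEvoRate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determinants of protein evolutionary rates in PPI networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiEvoRate)
```

## The scientific question

Why do some proteins accumulate amino-acid substitutions faster than
others?  In yeast, several properties of a protein's place in the cell
have been proposed as rate determinants: how highly it is expressed, how
many interaction partners it has in the protein--protein interaction
(PPI) network, and whether it works as a subunit of stable protein
complexes.  These properties are mutually correlated, so showing that any
one of them matters *independently* requires an inference chain that goes
beyond pairwise correlation: partial correlations controlling the other
factors, a joint regression, and a principal-component summary of the
shared structure.  A further layer asks whether features of a protein's
*partners* — whether they share its functional class, and whether the
protein sits in a locally dense or sparse region of the network — carry
any signal once complex membership is taken into account.

ppiEvoRate implements that chain as a reusable pipeline: per-protein
feature computation, ortholog-based evolutionary distance estimation, the
statistical battery, and a synthetic-data generator that plants the
assumed causal structure so the whole pipeline can be validated end to
end without access to the original interaction, annotation, complex and
expression databases.

## Per-protein features

**Degree** `v` is the number of distinct interaction partners in a simple
undirected network (self-interactions removed, duplicate edges
collapsed at ingestion, with counts logged).

**Clustering coefficient**: for a protein whose `v` partners have `l`
interactions among themselves,

$$C = \frac{2l}{v(v-1)}.$$

Proteins with `v < 2` have no defined coefficient.  They are excluded
both from the classification below and from its mean cutoff: a protein
with one partner would mechanically score `C = 0` and drag the cutoff
down without carrying any neighbourhood information.  (Excluding them
from labels but keeping them in the mean was the plausible alternative;
we chose the symmetric exclusion.)  Proteins at or above the dataset-mean
coefficient are classified **DP** (dense part), below it **SP** (sparse
part); ties go to DP because the rule is "greater than or equal".

**Coefficient of functionality**: for a protein with `m` partners of
which `n` share one of its annotated functional classes, the coefficient
is `n/m`.  For a multi-class protein the coefficient is evaluated for
each of its own classes and the largest value wins, the winning class
being recorded; exact ties break to the lexicographically smallest label
so runs are deterministic.  Proteins at or above the dataset-mean
coefficient are **SF** (same-functional), below it **DF**
(different-functional).  Two conventions are unstated in the literature
and are exposed as options:

* whether `m` counts *all* partners or only annotated ones — default is
  all partners (`partnerCount = "all"`), since unannotated partners are
  real interactions that dilute functional coherence; they can never
  count toward `n`;
* a partner matches class `c` if `c` is *any* of its annotated classes.

The default vocabulary is the 17 top-level MIPS functional-catalogue
classes (`mipsClasses()`); any custom vocabulary is accepted.  Both
classification cutoffs are parameters (`funcCutoff`, `clustCutoff`)
because the groupings should be — and in our planted-structure runs are —
robust over a range of cutoffs; `"mean"` is the default.

**Complex number** is the count of catalogued complexes in which the
protein appears as a subunit; a protein is **complex-forming** if that
count is at least one.  Absence from the catalog means complex number 0.

## Evolutionary distance

Orthologous pairs are screened by alignment summary statistics with the
acceptance rule: expectation value at most `1e-5`, percent similarity at
least 75, alignment overlap at least 80%, and gaps *strictly below* 3%.
All four thresholds are configurable; rejection reports the first failing
criterion.  Because published pipelines differ in whether "similarity"
means identity or positive-scoring matches, and in which sequence length
the overlap denominator uses, the filter consumes these fields exactly as
supplied by the upstream aligner rather than recomputing them.

From an aligned pair, columns with a gap in either sequence are excluded
pairwise and the observed difference proportion `p` is taken over the
remaining columns.  The corrected distance is Kimura's empirical
approximation

$$d = -\ln(1 - p - 0.2\,p^2),$$

defined for `p` below the root of `0.2p^2 + p - 1`, about 0.8541.  At or
beyond that boundary the pair is *saturated*: the package raises an error
and batch processing excludes the pair with a logged reason.  Saturated
pairs are never capped at some large value, because a cap would be an
arbitrary point mass distorting every rank-based statistic downstream.
`kimuraInverse()` provides the exact algebraic inverse
`p*(d) = (-1 + \sqrt{1 + 0.8(1 - e^{-d})})/0.4`, used by the simulator
and by round-trip tests.

## The statistical chain

* **Spearman correlation** is computed as the Pearson correlation of
  average ranks.  The two-sided p-value uses exact enumeration of the
  permutation null for tie-free samples of up to 7 observations, and the
  t transform with `n - 2` degrees of freedom otherwise.  (Enumeration at
  `n = 10` would already mean 3.6 million permutations; beyond 7 the t
  approximation is accurate far past any use this pipeline has for small
  samples.)  An optional `pFloor` reproduces the reporting convention of
  statistics packages that floor tiny p-values, e.g. at `1e-6`, for
  display parity with published tables; the computed value is the
  default.
* **Partial correlation** is partial *Spearman* by default — all
  variables are rank-transformed first, then a partial Pearson
  correlation is taken given the control ranks — since it accompanies
  Spearman correlations in the tables it feeds; `rankFirst = FALSE`
  gives the Pearson variant.  Two routes are implemented, inversion of
  the joint correlation matrix and double residualization, and the test
  suite requires them to agree to `1e-10`; degrees of freedom are
  `n - 2 - k` for `k` controls.
* **Multivariate regression** is ordinary least squares of distance on
  expression, degree and complex number jointly, z-standardized by
  default so coefficients are comparable (p-values are unaffected).  The
  variables are left untransformed by default because the original
  analyses do not state any transformation; log switches belong to the
  caller.  Exactly collinear designs raise an error rather than silently
  dropping a predictor.
* **PCA** runs on the *correlation* matrix (z-scored columns), not the
  covariance matrix: complex number, expression and degree live on wildly
  different scales, and the published loading pattern (two loadings near
  0.75 and one near 0.4 with PC1 carrying ~43% of variance) is only
  attainable with standardized inputs.  Components with eigenvalue at or
  above 1 are flagged retained (Kaiser rule).  Each component is
  sign-oriented so its largest-magnitude loading is positive, which makes
  the sign of the PC1--distance correlation deterministic.
* **Mann--Whitney U** comparisons report the U statistic for the first
  group, group sizes and group means.  The p-value is exact by
  enumeration when the pooled size is at most 12 and tie-free, and uses
  the tie-corrected normal approximation with continuity correction
  otherwise.
* **Fisher's exact test** (two-sided, probability-mass definition) is
  exported for contingency questions; within a single run the pipeline
  applies it to the association between complex-forming status and the
  SF/DF and SP/DP labels.  The published comparison of complex-forming
  ratios *between* two interaction datasets is the same function applied
  to the two runs' counts.

Every statistic is computed on the complete cases of its own variables,
and every result records its `n` — mirroring the varying sample sizes
that arise when networks, annotation, expression and ortholog coverage
only partially overlap.

## The synthetic generator

`generateDataset()` draws a complete study from a single latent
per-protein **constraint** variable `c_i ~ N(0,1)`:

| observable | mechanism | default |
|---|---|---|
| expression | `2 * exp(0.5 c_i + N(0, 0.4))` | log-normal, median ≈ 2 |
| complex membership | each of 491 complexes includes protein i with prob. `plogis(-6.5 + 1.2 c_i)` | ≈ half of proteins complex-forming |
| network edge i--j | prob. `plogis(logit(4/(n-1)) + 0.3 (c_i + c_j))` | mean degree ≈ 4 |
| planted distance | `softplus(-2.6 - 0.5 c_i + N(0, 0.25))` | ≈ 0.04--0.13 subst./site |
| sequences | ancestral length 500, `Binomial(L, p*(d))` substituted sites | — |

A single latent driver with independent noise on every observable is the
simplest mechanism that yields the studied sign pattern — negative
correlation of distance with expression, degree and complex number —
while keeping all partial correlations nonzero.  Distances are planted
per focal protein (the unit of analysis), not per pair.  The constraint
weight on connectivity (0.3) is deliberately the weakest, and the complex
weight (1.2) the strongest, matching the finding under study that complex
membership and expression dominate the first principal component while
degree contributes least.  The 491 complexes and 17 classes match the
catalog sizes of the original data sources; mean degree 4, ~50%
complex-forming proteins, 92% annotation coverage and distances around
0.05--0.1 are in the range of curated yeast data.  Functional classes are
drawn per protein, with members of a complex preferentially (probability
0.7) sharing a complex "theme" class, giving the functionality
coefficient realistic within-complex coherence.

Sequence evolution is site-independent uniform substitution without rate
heterogeneity or a substitution matrix, and gap-free by default (a
`gapRate` option injects gaps for testing the gap-exclusion path): only
the `p -> d` correction is under study, and `evolvePair()` inverts it
exactly, so the estimated distance is asymptotically unbiased for the
plant (verified at L = 500 and 5000).

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: scale-free degree distributions,
correlated assay noise between databases, biased ortholog detection,
rate variation across sites and proteins' domains, multi-species
distance calibration, and any causal structure other than a single
latent constraint.  Passing the planted-structure recovery test shows
the pipeline faithfully propagates a known signal; it does not validate
the biological model itself.

## Validation design and problem sizes

The test suite pairs every nontrivial computation with an independent
oracle: brute-force neighbour-pair enumeration for the clustering
coefficient (100 random graphs of 30 nodes), full permutation and
rank-assignment enumeration for the exact Spearman and Mann--Whitney
tails, hypergeometric enumeration for Fisher's test over all 2x2 tables
with margins up to 10, the textbook recursion formula and route
cross-agreement for partial correlations, and an SVD-based PCA as a
second eigendecomposition route.  End-to-end checks run the default
generator (2000 proteins, seed fixed a priori) through the file-based
pipeline and require the full planted sign pattern back.  Calibration
under the null uses 100 independent seeds at 200 proteins with all
constraint weights set to zero and pools each test family's rejections
across its applications within a run (three variable pairs for the
correlation families, three predictors for the regression, five group
comparisons), giving 300--500 draws per family; each family's rejection
rate at α = 0.05 must lie in [0.03, 0.07].  Pooling is deliberate: a
band that narrow is uninformative against the binomial noise of 100
draws for a single comparison.

## Numerical and degenerate-input policy

Constant vectors, empty groups, zero margins, exactly collinear designs,
all-missing coefficient sets and gap-only alignments raise typed errors
early rather than propagating NaNs.  Saturated distances are excluded,
never capped.  Class-assignment ties break lexicographically; cutoff
ties classify upward (DP/SF).  All randomness flows from one seed
argument; re-running any pipeline step on the same inputs is
byte-identical, and the generator's manifest records its seed and
configuration.

## Limitations

Real DIP/MIPS-era analyses involved identifier mapping across databases,
species filtering of interaction records and expression-platform
quirks; the package exposes only a generic identifier join and an
optional endpoint-identifier filter.  The ortholog filter screens
supplied alignment summaries — it does not run BLAST or the aligner.
Distances are amino-acid Kimura corrections only (no dN/dS, no
codon-aware models).  The pipeline applies no multiple-testing
correction across its report, matching the analysis style it
re-implements; users scanning many cutoffs should correct downstream.
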