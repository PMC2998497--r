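# ppiEvoRate

Tools for asking what governs the evolutionary rates of proteins embedded
in a protein–protein interaction (PPI) network — written for
computational and evolutionary biologists who have an interaction edge
list, functional annotations, a protein-complex catalog, expression
levels and aligned ortholog pairs, and want the full
correlation/partial-correlation/regression/PCA/group-comparison chain run
reproducibly over them.

## What it computes

Per protein, joined on identifier:

- **degree** *v* and the local **clustering coefficient**
  *C = 2l / (v(v−1))* (the fraction of the *v* partners' possible pairs
  that interact, *l* observed), with classification into dense-part (DP,
  *C* ≥ dataset mean) and sparse-part (SP) proteins; degree < 2 proteins
  are unclassified;
- the **coefficient of functionality** *n/m* (fraction of the *m*
  partners sharing one of the protein's functional classes, maximised
  over its own classes), with classification into same-functional (SF,
  *n/m* ≥ dataset mean) and different-functional (DF) proteins, on the
  17-class MIPS vocabulary by default;
- the **complex number** (count of complexes containing the protein as a
  subunit) and the complex-forming flag;
- the **Kimura protein distance** from an aligned ortholog pair:
  *d = −ln(1 − p − 0.2p²)*, where *p* is the proportion of differing
  gap-free alignment columns; saturated pairs (*p* ≳ 0.854) are excluded,
  and ortholog alignments can be screened first by e-value ≤ 1e−5,
  similarity ≥ 75%, overlap ≥ 80% and gaps < 3% (all configurable).

On the joined table it then runs: Spearman correlations of distance with
expression, degree and complex number; partial Spearman correlations of
each factor controlling the other two (matrix-inversion and
residualization routes, required to agree); multivariate OLS of distance
on all three; PCA on the correlation matrix with eigenvalue ≥ 1 component
retention and the PC1–distance correlation; Mann–Whitney comparisons of
SF vs DF, SP vs DP and complex vs non-complex groups (also within the
complex-forming and non-complex-forming subsets); and Fisher exact tests
of label–complex associations.

A synthetic-data generator (`generateDataset()`) plants a single latent
constraint variable that raises expression, complex propensity and
connectivity while lowering sequence divergence, and emits every input
file the pipeline reads — so the entire chain is testable end to end
without any database downloads.  See the vignette in `vignettes/` for
the model, defaults and design rationale.

## Worked example

```r
library(ppiEvoRate)

ds    <- generateDataset(syntheticConfig(nProteins = 500), seed = 42)
files <- writeDataset(ds, file.path(tempdir(), "demo"))
res   <- runPipeline(files[["edges"]], files[["annotations"]],
                     files[["complexes"]], files[["expression"]],
                     files[["alignments"]], quiet = TRUE)
res$report
#> AnalysisReport
#>  Spearman correlations with protein distance:
#>    expression      rho = -0.640  (p = 3.53e-57, n = 485)
#>    degree          rho = -0.446  (p = 4.37e-25, n = 485)
#>    complex_number  rho = -0.562  (p = 1.12e-41, n = 485)
#>  PCA: PC1 carries 64.5% of variance (eigenvalue 1.94, retained)
#>  Group comparisons: 9 Mann-Whitney tests

reportTables(res$report)$partials
#>         variable    rho  p_value   n
#> 1     expression -0.461 8.34e-27 485
#> 2         degree -0.216 1.70e-06 485
#> 3 complex_number -0.296 3.07e-11 485

round(res$report@pca$loadings[, 1], 3)
#> complex_number     expression         degree
#>          0.622          0.601          0.502
```

Reading: all three factors correlate negatively with evolutionary
distance (485 of the 500 proteins survive the network/distance join),
and each keeps a significant negative *partial* correlation when the
other two are controlled — the planted latent-constraint structure.  The
retained first principal component is dominated by complex number and
expression, with degree loading lowest, and the complex-forming group's
mean distance (0.061) is well below the non-complex group's (0.103;
Mann–Whitney p ≈ 4e−23).

A thin command-line wrapper with `generate`, `run` and `report`
subcommands is installed at `inst/scripts/ppi-evo-pipeline.R`:

```sh
Rscript inst/scripts/ppi-evo-pipeline.R run --edges edges.tsv \
    --annotations ann.tsv --complexes cpx.tsv --expression expr.tsv \
    --alignments pairs.fasta --out results/
```

writes `features.tsv`, `report.json` and `tables/*.tsv`.

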