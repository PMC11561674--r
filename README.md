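# rapasens

Quantitative genetics and metabolomics of rapamycin sensitivity in panels
of fully inbred *Drosophila* lines.

Rapamycin, an mTOR inhibitor, delays larval development — but how much
depends strongly on genetic background. Given a DGRP-style screen (fully
homozygous lines, biallelic genotypes, replicated pupation records under
control and drug treatment, and larval metabolomes for a subset of
resistant and sensitive lines), `rapasens` implements the complete
analysis chain:

* **Phenotyping** — per-vial pupation counts become per-line developmental
  delays (rapamycin mean − control mean, days) with pooled errors
  `s = sqrt(((n_r−1)s_r² + (n_c−1)s_c²)/(n_r+n_c−2))`,
  `SE = s·sqrt(1/n_r + 1/n_c)`, then Box–Cox normalisation and batch
  centring on reference lines for association testing.
* **SNP heritability** — gBLUP: `y = Xβ + g + ε` with
  `g ~ N(0, K σ²_g)` on the genomic relationship matrix `K = WWᵀ/m`
  (centred, scaled doses; MAF ≥ 5 %, call rate ≥ 95 %, LD-pruned to
  r² ≤ 0.8 in 200 kb windows sliding 5 kb). REML by eigendecomposition and
  1-D profiling of `λ = σ²_g/σ²_e`; `H²_SNP = σ²_g/(σ²_g+σ²_e)` with
  bootstrap subsampling and a phenotype-permutation null.
* **Marker and set association** — a vectorised single-marker scan against
  the genomic BLUPs; the covariance association test (CVAT),
  `T_feature = Σ_{i∈feature} cov(ĝ, w_i ŝ_i)`, over gene, gene ± 1 kb and
  pathway features, with permutation empirical p-values and Storey
  q-values.
* **Metabolomics** — log/per-sample normalisation, empirical-Bayes batch
  correction, PCA, per-metabolite mixed models
  (`metabolite ~ β_T + β_P + β_T×P + (1|line)`, Type-III tests), and
  projection onto a starvation axis: PC1 of an external starvation time
  course, whose trajectory follows `PC(t) = a·t/(t+b) − c`.

A first-class synthetic-data module emulates every input (genotypes with
LD, pupation records, metabolomes with batch structure, the starvation
time course) with recorded ground truth, so the whole pipeline runs and
validates offline.

## Worked example

```r
library(rapasens)

G  <- simulate_genotypes(140, 20000, seed = 4)   # homozygous panel with LD
ph <- simulate_phenotype(G, h2 = 0.8, seed = 4)  # polygenic delay, truth recorded

Gq <- qc_markers(G, maf_min = 0.05, callrate_min = 0.95)
Gq <- subset_markers(Gq, match(ld_prune(Gq), Gq$map$id))
K  <- compute_grm(Gq)
fit <- fit_gblup(ph$phenotype$delay, NULL, K)
fit
#> gBLUP/REML fit on 140 lines
#>   H2_SNP = 0.861 +/- 0.760 (SE)  (s2g = 0.8264, s2e = 0.1336)

perm <- permute_h2(ph$phenotype$delay, NULL, K, n_perm = 999, seed = 4)
sprintf("permutation p = %.3f", perm$p_value)
#> "permutation p = 0.096"
```

The estimate recovers the simulated heritability (0.8) but with a large
standard error — at 140 lines the sampling spread of `H²_SNP` is wide, as
the bootstrap utility (`bootstrap_h2()`) makes explicit; averaged over
repeated simulations at 200 lines the estimator is unbiased to within
±0.10 (see the test suite). The permutation p-value asks how often a
phenotype with no genetic structure would score this high.

The saturating starvation trajectory refits its generating constants from
clean data:

```r
t5 <- rep(c(0, 2, 4, 6, 8), each = 5)
fit_trajectory(starvation_score(t5, 20.53, 2.77, 10.01) + rnorm(25, 0, 0.3), t5)[c("a", "b", "c", "r2")]
#> a = 20.15, b = 2.81, c = 9.84 (r2 = 0.997)
```

An end-to-end run on a small synthetic study (genotypes → phenotypes →
heritability → CVAT → metabolome → starvation projection), writing TSV/
JSON/PLINK outputs deterministically:

```r
cfg <- read_config(system.file("extdata", "demo_config.yaml", package = "rapasens"))
run_pipeline(cfg, outdir = "rapasens_demo")
```

A thin command-line wrapper is installed at
`inst/scripts/run-pipeline.R`. The methods vignette
(`vignettes/rapamycin-sensitivity-methods.Rmd`) documents the models,
default parameters, generator assumptions and numerical choices.

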