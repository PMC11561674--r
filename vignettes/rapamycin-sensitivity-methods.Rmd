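---
title: "Methods: quantitative genetics and metabolomics of rapamycin sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative genetics and metabolomics of rapamycin sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Inhibiting mTOR with rapamycin slows *Drosophila* larval development, but
the size of the effect varies enormously across wild-derived inbred lines:
some lines barely notice the drug, others pupariate nearly a week late.
`rapasens` implements the full analysis chain for such a screen on a panel
of fully inbred lines (a DGRP-style design, where every line is homozygous
and allele doses are 0 or 2):

1. **Phenotyping.** Per-vial pupation counts become per-line developmental
   delays with pooled errors.
2. **Quantitative genetics.** SNP heritability by gBLUP/REML on a genomic
   relationship matrix, with bootstrap subsampling and a permutation null.
3. **Association.** A single-marker scan against the genomic BLUPs, and
   set-level tests (genes, genes ± 1 kb, pathways) with the covariance
   association test (CVAT) and Storey q-values.
4. **Metabolomics.** Normalisation, empirical-Bayes batch correction, PCA,
   per-metabolite mixed models, and projection of the study metabolome onto
   a starvation axis derived from an external time course.

Because the screen's raw inputs are external downloads, the package ships a
synthetic-data module that emulates each input's statistical structure with
recorded ground truth, so that every stage can be validated end to end by
simulation.

# Phenotyping

The delay of a line is the mean pupation time on rapamycin minus the mean on
control, pooling all pupae across replicate vials. Its error uses the pooled
standard deviation

$$ s = \sqrt{\frac{(n_r - 1) s_r^2 + (n_c - 1) s_c^2}{n_r + n_c - 2}},
\qquad \mathrm{SE} = s \sqrt{\tfrac{1}{n_r} + \tfrac{1}{n_c}}, $$

the standard two-sample pooled-variance formula (`pooled_se()` is checked
against an independent implementation at 1e-12 on 1,000 random inputs).

For association testing, delays are shifted by +1 day (delays slightly below
zero occur), Box–Cox transformed with a single $\lambda$ maximising the
profile log-likelihood (grid $[-2, 2]$ in steps of 0.01, then Brent
refinement in the winning cell), centred within each experimental batch on
the mean of the reference lines assayed in every batch, and scaled by the
batch SD. Two choices here were genuinely open and are fixed as follows:

* **Batch scaling** divides by the SD over *all* lines in the batch after
  centring, not only the reference lines — "the batchwise standard
  deviation" is read as batch-wide.
* **One global $\lambda$** is fitted for the whole screen, because the
  phenotype is normalised once, not per batch.

Recorded pupation days are treated as exact; no interval-censoring
correction is applied for the once-or-twice-daily observation schedule.

# Heritability and the gBLUP model

The line phenotype is modelled as $y = X\beta + g + \varepsilon$ with
$g \sim N(0, K\sigma_g^2)$ and $\varepsilon \sim N(0, I\sigma_e^2)$, where
$K = WW^\top/m$ is the genomic relationship matrix over centred, unit-
variance doses (missing doses imputed once to the marker mean, before both
the GRM and the scan). Fixed effects hold Wolbachia infection status and
the common inversion genotypes. SNP heritability is
$H^2_{SNP} = \sigma^2_g / (\sigma^2_g + \sigma^2_e)$.

Estimation is REML: $K$ is eigendecomposed once, the restricted likelihood
is profiled over $\lambda = \sigma^2_g/\sigma^2_e$, and $\log\lambda$ is
optimised by bracketed 1-D search on $[-10, 10]$ (an optimum at the bracket
edge is flagged). The fit is validated against a dense REML oracle (explicit
covariance, generic optimiser) to $|\Delta H^2| < 10^{-4}$. The SE of
$H^2$ comes from the numerical Hessian of the restricted likelihood in
$(\sigma_g^2, \sigma_e^2)$ with the delta method; this is an approximation
whose behaviour near the $\sigma_g^2 = 0$ boundary is undefined, so the SE
is reported as `NA` there.

Resampling follows the screen's two designs:

* **Bootstrap**: subsamples of $n$ lines drawn *without* replacement
  (duplicated lines would make $K$ singular), refit per subsample.
* **Permutation null**: the phenotype vector is permuted against $(X, K)$
  held fixed together, breaking both covariate and kinship association; the
  empirical p is `count / n_perm`, floored at `1/n_perm` when no permuted
  estimate reaches the observed one.

Marker QC defaults reproduce the screen's settings — GRM set: MAF ≥ 5%,
call rate ≥ 95%, LD-pruned to $r^2 \le 0.8$ in 200 kb windows sliding 5 kb;
scan set: MAF > 5%, call rate > 80% — and are asserted in one place
(`default_config()`).

# Marker-set association (CVAT)

Marker effects are backsolved from the BLUPs,
$\hat{s} = W^\top K^{+} \hat{g} / m$, so that marker $i$ contributes the
line-level vector $g_i = W_{\cdot i} \hat{s}_i$, and a feature's statistic
is $T = \sum_{i \in \text{feature}} \mathrm{cov}(\hat{g}, g_i)$. Summed over
all markers this telescopes to $\mathrm{var}(\hat{g})$ when $K$ has full
rank, which the tests assert to 1e-8.

Significance is empirical: null statistics are sums of the per-marker
contributions over random marker subsets of the feature's size. This null
was chosen (over genotype rotation) because the statistic is additive over
markers, which makes the permutation exactly vectorisable; the test is
one-sided, treating a large positive covariance as association. Both
choices are isolated in `cvat_empirical_p()` so an alternative null can be
swapped in.

Features follow the annotation conventions of the fly genome: transcript
intervals are closed and 1-based (BED input is converted on read), a
gene-level feature needs ≥ 1 marker, the widened level adds ±1 kb, and
pathway features (unions of member genes, duplicates collapsed) require
≥ 2 genes and ≥ 200 markers. Markers inside several genes count in every
containing feature. Storey q-values use the $\lambda$-grid
0.05–0.95 with a df-3 smoothing spline evaluated at $\lambda = 0.95$,
clipped to $(0, 1]$; forcing $\pi_0 = 1$ reproduces Benjamini–Hochberg
exactly, which the tests assert.

# Metabolome analysis

Raw intensities are $\log_e$ transformed and each **sample** is centred to
mean 0 and scaled to SD 1; the operation is idempotent on its own output.
Extraction-batch effects are then removed per metabolite with the
parametric empirical-Bayes location/scale adjustment, with no covariates
preserved, via `sva::ComBat` — the canonical implementation of exactly
this adjustment. PCA runs on the per-sample-normalised, batch-corrected
matrix with metabolites as variables and **no further column scaling** (the
scaling already happened per sample); components are oriented so the
largest-magnitude loading is positive.

Per-metabolite models are REML random-intercept fits (`lme4`):

* `metabolite ~ treatment * phenotype + (1 | line)` with Type-III
  (sum-to-zero contrast) marginal F tests per fixed term, and
* `metabolite ~ treatment + (1 | line)` within each phenotype class, with a
  Wald t on the treatment effect,

with Storey q-values across metabolites per term. The denominator df is
residual-based, $n - p - (g - 1)$ for $g$ lines, collapsing to $n - p$ when
the line variance hits the boundary — in which case the fit reduces
*exactly* to the fixed-effects Type-III ANOVA, which the tests assert to
1e-6. Satterthwaite df were deliberately not used; the choice is validated
by a null calibration (interaction-term type-I error within 0.05 ± 0.02
over 500 simulated null metabolites at the study's 54-sample design).

# The starvation axis

An external starvation time course (five replicates at 0, 2, 4, 6, 8 h) is
harmonised with the study metabolome in this order: metabolites with more
than one missing value are dropped; single-missing metabolites are imputed
by 10-nearest-neighbour means (neighbours are metabolites, Euclidean
distance over pairwise-complete samples — the convention of the R
imputation tools this mirrors); samples are centred/scaled; duplicate-ion
pairs (one metabolite measured in both ionisation modes) are scaled per
metabolite and averaged; names are matched and intersected. Filtering
before averaging follows the order in which the operations are described
for the original analysis.

PC1 of the harmonised reference is the axis, oriented so training scores
increase with starvation time, and its time trajectory is fitted by bounded
nonlinear least squares to

$$ \mathrm{score}(t) = \frac{a\,t}{t + b} - c, $$

with starts $a_0 = \mathrm{range}$, $b_0 = \mathrm{median}(t)$,
$c_0 = -\min$, four fixed jittered restarts, and $b > 0$ enforced; the
fitted curve at $t = 0$ equals $-\hat{c}$ identically. Query samples are
projected as $\sum_i \ell_i (x_i - \bar{x}_i^{\mathrm{train}})$ — reference
training means are subtracted before applying loadings (standard PCA
projection; a raw dot product is available behind `center = FALSE` since
the original description leaves this implicit). Displacement along the
axis is tested with the same mixed-model machinery as the per-metabolite
interaction ANOVA.

# The synthetic-data module

The generators define the study conditions used throughout the tests:

* **Genotypes**: homozygous doses \{0, 2\} only (heterozygotes are never
  simulated; the real panel uses only homozygous calls). LD comes from
  first-order Markov copying along each chromosome — marker $j$ copies a
  line's previous allele with probability `ld_decay` (default 0.8), else
  draws fresh at the marker's target frequency (MAF uniform on
  [0.05, 0.5]). This gives controllable adjacent-$r^2$ and is documented
  as *not* a coalescent. Positions are strictly increasing with spacings
  uniform on 1–3 kb, matching the panel's marker density to order of
  magnitude.
* **Phenotypes**: marker effects on centred/scaled doses, with genetic and
  residual components each rescaled to their exact target sample variances
  so the realised genetic fraction equals the requested $h^2$; batch
  offsets and binary covariate effects are layered on top and recorded in
  the truth object.
* **Pupation records**: individual development time is Gaussian around the
  line-condition mean, recorded as a rounded day; survival is binomial
  thinning (default 0.85 per larva — the original report gives no per-vial
  survival rate, so this is the package's own choice of a realistic value).
  The default four vials of 40 larvae reproduce the screen's seeding.
* **Metabolome**: 154 metabolites over 6 resistant + 7 sensitive lines,
  two treatments, two extraction batches. Effects are specified in units
  of a metabolite's total between-sample SD with line variance (SD 1.0)
  dominating vial-replicate noise (SD 0.35) — pooled-larvae LC-MS has
  technical CVs of a few percent, so biological line variation dominates.
  Batch location shifts vary per metabolite around the requested batch
  mean (SD 0.5): a perfectly uniform shift would already be removed by
  per-sample centring and would leave the empirical-Bayes correction
  untested.
* **Starvation time course**: the latent score follows
  $a\,t/(t+b) - c$ with defaults $a = 20.53$, $b = 2.77$, $c = 10.01$ —
  the constants of the published trajectory — and metabolite values are
  `loading × score + noise`, with configurable missing cells and
  duplicate-ion pairs.

One global integer seed drives everything; each generator derives an
independent stream from `(seed, stage-name)` so enlarging one stage never
perturbs another, and fixed seeds give bit-identical outputs (the pipeline
determinism test compares output directories by checksum).

What the simulations do **not** emulate: realistic demography or
coalescent LD, sex-specific effects, family structure beyond the line
level, censored or truncated pupation observation, heavy-tailed intensity
noise, or metabolite–metabolite correlation beyond the shared latent axis.
Passing the recovery and calibration tests therefore demonstrates
correctness of the estimators under their assumed models, not robustness
to everything real data can do.

# Validation scales and numerical choices

The test suite validates at these problem sizes (chosen to keep the whole
suite within a desk-scale run):

* heritability recovery: 200 lines × 5,000 markers, $h^2 \in \{0.2, 0.5,
  0.8\}$, 25 seeds each, mean $\hat{H}^2$ within ±0.10;
* permutation calibration: 100 lines × 400 markers under $h^2 = 0$, 200
  replicates × 99 permutations, rejection rate within 0.05 ± 0.02;
* CVAT: decomposition to 1e-8; exhaustive enumeration on 10-choose-3;
  type-I error within [0.03, 0.07] over 1,000 null features; ≥ 80% power
  across 25 seeds for a pathway carrying half the genetic variance at
  $h^2 = 0.5$ with 300 lines;
* metabolome: ≥ 95% of an injected batch shift removed at 54 × 154; the
  calibration and power checks above;
* starvation axis: the generating constants refit to 1e-6 from clean
  data, loading recovery at cosine ≥ 0.95 under noise SD 0.2.

Numerical conventions: REML optimisation tolerance 1e-9 on
$\log\lambda$; eigenvalues clipped at 0 with PSD tolerance `-1e-8`
relative; pseudo-inverse cutoff `1e-10` of the top eigenvalue; empirical
p-values floored at `1/n_perm`; q-values monotonised by running minima;
ties in Spearman ranks averaged. Degenerate inputs (constant markers,
zero within-sample SD, batches with one sample, delays ≤ −1 day, constant
trajectory scores) are reported as errors or flagged degenerate results
rather than silently patched.

# Known limitations

* The H² standard error is a curvature approximation and is unreliable
  near the variance boundary.
* The CVAT null resamples marker subsets; if LD made contributions
  strongly dependent within features, a rotation-based null would be more
  conservative. The choice is isolated behind one function so an
  alternative null can be swapped in.
* Mixed-model df are residual-based, not Satterthwaite; for badly
  unbalanced designs the between-line (phenotype) term's test is the most
  affected.
* The pipeline's demo phenotype maps the Gaussian liability through an
  exponential onto a skewed delay scale; heritability on the delay scale
  is therefore not numerically the liability-scale $h^2$ until the
  Box–Cox normalisation undoes the transform.
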