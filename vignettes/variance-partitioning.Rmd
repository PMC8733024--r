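---
title: "Temporal and genomic partitioning of additive genetic variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal and genomic partitioning of additive genetic variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breedvar)
```

## The problem

Breeders care about how much additive genetic variance their programme has
left, because the variance sets the ceiling on future selection response.
Routine variance estimates pertain to a fixed base population and a whole
genome; they say nothing about how the variance moves over years and breeding
stages, or which population processes move it. `breedvar` implements a
three-layer framework for that question:

1. **fit** a marker-based linear model to all available phenotype and marker
   data;
2. **sample** realisations of marker effects from the fitted model, and for
   each realisation compute genetic values `a = W m` for any set of
   individuals;
3. **partition** the variance of those sampled genetic values by *time*
   (cohorts of a breeding programme) and by *genome* (chromosomes and loci),
   giving a posterior distribution for every partition.

A breeding-programme simulator generates the ground truth used to validate
the whole chain.

## The decomposition

For individuals with genotype dosages `Q` (values 0/1/2) and additive allele
substitution effects `α`, genetic values are `a = Qα` and genetic variance is
the *population* variance of `a` — divisor `n`, not `n − 1`. Summing locus
genetic values per chromosome gives chromosome genetic values; applying the
variance sum rule twice decomposes the total into

* **genic variance** — per locus, the empirical variance of its dosages times
  the squared effect, summed within chromosomes;
* **within-chromosome LD covariance** — all ordered pairs of loci on one
  chromosome, `α_l' · cov(Q[,l'], Q[,l]) · α_l`;
* **between-chromosome LD covariance** — all locus pairs across distinct
  chromosomes, equivalently all off-diagonal chromosome-value covariances.

Two conventions deserve emphasis. First, the genic term uses the *empirical*
dosage variance rather than the Hardy–Weinberg expression `2p(1−p)`: in fully
inbred material (dosages only 0 or 2) the empirical variance is `4p(1−p)`,
i.e. the `(1+F)` inflation with `F = 1` comes out automatically. Second, with
`n_c` chromosomes carrying `n_lc` loci each there are `(n_c·n_lc)²` locus
combinations, `n_c·n_lc·(n_lc−1)` ordered within-chromosome pairs and
`(n_c·n_lc)² − n_c·n_lc²` ordered between-chromosome pairs (for 21 × 100 QTL:
4,410,000, 207,900 and 4,200,000). Between-chromosome terms are individually
tiny but extremely numerous, which is why selection can move the total
through them. `genomic_partition()` never materialises the locus-pair matrix;
it aggregates through chromosome genetic-value columns, which is
algebraically identical and keeps 10,500-marker panels cheap.

Directional selection induces *negative* LD between trait loci (the Bulmer
effect): the package's simulated programmes show the total genetic variance
dropping well below the genic variance within a breeding cycle, driven
predominantly by the between-chromosome LD term.

## The simulated breeding programme

`run_programme()` simulates a conventional phenotypic-selection programme for
a yield-like trait with doubled haploids (DH):

* **Genome**: 21 chromosome pairs, 1 Morgan each, 600 segregating loci per
  chromosome of which 100 are randomly flagged QTL and 500 serve as markers.
* **Founders**: 70 fully inbred lines. One haplotype per founder is drawn
  from a neutral coalescent and doubled. The generator splits each
  chromosome into independent genealogy blocks (default 10 blocks of
  0.1 Morgan); within a block a Kingman tree for the 70 haplotypes is
  simulated and mutations are dropped on branches proportionally to branch
  length, so every site is segregating by construction and the site
  frequency spectrum is the neutral one. Block independence stands in for
  ancestral recombination; it reproduces the two founder properties that
  matter downstream — segregating biallelic loci and within-chromosome LD
  decaying with map distance — without modelling a full ancestral
  recombination graph.
* **Trait**: QTL effects drawn from a standard normal, then rescaled by one
  common factor so the founder genetic variance is exactly 0.1.
* **Cycle** (one crop per year): 100 biparental crosses among 70 parents →
  100 F1 each → every F1 doubled into one DH line → 10,000 headrows
  (visually scored, heritability 0.1) → best 500 to the preliminary yield
  trial (h² 0.2) → best 50 to the advanced trial (h² 0.5) → best 10 to the
  elite trial for two consecutive years (h² 0.67) → one released variety.
  Meiosis uses Poisson crossover counts (mean = map length) with uniform
  placement and no interference (Haldane). Because parents are fully
  inbred, an F1's two haplotypes are exactly its parents' haplotypes, and a
  DH line requires a single meiosis — this is what makes 10,000 DH per year
  cheap.
* **Phenotypes**: genetic value plus normal noise with stage-specific
  residual variance fixed from the founder calibration,
  `Ve = 0.1·(1−h²)/h²`. Fixing `Ve` (rather than re-standardising per
  cohort) lets realised heritability drift downward as selection erodes
  variance, which is the convention of forward breeding simulators.
* **Parent refresh**: each year the 50 advanced-trial lines plus the 20
  elite-trial lines (both elite years) become the next parents. The first
  few warm-up years top the parent list up with founders until the pipeline
  is primed; analyses use the steady-state years.
* **Training data**: all preliminary/advanced/elite records of the last six
  years — under the defaults exactly 3,070 lines, 3,420 records (elite
  lines contribute one record per trial year) and 10,500 markers.

Year effects are zero by default (the fitted model still estimates them).
The genotype-by-year scenario adds per-year deviations to every QTL effect,
drawn independently per year and scaled so the expected variance of the
deviation genetic values over founder genotypes equals the configured amount
(0.2 in the sensitivity setting); that calibration follows from
`E[var(Qd)] = s²·Σ_l var(Q[,l])` for `d ~ N(0, s²I)`.

### What the simulator does not emulate

Real multi-environment trials have heterogeneous error variances and
spatial structure; the simulator uses one residual variance per stage.
Founders carry no population structure or admixture, dominance and epistasis
are absent (the material is fully inbred from the DH step onwards), and QTL
are placed uniformly at random. Passing tests therefore demonstrate the
estimation machinery under a clean additive architecture, not robustness to
structured germplasm.

## The marker model and its samplers

The observation model is a Bayesian ridge regression (SNP-BLUP):
`y = Xb + ZWm + e` with `m ~ N(0, I σ²_m)` and `e ~ N(0, I σ²_e)`; `X`
carries an intercept and reference-coded year contrasts, `Z` maps records to
lines, and `W` holds uncentred marker dosages (the intercept absorbs the
mean; centring `W` would only shift the intercept). σ²_m is a *model*
parameter — variance between marker effects — and is never interpreted as
genetic variance; all variance statements come from post-processing samples
of `m`.

* **Conditional (empirical Bayes) path**: given (σ²_m, σ²_e), Henderson's
  mixed model equations give `E(b, m | y)`; the conditional covariance is
  the inverse coefficient matrix times σ²_e. `sample_effects_conditional()`
  factorises the coefficient matrix once (Cholesky) and turns standard
  normal vectors into draws by back-substitution. The plug-in variances are
  the posterior means from a full-Bayes run, so the empirical path differs
  from the full path only by ignoring variance-component uncertainty — its
  posterior spread is accordingly slightly smaller.
* **Full Bayes path**: `gibbs_fit()` runs single-site Gibbs with residual
  updating; variances get scaled-inverse-χ² updates. The reference chain
  profile is 100,000 iterations, 10,000 burn-in, thinning 100 → 900 retained
  draws. Hyperpriors default to 4 degrees of freedom with scales from an
  even split of the phenotypic variance (half residual; half marker, divided
  by the summed marker-dosage variances). These defaults are deliberately
  weak; the data dominate at training-set sizes.
* **Reduced model**: `svd_reduce()` column-centres `W` and keeps the leading
  principal components (`T = US`); the model is refitted on `T` and
  component draws are mapped back by `m = Vs`. With at least `rank(W_c)`
  components the reduced fit reproduces the full fit's genetic values
  exactly (the ridge solution lives in the row space of `W_c`), and the
  explained marker-variation fraction is 1. Centring for the SVD (but not
  for the model) matches the "explained marker genotype variation" reading.

With zero phenotype records the conditional sampler returns prior draws
`N(0, σ²_m)` — the framework then correctly reports prior uncertainty
instead of a spurious zero variance.

## Posterior partitions and scoring

`partition_posterior()` treats marker genotypes and sampled marker effects
as if they were QTL genotypes and effects: per draw, genetic values per
group, then the full decomposition. Per draw the identity
`total = genic + within-LD + between-LD` holds to numerical precision, so
posterior means inherit it by linearity. Summaries use the draw mean,
standard deviation with divisor S − 1 (a summary over samples, distinct from
the 1/n convention over individuals) and linearly interpolated empirical
quantiles (R type 7) — the quantile rule is a documented choice, as is using
all retained draws.

Scoring uses the exact pairwise-sample CRPS estimator
`mean|x_s − y| − ½·mean|x_s − x_t|` (computed via the sorted-draw identity in
O(S log S)) and Lin's concordance correlation coefficient
`2·cov/(var_x + var_y + (mean_x − mean_y)²)`. The trait-specific effective
population size inverts the drift-decay model `V_t = V_0(1 − 1/(2Ne))^t`
through a log-linear least-squares fit of the genic-variance trend — a
documented interpretation of "effective size from genic-variance decay", not
a replication of any particular published estimator; a non-decaying trend
returns `Inf`.

## Numerical choices and degenerate inputs

* All genetic variances use divisor `n`; single-member groups return 0; the
  `n − 1` convention appears only in posterior summaries across draws.
* Truncation selection breaks phenotype ties deterministically by line id;
  lines with several records are ranked on their mean.
* The MME Cholesky fails loudly on collinear fixed effects; σ²_m → 0 drives
  all marker estimates to zero (prior dominance), which is exercised in
  tests rather than special-cased.
* SVD components beyond the numerical rank get zero scores and loadings;
  requests beyond `min(dim)` are capped there (where the explained fraction
  is exactly 1).
* One master seed drives every run; each stochastic operation draws from a
  named sub-stream, so any stage can be reproduced in isolation and two
  runs with equal (configuration, seed) are bit-identical.

## Problem sizes used in the test suite

The shipped tests validate the machinery at reduced problem sizes chosen so
the whole suite runs on a laptop core: a miniature programme (3 chromosomes
× 60 loci, 2,000 DH per year, 10 years) for unit and integration tests;
chains of 3,000–30,000 iterations for sampler checks; and, for the
within-cycle erosion replicates, a reduced genome (21 chromosomes × 120
loci, 20 QTL each) with the full 10,000 → 500 → 50 → 10 selection cascade.
The default-scale 21-year configuration is exercised once to pin the exact
training-set structure. The within-cycle erosion analysis compares the
headrow cohort of one crop with the same crop's first elite-trial year
(component shares expressed relative to the total change); because that
elite cohort holds only 10 lines, single-replicate shares scatter widely
around their means, so the checks test direction and dominance per replicate
and magnitudes on replicate means.

## Known limitations

* The dense MME factorisation scales as the cube of the marker count; for
  panels much beyond ~10⁴ markers the SVD-reduced model is the intended
  escape hatch (genic variance is then systematically underestimated — null
  components carry estimation uncertainty that the truncation discards, so
  reduced fits recover genetic variance long before genic variance).
* The Gibbs sampler assumes homogeneous residual variance across trials.
* Effective-population-size estimates assume log-linear genic decay; short
  or noisy series give unstable values.
* The coalescent founder generator approximates recombination by block
  independence; fine-scale founder LD patterns (e.g. demography-specific
  long-range LD) are out of scope.
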