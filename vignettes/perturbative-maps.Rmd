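---
title: "Building and benchmarking perturbative maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and benchmarking perturbative maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perturbmap)
```

## The problem

A genome-scale perturbation screen measures, for each perturbed gene, a
handful to hundreds of *perturbation units* — wells in arrayed screens,
cells in pooled single-cell screens — each summarized as a numeric
embedding vector. Two obstacles stand between those unit-level vectors
and usable biology. First, technical variation: units are acquired in
batches (plates, runs, experiments, emulsion groups), and batch-to-batch
shifts and covariance distortions are routinely larger than the
biological effect of a single gene knockout. Second, evaluation: once a
map is built, one needs statistics that say whether individual
perturbations register at all, and whether the geometry of the map
recapitulates known gene–gene relationships.

`perturbmap` addresses both. A map is built by five composable stages —
embed, filter, align, aggregate, relate — and evaluated by two benchmark
families: perturbation-signal statistics (replicate consistency, energy
distance to controls, permutation significance against an
unexpressed-gene null) and biological-relationship statistics
(percentile-tail recall of annotated pairs, KS-based complex
identification, hypergeometric enrichment).

## The pipeline stages

**Embed.** `embed_pca()` projects units onto principal components. The
rotation can be fitted on all units or on controls only, and the features
can be standardized within each batch (all units) before the fit — the
convention used for some image-based screens. PCA is computed from the
eigendecomposition of the feature covariance rather than an SVD of the
data matrix, so that all `d` components exist even when the fit set has
fewer rows than features; the sign of each component is fixed so its
largest-magnitude loading is positive, which makes results reproducible
across linear-algebra backends.

**Filter.** `apply_filters()` executes an ordered rule list.
`filter_robust_outliers()` mirrors the elliptic-envelope approach: it fits
a robust Gaussian via the minimum-covariance-determinant estimator
(`MASS::cov.rob`) to the selected QC columns and removes the declared
fraction of units with the largest robust Mahalanobis distance —
equivalently, the lowest density under the fitted Gaussian.
`filter_range()` keeps units inside an inclusive interval (the
cell-count window `[50, 350]` is the motivating case), and
`filter_drop_columns()` removes whole-image feature columns by prefix.
The shipped order — intensity outliers, then count window, then column
drop — follows the order these operations are applied to Cell Painting
profiles.

**Align.** `align_center_scale()` shifts and scales every feature by the
mean and standard deviation of reference units (controls by default),
per batch or globally. `align_tvn()` implements typical-variation
normalization: (1) center/scale features to global control statistics;
(2) fit PCA on controls only, keeping all components, and project all
units; (3) center/scale the scores to global control statistics; (4) per
batch, correlation alignment — center on the batch controls and whiten by
the inverse principal square root of their covariance, so every batch's
controls land in a common zero-mean, identity-covariance frame.

Two choices here deserve comment. The CORAL step *centers on batch
controls* before whitening: whitening second moments around a biased
mean would leave additive batch offsets untouched, and the point of the
construction is that controls define the typical variation in every
batch. And the recoloring target is the identity (pure whitening) rather
than some reference batch's covariance, since all batches are being
mapped into the common control frame. Covariances are regularized with a
ridge of `1e-6` times their mean diagonal before the matrix square root;
batch-level control counts are often small relative to the embedding
dimension and the raw covariance can be ill-conditioned. TVN should be
used with control counts comfortably above the embedding dimension in
every batch — with fewer controls the whitening step amplifies noise in
the poorly-estimated directions.

**Aggregate.** `aggregate_mean()` takes the coordinate-wise mean of the
aligned embeddings over all units sharing a perturbation label. Controls
never enter the gene universe. Replicates are whatever rows share a
label — no stratification by guide or batch — and the per-gene counts are
recorded in provenance. (Outlier-resistant aggregators such as the Tukey
median are deliberately out of scope.)

**Relate.** `relate_cosine()` produces the full symmetric matrix of
cosine similarities. A zero-norm aggregated vector is an error, not a
silent `NaN`: it indicates degenerate upstream filtering and should stop
the run.

`pipeline_preset()` names the standard compositions: `PCA` (plain PCA,
no alignment), `PCA-CS`, `PCA-TVN`, and `Raw-CS` / `Raw-TVN` which skip
the embedding. The per-batch pre-scaling variant of the PCA presets is
available via `scale_per_batch = TRUE`.

## Signal statistics

`consistency()` computes avgsim, the mean cosine similarity over
unordered replicate pairs. The literal all-pairs double sum includes the
`i = j` terms and therefore equals `1/n` — not zero — for mutually
orthogonal replicates, contradicting the property the statistic is meant
to have; the default therefore excludes self-pairs, and
`include_self = TRUE` restores the literal form for comparison.

`magnitude()` computes the standard two-sample energy distance with full
double sums and Euclidean norms. It is zero iff the two distributions
coincide, symmetric, and scales with effect size in high dimension,
which is why it is preferred over parametric location tests whose
assumptions these embeddings do not meet.

`permutation_pvalue()` compares an observed statistic against the
empirical null built from unexpressed-gene perturbations processed by
the identical code path, with `p = max(#{null ≥ obs}, 1)/K`. Ties count
as exceedances; the clamp keeps p-values in `[1/K, 1]`. At least 1000
unexpressed genes are required (configurable floor) — below that the
tail of the null is too coarse for a representative p-value.
`signal_benchmark()` assembles per-gene statistics and p-values and
reports the fraction of expressed genes significant at `alpha = 0.05`
per metric and jointly. Raw p-values are thresholded deliberately — the
benchmark compares identically-constructed fractions across pipelines,
so multiple-testing correction would only rescale both sides.

## Relationship benchmarks

`recall()` ranks all off-diagonal unordered pairwise similarities, cuts
at the 5th and 95th empirical percentiles (linear-interpolation
definition; each unordered pair counted once — recall is identical under
the ordered-pair convention), and scores the percentage of annotated
pairs falling strictly outside the cuts. Both tails count because strong
negative similarity can indicate opposing function. Annotated pairs with
either gene absent from the map are removed from the denominator, so
maps over different perturbation sets are comparable; a source with no
evaluable pair raises an error rather than reporting 0. The expected
recall of an uninformative map is `2 × tail × 100 = 10%`.

`identify_complexes()` compares, for every catalog cluster with at least
ten mapped genes, the within-cluster pair similarities against all
(member, non-member) pair similarities with a two-sided two-sample KS
test. The asymptotic p-value is used: the pair counts involved are in
the hundreds to hundreds of thousands, where the asymptotic and exact
computations agree and the exact one is unaffordable. Identification
means p < .01. Note the pair sets are built from a shared similarity
matrix, so the KS independence assumption holds only approximately;
planted-complex simulations show the test is nonetheless well behaved at
these cluster sizes.

`enrich()` performs the upper-tail hypergeometric test on the map's gene
universe — not the collection's — because the screen only had a chance to
observe genes it perturbed. Only terms with at least ten genes in the
universe are evaluated, and the Bonferroni denominator counts evaluated
terms only. `top_neighbors()` returns the k most cosine-similar genes
(default 25), self excluded, with exact ties broken lexicographically so
results are deterministic across platforms.

`noise_sensitivity()` subsamples replicates per gene at given levels,
rebuilds the map, and reports mean ± sd of recall over three redraws per
level (the number of redraws is configurable). Genes with fewer
replicates than the level keep all their units, with a logged count. One
master seed spawns per-level, per-repeat child seeds through named
sub-streams (`substream_seed()`), so adding a level never shifts the
draws of another.

## The synthetic-screen generator

`simulate_screen()` produces the statistical structure the benchmarks
assume, with known ground truth:

* **Effects.** Each planted complex receives a shared latent unit
  direction; member effects are the normalized sum of that direction and
  gene-specific jitter (default 0.35, giving within-complex effect
  cosines near 0.9). Other expressed genes get independent random unit
  directions; unexpressed genes get exactly zero effect. All expressed
  effects have norm `effect_scale`.
* **Batch artifacts.** Each batch draws an additive offset (per-feature
  sd `batch_shift_scale`) and a symmetric positive-definite covariance
  coloring `A_b = I + spread · S_b` with eigenvalues floored at 0.1. A
  *symmetric* coloring was a deliberate choice: an arbitrary linear
  distortion contains a rotation component that no second-moment method
  can recover, whereas covariance coloring is exactly the model class
  CORAL addresses. Diagonal scaling is the special case of a diagonal
  coloring. Purely additive-plus-diagonal artifacts would be removed
  *exactly* by per-batch control centering/scaling, leaving TVN nothing
  to improve on — the coloring is what makes the alignment ladder
  (unaligned < CS < TVN) observable.
* **Units.** A unit is `A_b (effect + noise) + shift_b` with isotropic
  Gaussian noise (per-coordinate sd `noise_sd`); controls carry
  artifacts and noise only. Replicates are assigned to batches uniformly
  at random.

Defaults describe a high-quality arrayed screen: 128 dimensions, four
replicates per gene across six batches, `effect_scale = 2` against
`noise_sd = 0.1` (within-gene replicate cosines around 0.75 after
perfect alignment), batch offsets whose per-feature scale is five times
the noise, and 384 controls per batch so TVN's per-batch covariances are
well-conditioned at 128 dimensions.

What the generator does *not* emulate: non-linear batch effects,
plate-position (layout) effects correlated with gene identity,
guide-level heterogeneity or off-target activity, heavy-tailed noise,
and count-based readouts. Benchmarks passing on this generator therefore
demonstrate correctness of the statistics and the expected behavior of
linear alignment under affine artifacts — not performance on any real
dataset.

## Numerical choices and degenerate inputs

* Self-distances in the energy statistic are set to exactly zero rather
  than `sqrt` of floating-point residue, and identical query/control
  samples return exactly 0.
* Cosine matrices are symmetrized and clamped to `[-1, 1]` after the
  cross-product to absorb rounding.
* Percentile cuts use the linear-interpolation empirical percentile;
  pairs exactly at a cut are *not* predicted (strict inequalities).
* Zero feature variance in a scaling reference, fewer than two reference
  units in a batch, a batch covariance singular beyond the ridge, a
  filter that removes every unit, and an annotation source with no
  mappable pair are all hard errors naming the offender.
* Rows with missing feature values are dropped at read time with a
  warning (one corrupt row should not abort a large load); the in-memory
  container never holds missing features.
* Map tables are written with 17 significant digits so a write/read
  round trip is bit-exact.

## Benchmark problem sizes

The shipped tests and the acceptance script exercise the full machinery
at desk scale, chosen so every statistical property is measurable in
seconds: the alignment-ladder and complex-identification benchmarks use
120 genes (six planted 12-gene complexes) in 32 dimensions over six
batches of 200 controls, with `effect_scale = 0.5`,
`batch_shift_scale = 1`, `batch_scale_spread = 1`, `noise_sd = 0.3` —
offsets an order of magnitude above the noise, the regime alignment
exists for. Type-I calibration uses 1000 expressed genes with zero
effect against a null of 1000 unexpressed genes, the minimum null size
the permutation test accepts. The random-map baseline uses 1000 genes in
128 dimensions with 2000 random annotated pairs, averaged over ten
draws.

## Known limitations

TVN requires per-batch control counts above the embedding dimension;
there is no shrinkage estimator fallback. The cross-pair set in complex
identification is materialized in memory, which is fine to a few
thousand genes but would need streaming beyond that. Gene identifiers
are matched case-sensitively with no alias reconciliation beyond
whitespace trimming — symbol harmonization across annotation sources is
the caller's responsibility. Deep-learning embeddings (scVI,
CNN-derived) are accepted as precomputed inputs only; the package does
not train them.
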