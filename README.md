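# perturbmap

Genome-scale perturbation screens — pooled CRISPR knockouts read out by
imaging or single-cell RNA-seq, arrayed Cell Painting plates — produce one
embedding vector per *perturbation unit* (a well, or a cell). Turning those
unit-level readouts into a **perturbative map** — one vector per perturbed
gene, plus the pairwise relationships between genes — requires a chain of
processing choices, and those choices (how to embed, which units to filter,
how to remove batch effects, how to aggregate replicates, how to relate
genes) largely determine how much biology the map recovers.

`perturbmap` implements that chain as five composable stages — **E**mbed,
**F**ilter, **A**lign, **A**ggregate, **R**elate — together with the
benchmark statistics needed to compare pipeline variants, and a
synthetic-screen generator with known ground truth so the whole machinery
can be exercised and validated without any external dataset.

## What it computes

**Map building.** PCA embedding (optionally per-batch standardized);
unit-level QC filters (robust-Gaussian outlier removal at a fixed
contamination rate, inclusive range filters on object counts, prefix-based
column drops); alignment by control-anchored centering/scaling (per batch
or global) or by typical-variation normalization, which fits PCA on control
units, standardizes scores to global control statistics, and then applies
correlation alignment (CORAL) per batch — centering on batch controls and
whitening by the inverse principal square root of their covariance;
aggregation by the per-gene mean; relationships by cosine similarity.

**Perturbation-signal benchmarks.** For a gene g with replicate embeddings
x_{g,1}, …, x_{g,n}:

- *Consistency*: `avgsim(g)` = mean cosine similarity over all unordered
  replicate pairs (1 when replicates share an orientation, 0 when mutually
  orthogonal).
- *Magnitude*: the two-sample energy distance between the gene's units
  {x_i} and the negative controls {y_j},
  `E = 2/(n1·n2)·ΣΣ‖x_i−y_j‖ − 1/n1²·ΣΣ‖x_i−x_j‖ − 1/n2²·ΣΣ‖y_i−y_j‖`.
- *Significance*: a permutation p-value against the empirical null formed
  by the same statistic over genes unexpressed in the assayed cell type,
  `p = max(#{null ≥ observed}, 1)/K`, requiring K ≥ 1000 unexpressed genes.

**Biological-relationship benchmarks.** Percentile-tail recall: the
percentage of annotated gene pairs (complex co-membership, pathway edges,
high-confidence protein links) whose cosine similarity falls below the 5th
or above the 95th percentile of all pairwise similarities — a random map
scores 10%. Protein-complex identification: a two-sample KS test comparing
within-complex pair similarities to (member, non-member) pair similarities
for every complex with ≥ 10 mapped genes, identified at p < .01.
Hypergeometric gene-set enrichment with Bonferroni correction over terms
with ≥ 10 genes in the map. A replicate-subsampling noise-sensitivity
analysis (3 random redraws per level, mean ± sd).

## Worked example

Simulate a screen with six planted 12-gene complexes, strong additive
batch offsets and per-batch covariance coloring, plus 1000 unexpressed
genes for the permutation null; build a PCA-TVN map; benchmark it:

```r
library(perturbmap)

cfg <- sim_config(n_genes = 120, n_unexpressed = 1000, n_complexes = 6,
                  complex_size = 12, dims = 32, n_batches = 6,
                  controls_per_batch = 200, effect_scale = 1,
                  batch_shift_scale = 1, batch_scale_spread = 1,
                  noise_sd = 0.3, seed = 1)
sim <- simulate_screen(cfg)
#> perturb_sim: 120 expressed + 1000 unexpressed genes, 6 complexes, 5680 units

res <- run_pipeline(sim$units, pipeline_preset("PCA-TVN", k = 32, seed = 1))
recall(res$sim, sim$pairs)
#>              source recall_percent n_eval_pairs  lower_cut upper_cut
#> 1 planted_complexes       92.17172          396 -0.2932786 0.2979853

signal_benchmark(res$units, alpha = 0.05)
#> signal_report: 120 expressed genes, K = 1000
#>   significant (p < 0.05): consistency 87.5%, magnitude 95.0%, both 87.5%

head(identify_complexes(res$sim, sim$catalog), 3)
#>   complex n_in_map evaluated ks_statistic p_value identified
#> 1 CPLX001       12      TRUE    0.9237775       0       TRUE
#> 2 CPLX002       12      TRUE    0.8723745       0       TRUE
#> 3 CPLX003       12      TRUE    0.9431818       0       TRUE
```

92% of the planted within-complex pairs land in the 10% similarity tails
(a random map would recover 10%), the permutation tests call most genes
significant on both signal metrics, and every planted complex is
identified by the KS test. Swapping `"PCA-TVN"` for `"PCA"` (no
alignment) or `"PCA-CS"` (per-batch control centering/scaling only) shows
the alignment ladder: under these batch artifacts the unaligned map drops
to near the random baseline, CS recovers the additive offsets, and TVN
additionally removes the covariance coloring.

A thin command-line front end (`inst/cli/perturbmap.R`) drives the same
functions from the shell: `simulate`, `build-map`, `benchmark`, `explore`,
each writing delimited tables plus a `manifest.json` with seeds and config
digests.

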