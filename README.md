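# scRefCluster

Supervised clustering and annotation of single-cell RNA-seq data: transfer
cell-type labels from an annotated reference ("source") dataset to an
unlabeled query ("target") dataset by clustering their union in a shared
latent space — and flag clusters that match nothing in the reference as
`unassigned`, so novel cell types surface instead of being forced onto known
labels.

## Who this is for

Anyone with a QC'd, labeled reference count matrix and a new unlabeled count
matrix from the same (or similar) tissue who wants per-cell type annotations,
cluster memberships, and an explicit novelty call, without hand-curating
marker genes.

## The model

Counts are modeled by a zero-inflated negative binomial (ZINB),
`P(x) = π δ₀(x) + (1−π) NB(x | μ, θ)`, whose parameter fields are produced by
a batch-conditional denoising autoencoder: encoder input `[x ‖ b]` (z-scored
expression plus one-hot batch), hidden layers 256 → 64, latent code z of
dimension 32, decoder input `[z ‖ b]`, and three output heads (π logistic,
μ exponential × cell size factor, θ softplus). Training proceeds in three
stages, each keeping the reconstruction loss L1 to preserve global structure:

1. **Pretraining** — L1 + L2, cross-entropy on labeled reference cells;
2. **Similarity fusion** — L1 + λ₁L3, a pairwise pseudo-label loss on cosine
   similarities with dynamic thresholds `u(t) = 0.95 − 0.0045 t`,
   `l(t) = 0.455 + 0.00045 t` (similar pair if S > u or same labels,
   dissimilar if S < l or different labels, otherwise skipped), run until the
   thresholds meet at 0.5;
3. **Clustering refinement** — L1 + λ₂L4, entropy-regularized soft k-means on
   the unit sphere with closed-form memberships
   `w_ij ∝ exp(−2(1 − zᵢᵀv_j)/σ)`, σ = 1, centers initialized by k-means.

Clusters are annotated by the *clarity score*: for cluster i and reference
type c, `f(i, c)` is the fraction of all type-c reference cells captured by
cluster i; the type with the largest `f > 0.5` annotates the cluster
(clarity = that fraction), otherwise the cluster is `unassigned`. Target
cells inherit their cluster's annotation. Performance is reported as the
adjusted Rand index of target-cell clusters against true types and the
annotation accuracy on cell types shared with the reference.

A two-batch Splat-style count simulator (gene-level differential expression,
batch effects, mean-dependent logistic dropout, `dropout.mid`-controlled
zero inflation, geometric group imbalance) generates the benchmark designs.

## Worked example

```r
library(scRefCluster)

# simulate a small reference + query pair from the same six cell groups
cfg <- sim_config(n_genes = 1500, source_cells = 900, target_cells = 900,
                  dropout_mid = -1, seed = 1)
sim <- simulate_two_batch(cfg)

merged <- merge_on_shared_genes(sim$source, sim$target)
pd <- preprocess(merged, n_hvg = 400)

plan <- train_plan(network_config(epochs_pretrain = 150, epochs_fuse = 100,
                                  seed = 1))
fit <- run_pipeline(pd, k = 6, plan = plan)
annotation <- annotate_fit(fit)
annotation$clusters
evaluate_fit(fit, sim$target$labels, annotation = annotation)
```

Output:

```
  cluster annotated_type clarity size n_source
1       1              5       1  294      150
2       2              4       1  284      150
3       3              1       1  296      150
4       4              3       1  309      150
5       5              0       1  293      150
6       6              2       1  324      150
ARI (target cells):      0.8207
Annotation accuracy:     0.9222  (on 900 overlapping of 900 target cells)
```

Each cluster captured all 150 reference cells of exactly one type (clarity
1.0), so every cluster inherits an unambiguous label; 92% of query cells
received their true type, and the clustering of the query cells agrees with
the true groups at ARI 0.82. This is a deliberately small, fast example —
accuracy rises with more cells, genes and training epochs (the benchmark
designs in the vignette run at 3600 + 3600 cells), and deleting groups from
the reference before merging demonstrates novel-type discovery: clusters
formed by reference-free query cells come out `unassigned`.

## Command line

A thin CLI wraps the same functions (`inst/exec/screfcluster`):

```sh
Rscript inst/exec/screfcluster simulate --scenario equal,balanced,0.5 --seed 3 --out sim/
Rscript inst/exec/screfcluster run-all --source sim/source.csv --target sim/target.csv \
    --meta sim/meta.tsv --truth sim/truth.tsv --k 6 --seed 1 --out run/
```

`run-all` chains preprocess → train → annotate → evaluate and writes a
manifest with content hashes of every output.

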