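# spatlo

Spatial transcriptomics (ST) analysis of tertiary lymphoid organs (TLOs) in
inflamed synovial tissue.

In rheumatoid arthritis, infiltrating leukocytes organize into dense,
lymph-node-like aggregates (TLOs) inside the synovium. Barcoded-array ST
profiles the transcriptome of ~100 µm tissue spots while retaining their
(x, y) position, and serial sections extend the picture to a 3D volume.
`spatlo` implements a complete, tested pipeline for this kind of data, for
computational biologists analysing multi-section ST volumes of inflamed
tissue:

* **Preprocessing** — spot quality filtering (≥ 200 detected genes),
  size-factor or regression-residual normalization, and variable-gene
  ranking by the squared coefficient of variation,
  `CV²_g − median_g(CV²)`, on size-factor-scaled counts.
* **Spatial clustering** — PCA with a deflated permutation (parallel
  analysis) test selecting the number of informative components at 5% FDR,
  3-component tSNE, and `ward.D2` hierarchical clustering; cluster 1 is by
  convention the densest (infiltrate) cluster. Cluster markers are called by
  a negative-binomial likelihood-ratio test with a log-depth offset
  (DE gate: p < 0.001 and log-ratio > 0.5); group contrasts use Welch t
  tests with Benjamini–Hochberg adjustment.
* **Cell-type scoring** — marker signatures (avg log fold-change > 1,
  FDR < 5%, top 200 per type) are pruned by a co-expression validity filter
  (a marker is kept when its mean Pearson correlation with the type's other
  markers is positive), summed per spot into a raw score
  `c_{l,r} = Σ_m Y_{m,r}`, max-scaled per type
  `C_{l,r} = c_{l,r} / max_r c_{l,r}`, and renormalized within each spot to
  cell-type proportions.
* **TLO detection** — segmented cells are aggregated into per-spot windows;
  the within-section percentile of the cell count is the density score, and
  spots scoring above 70 are TLO candidates.
* **3D reconstruction** — serial sections are registered by least-squares
  point-set alignment (rigid or scaled-rotation similarity transforms) and
  each section's scalar fields are interpolated on the Delaunay
  triangulation with convex-hull masking.
* **Interactions & enrichment** — receptor–ligand pairs are scored within
  spot subsets by the mean of the partners' average expression with a
  label-permutation p-value (significant at log mean ratio > 0.1,
  p < 0.01); gene sets are tested by the hypergeometric upper tail with BH
  control.
* **Power analysis** — Monte-Carlo power for nested designs (patients /
  sections / annotated spots) under a linear mixed model
  `y = β·group + u_patient + v_section + ε`, testing the group effect on
  patient means.
* **Synthetic data** — a generator producing multi-section volumes with a
  lymphocyte-rich TLO core, radially arranged surrounding zones, known
  per-spot cell-type mixtures, negative-binomial counts and matched cell
  tables, used as ground truth for every stage.

## Worked example

```r
library(spatlo)

params <- sim_params(seed = 42)                 # 3 sections x 650 spots
ref    <- make_reference(params)                # marker blocks + signatures
vol    <- simulate_volume(params, ref$signature_matrix, group = "seropositive")
vol$counts
#> <spot_matrix> 1950 spots x 1000 genes, layer = raw

## TLO detection from the cell table
agg  <- aggregate_cells_to_spots(vol$cells, vol$spots,
                                 window = attr(vol$cells, "window"))
dens <- density_score(agg$cell_count, agg$section_id)
annotation_overlap(dens, vol$spots$annotation)
#> [1] 1        # all annotated infiltrate spots exceed the 70% density score

## spatial clustering (variable genes -> PCA -> tSNE -> ward.D2)
cfg <- run_config(n_variable_genes = 500, n_clusters = 4, rng_seed = 42,
                  normalization_mode = "size_factor_log")
res <- cluster_spots(vol$counts, cfg, perplexity = 50,
                     density = setNames(agg$cell_count, agg$barcode))
res$embedding$n_pcs_selected
#> [1] 5
res$clusters
#> <cluster_assignment> 1950 spots, k = 4 (ward.D2 on tSNE components), scope = whole_volume
#>   1   2   3   4
#> 249 625 432 644

## cluster 1 (the densest) is the infiltrate cluster
cl1  <- names(res$clusters$labels)[res$clusters$labels == 1]
mean(vol$truth$true_cluster[match(cl1, vol$truth$barcode)] == "TLO_core")
#> [1] 0.96

## cell-type proportions per spot and co-localization with density
scores <- score_cell_types(res$normalized, ref$signatures)
colocalize(scores$proportions[, "CT1"], agg$cell_count)$pearson_r
#> [1] 0.69     # B-cell proportion tracks cell density

## 3D reconstruction
vol3d <- register_sections(vol$spots, mode = "scaled_rotation")
vol3d <- interpolate_volume(vol3d,
                            setNames(scores$proportions[, "CT1"],
                                     rownames(scores$proportions)),
                            grid_step = 2)
vol3d$z
#> sec01 sec02 sec03
#>     0     7    14
```

The numbers mean: the density-percentile rule recovers every simulated
infiltrate spot; the clustering pipeline isolates the TLO cores as the
densest cluster with 96% purity; the B-cell proportion map co-localizes
with cell density (r = 0.69); and the three sections are registered and
interpolated into a z-indexed volume. The full-size example takes a few
minutes, almost all of it in the permutation test for the number of
principal components.

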