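#' Spatial clustering pipeline: variable genes -> PCA -> tSNE -> ward.D2
#'
#' Convenience wrapper chaining the clustering stages with one
#' configuration: spot filtering, variable-gene selection on raw counts,
#' normalization, PCA with permutation-selected dimensions, 3-component
#' tSNE, and ward.D2 hierarchical clustering cut at `n_clusters`.
#'
#' @param counts raw-layer [spot_matrix].
#' @param config a [run_config()].
#' @param min_genes spot filter threshold (default 200); use 0 to skip.
#' @param density optional per-spot density (named by barcode) used to order
#'   cluster labels so cluster 1 is the densest.
#' @param section_id optional per-spot section ids (named by barcode).
#' @param perplexity,n_perm,max_pcs tuning forwarded to the stages.
#' @return list: `clusters` (a `cluster_assignment`), `embedding`
#'   (`embedding_result`), `variable_genes` (selection table), `normalized`
#'   ([spot_matrix]), `filtered` (raw [spot_matrix] after spot filter).
#' @export
cluster_spots <- function(counts, config = run_config(), min_genes = 200,
                          density = NULL, section_id = NULL,
                          perplexity = 30, n_perm = 200, max_pcs = 20) {
  stopifnot(inherits(counts, "spot_matrix"), inherits(config, "run_config"))
  filt <- if (min_genes > 0) filter_spots(counts, min_genes) else counts
  vg <- select_variable_genes(filt, config$n_variable_genes)
  norm <- normalize_spots(filt, config$normalization_mode)
  sub <- subset_genes(norm, vg$gene[vg$selected])
  emb <- pca_with_permutation(sub, max_pcs = max_pcs, n_perm = n_perm,
                              seed = config$rng_seed)
  emb <- embed_tsne(emb, n_components = 3, perplexity = perplexity,
                    seed = config$rng_seed)
  bc <- rownames(emb$tsne)
  dens <- if (!is.null(density)) unname(density[bc]) else NULL
  sec <- if (!is.null(section_id)) unname(section_id[bc]) else NULL
  cl <- cluster_ward(emb, k = config$n_clusters, density = dens,
                     section_id = sec)
  list(clusters = cl, embedding = emb, variable_genes = vg,
       normalized = norm, filtered = filt)
}
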