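make_sm <- function(v) {
  dimnames(v) <- list(sprintf("b%04d", seq_len(nrow(v))),
                      sprintf("g%04d", seq_len(ncol(v))))
  spot_matrix(v, "sizefactor")
}

test_that("pure noise selects the enforced floor of two components", {
  set.seed(21)
  m <- make_sm(matrix(rnorm(150 * 60), 150, 60))
  e <- pca_with_permutation(m, max_pcs = 10, n_perm = 99, seed = 2)
  expect_equal(e$n_pcs_selected, 2L)
  expect_true(all(e$perm_pvalues >= 0 & e$perm_pvalues <= 1))
  expect_warning(pca_with_permutation(m, max_pcs = 5, n_perm = 10, seed = 2),
                 "resolution")
})

test_that("planted rank-2 structure is recovered across seeds", {
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n <- 120; g <- 60
    u1 <- rnorm(n); u2 <- rnorm(n)
    v1 <- rnorm(g); v2 <- rnorm(g)
    snr <- 5
    x <- sqrt(snr / g) * (u1 %o% v1 + u2 %o% v2) + matrix(rnorm(n * g), n, g)
    e <- pca_with_permutation(make_sm(x), max_pcs = 10, n_perm = 199,
                              seed = seed)
    hits <- hits + (e$n_pcs_selected == 2L)
  }
  expect_gte(hits, 18L)
})

test_that("tSNE is deterministic for a fixed seed and separates blobs", {
  set.seed(22)
  n <- 120
  lab <- rep(1:2, each = n / 2)
  x <- matrix(rnorm(n * 20), n, 20)
  x[lab == 2, 1] <- x[lab == 2, 1] + 12
  m <- make_sm(x)
  e <- pca_with_permutation(m, max_pcs = 5, n_perm = 49, seed = 1)
  e1 <- embed_tsne(e, perplexity = 20, seed = 7)
  e2 <- embed_tsne(e, perplexity = 20, seed = 7)
  expect_identical(e1$tsne, e2$tsne)
  expect_equal(ncol(e1$tsne), 3L)
  sil <- cluster::silhouette(lab, dist(e1$tsne))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_error(embed_tsne(e, perplexity = n / 3, seed = 1),
               class = "spatlo_parameter_error")
})

test_that("ward clustering on tSNE: singleton limit and spot-order invariance", {
  set.seed(23)
  e <- structure(list(tsne = matrix(rnorm(30), 10, 3,
                                    dimnames = list(sprintf("b%02d", 1:10), NULL)),
                      n_pcs_selected = 2L),
                 class = "embedding_result")
  ca <- cluster_ward(e, k = 10)
  expect_equal(sort(unique(ca$labels)), 1:10)
  e2 <- e; perm <- sample(10)
  e2$tsne <- e$tsne[perm, ]
  ca4 <- cluster_ward(e, k = 4)
  ca4p <- cluster_ward(e2, k = 4)
  expect_equal(ca4p$labels[names(ca4$labels)], ca4$labels)
})

test_that("density-ordered labels make cluster 1 the densest", {
  set.seed(24)
  n <- 60
  e <- structure(list(tsne = cbind(c(rnorm(n/2), rnorm(n/2, 20)),
                                   rnorm(n), rnorm(n)),
                      n_pcs_selected = 2L), class = "embedding_result")
  rownames(e$tsne) <- sprintf("b%02d", 1:n)
  dens <- c(rep(1, n/2), rep(50, n/2))
  ca <- cluster_ward(e, k = 2, density = dens)
  by_cl <- tapply(dens, ca$labels, mean)
  expect_equal(unname(which.max(by_cl)), 1L)
})

test_that("planted zones are recovered by the full clustering pipeline", {
  fx <- small_sim(seed = 3)
  cfg <- run_config(n_variable_genes = 200, n_clusters = 4, rng_seed = 3,
                    normalization_mode = "size_factor_log")
  res <- cluster_spots(fx$sim$counts, cfg, min_genes = 100)
  zone <- fx$sim$truth$true_cluster[
    match(names(res$clusters$labels), fx$sim$truth$barcode)]
  expect_gte(mclust::adjustedRandIndex(res$clusters$labels, zone), 0.9)
})

test_that("NB LRT flags a planted fold change and skips all-zero genes", {
  set.seed(25)
  n <- 120; G <- 40
  depth <- rep(1000, n)
  base <- rep(1 / G, G)
  mu <- outer(depth, base)
  lab <- rep(1:2, each = n / 2)
  mu[lab == 1, 5] <- mu[lab == 1, 5] * 4   # 4-fold in cluster 1
  cnt <- matrix(rnbinom(n * G, size = 5, mu = mu), n, G,
                dimnames = list(sprintf("b%03d", 1:n), sprintf("g%03d", 1:G)))
  cnt[, 40] <- 0L
  asg <- spatlo:::new_cluster_assignment(setNames(lab, rownames(cnt)), NULL, 2)
  de <- de_between_clusters(spot_matrix(cnt), asg)
  hit <- de[de$gene == "g005" & de$cluster == 1, ]
  expect_true(hit$is_de)
  expect_gt(hit$log_ratio, 0.5)
  zero <- de[de$gene == "g040", ]
  expect_true(all(zero$p_value == 1))
  expect_true(all(de$lrt_statistic >= 0))
})

test_that("NB LRT p-values are calibrated under a permuted null", {
  set.seed(26)
  n <- 200; G <- 500
  depth <- rlnorm(n, log(2000), 0.3)
  base <- rlnorm(G); base <- base / sum(base)
  mu <- outer(depth, base)
  cnt <- matrix(rnbinom(n * G, size = 5, mu = mu), n, G,
                dimnames = list(sprintf("b%03d", 1:n), sprintf("g%03d", 1:G)))
  lab <- sample(rep(1:2, each = n / 2))
  asg <- spatlo:::new_cluster_assignment(setNames(lab, rownames(cnt)), NULL, 2)
  de <- de_between_clusters(spot_matrix(cnt), asg)
  p <- de$p_value[de$cluster == 1]
  expect_gte(mean(p < 0.05), 0.03)
  expect_lte(mean(p < 0.05), 0.07)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("group comparison: identical samples, planted shift, BH arithmetic", {
  set.seed(27)
  a <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  res_same <- group_compare(a, a)
  expect_true(all(res_same$p == 1))
  b <- a; b[, 2] <- b[, 2] + 2  # d = 2 at n = 50/side: power ~ 1
  res <- group_compare(a, b)
  expect_true(res$significant[res$feature == "f2"])
  expect_equal(res$bh_p, manual_bh(res$p))
  # constant unequal-mean feature
  ca <- matrix(c(rep(1, 5), rep(2, 5)), 5, 2,
               dimnames = list(NULL, c("u", "v")))
  cb <- matrix(c(rep(1, 5), rep(3, 5)), 5, 2,
               dimnames = list(NULL, c("u", "v")))
  rc <- group_compare(ca, cb)
  expect_equal(rc$p, c(1, 0))
})
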