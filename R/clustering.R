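#' PCA with permutation-based dimension selection
#'
#' Computes principal components of the (column-centered) normalized
#' expression matrix and selects the number of leading components to carry
#' into the tSNE embedding by a deflated permutation (parallel-analysis)
#' test. Component k is tested against the residual matrix left after
#' projecting out the first k-1 components: each gene column of the residual
#' is independently shuffled across spots and the observed k-th eigenvalue
#' is compared with the top eigenvalue of the shuffled residual. Deflation
#' keeps variance carried by already-accepted components from inflating the
#' null spectrum of later ones, which would otherwise mask weaker structure.
#' Testing stops at the first clearly null component (raw p > 0.25;
#' untested components get p = 1). P-values are Benjamini-Hochberg adjusted
#' across components and components significant at the given FDR are
#' retained, with a floor of two so an embedding always exists.
#'
#' @param m normalized [spot_matrix], typically restricted to the selected
#'   variable genes.
#' @param max_pcs number of leading components to compute and test.
#' @param n_perm number of permutations (< 20 triggers a resolution warning).
#' @param seed RNG seed for the permutations.
#' @param fdr FDR level for component selection (default 0.05).
#' @return list of class `embedding_result`: `pca_scores` (spots x max_pcs),
#'   `eigenvalues`, `perm_pvalues`, `bh_pvalues`, `n_pcs_selected`, and a
#'   `tsne` slot filled by [embed_tsne()].
#' @export
pca_with_permutation <- function(m, max_pcs = 20, n_perm = 200, seed = 1,
                                 fdr = 0.05) {
  stopifnot(inherits(m, "spot_matrix"))
  if (n_perm < 20)
    warning("n_perm < 20 gives poor p-value resolution")
  v <- as.matrix(m$values)
  n <- nrow(v); g <- ncol(v)
  if (n < max_pcs + 1 || g < max_pcs + 1)
    max_pcs <- min(n, g) - 1L
  ctr <- scale(v, center = TRUE, scale = FALSE)
  top_eig <- function(x) {
    if (min(dim(x)) <= 60) svd(x, nu = 0, nv = 0)$d[1]^2 / (nrow(x) - 1)
    else irlba::irlba(x, nv = 1, nu = 0, tol = 1e-4)$d[1]^2 / (nrow(x) - 1)
  }
  # shuffle every column independently (vectorized index construction)
  shuffle_cols <- function(x) {
    nn <- nrow(x); gg <- ncol(x)
    idx <- vapply(seq_len(gg), function(j) sample.int(nn), integer(nn))
    matrix(x[as.vector(idx) + rep((seq_len(gg) - 1L) * nn, each = nn)],
           nn, gg)
  }
  sv <- if (min(dim(ctr)) <= max(3 * max_pcs, 60)) svd(ctr, nv = max_pcs)
        else irlba::irlba(ctr, nv = max_pcs)
  obs <- sv$d[seq_len(max_pcs)]^2 / (n - 1)
  V <- sv$v[, seq_len(max_pcs), drop = FALSE]
  scores <- ctr %*% V
  rownames(scores) <- rownames(v)
  colnames(scores) <- paste0("PC", seq_len(max_pcs))
  pvals <- rep(1, max_pcs)
  with_sim_seed(seed, {
    resid <- ctr
    stop_at <- ceiling(0.25 * (n_perm + 1))  # p is > 0.25 beyond this count
    for (k in seq_len(max_pcs)) {
      exceed <- 0L
      for (p in seq_len(n_perm)) {
        exceed <- exceed + (top_eig(shuffle_cols(resid)) >= obs[k])
        if (exceed >= stop_at) break
      }
      pvals[k] <- if (exceed >= stop_at) 1 else (1 + exceed) / (n_perm + 1)
      if (pvals[k] > 0.25) break
      resid <- resid - scores[, k] %o% V[, k]
    }
  })
  bh <- p.adjust(pvals, method = "BH")
  n_sel <- max(2L, sum(bh < fdr))
  structure(list(pca_scores = scores, eigenvalues = obs,
                 perm_pvalues = pvals, bh_pvalues = bh,
                 n_pcs_selected = n_sel, tsne = NULL),
            class = "embedding_result")
}

#' tSNE embedding of the selected principal components
#'
#' Runs Barnes-Hut tSNE on the permutation-selected principal components.
#' Three output components are the default so that downstream hierarchical
#' clustering operates on the first three tSNE dimensions.
#'
#' @param e an `embedding_result` from [pca_with_permutation()].
#' @param n_components tSNE output dimensionality (default 3).
#' @param perplexity tSNE perplexity; must be below `(n_spots - 1) / 3`.
#' @param seed RNG seed; fixed seed gives an identical embedding.
#' @param max_iter tSNE iterations.
#' @return the `embedding_result` with its `tsne` slot filled.
#' @export
embed_tsne <- function(e, n_components = 3, perplexity = 30, seed = 1,
                       max_iter = 1000) {
  stopifnot(inherits(e, "embedding_result"))
  X <- e$pca_scores[, seq_len(e$n_pcs_selected), drop = FALSE]
  n <- nrow(X)
  if (perplexity >= (n - 1) / 3)
    stop_spatlo("perplexity must be < (n_spots - 1) / 3",
                "spatlo_parameter_error")
  emb <- with_sim_seed(seed,
    Rtsne::Rtsne(X, dims = n_components, perplexity = perplexity,
                 pca = FALSE, check_duplicates = FALSE,
                 max_iter = max_iter, verbose = FALSE)$Y)
  rownames(emb) <- rownames(X)
  colnames(emb) <- paste0("tSNE", seq_len(n_components))
  e$tsne <- emb
  e
}

new_cluster_assignment <- function(labels, section_id, k,
                                   scope = "whole_volume",
                                   linkage = "ward.D2 on tSNE components") {
  structure(list(labels = labels, section_id = section_id, k = as.integer(k),
                 scope = scope, linkage = linkage),
            class = "cluster_assignment")
}

#' @export
as.data.frame.cluster_assignment <- function(x, ...) {
  data.frame(barcode = names(x$labels),
             section_id = x$section_id %||% NA_character_,
             cluster = as.integer(x$labels), row.names = NULL)
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d spots, k = %d (%s), scope = %s\n",
              length(x$labels), x$k, x$linkage, x$scope))
  print(table(x$labels))
  invisible(x)
}

#' Ward hierarchical clustering of the tSNE embedding
#'
#' Agglomerative clustering with the ward.D2 criterion on Euclidean
#' distances between the tSNE components, cut at `k` clusters. When a
#' per-spot density is supplied, cluster labels are renumbered by descending
#' mean density so that cluster 1 is the densest (the infiltrate cluster by
#' convention); otherwise labels are renumbered by descending cluster size.
#'
#' @param e an `embedding_result` with a filled `tsne` slot.
#' @param k number of clusters (2..n_spots).
#' @param density optional per-spot numeric (same order as spots) used to
#'   order cluster labels.
#' @param section_id optional per-spot section identifiers carried through
#'   to the output.
#' @param scope `"whole_volume"` or `"infiltrate_only"`.
#' @return a `cluster_assignment`.
#' @export
cluster_ward <- function(e, k, density = NULL, section_id = NULL,
                         scope = c("whole_volume", "infiltrate_only")) {
  stopifnot(inherits(e, "embedding_result"))
  scope <- match.arg(scope)
  if (is.null(e$tsne))
    stop_spatlo("run embed_tsne before cluster_ward", "spatlo_validation_error")
  n <- nrow(e$tsne)
  if (k < 1 || k > n)
    stop_spatlo("k must be between 1 and the number of spots",
                "spatlo_parameter_error")
  if (k > nrow(unique(e$tsne)))
    stop_spatlo("k exceeds the number of distinct embedded points",
                "spatlo_parameter_error")
  hc <- hclust(dist(e$tsne), method = "ward.D2")
  raw <- cutree(hc, k = k)
  # deterministic label order: densest (or largest) first, ties broken by
  # the smallest member barcode so labels do not depend on spot order
  anchor <- vapply(split(rownames(e$tsne), raw), min, "")
  ord <- if (!is.null(density)) {
    stopifnot(length(density) == n)
    order(-vapply(split(density, raw), mean, 1), anchor)
  } else {
    order(-tabulate(raw, k), anchor)
  }
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- relabel[raw]
  names(labels) <- rownames(e$tsne)
  new_cluster_assignment(labels, section_id, k, scope)
}

# moment estimate of the NB dispersion alpha under the offset-only model:
# match the Pearson chi-square statistic sum (y-mu)^2 / (mu + alpha mu^2)
# to its degrees of freedom (bisection; monotone decreasing in alpha)
mom_theta <- function(v, depth) {
  p_g <- colSums(v) / sum(depth)
  vapply(seq_len(ncol(v)), function(j) {
    mu <- depth * p_g[j]
    y <- v[, j]
    if (all(y == 0)) return(1e8)
    df <- length(y) - 1
    f <- function(a) sum((y - mu)^2 / (mu + a * mu^2)) - df
    if (f(1e-8) <= 0) return(1e8)  # at or below Poisson variation
    lo <- 1e-8; hi <- 1
    while (f(hi) > 0 && hi < 1e4) hi <- hi * 10
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    1 / ((lo + hi) / 2)
  }, 1)
}

#' Cluster-versus-rest differential expression by negative-binomial LRT
#'
#' For every gene and cluster, fits a negative-binomial GLM of counts on a
#' cluster-membership indicator with a log-depth offset, with per-gene
#' dispersion estimated by the method of moments (floored at 1e-8), and
#' tests the indicator by a likelihood-ratio test (1 df). The effect size is
#' the log-ratio: mean log1p size-factor-normalized expression inside the
#' cluster minus outside. A gene is flagged DE in a cluster when
#' `p < p_threshold` and `log_ratio > logratio_threshold`.
#'
#' @param m raw-layer [spot_matrix].
#' @param assignment a `cluster_assignment` covering the same spots.
#' @param p_threshold,logratio_threshold DE gate (defaults 0.001 and 0.5).
#' @return data.frame with one row per (gene, cluster): `log_ratio`,
#'   `lrt_statistic`, `p_value`, `bh_adjusted_p`, `is_de`.
#' @export
de_between_clusters <- function(m, assignment, p_threshold = 0.001,
                                logratio_threshold = 0.5) {
  stopifnot(inherits(m, "spot_matrix"), inherits(assignment, "cluster_assignment"))
  if (m$layer != "raw")
    stop_spatlo("de_between_clusters requires raw counts", "spatlo_validation_error")
  v <- as.matrix(m$values)
  labels <- assignment$labels[rownames(v)]
  if (any(is.na(labels)))
    stop_spatlo("assignment does not cover all spots", "spatlo_validation_error")
  ks <- sort(unique(labels))
  if (length(ks) < 2)
    stop_spatlo("need at least two clusters", "spatlo_validation_error")
  if (any(table(labels) < 3))
    stop_spatlo("each cluster needs at least 3 spots", "spatlo_validation_error")
  depth <- rowSums(v)
  off <- log(depth)
  theta <- mom_theta(v, depth)
  sf <- depth / median(depth)
  ln <- log1p(v / sf)
  out <- vector("list", length(ks))
  X0 <- matrix(1, nrow = nrow(v))
  for (ci in seq_along(ks)) {
    k <- ks[ci]
    ind <- as.numeric(labels == k)
    X1 <- cbind(1, ind)
    lrt <- p <- lr <- numeric(ncol(v))
    for (j in seq_len(ncol(v))) {
      y <- v[, j]
      if (all(y == 0)) { lrt[j] <- 0; p[j] <- 1; lr[j] <- 0; next }
      fam <- MASS::negative.binomial(theta = theta[j])
      f0 <- suppressWarnings(glm.fit(X0, y, family = fam, offset = off))
      f1 <- suppressWarnings(glm.fit(X1, y, family = fam, offset = off))
      lrt[j] <- max(f0$deviance - f1$deviance, 0)
      p[j] <- pchisq(lrt[j], df = 1, lower.tail = FALSE)
      lr[j] <- mean(ln[ind == 1, j]) - mean(ln[ind == 0, j])
    }
    out[[ci]] <- data.frame(gene = colnames(v), cluster = k,
                            log_ratio = lr, lrt_statistic = lrt,
                            p_value = p, row.names = NULL)
  }
  res <- do.call(rbind, out)
  res$bh_adjusted_p <- p.adjust(res$p_value, method = "BH")
  res$is_de <- res$p_value < p_threshold & res$log_ratio > logratio_threshold
  res
}

#' Feature-wise Welch t tests between two groups with BH adjustment
#'
#' Runs a two-sided Welch t test per feature (gene or cell-type score)
#' between two groups of spots and adjusts across features by
#' Benjamini-Hochberg. Features constant in both groups with equal means
#' get p = 1; constant with unequal means, p = 0.
#'
#' @param values_a,values_b numeric matrices (observations x features) with
#'   matching columns, or vectors for a single feature.
#' @param alpha adjusted significance level (default 0.05).
#' @return data.frame (feature, mean_a, mean_b, t, p, bh_p, significant).
#' @export
group_compare <- function(values_a, values_b, alpha = 0.05) {
  if (is.null(dim(values_a))) values_a <- matrix(values_a, ncol = 1,
                                                 dimnames = list(NULL, "feature"))
  if (is.null(dim(values_b))) values_b <- matrix(values_b, ncol = 1,
                                                 dimnames = list(NULL, "feature"))
  stopifnot(identical(colnames(values_a), colnames(values_b)),
            nrow(values_a) >= 2, nrow(values_b) >= 2)
  feats <- colnames(values_a)
  tstat <- pval <- numeric(length(feats))
  for (j in seq_along(feats)) {
    a <- values_a[, j]; b <- values_b[, j]
    if (var(a) == 0 && var(b) == 0) {
      same <- isTRUE(all.equal(mean(a), mean(b)))
      tstat[j] <- if (same) 0 else Inf * sign(mean(a) - mean(b))
      pval[j] <- if (same) 1 else 0
    } else {
      tt <- t.test(a, b)
      tstat[j] <- unname(tt$statistic)
      pval[j] <- tt$p.value
    }
  }
  bh <- p.adjust(pval, method = "BH")
  data.frame(feature = feats, mean_a = colMeans(values_a),
             mean_b = colMeans(values_b), t = tstat, p = pval, bh_p = bh,
             significant = bh <= alpha, row.names = NULL)
}
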