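#' Receptor-ligand interaction scoring within spot subsets
#'
#' CellPhoneDB-style statistic applied to spot subsets (e.g. the TLO cluster
#' of each patient group): for each receptor-ligand pair and subset, the
#' observed statistic is the mean of the two partners' average normalized
#' expression within the subset. The null distribution is built by permuting
#' subset labels across spots; the permutation p-value uses the add-one
#' convention `p = (1 + #(null >= obs)) / (n_perm + 1)` so p is never zero.
#' The effect size is the natural-log ratio of the subset statistic to the
#' same statistic over all spots; an interaction is reported significant at
#' `log_mean_ratio > 0.1` and `p < 0.01`.
#'
#' @param m normalized [spot_matrix].
#' @param subsets named per-spot labels (names = barcodes) or a vector in
#'   spot order; each scored subset needs >= 5 spots.
#' @param pairs data.frame with columns gene_a, gene_b and optionally name.
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @param ratio_threshold,p_threshold significance gate (defaults 0.1, 0.01).
#' @return data.frame per (pair, subset): mean_expr, global_mean_expr,
#'   log_mean_ratio, p_value, significant. Pairs with a missing partner gene
#'   are skipped with a warning.
#' @export
score_interactions <- function(m, subsets, pairs, n_perm = 1000, seed = 1,
                               ratio_threshold = 0.1, p_threshold = 0.01) {
  stopifnot(inherits(m, "spot_matrix"))
  v <- as.matrix(m$values)
  lab <- if (!is.null(names(subsets))) subsets[rownames(v)] else subsets
  stopifnot(length(lab) == nrow(v))
  if (!"name" %in% names(pairs))
    pairs$name <- paste(pairs$gene_a, pairs$gene_b, sep = "_")
  have <- pairs$gene_a %in% colnames(v) & pairs$gene_b %in% colnames(v)
  if (any(!have))
    warning("skipping pairs with missing partner genes: ",
            paste(pairs$name[!have], collapse = ", "))
  pairs <- pairs[have, , drop = FALSE]
  if (!nrow(pairs))
    stop_spatlo("no scoreable pairs", "spatlo_empty_result_error")
  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  expr <- v[, genes, drop = FALSE]
  glob <- colMeans(expr)
  tab <- table(lab)
  use_subsets <- names(tab)[tab >= 5]
  if (!length(use_subsets))
    stop_spatlo("no subset has >= 5 spots", "spatlo_validation_error")
  ia <- match(pairs$gene_a, genes); ib <- match(pairs$gene_b, genes)
  res <- list()
  with_sim_seed(seed, {
    for (s in use_subsets) {
      insub <- lab == s
      obs_means <- colMeans(expr[insub, , drop = FALSE])
      obs <- (obs_means[ia] + obs_means[ib]) / 2
      gstat <- (glob[ia] + glob[ib]) / 2
      exceed <- integer(nrow(pairs))
      ns <- sum(insub)
      for (p in seq_len(n_perm)) {
        pick <- sample.int(nrow(expr), ns)
        pm <- colMeans(expr[pick, , drop = FALSE])
        null <- (pm[ia] + pm[ib]) / 2
        exceed <- exceed + (null >= obs)
      }
      pval <- (1 + exceed) / (n_perm + 1)
      lmr <- ifelse(obs > 0 & gstat > 0, log(obs / gstat),
                    ifelse(obs == 0, -Inf, Inf))
      res[[s]] <- data.frame(
        name = pairs$name, gene_a = pairs$gene_a, gene_b = pairs$gene_b,
        subset = s, mean_expr = unname(obs),
        global_mean_expr = unname(gstat), log_mean_ratio = unname(lmr),
        p_value = pval,
        significant = lmr > ratio_threshold & pval < p_threshold,
        row.names = NULL)
    }
  })
  do.call(rbind, res)
}

#' Gene-set over-representation by the hypergeometric test
#'
#' One-sided hypergeometric upper-tail test of the overlap between a query
#' gene list and each gene set, against a stated gene universe, with
#' Benjamini-Hochberg adjustment across sets. Sets are reported at adjusted
#' p below `fdr`. The degenerate case where the query saturates a set
#' (overlap cannot be smaller than observed) yields p = 1 and is flagged.
#'
#' @param query character vector of genes (must be a subset of `universe`).
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe character vector of all considered genes.
#' @param fdr reporting threshold on adjusted p (default 0.05).
#' @return data.frame per set: set, overlap k, set_size K (within universe),
#'   query_size n, universe_size N, p, bh_p, reported, degenerate.
#' @export
enrich <- function(query, sets, universe, fdr = 0.05) {
  universe <- unique(universe)
  if (!length(universe))
    stop_spatlo("empty universe", "spatlo_validation_error")
  if (!all(query %in% universe))
    stop_spatlo("query genes missing from the universe", "spatlo_validation_error")
  query <- unique(query)
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(query, set))
    # P[X >= k] for X ~ Hypergeom(N, K, n)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    degenerate <- k > 0 && k == K + n - N  # overlap at a forced positive minimum
    data.frame(set = nm, overlap = k, set_size = K, query_size = n,
               universe_size = N, p = p, degenerate = degenerate,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out$bh_p <- p.adjust(out$p, method = "BH")
  out$reported <- out$bh_p < fdr
  out[, c("set", "overlap", "set_size", "query_size", "universe_size",
          "p", "bh_p", "reported", "degenerate")]
}
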