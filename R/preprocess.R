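#' Remove low-complexity spots
#'
#' Drops spots detecting fewer than `min_genes` genes (count > 0). The
#' default of 200 detected genes is the study's spot-quality gate; a spot
#' with exactly `min_genes` detected genes is kept (inclusive lower bound).
#'
#' @param m raw-layer [spot_matrix].
#' @param min_genes minimum number of detected genes per spot.
#' @return filtered [spot_matrix], gene set unchanged.
#' @export
filter_spots <- function(m, min_genes = 200) {
  stopifnot(inherits(m, "spot_matrix"))
  if (m$layer != "raw")
    stop_spatlo("filter_spots requires the raw layer", "spatlo_validation_error")
  detected <- if (inherits(m$values, "Matrix"))
    Matrix::rowSums(m$values > 0) else rowSums(m$values > 0)
  keep <- detected >= min_genes
  if (!any(keep))
    stop_spatlo("all spots removed by the detected-gene filter",
                "spatlo_empty_result_error")
  spot_matrix(m$values[keep, , drop = FALSE], m$layer)
}

#' Normalize spot expression for sequencing depth
#'
#' Two modes:
#' \describe{
#'   \item{size_factor_log}{`log1p(count / sf)` with size factor
#'     `sf = spot_total / median(spot_totals)`.}
#'   \item{regression_residual}{per-gene Pearson residuals of a Poisson
#'     mean-depth regression with `log(spot_total)` as the single covariate,
#'     clipped at plus/minus `sqrt(n_spots)` (the default; removes depth as a
#'     nuisance covariate rather than assuming strict proportionality).}
#' }
#'
#' @param m raw-layer [spot_matrix], already spot-filtered.
#' @param mode `"regression_residual"` or `"size_factor_log"`.
#' @return [spot_matrix] with the corresponding layer tag.
#' @export
normalize_spots <- function(m, mode = c("regression_residual",
                                        "size_factor_log")) {
  stopifnot(inherits(m, "spot_matrix"))
  mode <- match.arg(mode)
  if (m$layer != "raw")
    stop_spatlo("normalize_spots requires the raw layer", "spatlo_validation_error")
  v <- as.matrix(m$values)
  totals <- rowSums(v)
  if (any(totals == 0))
    stop_spatlo("zero-total spot reached normalization (filter first)",
                "spatlo_internal_error")
  if (mode == "size_factor_log") {
    sf <- totals / median(totals)
    out <- log1p(v / sf)
    return(spot_matrix(out, "sizefactor"))
  }
  # Poisson GLM per gene: log mu = b0 + b1 * log(total); Pearson residuals
  lt <- log(totals)
  X <- cbind(1, lt)
  n <- nrow(v)
  clip <- sqrt(n)
  res <- matrix(0, nrow = n, ncol = ncol(v), dimnames = dimnames(v))
  for (j in seq_len(ncol(v))) {
    y <- v[, j]
    if (all(y == 0)) next
    fit <- suppressWarnings(
      glm.fit(X, y, family = stats::poisson(), control = list(maxit = 50)))
    mu <- fit$fitted.values
    r <- (y - mu) / sqrt(pmax(mu, 1e-12))
    res[, j] <- pmin(pmax(r, -clip), clip)
  }
  spot_matrix(res, "residual")
}

#' Rank genes by the squared coefficient of variation
#'
#' Counts are first divided by the per-spot size factor (the spot's total
#' count); for each gene the mean and squared coefficient of variation
#' (CV2 = variance / mean^2) across spots are computed, and genes are ranked
#' by `CV2 - median(CV2)`. Genes with zero mean are excluded. Ties are
#' broken by higher mean, then gene symbol, for determinism.
#'
#' @param m raw-layer [spot_matrix].
#' @param n_top number of top-ranked genes to flag as selected.
#' @return data.frame (gene, mean, cv2, statistic, rank, selected), ordered
#'   by rank.
#' @export
select_variable_genes <- function(m, n_top) {
  stopifnot(inherits(m, "spot_matrix"))
  if (m$layer != "raw")
    stop_spatlo("select_variable_genes works on the raw layer",
                "spatlo_validation_error")
  v <- as.matrix(m$values)
  totals <- rowSums(v)
  if (any(totals == 0))
    stop_spatlo("zero-total spot present; run filter_spots first",
                "spatlo_internal_error")
  y <- v / totals
  mu <- colMeans(y)
  keep <- mu > 0
  y <- y[, keep, drop = FALSE]
  mu <- mu[keep]
  cv2 <- apply(y, 2, var) / mu^2
  statistic <- cv2 - median(cv2)
  ord <- order(-statistic, -mu, colnames(y))
  if (n_top > length(ord)) {
    warning("n_top exceeds number of eligible genes; returning all")
    n_top <- length(ord)
  }
  out <- data.frame(gene = colnames(y)[ord], mean = mu[ord], cv2 = cv2[ord],
                    statistic = statistic[ord], rank = seq_along(ord),
                    selected = seq_along(ord) <= n_top,
                    row.names = NULL)
  out
}

#' Restrict a matrix to a gene subset
#'
#' @param m a [spot_matrix].
#' @param genes character vector of gene symbols (order preserved).
#' @return [spot_matrix] restricted to the genes present.
#' @export
subset_genes <- function(m, genes) {
  stopifnot(inherits(m, "spot_matrix"))
  genes <- intersect(genes, colnames(m$values))
  spot_matrix(m$values[, genes, drop = FALSE], m$layer)
}
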