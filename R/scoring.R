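#' Co-expression validity filter for a marker set
#'
#' Given the normalized expression of a cell type's marker genes across
#' spots, computes all pairwise Pearson correlations and retains the genes
#' whose co-expression with the rest of the marker set is positive. Two
#' rules are available: `"mean"` (default) keeps gene j when its mean
#' correlation with the other present markers exceeds zero, which reduces to
#' the plain pairwise rule for two markers; `"all_pairs"` keeps gene j only
#' when every pairwise correlation involving it is positive.
#'
#' @param m normalized [spot_matrix].
#' @param markers character vector of marker gene symbols.
#' @param min_markers minimum number of markers that must be present in the
#'   matrix for the type to be scoreable (default 4, i.e. more than 3).
#' @param rule `"mean"` or `"all_pairs"`.
#' @return character vector of retained genes M; `character(0)` when fewer
#'   than `min_markers` markers are present. Zero-variance markers are
#'   dropped with a warning (their correlation is undefined).
#' @export
valid_coexpressed_genes <- function(m, markers, min_markers = 4,
                                    rule = c("mean", "all_pairs")) {
  stopifnot(inherits(m, "spot_matrix"))
  rule <- match.arg(rule)
  present <- intersect(markers, colnames(m$values))
  if (length(present) < min_markers) return(character(0))
  v <- as.matrix(m$values[, present, drop = FALSE])
  sds <- apply(v, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance markers: ",
            paste(present[sds == 0], collapse = ", "))
    v <- v[, sds > 0, drop = FALSE]
    present <- colnames(v)
    if (length(present) < 2) return(present)
  }
  if (length(present) == 1) return(present)
  cc <- cor(v)
  keep <- if (rule == "mean") {
    vapply(seq_along(present), function(j)
      mean(cc[j, -j]) > 0, logical(1))
  } else {
    vapply(seq_along(present), function(j)
      all(cc[j, -j] > 0), logical(1))
  }
  present[keep]
}

#' Score cell types per spot from marker signatures
#'
#' Implements the signature-sum scoring scheme. For each cell type, the
#' normalized matrix is subset to the type's markers, the co-expression
#' validity filter applied ([valid_coexpressed_genes()]), and the raw score
#' of a spot is the sum of the retained genes' normalized expression. Raw
#' scores are max-scaled per type across spots (so each type's best spot
#' scores 1), and finally renormalized within each spot across cell types so
#' that the per-spot values represent approximate cell-type proportions
#' summing to one. Cell types with fewer than `min_markers` markers present
#' are reported as not scoreable and excluded from the proportion
#' denominator rather than distorting it.
#'
#' @param m normalized [spot_matrix] (non-negative layer, e.g. size-factor
#'   log, so scores are non-negative sums).
#' @param signatures a [signature_set].
#' @param min_markers markers required for a type to be scoreable.
#' @param rule co-expression rule passed to [valid_coexpressed_genes()].
#' @param proportion_mode `"per_spot"` normalizes max-scaled scores across
#'   cell types within each spot (the scheme's stated intent);
#'   `"per_type"` divides by each type's sum over spots instead, provided
#'   for comparison only.
#' @return list of class `cell_type_scores`: matrices `raw`, `max_scaled`,
#'   `proportions` (spots x types; not-scoreable types are all-NA columns),
#'   list `valid_genes`, integer `n_markers_present`, logical `scoreable`.
#' @export
score_cell_types <- function(m, signatures, min_markers = 4,
                             rule = c("mean", "all_pairs"),
                             proportion_mode = c("per_spot", "per_type")) {
  stopifnot(inherits(m, "spot_matrix"), inherits(signatures, "signature_set"))
  rule <- match.arg(rule)
  proportion_mode <- match.arg(proportion_mode)
  v <- as.matrix(m$values)
  types <- names(signatures)
  n <- nrow(v)
  raw <- matrix(NA_real_, n, length(types),
                dimnames = list(rownames(v), types))
  valid <- setNames(vector("list", length(types)), types)
  npresent <- setNames(integer(length(types)), types)
  for (l in types) {
    markers <- signatures[[l]]$gene
    npresent[l] <- length(intersect(markers, colnames(v)))
    M <- valid_coexpressed_genes(m, markers, min_markers = min_markers,
                                 rule = rule)
    valid[[l]] <- M
    if (length(M) >= 1)
      raw[, l] <- rowSums(v[, M, drop = FALSE])
  }
  scoreable <- !is.na(raw[1, ])
  if (!any(scoreable))
    stop_spatlo("no scoreable cell types", "spatlo_empty_result_error")
  max_scaled <- raw
  for (l in types[scoreable]) {
    mx <- max(raw[, l])
    max_scaled[, l] <- if (mx > 0) raw[, l] / mx else 0
  }
  proportions <- max_scaled
  if (proportion_mode == "per_spot") {
    denom <- rowSums(max_scaled[, scoreable, drop = FALSE])
    proportions[, scoreable] <- max_scaled[, scoreable, drop = FALSE] /
      ifelse(denom > 0, denom, NA_real_)
  } else {
    for (l in types[scoreable]) {
      s <- sum(max_scaled[, l])
      proportions[, l] <- if (s > 0) max_scaled[, l] / s else 0
    }
  }
  structure(list(raw = raw, max_scaled = max_scaled,
                 proportions = proportions, valid_genes = valid,
                 n_markers_present = npresent, scoreable = scoreable),
            class = "cell_type_scores")
}

#' @export
as.data.frame.cell_type_scores <- function(x, ...) {
  types <- colnames(x$raw)
  bc <- rownames(x$raw)
  do.call(rbind, lapply(types, function(l)
    data.frame(barcode = bc, cell_type = l, raw_score = x$raw[, l],
               max_scaled = x$max_scaled[, l],
               proportion = x$proportions[, l], row.names = NULL)))
}

#' @export
print.cell_type_scores <- function(x, ...) {
  cat(sprintf("<cell_type_scores> %d spots x %d cell types (%d scoreable)\n",
              nrow(x$raw), ncol(x$raw), sum(x$scoreable)))
  invisible(x)
}

#' Co-localization of two per-spot score maps
#'
#' Pearson correlation across spots between two score (or expression) maps,
#' with a two-sided p-value.
#'
#' @param scores_a,scores_b numeric vectors over the same spots.
#' @return list `(pearson_r, p_value, n)`; `pearson_r` is NaN with a warning
#'   when either map has zero variance.
#' @export
colocalize <- function(scores_a, scores_b) {
  ok <- is.finite(scores_a) & is.finite(scores_b)
  a <- scores_a[ok]; b <- scores_b[ok]
  if (length(a) < 3)
    stop_spatlo("colocalize needs at least 3 paired finite values",
                "spatlo_validation_error")
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance in a score map; correlation undefined")
    return(list(pearson_r = NaN, p_value = NaN, n = length(a)))
  }
  ct <- cor.test(a, b, method = "pearson")
  list(pearson_r = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}
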