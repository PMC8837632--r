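#' Construct a spot-by-gene expression matrix
#'
#' Light container for ST expression data: a spots x genes matrix (dense or
#' `Matrix` sparse) with barcodes as row names, gene symbols as column names,
#' and a layer tag recording what the values are.
#'
#' @param values numeric matrix or `Matrix::Matrix`, spots in rows, genes in
#'   columns; row and column names required.
#' @param layer one of `"raw"` (integer counts), `"sizefactor"`
#'   (log1p size-factor-normalized), `"residual"` (regression Pearson
#'   residuals).
#' @return An object of class `spot_matrix`: a list with elements `values`
#'   and `layer`.
#' @export
spot_matrix <- function(values, layer = c("raw", "sizefactor", "residual")) {
  layer <- match.arg(layer)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_spatlo("spot_matrix requires barcode rownames and gene colnames",
                "spatlo_validation_error")
  if (anyDuplicated(rownames(values))) {
    dups <- unique(rownames(values)[duplicated(rownames(values))])
    stop_spatlo(paste0("duplicate barcodes: ", paste(head(dups, 5), collapse = ", ")),
                "spatlo_validation_error")
  }
  v <- if (inherits(values, "Matrix")) values@x else values
  if (any(!is.finite(v)))
    stop_spatlo("non-finite values in expression matrix", "spatlo_validation_error")
  if (layer == "raw") {
    if (any(v < 0))
      stop_spatlo("negative counts in raw layer", "spatlo_validation_error")
    if (any(v != floor(v)))
      stop_spatlo("non-integer counts in raw layer", "spatlo_validation_error")
  }
  structure(list(values = values, layer = layer), class = "spot_matrix")
}

#' @export
dim.spot_matrix <- function(x) dim(x$values)

#' @export
print.spot_matrix <- function(x, ...) {
  cat(sprintf("<spot_matrix> %d spots x %d genes, layer = %s\n",
              nrow(x$values), ncol(x$values), x$layer))
  invisible(x)
}

#' Read a spot-by-gene count matrix
#'
#' Reads either a tab-delimited table (spots in rows, genes in columns,
#' header row of gene symbols, first column of barcodes) or a MatrixMarket
#' coordinate file with sibling plain-text barcode and gene name files
#' (one name per line; rows of the MTX are spots).
#'
#' @param path path to the `.tsv` or `.mtx` file.
#' @param format `"tsv"` or `"mtx"`.
#' @param barcodes_file,genes_file for MTX input, the row/column name files;
#'   default to `barcodes.tsv` / `genes.tsv` next to `path`.
#' @return A [spot_matrix] with layer `"raw"`.
#' @export
read_counts <- function(path, format = c("tsv", "mtx"),
                        barcodes_file = file.path(dirname(path), "barcodes.tsv"),
                        genes_file = file.path(dirname(path), "genes.tsv")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_spatlo(paste0("file not found: ", path), "spatlo_io_error")
  if (format == "tsv") {
    df <- tryCatch(read.delim(path, check.names = FALSE, row.names = 1),
                   error = function(e) stop_spatlo(
                     paste0("malformed TSV: ", conditionMessage(e)),
                     "spatlo_format_error"))
    m <- as.matrix(df)
    storage.mode(m) <- "double"
  } else {
    m <- tryCatch(as(Matrix::readMM(path), "CsparseMatrix"),
                  error = function(e) stop_spatlo(
                    paste0("malformed MTX: ", conditionMessage(e)),
                    "spatlo_format_error"))
    for (f in c(barcodes_file, genes_file))
      if (!file.exists(f))
        stop_spatlo(paste0("missing MTX name file: ", f), "spatlo_io_error")
    bc <- readLines(barcodes_file)
    gn <- readLines(genes_file)
    if (length(bc) != nrow(m) || length(gn) != ncol(m))
      stop_spatlo("barcode/gene name files do not match MTX dimensions",
                  "spatlo_format_error")
    dimnames(m) <- list(bc, gn)
  }
  spot_matrix(m, layer = "raw")
}

#' Read a spot coordinate table and assign section depth
#'
#' Expects a tab-delimited table with columns `barcode`, `x`, `y`,
#' `section_id` and optionally `section_order` and `annotation`. The z
#' coordinate (micrometres) is assigned as `section_index *
#' section_spacing_um`, with section order taken from `section_order` when
#' present and otherwise from the sorted unique `section_id` values.
#'
#' @param path TSV file path.
#' @param section_spacing_um distance between consecutive sections in
#'   micrometres (7 for consecutive 7-um cryosections; 21 when every third
#'   section is profiled).
#' @return data.frame with columns barcode, x, y, section_id, z and, when
#'   present in the input, annotation.
#' @export
read_spot_table <- function(path, section_spacing_um = 7) {
  if (!file.exists(path))
    stop_spatlo(paste0("file not found: ", path), "spatlo_io_error")
  df <- read.delim(path, check.names = FALSE)
  need <- c("barcode", "x", "y", "section_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_spatlo(paste0("spot table missing columns: ", paste(miss, collapse = ", ")),
                "spatlo_schema_error")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop_spatlo("non-finite spot coordinates", "spatlo_validation_error")
  key <- paste(df$barcode, df$section_id)
  if (anyDuplicated(key))
    stop_spatlo("duplicate (barcode, section_id) pairs", "spatlo_validation_error")
  df$section_id <- as.character(df$section_id)
  if ("section_order" %in% names(df)) {
    ord <- unique(df[, c("section_id", "section_order")])
    idx <- setNames(rank(ord$section_order) - 1, ord$section_id)
  } else {
    ids <- sort(unique(df$section_id))
    idx <- setNames(seq_along(ids) - 1, ids)
  }
  df$z <- idx[df$section_id] * section_spacing_um
  rownames(df) <- NULL
  df
}

#' Construct a marker signature set
#'
#' @param markers data.frame with columns `cell_type`, `gene`, `avg_logfc`,
#'   `fdr`; assumed already filtered.
#' @return Object of class `signature_set`: a named list of per-type marker
#'   data.frames.
#' @export
signature_set <- function(markers) {
  sets <- split(markers[, c("gene", "avg_logfc", "fdr")], markers$cell_type)
  structure(lapply(sets, function(d) d[order(-d$avg_logfc, d$gene), , drop = FALSE]),
            class = "signature_set")
}

#' @export
`[.signature_set` <- function(x, i) {
  structure(unclass(x)[i], class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("<signature_set> %d cell types; markers per type: %s\n",
              length(x), paste(vapply(x, nrow, 1L), collapse = ", ")))
  invisible(x)
}

#' Read single-cell marker signatures
#'
#' Reads a marker reference table (columns `cell_type`, `gene`, `avg_logfc`,
#' `fdr`, as exported from scRNA-seq differential expression) and applies
#' the study's marker filter: average log fold-change strictly greater than 1,
#' FDR below 5%, then the 200 largest-fold-change markers per cell type.
#'
#' @param path TSV file path.
#' @param max_markers markers retained per type after filtering (default 200).
#' @return A [signature_set]. Cell types whose markers all fail the filter
#'   are retained with an empty marker list, with a warning.
#' @export
read_signatures <- function(path, max_markers = 200) {
  if (!file.exists(path))
    stop_spatlo(paste0("file not found: ", path), "spatlo_io_error")
  df <- read.delim(path, check.names = FALSE)
  need <- c("cell_type", "gene", "avg_logfc", "fdr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_spatlo(paste0("signature table missing columns: ", paste(miss, collapse = ", ")),
                "spatlo_schema_error")
  types <- unique(df$cell_type)
  keep <- df$avg_logfc > 1 & df$fdr < 0.05
  filt <- df[keep, , drop = FALSE]
  out <- lapply(types, function(ct) {
    d <- filt[filt$cell_type == ct, c("gene", "avg_logfc", "fdr"), drop = FALSE]
    d <- d[order(-d$avg_logfc, d$gene), , drop = FALSE]
    head(d, max_markers)
  })
  names(out) <- types
  empty <- types[vapply(out, nrow, 1L) == 0]
  if (length(empty))
    warning("cell types with no markers surviving the filter: ",
            paste(empty, collapse = ", "))
  structure(lapply(out, function(d) { rownames(d) <- NULL; d }),
            class = "signature_set")
}

#' Read a receptor-ligand pair list
#'
#' @param path TSV with columns `gene_a`, `gene_b` and optionally `name`.
#' @return data.frame of pairs.
#' @export
read_pairs <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  miss <- setdiff(c("gene_a", "gene_b"), names(df))
  if (length(miss))
    stop_spatlo(paste0("pair list missing columns: ", paste(miss, collapse = ", ")),
                "spatlo_schema_error")
  if (!"name" %in% names(df)) df$name <- paste(df$gene_a, df$gene_b, sep = "_")
  df
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated: name, description, genes.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3
  if (any(bad))
    stop_spatlo("GMT lines must have at least name, description and one gene",
                "spatlo_format_error")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  sets
}

#' Pipeline run configuration
#'
#' Bundles the tunable analysis settings with validation. The defaults
#' reproduce the settings used for the densest biopsy volume: 2000 variable
#' genes, 4 spatial clusters, 2 infiltrate sub-clusters, DE thresholds
#' p < 0.001 and log-ratio > 0.5, and the 70% density percentile for TLO
#' calling.
#'
#' @param n_variable_genes,n_clusters,n_infiltrate_clusters positive integers.
#' @param de_p_threshold,de_logratio_threshold DE gate.
#' @param density_percentile TLO percentile threshold in (0,100).
#' @param rng_seed integer seed funnelled to every stochastic step.
#' @param normalization_mode `"regression_residual"` or `"size_factor_log"`.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_variable_genes = 2000, n_clusters = 4,
                       n_infiltrate_clusters = 2,
                       de_p_threshold = 0.001, de_logratio_threshold = 0.5,
                       density_percentile = 70, rng_seed = 1,
                       normalization_mode = c("regression_residual",
                                              "size_factor_log")) {
  normalization_mode <- match.arg(normalization_mode)
  stopifnot(n_variable_genes >= 1, n_clusters >= 1, n_infiltrate_clusters >= 1,
            de_p_threshold > 0, de_p_threshold < 1,
            density_percentile > 0, density_percentile < 100)
  structure(list(n_variable_genes = as.integer(n_variable_genes),
                 n_clusters = as.integer(n_clusters),
                 n_infiltrate_clusters = as.integer(n_infiltrate_clusters),
                 de_p_threshold = de_p_threshold,
                 de_logratio_threshold = de_logratio_threshold,
                 density_percentile = density_percentile,
                 rng_seed = as.integer(rng_seed),
                 normalization_mode = normalization_mode),
            class = "run_config")
}

#' Write a pipeline result to disk
#'
#' TSV for tabular results (cluster assignments, cell-type scores, spot
#' tables); interpolated volumes are written as one TSV grid per section plus
#' a JSON metadata file. All writers round-trip losslessly through the
#' corresponding readers.
#'
#' @param x result object.
#' @param path output file (or, for volumes, a directory).
#' @export
write_results <- function(x, path) UseMethod("write_results")

#' @export
write_results.data.frame <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.cluster_assignment <- function(x, path) {
  df <- as.data.frame(x)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.cell_type_scores <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.spot_matrix <- function(x, path) {
  m <- as.matrix(x$values)
  df <- data.frame(barcode = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
write_results.spatlo_volume <- function(x, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(reference = x$reference, mode = x$mode, z = x$z,
               sections = names(x$transforms),
               transforms = x$transforms)
  jsonlite::write_json(meta, file.path(path, "volume.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(x$spots, file.path(path, "registered_spots.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$grids)) {
    for (s in names(x$grids)) {
      g <- x$grids[[s]]
      write.table(g$z, file.path(path, paste0("grid_", s, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read back a cluster assignment written by [write_results()]
#' @param path TSV path.
#' @return `cluster_assignment` object.
#' @export
read_cluster_assignment <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  new_cluster_assignment(setNames(df$cluster, df$barcode),
                         section_id = df$section_id,
                         k = max(df$cluster), scope = attr(df, "scope") %||% "whole_volume")
}
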