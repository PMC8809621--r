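# Lightweight S3 containers, in the list-of-components style of edgeR's
# DGEList: a matrix slot plus aligned metadata data.frames.

#' Construct a cell-level expression set
#'
#' Bundles a cell x gene UMI count matrix with per-cell metadata. The
#' derived QC fields `n_umi` (row sums) and `n_genes_detected` (number of
#' nonzero genes per cell) are recomputed if absent, and validated if present.
#'
#' @param counts cell x gene matrix of non-negative integer counts; rownames
#'   are cell barcodes, colnames are gene ids.
#' @param cell_meta data.frame with one row per cell, aligned to
#'   `rownames(counts)`. Expected fields (by the downstream steps that need
#'   them): `line`, `day`, `pseudotime`, `cell_type`, `doublet_prob`,
#'   `assignment`, `mito_fraction`.
#' @return An object of class `cell_expression_set` with elements `counts`
#'   and `cell_meta`.
#' @export
cell_expression_set <- function(counts, cell_meta) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("gene", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("duplicate cell barcodes: ",
         paste(head(rownames(counts)[duplicated(rownames(counts))], 3),
               collapse = ", "))
  if (nrow(cell_meta) != nrow(counts))
    stop("cell_meta rows (", nrow(cell_meta), ") do not match cells (",
         nrow(counts), ")")
  cell_meta <- as.data.frame(cell_meta)
  rownames(cell_meta) <- rownames(counts)
  cell_meta$n_umi <- as.numeric(rowSums(counts))
  cell_meta$n_genes_detected <- as.integer(rowSums(counts > 0))
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "cell_expression_set")
}

#' @export
print.cell_expression_set <- function(x, ...) {
  cat("cell_expression_set:", nrow(x$counts), "cells x",
      ncol(x$counts), "genes\n")
  if (!is.null(x$cell_meta$line))
    cat("  lines:", length(unique(x$cell_meta$line)), "\n")
  invisible(x)
}

#' @export
dim.cell_expression_set <- function(x) dim(x$counts)

#' Subset a cell expression set by cells and/or genes
#'
#' @param x a `cell_expression_set`.
#' @param cells,genes logical, integer or character index into cells (rows)
#'   and genes (columns); `NULL` keeps all.
#' @return a `cell_expression_set`.
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(is(x, "cell_expression_set"))
  if (is.null(cells)) cells <- seq_len(nrow(x$counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$counts))
  cell_expression_set(x$counts[cells, genes, drop = FALSE],
                      x$cell_meta[cells, , drop = FALSE])
}

#' Construct a genotype panel
#'
#' Variant x line dosage matrix with per-variant metadata. The minor allele
#' frequency is recomputed from the dosages (`mean(dosage)/2`, folded to the
#' minor allele) and stored as `variant_meta$maf_sample`; a generator-supplied
#' population MAF, when given, is kept as `variant_meta$maf`.
#'
#' @param dosages variant x line numeric matrix with values in \[0, 2\].
#' @param variant_meta data.frame with columns `chrom` and `pos` (1-based),
#'   one row per variant; a `maf` column is preserved if present.
#' @param line_ids character vector of cell-line identifiers (columns).
#' @return object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, variant_meta, line_ids = colnames(dosages)) {
  dosages <- as.matrix(dosages)
  if (anyNA(dosages)) stop("dosages must have no missing values")
  if (any(dosages < 0 | dosages > 2)) stop("dosages must lie in [0, 2]")
  if (is.null(line_ids)) line_ids <- paste0("line", seq_len(ncol(dosages)))
  colnames(dosages) <- line_ids
  if (is.null(rownames(dosages)))
    rownames(dosages) <- paste0("var", seq_len(nrow(dosages)))
  variant_meta <- as.data.frame(variant_meta)
  if (nrow(variant_meta) != nrow(dosages))
    stop("variant_meta rows do not match variants")
  rownames(variant_meta) <- rownames(dosages)
  af <- rowMeans(dosages) / 2
  variant_meta$maf_sample <- pmin(af, 1 - af)
  structure(list(dosages = dosages, variant_meta = variant_meta,
                 line_ids = line_ids),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", nrow(x$dosages), "variants x",
      length(x$line_ids), "lines\n")
  invisible(x)
}

#' Construct a pseudobulk set
#'
#' @param counts sample x gene matrix of (possibly fractional) aggregated
#'   counts.
#' @param sample_meta data.frame with per-sample `line`, `lineage`, `unit`
#'   (day value or bin index), `t` (time covariate) and `n_cells`.
#'   `lib_size` is recomputed as the row sum of `counts`.
#' @param expr optional sample x gene normalized expression (logCPM/logTPM).
#' @param tmm_factor optional per-sample normalization factors.
#' @return object of class `pseudobulk_set`.
#' @export
pseudobulk_set <- function(counts, sample_meta, expr = NULL, tmm_factor = NULL) {
  counts <- as.matrix(counts)
  sample_meta <- as.data.frame(sample_meta)
  if (nrow(sample_meta) != nrow(counts))
    stop("sample_meta rows do not match samples")
  sample_meta$lib_size <- as.numeric(rowSums(counts))
  if (!is.null(tmm_factor)) sample_meta$tmm_factor <- tmm_factor
  rownames(sample_meta) <- rownames(counts)
  structure(list(counts = counts, expr = expr, sample_meta = sample_meta),
            class = "pseudobulk_set")
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat("pseudobulk_set:", nrow(x$counts), "samples x", ncol(x$counts),
      "genes\n")
  if (!is.null(x$sample_meta$lineage))
    cat("  lineages:", paste(unique(x$sample_meta$lineage), collapse = ", "),
        "\n")
  cat("  expr:", if (is.null(x$expr)) "not computed" else "computed", "\n")
  invisible(x)
}

# canonical cell-type labels used throughout; UNK cells are excluded from
# lineage-based analyses
.cell_types <- c("IPSC", "MES", "CMES", "PROG", "CM", "CF", "UNK")
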