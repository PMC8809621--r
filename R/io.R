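# Readers and writers for the standard exchange formats: MatrixMarket MTX
# with barcodes/features TSVs for counts, VCF (DS/GT) or TSV dosages for
# genotypes, and plain TSV tables elsewhere. All genomic positions are
# 1-based throughout.

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
}

.read_tsv <- function(path) {
  read.delim(path, sep = "\t", na.strings = ".", check.names = FALSE)
}

#' Write a cell expression set as MTX + barcodes + features + metadata
#'
#' @param cells a [cell_expression_set()].
#' @param dir output directory (created if needed). Files written:
#'   `matrix.mtx`, `barcodes.tsv`, `features.tsv`, `cell_metadata.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(cells, dir) {
  stopifnot(is(cells, "cell_expression_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # MTX convention: genes (features) as rows, cells as columns
  Matrix::writeMM(Matrix::Matrix(t(cells$counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(cells$counts), file.path(dir, "barcodes.tsv"))
  writeLines(colnames(cells$counts), file.path(dir, "features.tsv"))
  meta <- cbind(barcode = rownames(cells$counts), cells$cell_meta)
  .write_tsv(meta, file.path(dir, "cell_metadata.tsv"))
  invisible(dir)
}

#' Read a cell expression set from MTX + barcodes + features + metadata
#'
#' Counts and metadata are aligned by barcode; `n_umi` and
#' `n_genes_detected` are recomputed. Gzip-compressed inputs are accepted
#' (R's readers decompress transparently).
#'
#' @param mtx,barcodes,features,metadata file paths. `metadata` may be
#'   `NULL`.
#' @return a [cell_expression_set()].
#' @export
read_counts <- function(mtx, barcodes, features, metadata = NULL) {
  m <- as.matrix(Matrix::readMM(mtx))
  bc <- readLines(barcodes)
  ft <- readLines(features)
  if (nrow(m) != length(ft) || ncol(m) != length(bc))
    stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
         " but features = ", length(ft), ", barcodes = ", length(bc))
  if (anyDuplicated(bc))
    stop("duplicate barcodes: ", paste(head(bc[duplicated(bc)], 3),
                                       collapse = ", "))
  counts <- t(m)
  dimnames(counts) <- list(bc, ft)
  if (is.null(metadata)) {
    meta <- data.frame(row.names = bc)
  } else {
    meta <- .read_tsv(metadata)
    if (!"barcode" %in% names(meta)) stop("metadata must have a barcode column")
    extra <- setdiff(meta$barcode, bc)
    if (length(extra) > 0)
      stop("metadata barcodes absent from matrix: ",
           paste(head(extra, 3), collapse = ", "))
    meta <- meta[match(bc, meta$barcode), , drop = FALSE]
    if (anyNA(meta$barcode)) stop("matrix barcodes missing from metadata")
    meta$barcode <- NULL
  }
  cell_expression_set(counts, meta)
}

#' Write a genotype panel as VCF v4.2 (DS field) or TSV
#'
#' @param panel a [genotype_panel()].
#' @param path output file.
#' @param format `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(panel, path, format = c("vcf", "tsv")) {
  format <- match.arg(format)
  stopifnot(is(panel, "genotype_panel"))
  if (format == "tsv") {
    df <- data.frame(variant = rownames(panel$dosages),
                     chrom = panel$variant_meta$chrom,
                     pos = panel$variant_meta$pos,
                     panel$dosages, check.names = FALSE)
    .write_tsv(df, path)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("##FORMAT=<ID=DS,Number=1,Type=Float,",
                      "Description=\"Dosage\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", panel$line_ids), collapse = "\t")),
             con)
  gt_of <- function(d) c("0/0", "0/1", "1/1")[round(d) + 1]
  for (i in seq_len(nrow(panel$dosages))) {
    d <- panel$dosages[i, ]
    fields <- paste(gt_of(d), format(d, trim = TRUE), sep = ":")
    writeLines(paste(c(panel$variant_meta$chrom[i],
                       panel$variant_meta$pos[i],
                       rownames(panel$dosages)[i], "A", "G", ".", "PASS",
                       ".", "GT:DS", fields), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a genotype panel from VCF or dosage TSV
#'
#' VCF dosages come from the DS FORMAT field when present, otherwise from
#' the GT allele count. Variants with any missing genotype are dropped when
#' `drop_missing = TRUE` (the default, matching a no-missingness filter).
#'
#' @param path input file.
#' @param format `"vcf"` or `"tsv"`.
#' @param line_map optional named character vector mapping file sample ids
#'   to cell-line ids; unmappable sample ids are an error.
#' @param drop_missing drop variants with missing genotypes.
#' @return a [genotype_panel()].
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv"), line_map = NULL,
                           drop_missing = TRUE) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- .read_tsv(path)
    meta_cols <- c("variant", "chrom", "pos")
    dos <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
    rownames(dos) <- df$variant
    meta <- df[, c("chrom", "pos")]
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                   error = function(e) NULL)
    if (is.null(ds) || all(is.na(ds))) {
      gt <- vcfR::extract.gt(v, element = "GT")
      count_alt <- function(g) {
        ifelse(is.na(g), NA_real_,
               vapply(strsplit(g, "[/|]"),
                      function(a) sum(a == "1"), numeric(1)))
      }
      ds <- apply(gt, 2, count_alt)
      rownames(ds) <- rownames(gt)
    }
    dos <- ds
    ids <- vcfR::getID(v)
    if (anyNA(ids)) ids <- paste0("var", seq_len(nrow(dos)))
    rownames(dos) <- ids
    meta <- data.frame(chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v))
  }
  if (!is.null(line_map)) {
    unk <- setdiff(colnames(dos), names(line_map))
    if (length(unk) > 0)
      stop("sample ids not mappable to cell lines: ",
           paste(unk, collapse = ", "))
    colnames(dos) <- unname(line_map[colnames(dos)])
  }
  if (drop_missing) {
    keep <- rowSums(is.na(dos)) == 0
    dos <- dos[keep, , drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
  } else if (anyNA(dos)) {
    stop("missing dosages present; use drop_missing = TRUE")
  }
  genotype_panel(dos, meta)
}

#' Write gene annotation as TSV
#'
#' @param annotation data.frame with `gene_id`, `chrom`, `tss`, `strand`,
#'   `length_kb`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  .write_tsv(annotation, path)
  invisible(path)
}

#' Read gene annotation from TSV
#'
#' @param path input file.
#' @return annotation data.frame.
#' @export
read_annotation <- function(path) {
  ann <- .read_tsv(path)
  need <- c("gene_id", "chrom", "tss", "length_kb")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0)
    stop("annotation missing column(s): ", paste(miss, collapse = ", "))
  if (any(ann$length_kb <= 0)) stop("length_kb must be positive")
  if (anyDuplicated(ann$gene_id)) stop("duplicate gene_id values")
  ann
}

#' Write a pseudobulk set as TSV tables
#'
#' @param pb a [pseudobulk_set()].
#' @param dir output directory; writes `pseudobulk_counts.tsv`,
#'   `pseudobulk_expr.tsv` (if computed) and `pseudobulk_samples.tsv`.
#' @return `dir`, invisibly.
#' @export
write_pseudobulk <- function(pb, dir) {
  stopifnot(is(pb, "pseudobulk_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv(data.frame(sample = rownames(pb$counts), pb$counts,
                        check.names = FALSE),
             file.path(dir, "pseudobulk_counts.tsv"))
  if (!is.null(pb$expr))
    .write_tsv(data.frame(sample = rownames(pb$counts), pb$expr,
                          check.names = FALSE),
               file.path(dir, "pseudobulk_expr.tsv"))
  .write_tsv(data.frame(sample = rownames(pb$counts), pb$sample_meta,
                        check.names = FALSE),
             file.path(dir, "pseudobulk_samples.tsv"))
  invisible(dir)
}
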