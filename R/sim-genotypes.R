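# Genotype and annotation simulators.

#' Simulate a genotype panel
#'
#' Draws per-variant minor allele frequencies from Uniform(maf_low, maf_high)
#' and dosages independently per line as Binomial(2, MAF).
#'
#' @param n_lines number of cell lines (>= 2).
#' @param n_variants number of variants.
#' @param maf_low,maf_high MAF range, 0 <= maf_low <= maf_high <= 0.5.
#' @param seed integer seed.
#' @return a [genotype_panel()]; `variant_meta$maf` holds the drawn
#'   (population) MAF, `variant_meta$maf_sample` the realized sample MAF.
#' @export
simulate_genotypes <- function(n_lines, n_variants, maf_low = 0.1,
                               maf_high = 0.5, seed = 1L) {
  if (!(maf_low >= 0 && maf_low <= maf_high && maf_high <= 0.5))
    stop("invalid MAF range: need 0 <= maf_low <= maf_high <= 0.5")
  if (n_lines < 2) stop("n_lines must be >= 2")
  set.seed(seed)
  maf <- runif(n_variants, maf_low, maf_high)
  dos <- matrix(rbinom(n_variants * n_lines, 2L, rep(maf, n_lines)),
                nrow = n_variants, ncol = n_lines)
  rownames(dos) <- sprintf("var%04d", seq_len(n_variants))
  meta <- data.frame(chrom = "chr1",
                     pos = seq_len(n_variants),  # placeholder, see annotation
                     maf = maf)
  genotype_panel(dos, meta, line_ids = sprintf("line%02d", seq_len(n_lines)))
}

#' Simulate gene annotation and cis variant positions
#'
#' Places genes along one chromosome with TSS spaced `tss_spacing` apart, so
#' each gene's cis window is disjoint from its neighbours' when
#' `tss_spacing > 2 * window`. Each gene's variants are placed at controlled
#' distances from its TSS: most within `window`, and (when
#' `variants_per_gene >= 3`) one exactly at the window boundary and one
#' outside it, so downstream test selection is exercised on both sides.
#'
#' @param n_genes number of genes.
#' @param variants_per_gene variants placed per gene.
#' @param window cis window half-width in bp (default 50000).
#' @param tss_spacing distance between consecutive TSS (default 1e6).
#' @param seed integer seed.
#' @return list with `annotation` (data.frame: gene_id, chrom, tss, strand,
#'   length_kb) and `variant_pos` (data.frame: variant index, chrom, pos,
#'   gene_id of the anchoring gene).
#' @export
simulate_gene_annotation <- function(n_genes, variants_per_gene = 3,
                                     window = 50000, tss_spacing = 1e6,
                                     seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  set.seed(seed)
  tss <- tss_spacing * seq_len(n_genes)
  ann <- data.frame(gene_id = sprintf("gene%04d", seq_len(n_genes)),
                    chrom = "chr1",
                    tss = tss,
                    strand = sample(c("+", "-"), n_genes, replace = TRUE),
                    length_kb = round(rlnorm(n_genes, log(2), 0.6), 3))
  vp <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    k <- variants_per_gene
    off <- sample(seq(-window + 1000, window - 1000, by = 500), k,
                  replace = TRUE)
    if (k >= 3) {
      off[1] <- window          # exactly on the boundary (included)
      off[2] <- window + 10000  # outside the window (excluded)
    }
    vp[[g]] <- data.frame(chrom = "chr1", pos = tss[g] + off,
                          gene_id = ann$gene_id[g])
  }
  vp <- do.call(rbind, vp)
  vp$variant <- sprintf("var%04d", seq_len(nrow(vp)))
  rownames(vp) <- vp$variant
  list(annotation = ann, variant_pos = vp[, c("variant", "chrom", "pos",
                                              "gene_id")])
}

#' Attach simulated variant positions to a genotype panel
#'
#' @param panel a [genotype_panel()].
#' @param variant_pos `variant_pos` table from [simulate_gene_annotation()];
#'   rows are matched to panel variants by order (recycled positions are an
#'   error).
#' @return the panel with `variant_meta$chrom`/`pos` replaced.
#' @export
place_variants <- function(panel, variant_pos) {
  if (nrow(variant_pos) != nrow(panel$dosages))
    stop("variant_pos rows must match panel variants")
  panel$variant_meta$chrom <- variant_pos$chrom
  panel$variant_meta$pos <- variant_pos$pos
  rownames(panel$dosages) <- variant_pos$variant
  rownames(panel$variant_meta) <- variant_pos$variant
  panel
}
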