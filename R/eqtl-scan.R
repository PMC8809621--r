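# Cis-test enumeration, genome-wide scan driver, and gene-level multiple
# testing (per-gene Bonferroni over variants, then Storey q across genes).

#' Enumerate cis (gene, variant) tests
#'
#' Genes must reach `cpm_min` CPM in at least `cpm_n` samples and
#' `count_min` counts in at least `count_n` samples (both computed on the
#' aggregation scheme under test); variants must have no missing dosages and
#' sample MAF >= `maf_min`; a pair is tested iff the variant lies within
#' `window` bp of the gene's TSS (inclusive).
#'
#' @param pb a [pseudobulk_set()].
#' @param genotypes a [genotype_panel()] with `chrom`/`pos` metadata.
#' @param annotation data.frame with `gene_id`, `chrom`, `tss`.
#' @param window cis half-window in bp.
#' @param maf_min,cpm_min,cpm_n,count_min,count_n filter thresholds.
#' @return data.frame with columns `gene`, `variant`, `tss_dist`.
#' @export
enumerate_cis_tests <- function(pb, genotypes, annotation, window = 50000,
                                maf_min = 0.1, cpm_min = 0.1, cpm_n = 10,
                                count_min = 6, count_n = 10) {
  stopifnot(is(pb, "pseudobulk_set"), is(genotypes, "genotype_panel"))
  cpm <- log_cpm(pb$counts, log = FALSE)
  genes <- colnames(pb$counts)
  pass_expr <- colSums(cpm >= cpm_min) >= cpm_n &
    colSums(pb$counts >= count_min) >= count_n
  genes <- genes[pass_expr]
  missing_ann <- setdiff(genes, annotation$gene_id)
  if (length(missing_ann) > 0) {
    warning("genes without annotation skipped: ",
            paste(head(missing_ann, 5), collapse = ", "),
            if (length(missing_ann) > 5) " ...")
    genes <- setdiff(genes, missing_ann)
  }
  vm <- genotypes$variant_meta
  ok_var <- vm$maf_sample >= maf_min & !is.na(vm$maf_sample)
  variants <- rownames(genotypes$dosages)[ok_var]
  ann <- annotation[match(genes, annotation$gene_id), ]
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    same <- vm$chrom[ok_var] == ann$chrom[i]
    d <- abs(vm$pos[ok_var] - ann$tss[i])
    hit <- same & d <= window
    if (!any(hit)) next
    out[[i]] <- data.frame(gene = genes[i], variant = variants[hit],
                           tss_dist = d[hit])
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(gene = character(), variant = character(),
                      tss_dist = numeric())
  rownames(out) <- NULL
  out
}

#' Run a dynamic eQTL scan over all enumerated cis tests
#'
#' Standardizes each gene's expression across the given samples, broadcasts
#' the line-collapsed PCs, fits [fit_dynamic_eqtl()] per (gene, variant)
#' pair, and summarizes per gene with [gene_level_significance()].
#'
#' @param pb a normalized [pseudobulk_set()], typically subset to one
#'   lineage.
#' @param genotypes a [genotype_panel()].
#' @param annotation gene annotation (`gene_id`, `chrom`, `tss`).
#' @param line_covars a `line_covariates` from [collapsed_line_pca()], or
#'   `NULL` for no PC covariates.
#' @param degree interaction degree (1 linear, 2 quadratic).
#' @param tests optional precomputed test table (from
#'   [enumerate_cis_tests()]); enumerated with defaults otherwise.
#' @param ... passed to [enumerate_cis_tests()].
#' @return list with `fits` (per-test table: gene, variant, beta, se, t, df,
#'   p, singular) and `genes` (the [gene_level_significance()] table).
#' @export
run_dynamic_eqtl_scan <- function(pb, genotypes, annotation,
                                  line_covars = NULL, degree = 1,
                                  tests = NULL, ...) {
  stopifnot(is(pb, "pseudobulk_set"))
  if (is.null(pb$expr)) pb <- normalize_pseudobulk(pb)
  if (is.null(tests))
    tests <- enumerate_cis_tests(pb, genotypes, annotation, ...)
  if (nrow(tests) == 0)
    return(list(fits = data.frame(), genes = data.frame()))
  line <- as.character(pb$sample_meta$line)
  pcs <- if (is.null(line_covars)) NULL else
    broadcast_line_pcs(line_covars, line)
  tvec <- pb$sample_meta$t
  dos <- genotypes$dosages[, line, drop = FALSE]
  Ez <- apply(pb$expr, 2, .standardize)
  res <- vector("list", nrow(tests))
  for (i in seq_len(nrow(tests))) {
    f <- fit_dynamic_eqtl(Ez[, tests$gene[i]], dos[tests$variant[i], ],
                          tvec, pcs, degree = degree, standardize = FALSE)
    res[[i]] <- data.frame(gene = tests$gene[i], variant = tests$variant[i],
                           beta = f$beta, se = f$se, t = f$t, df = f$df,
                           p = f$p, singular = f$singular)
  }
  fits <- do.call(rbind, res)
  list(fits = fits, genes = gene_level_significance(fits))
}

#' Storey pi0 estimate
#'
#' `pi0(lambda) = #(p > lambda) / (m (1 - lambda))` on the grid
#' `lambda = 0.05, 0.10, ..., 0.95`, smoothed with a cubic smoothing spline
#' (3 df) and evaluated at the largest lambda, clipped to (0, 1].
#'
#' @param p p-values.
#' @param lambda evaluation grid.
#' @return scalar pi0 estimate.
#' @export
storey_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p-values")
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  fit <- smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- predict(fit, x = max(lambda))$y
  min(max(pi0, 1e-8), 1)
}

#' Storey q-values
#'
#' @param p p-values.
#' @param pi0 null proportion; estimated via [storey_pi0()] when `NULL`.
#' @return monotone q-values aligned with `p`.
#' @export
storey_qvalue <- function(p, pi0 = NULL) {
  if (is.null(pi0)) pi0 <- storey_pi0(p)
  m <- length(p)
  o <- order(p)
  q <- pi0 * m * p[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Gene-level significance: Bonferroni over variants, Storey q across genes
#'
#' Per gene, the most significant variant's p-value is Bonferroni-adjusted
#' for the number of (non-singular) variants tested for that gene; Storey
#' q-values are then computed across genes' adjusted p-values. With fewer
#' than 20 genes pi0 is fixed at 1 (conservative).
#'
#' @param fits per-test data.frame with `gene`, `variant`, `p` (and
#'   optionally `singular`, excluded from multiplicity).
#' @return data.frame: `gene`, `top_variant`, `n_variants`, `p_min`,
#'   `p_adj`, `q`; `attr(, "pi0")` holds the study-level pi0.
#' @export
gene_level_significance <- function(fits) {
  if (!is.null(fits$singular)) fits <- fits[!fits$singular, , drop = FALSE]
  fits <- fits[!is.na(fits$p), , drop = FALSE]
  if (nrow(fits) == 0) stop("no valid fits")
  sp <- split(fits, fits$gene)
  tab <- do.call(rbind, lapply(sp, function(d) {
    i <- which.min(d$p)
    data.frame(gene = d$gene[1], top_variant = d$variant[i],
               n_variants = nrow(d), p_min = d$p[i],
               p_adj = min(1, nrow(d) * d$p[i]))
  }))
  rownames(tab) <- NULL
  if (nrow(tab) < 20) {
    warning("fewer than 20 genes; pi0 fixed at 1")
    pi0 <- 1
  } else pi0 <- storey_pi0(tab$p_adj)
  tab$q <- storey_qvalue(tab$p_adj, pi0 = pi0)
  attr(tab, "pi0") <- pi0
  tab
}

#' Estimate the pi1 replication rate
#'
#' `pi1 = 1 - pi0` over a set of replication p-values, with pi0 from
#' [storey_pi0()].
#'
#' @param p replication p-values (>= 50 recommended; fewer warns).
#' @return scalar pi1.
#' @export
estimate_pi1 <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("empty p-value vector")
  if (length(p) < 50) warning("fewer than 50 p-values; pi1 is unstable")
  1 - storey_pi0(p)
}
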