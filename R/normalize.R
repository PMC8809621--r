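# Between-sample normalization: TMM with singleton pairing (TMMwsp) and
# library-size-adapted log-CPM, via edgeR; plus the bulk RPK -> logTPM path.

#' Compute TMM normalization factors
#'
#' Trimmed-mean-of-M-values factors with the singleton-pairing variant
#' (`TMMwsp`) suited to sparse pseudobulk counts: genes positive in only one
#' of (sample, reference) are paired by decreasing count and included in the
#' trimmed mean. Factors are rescaled to have geometric mean 1.
#'
#' @param counts sample x gene non-negative matrix (>= 2 samples for
#'   meaningful factors; a single sample gets factor 1).
#' @param singleton_pairing use `TMMwsp` (default) rather than plain `TMM`.
#' @return numeric vector of per-sample factors.
#' @export
compute_tmm_factors <- function(counts, singleton_pairing = TRUE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (nrow(counts) < 2) return(setNames(1, rownames(counts)))
  method <- if (singleton_pairing) "TMMwsp" else "TMM"
  f <- edgeR::calcNormFactors(t(counts), method = method)
  setNames(as.numeric(f), rownames(counts))
}

#' Library-size-adapted log2 counts per million
#'
#' Uses the effective library `L*_s = lib_s * factor_s` and a sample-scaled
#' pseudocount `p_s = prior * L*_s / mean(L*)`:
#' `expr = log2((x + p_s) / (L*_s + 2 p_s) * 1e6)`.
#'
#' @param counts sample x gene matrix.
#' @param factors per-sample normalization factors (default all 1).
#' @param prior prior count (default 2). `prior = 0` gives plain log2 CPM
#'   (zero counts then map to `-Inf`).
#' @param log return log2 values (default); `FALSE` returns (pseudocount-free)
#'   CPM.
#' @return sample x gene expression matrix.
#' @export
log_cpm <- function(counts, factors = NULL, prior = 2, log = TRUE) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- rep(1, nrow(counts))
  if (any(factors <= 0)) stop("factors must be positive")
  lib <- rowSums(counts) * factors
  if (any(lib <= 0)) stop("zero effective library size")
  if (!log) return(counts / lib * 1e6)
  pr <- prior * lib / mean(lib)
  log2((counts + pr) / (lib + 2 * pr) * 1e6)
}

#' Length-normalize bulk counts to reads per kilobase
#'
#' Feeding the result through [compute_tmm_factors()] and [log_cpm()] yields
#' logTPM (the length bias is removed before the per-million scaling).
#'
#' @param counts sample x gene read counts.
#' @param length_kb per-gene lengths in kilobases (aligned to columns).
#' @return sample x gene RPK matrix.
#' @export
length_normalize <- function(counts, length_kb) {
  counts <- as.matrix(counts)
  if (length(length_kb) != ncol(counts))
    stop("length_kb must have one entry per gene")
  if (any(length_kb <= 0)) stop("gene lengths must be positive")
  sweep(counts, 2, length_kb, "/")
}

#' Normalize a pseudobulk set in place
#'
#' Computes TMMwsp factors and logCPM expression and stores them on the set.
#'
#' @param pb a [pseudobulk_set()].
#' @param prior prior count for [log_cpm()].
#' @param singleton_pairing passed to [compute_tmm_factors()].
#' @return the `pseudobulk_set` with `expr` and `sample_meta$tmm_factor`
#'   filled in.
#' @export
normalize_pseudobulk <- function(pb, prior = 2, singleton_pairing = TRUE) {
  stopifnot(is(pb, "pseudobulk_set"))
  f <- compute_tmm_factors(pb$counts, singleton_pairing)
  pb$expr <- log_cpm(pb$counts, f, prior = prior)
  pb$sample_meta$tmm_factor <- as.numeric(f)
  pb
}
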