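# Calibration and confounding checks: per-test time permutation in the
# interaction term, cell-level pseudotime permutation with empirical nulls,
# a genotype-correlation confounding check, and the batch-composition
# t-test.

#' Permute the time variable inside the interaction term
#'
#' For each (gene, variant) test, an independent permutation of `t` is used
#' in the genotype-by-time column only; the time main effect keeps the true
#' `t`, and by default so do the PC-by-time columns (`permute_pc_t = TRUE`
#' also permutes those, a sensitivity variant). Under the null reading of
#' the design, the permuted interaction should carry no signal and the
#' resulting p-values should be uniform.
#'
#' @param tests data.frame of `gene`, `variant` pairs.
#' @param pb normalized [pseudobulk_set()].
#' @param genotypes a [genotype_panel()].
#' @param line_covars optional `line_covariates`.
#' @param degree interaction degree.
#' @param permute_pc_t also permute `t` within the PC interaction columns.
#' @param seed integer seed.
#' @return list of class `permutation_null`: `p` (per-test permuted
#'   p-values), `t` (permuted t statistics), `seed`, and a `qq` summary of
#'   observed-vs-uniform quantiles.
#' @export
interaction_time_permutation <- function(tests, pb, genotypes,
                                         line_covars = NULL, degree = 1,
                                         permute_pc_t = FALSE, seed = 1L) {
  stopifnot(is(pb, "pseudobulk_set"))
  if (is.null(pb$expr)) pb <- normalize_pseudobulk(pb)
  set.seed(seed)
  line <- as.character(pb$sample_meta$line)
  pcs <- if (is.null(line_covars)) matrix(0, nrow(pb$expr), 0) else
    broadcast_line_pcs(line_covars, line)
  tvec <- pb$sample_meta$t
  dos <- genotypes$dosages[, line, drop = FALSE]
  Ez <- apply(pb$expr, 2, .standardize)
  n <- nrow(Ez)
  pv <- tv <- rep(NA_real_, nrow(tests))
  for (i in seq_len(nrow(tests))) {
    tp <- sample(tvec)
    G <- dos[tests$variant[i], ]
    t_pc <- if (permute_pc_t) tp else tvec
    X <- if (degree == 1) {
      cbind(1, G, tvec, pcs, pcs * t_pc, G * tp)
    } else {
      cbind(1, G, tvec, tvec^2, pcs, pcs * t_pc, pcs * t_pc^2,
            G * tp, G * tp^2)
    }
    f <- .ols_last_coef(X, Ez[, tests$gene[i]])
    pv[i] <- f$p; tv[i] <- f$t
  }
  ok <- !is.na(pv)
  qq <- data.frame(expected = -log10(stats::ppoints(sum(ok))),
                   observed = -log10(sort(pv[ok])))
  structure(list(p = pv, t = tv, seed = seed, qq = qq),
            class = "permutation_null")
}

#' Cell-level pseudotime permutation with empirical nulls
#'
#' Permutes pseudotime across all cells (within each lineage), re-bins,
#' re-aggregates pseudobulk and re-runs the dynamic eQTL fits, `B` times.
#' The per-gene empirical p-value compares the observed top-variant |t| with
#' the permutation |t| distribution using the add-one estimator
#' `p = (1 + #{b : |t_b| >= |t_obs|}) / (B + 1)`, so p is never 0 and its
#' floor is exactly `1/(B+1)`.
#'
#' @param cells a QC-filtered [cell_expression_set()].
#' @param genotypes a [genotype_panel()].
#' @param annotation gene annotation.
#' @param lineage `"CM"` or `"CF"`.
#' @param n_bins pseudotime quantile bins.
#' @param B number of permutations (a warning is raised below 10).
#' @param n_line_pcs line-collapsed PCs to control for.
#' @param min_lib pseudobulk depth filter.
#' @param tests optional fixed test table (recomputed otherwise).
#' @param seed integer seed.
#' @param ... passed to [enumerate_cis_tests()].
#' @return data.frame per gene: `gene`, `t_obs`, `empirical_p`, plus the
#'   observed nominal p for reference; `attr(, "null_t")` is the gene x B
#'   matrix of permutation |t| values.
#' @export
cell_pseudotime_permutation <- function(cells, genotypes, annotation,
                                        lineage = "CM", n_bins = 16, B = 100,
                                        n_line_pcs = 5, min_lib = 0,
                                        tests = NULL, seed = 1L, ...) {
  if (B < 10) warning("B < 10 gives very coarse empirical p-values")
  set.seed(seed)
  run_once <- function(cs) {
    pb <- aggregate_pseudobulk(cs, "lineage_pseudotime", n_bins = n_bins)
    keep <- pb$sample_meta$lineage == lineage
    pb <- pseudobulk_set(pb$counts[keep, , drop = FALSE],
                         pb$sample_meta[keep, , drop = FALSE])
    if (min_lib > 0) pb <- filter_low_depth(pb, min_lib)
    pb <- normalize_pseudobulk(pb)
    lc <- collapsed_line_pca(pb, n_pcs = n_line_pcs)
    if (is.null(tests))
      tests <<- enumerate_cis_tests(pb, genotypes, annotation, ...)
    run_dynamic_eqtl_scan(pb, genotypes, annotation, line_covars = lc,
                          tests = tests)
  }
  obs <- run_once(cells)
  top <- obs$genes[, c("gene", "top_variant")]
  t_obs <- abs(obs$fits$t[match(paste(top$gene, top$top_variant),
                                paste(obs$fits$gene, obs$fits$variant))])
  null_t <- matrix(NA_real_, nrow(top), B)
  perm <- cells
  for (b in seq_len(B)) {
    perm$cell_meta$pseudotime <- sample(cells$cell_meta$pseudotime)
    pr <- run_once(perm)
    # per permutation, take each observed top pair's |t|
    idx <- match(paste(top$gene, top$top_variant),
                 paste(pr$fits$gene, pr$fits$variant))
    null_t[, b] <- abs(pr$fits$t[idx])
  }
  emp <- (1 + rowSums(null_t >= t_obs, na.rm = TRUE)) / (B + 1)
  out <- data.frame(gene = top$gene, top_variant = top$top_variant,
                    t_obs = t_obs, p_nominal = obs$genes$p_min,
                    empirical_p = emp)
  attr(out, "null_t") <- null_t
  out
}

#' Genotype-correlation confounding check
#'
#' If broad cell-line differences (speed, lineage preference) drive false
#' dynamic eQTLs, cell lines would share dosage patterns across the top
#' hits. The statistic is the mean absolute off-diagonal entry of the
#' line-by-line correlation matrix over the hit variants' dosages, compared
#' to `n_bg` resampled variant sets matched for MAF (bins of width
#' `maf_bin`) and distance to the nearest TSS (bins of width `dist_bin`).
#' The empirical p uses the add-one estimator.
#'
#' @param hits character vector of hit variant ids (the top `n_top` are
#'   used; fewer than `n_top` warns and uses all).
#' @param genotypes a [genotype_panel()].
#' @param annotation gene annotation (for TSS distances).
#' @param n_top number of hits used (default 200).
#' @param n_bg background resamples (default 500).
#' @param maf_bin,dist_bin matching bin widths (MAF fraction, bp).
#' @param seed integer seed.
#' @return list: `statistic`, `background` (length `n_bg`), `p`.
#' @export
genotype_correlation_check <- function(hits, genotypes, annotation,
                                       n_top = 200, n_bg = 500,
                                       maf_bin = 0.05, dist_bin = 10000,
                                       seed = 1L) {
  stopifnot(is(genotypes, "genotype_panel"))
  set.seed(seed)
  if (length(hits) < 2) stop("need at least 2 hit variants")
  if (length(hits) < n_top)
    warning("fewer than ", n_top, " hits; using all ", length(hits))
  hits <- hits[seq_len(min(n_top, length(hits)))]
  vm <- genotypes$variant_meta
  # distance to the nearest TSS for every panel variant
  d_near <- vapply(seq_len(nrow(vm)), function(i) {
    same <- annotation$chrom == vm$chrom[i]
    if (!any(same)) return(NA_real_)
    min(abs(annotation$tss[same] - vm$pos[i]))
  }, numeric(1))
  mean_abs_offdiag <- function(ids) {
    cc <- cor(t(genotypes$dosages[ids, , drop = FALSE]))
    mean(abs(cc[upper.tri(cc)]), na.rm = TRUE)
  }
  obs <- mean_abs_offdiag(hits)
  mbin <- floor(vm$maf_sample / maf_bin)
  dbin <- floor(d_near / dist_bin)
  key <- paste(mbin, dbin)
  pool <- split(rownames(genotypes$dosages), key)
  hit_key <- key[match(hits, rownames(genotypes$dosages))]
  # widen bins (drop the distance stratum) when a matching bin is too thin
  thin <- !(hit_key %in% names(pool)) |
    vapply(pool[hit_key], length, integer(1)) < 2
  if (any(thin)) {
    warning(sum(thin), " hit(s) in thin matching bins; ",
            "matched on MAF bin only for those")
    pool_maf <- split(rownames(genotypes$dosages), as.character(mbin))
    hit_mkey <- as.character(mbin[match(hits, rownames(genotypes$dosages))])
  }
  bg <- vapply(seq_len(n_bg), function(b) {
    draw <- vapply(seq_along(hits), function(j) {
      cand <- if (!thin[j]) pool[[hit_key[j]]] else pool_maf[[hit_mkey[j]]]
      cand[sample.int(length(cand), 1)]
    }, character(1))
    mean_abs_offdiag(draw)
  }, numeric(1))
  p <- (1 + sum(bg >= obs)) / (n_bg + 1)
  list(statistic = obs, background = bg, p = p)
}

#' Batch effect on terminal cell-type composition
#'
#' Pairs a day-11 sample with a day-15 sample within each batch, computes
#' the absolute difference in each terminal type's proportion per pair, and
#' compares within-batch pairs to a background of cross-batch pairs matched
#' for differentiation day with a two-sample t-test, separately for CM and
#' CF.
#'
#' @param samples data.frame with columns `line`, `day`, `batch`, `CM`,
#'   `CF` (terminal-type proportions per sample).
#' @param days the two differentiation days to pair (default 11 and 15).
#' @return data.frame per terminal type: `type`, `t`, `p`,
#'   `n_within`, `n_cross`. Zero-variance inputs return p = 1 with a
#'   warning.
#' @export
batch_composition_test <- function(samples, days = c(11, 15)) {
  a <- samples[samples$day == days[1], ]
  b <- samples[samples$day == days[2], ]
  pairs <- expand.grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  within <- a$batch[pairs$i] == b$batch[pairs$j]
  if (sum(within) < 2 || sum(!within) < 2)
    stop("need at least 2 within-batch and 2 cross-batch pairs")
  out <- lapply(c("CM", "CF"), function(type) {
    d <- abs(a[[type]][pairs$i] - b[[type]][pairs$j])
    if (sd(d[within]) == 0 && sd(d[!within]) == 0) {
      warning("zero variance in |delta ", type, "|; p = 1")
      return(data.frame(type = type, t = 0, p = 1,
                        n_within = sum(within), n_cross = sum(!within)))
    }
    tt <- t.test(d[within], d[!within])
    data.frame(type = type, t = unname(tt$statistic), p = tt$p.value,
               n_within = sum(within), n_cross = sum(!within))
  })
  do.call(rbind, out)
}
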