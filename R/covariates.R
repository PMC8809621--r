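# Cell-line-collapsed PCA, sample PCA and PC-by-covariate variance
# diagnostics.

#' Cell-line-collapsed PCA
#'
#' Rearranges the normalized pseudobulk expression into a wide matrix with
#' one row per cell line and one column per (gene, unit[, lineage])
#' combination, standardizes each column to mean 0 / unit variance, fills
#' missing (line, unit) entries with 0 after standardization (column-mean
#' imputation), and runs PCA. The resulting per-line scores capture broad
#' differences in how lines traverse differentiation (speed, lineage
#' preference) and are used as covariates in the interaction models.
#'
#' @param pb a normalized [pseudobulk_set()] (see [normalize_pseudobulk()]).
#' @param n_pcs number of PCs to return (default 5); must be < number of
#'   lines.
#' @return list of class `line_covariates`: `scores` (lines x n_pcs),
#'   `var_explained`, and `lines`.
#' @export
collapsed_line_pca <- function(pb, n_pcs = 5) {
  stopifnot(is(pb, "pseudobulk_set"))
  if (is.null(pb$expr)) stop("pseudobulk set has no normalized expression")
  meta <- pb$sample_meta
  lines <- sort(unique(as.character(meta$line)))
  if (n_pcs >= length(lines))
    stop("n_pcs must be smaller than the number of lines")
  unit_key <- paste(meta$lineage, meta$unit, sep = "|")
  units <- unique(unit_key)
  ng <- ncol(pb$expr)
  wide <- matrix(NA_real_, length(lines), length(units) * ng,
                 dimnames = list(lines, NULL))
  for (u in seq_along(units)) {
    rows <- which(unit_key == units[u])
    cols <- ((u - 1) * ng + 1):(u * ng)
    wide[match(as.character(meta$line[rows]), lines), cols] <-
      pb$expr[rows, , drop = FALSE]
  }
  mu <- colMeans(wide, na.rm = TRUE)
  sdv <- apply(wide, 2, sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  z <- sweep(sweep(wide, 2, mu), 2, sdv, "/")
  z[is.na(z)] <- 0                       # missing (line, unit) after scaling
  pc <- prcomp(z, center = FALSE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)],
                 lines = lines),
            class = "line_covariates")
}

#' Broadcast per-line PC scores to samples
#'
#' @param lc a `line_covariates` from [collapsed_line_pca()].
#' @param line character vector of sample cell lines.
#' @return samples x n_pcs matrix; every sample of a line carries that
#'   line's score vector.
#' @export
broadcast_line_pcs <- function(lc, line) {
  idx <- match(as.character(line), lc$lines)
  if (anyNA(idx)) stop("unknown line(s): ",
                       paste(unique(line[is.na(idx)]), collapse = ", "))
  lc$scores[idx, , drop = FALSE]
}

#' Sample-level PCA of normalized expression
#'
#' Genes are centered and (by default) scaled to unit variance across
#' samples before the decomposition; zero-variance genes are dropped.
#'
#' @param expr sample x gene normalized expression.
#' @param n_pcs number of components.
#' @param scale. scale genes to unit variance (default TRUE).
#' @return list of class `sample_covariates`: `scores` (samples x n_pcs) and
#'   `var_explained`.
#' @export
sample_pca <- function(expr, n_pcs = 10, scale. = TRUE) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 2) stop("need at least 2 samples")
  v <- apply(expr, 2, sd)
  keep <- v > 0
  if (!any(keep)) stop("expression matrix is constant")
  pc <- prcomp(expr[, keep, drop = FALSE], center = TRUE, scale. = scale.)
  k <- min(n_pcs, ncol(pc$x))
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 var_explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]),
            class = "sample_covariates")
}

#' Variance of each PC explained by each covariate
#'
#' Regresses each principal component on each covariate separately
#' (categorical covariates are expanded to factor dummies by `lm`) and
#' reports the R-squared.
#'
#' @param scores samples x PCs matrix.
#' @param covariates data.frame of per-sample covariates.
#' @return PCs x covariates matrix of R-squared values.
#' @export
pc_covariate_variance <- function(scores, covariates) {
  scores <- as.matrix(scores)
  if (nrow(covariates) != nrow(scores))
    stop("covariates must align with samples")
  out <- matrix(0, ncol(scores), ncol(covariates),
                dimnames = list(colnames(scores), colnames(covariates)))
  for (j in seq_len(ncol(covariates))) {
    x <- covariates[[j]]
    if (length(unique(x)) < 2) {
      warning("constant covariate '", colnames(covariates)[j],
              "'; R^2 reported as 0")
      next
    }
    for (i in seq_len(ncol(scores)))
      out[i, j] <- summary(lm(scores[, i] ~ x))$r.squared
  }
  out
}
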