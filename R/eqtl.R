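# Interaction eQTL models. Each (gene, variant) pair gets its own ordinary
# least squares fit; the interaction coefficient (always the last design
# column) is tested with a two-sided t-test on n - p residual degrees of
# freedom. Genotype stays on the dosage scale; expression is standardized
# per gene within the lineage/aggregation under test.

# OLS fit via QR testing the last coefficient; flags singular designs.
.ols_last_coef <- function(X, y) {
  qr_ <- qr(X)
  p <- ncol(X)
  if (qr_$rank < p)
    return(list(singular = TRUE, beta = NA_real_, se = NA_real_,
                t = NA_real_, df = nrow(X) - p, p = NA_real_,
                coefficients = rep(NA_real_, p), sigma = NA_real_))
  beta <- unname(qr.coef(qr_, y))
  res <- y - X %*% beta
  df <- nrow(X) - p
  s2 <- sum(res^2) / df
  XtXinv_pp <- chol2inv(qr.R(qr_))[p, p]
  se <- sqrt(s2 * XtXinv_pp)
  tstat <- beta[p] / se
  list(singular = FALSE, beta = beta[p], se = se, t = tstat, df = df,
       p = 2 * pt(-abs(tstat), df), coefficients = as.numeric(beta),
       sigma = sqrt(s2))
}

.standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x - mean(x))
  (x - mean(x)) / s
}

#' Fit a dynamic eQTL interaction model
#'
#' Degree 1 (linear dynamic eQTL): expression ~ intercept + G + t +
#' PC1..PCk + PC1 t..PCk t + G t; the genotype-by-time coefficient (the
#' last) is tested with a t-test on `N - (2k + 4)` degrees of freedom
#' (14 coefficients with the default 5 line PCs). Degree 2 (nonlinear) adds
#' `t^2`, each `PC t^2`, and `G t^2`, and tests the genotype-by-quadratic-
#' time coefficient (21 coefficients with 5 PCs).
#'
#' @param E expression vector across samples (standardized internally when
#'   `standardize = TRUE`).
#' @param G genotype dosage vector.
#' @param t time covariate (day or median bin pseudotime).
#' @param line_pcs samples x k matrix of broadcast cell-line-collapsed PCs
#'   (k = 5 in the study design); may have 0 columns.
#' @param degree 1 (linear) or 2 (quadratic).
#' @param standardize standardize `E` before fitting (default TRUE).
#' @return list of class `eqtl_fit`: `beta`, `se`, `t`, `df`, `p`,
#'   `coefficients`, `sigma`, `singular`, `model`.
#' @export
fit_dynamic_eqtl <- function(E, G, t, line_pcs = NULL, degree = 1,
                             standardize = TRUE) {
  if (is.null(line_pcs)) line_pcs <- matrix(0, length(E), 0)
  line_pcs <- as.matrix(line_pcs)
  if (standardize) E <- .standardize(E)
  if (degree == 1) {
    X <- cbind(1, G, t, line_pcs, line_pcs * t, G * t)
  } else if (degree == 2) {
    X <- cbind(1, G, t, t^2, line_pcs, line_pcs * t, line_pcs * t^2,
               G * t, G * t^2)
  } else stop("degree must be 1 or 2")
  if (nrow(X) < ncol(X) + 2)
    stop("need at least n_coefficients + 2 samples")
  fit <- .ols_last_coef(X, E)
  fit$model <- paste0("dynamic_deg", degree)
  class(fit) <- "eqtl_fit"
  fit
}

#' Fit a cell-type interaction eQTL model
#'
#' Replaces the time variable of the dynamic model with a cell-type
#' proportion `K`. Three variants: `base` is the dynamic model with
#' `t -> K`; `all_props` additionally adjusts for every cell-type
#' proportion as a main effect (the UNK column must be excluded by the
#' caller's `K_all`, since proportions sum to one); `sample_pcs` replaces
#' the proportion main effect with `m` sample-level principal components.
#' In every mode the tested coefficient is the final `G x K` term.
#'
#' @param E expression vector.
#' @param G genotype dosage vector.
#' @param K proportion of the focal cell type per sample.
#' @param line_pcs samples x k broadcast line PCs.
#' @param mode `"base"`, `"all_props"` or `"sample_pcs"`.
#' @param K_all samples x types proportion matrix excluding UNK
#'   (`all_props` mode).
#' @param sample_pcs samples x m sample-PC matrix (`sample_pcs` mode).
#' @param standardize standardize `E` before fitting.
#' @return an `eqtl_fit` (see [fit_dynamic_eqtl()]).
#' @export
fit_interaction_eqtl <- function(E, G, K, line_pcs = NULL,
                                 mode = c("base", "all_props", "sample_pcs"),
                                 K_all = NULL, sample_pcs = NULL,
                                 standardize = TRUE) {
  mode <- match.arg(mode)
  if (is.null(line_pcs)) line_pcs <- matrix(0, length(E), 0)
  line_pcs <- as.matrix(line_pcs)
  if (standardize) E <- .standardize(E)
  X <- switch(mode,
    base = cbind(1, G, K, line_pcs, line_pcs * K, G * K),
    all_props = {
      if (is.null(K_all)) stop("all_props mode requires K_all")
      cbind(1, G, as.matrix(K_all), line_pcs, line_pcs * K, G * K)
    },
    sample_pcs = {
      if (is.null(sample_pcs)) stop("sample_pcs mode requires sample_pcs")
      cbind(1, G, as.matrix(sample_pcs), line_pcs, line_pcs * K, G * K)
    })
  if (nrow(X) < ncol(X) + 2)
    stop("need at least n_coefficients + 2 samples")
  fit <- .ols_last_coef(X, E)
  fit$model <- paste0("interaction_", mode)
  class(fit) <- "eqtl_fit"
  fit
}

#' Fit a static per-context eQTL model
#'
#' Plain eQTL model within one context (a single day or cell type):
#' expression ~ intercept + G + sample PCs; the genotype main effect and its
#' standard error are exported for downstream cross-context sharing
#' analyses.
#'
#' @param E expression vector within the context.
#' @param G genotype dosage vector.
#' @param sample_pcs samples x m matrix of PCs computed from this context's
#'   expression (5 in the study design).
#' @param standardize standardize `E`.
#' @return list with `beta`, `se`, `t`, `df`, `p`, `singular`.
#' @export
fit_static_context_eqtl <- function(E, G, sample_pcs, standardize = TRUE) {
  sample_pcs <- as.matrix(sample_pcs)
  if (standardize) E <- .standardize(E)
  if (sd(E) == 0)
    return(list(singular = TRUE, beta = NA, se = NA, t = NA,
                df = NA, p = NA))
  X <- cbind(1, sample_pcs, G)  # G last so the shared core tests it
  if (nrow(X) < ncol(X) + 2)
    stop("need at least n_coefficients + 2 samples")
  fit <- .ols_last_coef(X, E)
  fit[c("singular", "beta", "se", "t", "df", "p")]
}

#' @export
print.eqtl_fit <- function(x, ...) {
  cat("eqtl_fit [", x$model, "]: beta =", signif(x$beta, 4),
      "t =", signif(x$t, 4), "df =", x$df, "p =", signif(x$p, 4), "\n")
  invisible(x)
}
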