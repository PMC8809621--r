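# Type-I-error study for pseudotime "double dipping": pseudotime is the
# first expression PC of the very data being tested, cells are split into
# three equal pseudotime bins, expression is averaged per (individual, bin),
# and the genotype-by-pseudotime interaction is tested per gene with a
# fixed-effect linear model and a random-intercept mixed model. All genes
# are null for the interaction by construction.

#' Fit a random-intercept mixed model and test the last fixed effect
#'
#' REML fit via `lme4::lmer`; the interaction is tested with a Wald t test
#' on `n - p` residual degrees of freedom (so the fit degenerates exactly to
#' the OLS t-test when the random-effect variance hits zero), or a
#' likelihood-ratio chi-squared test when `test = "lrt"`. When the
#' random-effect variance estimate is 0 (a boundary fit) the OLS fit is
#' returned with `boundary = TRUE`.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (no intercept column; one is added),
#'   the last column being the tested term.
#' @param group grouping factor for the random intercept; needs >= 2 groups.
#' @param test `"wald"` (default) or `"lrt"`.
#' @return list: `beta`, `se`, `z`, `p`, `re_sd`, `boundary`, `converged`.
#' @export
fit_random_intercept_model <- function(y, X, group, test = c("wald", "lrt")) {
  test <- match.arg(test)
  X <- as.matrix(X)
  group <- as.factor(group)
  if (nlevels(group) < 2) stop("need >= 2 groups")
  dat <- data.frame(y = y, X, group = group)
  xn <- paste0("x", seq_len(ncol(X)))
  names(dat)[1 + seq_len(ncol(X))] <- xn
  form <- stats::as.formula(paste("y ~", paste(xn, collapse = " + "),
                                  "+ (1 | group)"))
  fit <- tryCatch(
    lme4::lmer(form, data = dat, REML = (test == "wald")),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(beta = NA, se = NA, z = NA, p = NA, re_sd = NA,
                boundary = NA, converged = FALSE))
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  k <- length(cf)
  re_sd <- sqrt(unlist(lme4::VarCorr(fit))[1])
  boundary <- re_sd < 1e-8
  if (boundary) {
    # zero random-effect variance: the model coincides with OLS, so report
    # the fixed-effect fit (flagged)
    o <- .ols_last_coef(cbind(1, X), y)
    return(list(beta = o$beta, se = o$se, z = o$t, p = o$p, re_sd = 0,
                boundary = TRUE, converged = TRUE))
  }
  if (test == "wald") {
    z <- cf[k] / se[k]
    p <- 2 * pt(-abs(z), df = length(y) - k)
  } else {
    form0 <- stats::as.formula(paste("y ~",
                                     paste(xn[-k], collapse = " + "),
                                     "+ (1 | group)"))
    fit0 <- lme4::lmer(form0, data = dat, REML = FALSE)
    lr <- 2 * (as.numeric(stats::logLik(fit)) -
                 as.numeric(stats::logLik(fit0)))
    z <- sign(cf[k]) * sqrt(max(lr, 0))
    p <- pchisq(max(lr, 0), df = 1, lower.tail = FALSE)
  }
  list(beta = unname(cf[k]), se = unname(se[k]), z = unname(z), p = p,
       re_sd = unname(re_sd), boundary = boundary, converged = TRUE)
}

#' Bin cells on PC1 pseudotime and average into simulated pseudobulk
#'
#' Pseudotime is the first principal component of the pooled cell x gene
#' matrix (genes centered, not scaled); cells are split at the global
#' tertiles of PC1 (`per_individual = TRUE` uses per-individual tertiles
#' instead), and expression and pseudotime are averaged per (individual,
#' bin).
#'
#' @param sim a `selective_sim_data`.
#' @param n_bins number of pseudotime bins (default 3).
#' @param per_individual split at per-individual rather than global
#'   quantiles.
#' @param pseudotime optional replacement pseudotime per cell (e.g. the true
#'   maturity); PC1 is used when `NULL`.
#' @return list: `Ybar` (sample x gene means), `t` (mean pseudotime per
#'   sample), `individual`, `bin`, `pseudotime` (per cell).
#' @export
selective_pseudobulk <- function(sim, n_bins = 3, per_individual = FALSE,
                                 pseudotime = NULL) {
  stopifnot(is(sim, "selective_sim_data"))
  if (is.null(pseudotime)) {
    Yc <- sweep(sim$Y, 2, colMeans(sim$Y))
    sv <- svd(Yc, nu = 1, nv = 0)
    pseudotime <- as.numeric(sv$u[, 1] * sv$d[1])
  }
  probs <- seq(0, 1, length.out = n_bins + 1)
  if (per_individual) {
    bin <- integer(length(pseudotime))
    for (i in unique(sim$individual)) {
      idx <- sim$individual == i
      br <- quantile(pseudotime[idx], probs)
      br[1] <- -Inf; br[length(br)] <- Inf
      bin[idx] <- as.integer(cut(pseudotime[idx], br, include.lowest = TRUE))
    }
  } else {
    br <- quantile(pseudotime, probs)
    br[1] <- -Inf; br[length(br)] <- Inf
    bin <- as.integer(cut(pseudotime, br, include.lowest = TRUE))
  }
  key <- paste(sim$individual, bin, sep = "|")
  Ybar <- rowsum(sim$Y, key)
  nper <- as.integer(table(key)[rownames(Ybar)])
  Ybar <- Ybar / nper
  tbar <- vapply(split(pseudotime, key), mean, numeric(1))[rownames(Ybar)]
  info <- do.call(rbind, strsplit(rownames(Ybar), "|", fixed = TRUE))
  list(Ybar = Ybar, t = unname(tbar),
       individual = as.integer(info[, 1]), bin = as.integer(info[, 2]),
       pseudotime = pseudotime)
}

#' Run the selective-inference type-I-error study
#'
#' For each gene, fits (1) the fixed-effect linear model
#' `Ybar ~ G + t + G t` and (2) the random-intercept mixed model
#' `Ybar ~ G + t + G t + (1 | individual)`, where `t` is PC1-derived
#' pseudotime averaged per (individual, bin). The type-I error is the
#' fraction of genes with interaction p below `alpha`.
#'
#' @param config a [selective_sim_config()] (one grid setting).
#' @param alpha nominal level (default 0.05).
#' @param models character subset of `c("lm", "lmm")`.
#' @param true_pseudotime use the true maturity `M_ij` instead of PC1 (a
#'   no-double-dipping control).
#' @param lmm_test `"wald"` or `"lrt"` for the mixed model.
#' @return data.frame of class `type1_result`, one row per model: `model`,
#'   `alpha`, `type1`, `mc_se`, `n_genes`, `n_excluded` (non-converged
#'   mixed-model fits), plus the setting's `n`, `sigma_beta`, `ratio`;
#'   `attr(, "p")` holds the per-gene p-value matrix.
#' @export
run_selective_inference_study <- function(config, alpha = 0.05,
                                          models = c("lm", "lmm"),
                                          true_pseudotime = FALSE,
                                          lmm_test = "wald") {
  sim <- simulate_selective_inference_dataset(config)
  pbk <- selective_pseudobulk(
    sim, pseudotime = if (true_pseudotime) sim$truth$M else NULL)
  ng <- config$n_genes
  G_sample <- function(k) sim$truth$G[pbk$individual, k]
  pmat <- matrix(NA_real_, ng, 2, dimnames = list(NULL, c("lm", "lmm")))
  excl <- c(lm = 0L, lmm = 0L)
  tvec <- pbk$t
  for (k in seq_len(ng)) {
    G <- G_sample(k)
    y <- pbk$Ybar[, k]
    if ("lm" %in% models) {
      X <- cbind(1, G, tvec, G * tvec)
      if (sd(G) > 0) {
        f <- .ols_last_coef(X, y)
        pmat[k, "lm"] <- f$p
      } else excl["lm"] <- excl["lm"] + 1L
    }
    if ("lmm" %in% models) {
      if (sd(G) > 0) {
        f <- fit_random_intercept_model(y, cbind(G, tvec, G * tvec),
                                        pbk$individual, test = lmm_test)
        if (isTRUE(f$converged)) pmat[k, "lmm"] <- f$p
        else excl["lmm"] <- excl["lmm"] + 1L
      } else excl["lmm"] <- excl["lmm"] + 1L
    }
  }
  out <- do.call(rbind, lapply(intersect(c("lm", "lmm"), models),
                               function(mdl) {
    pv <- pmat[, mdl]
    nv <- sum(!is.na(pv))
    e <- mean(pv < alpha, na.rm = TRUE)
    data.frame(model = mdl, alpha = alpha, type1 = e,
               mc_se = sqrt(e * (1 - e) / nv), n_genes = nv,
               n_excluded = excl[[mdl]], n = config$n,
               sigma_beta = config$sigma_beta, ratio = config$ratio)
  }))
  rownames(out) <- NULL
  attr(out, "p") <- pmat
  class(out) <- c("type1_result", class(out))
  out
}
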