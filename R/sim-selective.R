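# Generative model for the selective-inference ("double dipping") study:
#   Y_ijk = beta_k G_ik + alpha_k M_ij + a_ik + eps_ijk
# with beta_k ~ N(0, sigma_beta^2), M_ij ~ N(0, 1), alpha_k ~ N(0,
# sigma_alpha^2), a_i. ~ N(0, sigma^2 Sigma), eps_ij. ~ N(0, D Sigma D) with
# a per-gene error scale D chosen so every gene has unit marginal variance.

#' Configuration for the selective-inference generator
#'
#' The maturity effect variance and the individual random-effect variance
#' are parameterized through their sum (`total_ma_var`, fixed at 0.3 so the
#' two jointly explain 30% of expression variance) and their ratio
#' (`ratio = sigma_alpha^2 / sigma^2`).
#'
#' @param n individuals (10 or 20 in the study grid).
#' @param n_genes number of genes.
#' @param n_cells cells per individual.
#' @param sigma_beta SD of per-gene genetic effect sizes (0.1 or 0.4).
#' @param ratio sigma_alpha^2 / sigma^2, one of 0, 0.1, 0.5, 1, 2, 10.
#' @param total_ma_var sigma_alpha^2 + sigma^2, in (0, 1).
#' @param sigma one of `"lowrank"` (default: k-factor correlation matrix
#'   standardized to unit diagonal), `"identity"`, or a user-supplied
#'   correlation matrix of dimension `n_genes`.
#' @param sigma_rank number of factors for the low-rank Sigma.
#' @param maf_low,maf_high cis-variant MAF range (Uniform draw).
#' @param seed integer seed.
#' @return list of class `selective_sim_config`.
#' @export
selective_sim_config <- function(n = 10, n_genes = 1000, n_cells = 100,
                                 sigma_beta = 0.1, ratio = 1,
                                 total_ma_var = 0.3, sigma = "lowrank",
                                 sigma_rank = 10, maf_low = 0.1,
                                 maf_high = 0.5, seed = 1L) {
  if (!(total_ma_var > 0 && total_ma_var < 1))
    stop("total_ma_var must lie in (0, 1)")
  if (ratio < 0) stop("ratio must be >= 0")
  structure(as.list(environment()), class = "selective_sim_config")
}

.make_sigma <- function(config) {
  ng <- config$n_genes
  s <- config$sigma
  if (is.matrix(s)) {
    if (nrow(s) != ng || ncol(s) != ng)
      stop("user Sigma must be n_genes x n_genes")
    if (max(abs(diag(s) - 1)) > 1e-8)
      stop("user Sigma must have unit diagonal")
    return(s)
  }
  if (identical(s, "identity")) return(diag(ng))
  if (identical(s, "lowrank")) {
    W <- matrix(rnorm(ng * config$sigma_rank), ng, config$sigma_rank)
    C <- tcrossprod(W) + diag(ng)         # positive definite
    d <- sqrt(diag(C))
    return(C / tcrossprod(d))
  }
  stop("sigma must be 'lowrank', 'identity' or a matrix")
}

#' Simulate the selective-inference dataset
#'
#' Draws `MAF_k ~ Uniform(maf_low, maf_high)`, `G_ik ~ Binomial(2, MAF_k)`,
#' and the model's effect sizes and random terms, with the per-gene error
#' variance set to `1 - beta_k^2 2 p_k (1 - p_k) - alpha_k^2 - sigma^2` so
#' each gene's marginal variance is exactly 1. Genes for which that residual
#' variance would fall below 0.01 have `beta_k`, `alpha_k` re-drawn (the
#' number of re-draws is recorded in the truth ledger).
#'
#' @param config a [selective_sim_config()].
#' @return list of class `selective_sim_data` with `Y` (an
#'   `(n * n_cells) x n_genes` matrix), `individual` (integer index per
#'   row/cell), and `truth` (beta, alpha, M, G, MAF, per-gene error SD,
#'   variance components and Sigma).
#' @export
simulate_selective_inference_dataset <- function(config) {
  stopifnot(is(config, "selective_sim_config"))
  set.seed(config$seed)
  n <- config$n; ng <- config$n_genes; nc <- config$n_cells
  sigma_alpha2 <- config$total_ma_var * config$ratio / (1 + config$ratio)
  sigma2 <- config$total_ma_var / (1 + config$ratio)

  maf <- runif(ng, config$maf_low, config$maf_high)
  G <- matrix(rbinom(n * ng, 2L, rep(maf, each = n)), n, ng)

  beta <- rnorm(ng, 0, config$sigma_beta)
  alpha <- rnorm(ng, 0, sqrt(sigma_alpha2))
  gvar <- beta^2 * 2 * maf * (1 - maf)
  redraws <- 0L
  repeat {
    bad <- which(1 - gvar - alpha^2 - sigma2 <= 0.01)
    if (length(bad) == 0) break
    redraws <- redraws + length(bad)
    beta[bad] <- rnorm(length(bad), 0, config$sigma_beta)
    alpha[bad] <- rnorm(length(bad), 0, sqrt(sigma_alpha2))
    gvar[bad] <- beta[bad]^2 * 2 * maf[bad] * (1 - maf[bad])
  }
  err_sd <- sqrt(1 - gvar - alpha^2 - sigma2)

  Sigma <- .make_sigma(config)
  R <- chol(Sigma)
  M <- matrix(rnorm(n * nc), n * nc)              # maturity, one per cell
  a <- (matrix(rnorm(n * ng), n, ng) %*% R) * sqrt(sigma2)
  eps <- sweep(matrix(rnorm(n * nc * ng), n * nc, ng) %*% R, 2, err_sd, "*")

  individual <- rep(seq_len(n), each = nc)
  Y <- sweep(G[individual, , drop = FALSE], 2, beta, "*") +
    tcrossprod(M[, 1], alpha) +
    a[individual, , drop = FALSE] + eps
  colnames(Y) <- sprintf("gene%04d", seq_len(ng))

  structure(list(
    Y = Y, individual = individual,
    truth = list(beta = beta, alpha = alpha, M = M[, 1], G = G, maf = maf,
                 err_sd = err_sd, genetic_var = gvar,
                 sigma_alpha2 = sigma_alpha2, sigma2 = sigma2,
                 Sigma = Sigma, redraws = redraws)),
    class = "selective_sim_data")
}

#' Per-gene variance decomposition of a selective-inference dataset
#'
#' Returns the truth-based fractions of each gene's (unit) variance
#' attributable to the genetic term, to maturity + individual random effect
#' jointly, and to the error term.
#'
#' @param sim a `selective_sim_data`.
#' @return data.frame with per-gene `genetic`, `maturity_individual`, and
#'   `error` variance fractions.
#' @export
variance_decomposition <- function(sim) {
  stopifnot(is(sim, "selective_sim_data"))
  tr <- sim$truth
  data.frame(gene = colnames(sim$Y),
             genetic = tr$genetic_var,
             maturity_individual = tr$alpha^2 + tr$sigma2,
             error = tr$err_sd^2)
}
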