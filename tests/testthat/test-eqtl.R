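# Interaction models against a normal-equations oracle, cis enumeration,
# Bonferroni/Storey machinery, pi1.

ols_oracle <- function(X, y) {
  # closed-form normal equations, independent of the qr path
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  se <- sqrt(s2 * diag(solve(XtX)))
  t <- b[length(b)] / se[length(se)]
  list(beta = as.numeric(b), t = as.numeric(t), df = df,
       p = 2 * pt(-abs(t), df))
}

make_dyn_fixture <- function(n = 20, seed = 1, effect = 0.8, noise = 0.1) {
  set.seed(seed)
  G <- rbinom(n, 2, 0.4)
  t <- runif(n)
  E <- effect * G * t + rnorm(n, 0, noise)
  list(E = E, G = G, t = t)
}

test_that("dynamic eQTL fit matches the normal-equations oracle to 1e-8", {
  fx <- make_dyn_fixture(n = 30)
  set.seed(2)
  pcs <- matrix(rnorm(30 * 5, 0, 0.3), 30, 5)
  for (deg in 1:2) {
    fit <- fit_dynamic_eqtl(fx$E, fx$G, fx$t, pcs, degree = deg,
                            standardize = FALSE)
    X <- if (deg == 1) cbind(1, fx$G, fx$t, pcs, pcs * fx$t, fx$G * fx$t)
         else cbind(1, fx$G, fx$t, fx$t^2, pcs, pcs * fx$t, pcs * fx$t^2,
                    fx$G * fx$t, fx$G * fx$t^2)
    expect_equal(ncol(X), if (deg == 1) 14 else 21)
    expect_equal(fit$df, 30 - ncol(X))
    oracle <- ols_oracle(X, fx$E)
    expect_equal(fit$coefficients, oracle$beta, tolerance = 1e-8)
    expect_equal(fit$t, oracle$t, tolerance = 1e-8)
    expect_equal(fit$p, oracle$p, tolerance = 1e-8)
  }
})

test_that("a strong planted interaction is recovered with the expected size", {
  fx <- make_dyn_fixture(n = 60, seed = 5)
  fit <- fit_dynamic_eqtl(fx$E, fx$G, fx$t, NULL, standardize = TRUE)
  expect_lt(fit$p, 1e-6)
  # standardized E scales the coefficient by 1/sd(E)
  expect_lt(abs(fit$beta - 0.8 / sd(fx$E)), 2 * fit$se)
  # constant genotype: singular flag
  s <- fit_dynamic_eqtl(fx$E, rep(1, 60), fx$t, NULL)
  expect_true(s$singular)
  expect_true(is.na(s$p))
})

test_that("interaction p is invariant to affine maps of time and expression", {
  fx <- make_dyn_fixture(n = 40, seed = 7, effect = 0.3, noise = 0.5)
  pcs <- matrix(rnorm(40 * 2), 40, 2)
  base <- fit_dynamic_eqtl(fx$E, fx$G, fx$t, pcs)
  shifted <- fit_dynamic_eqtl(fx$E, fx$G, 3 - 2 * fx$t, pcs)
  expect_equal(base$p, shifted$p, tolerance = 1e-10)
  rescaled <- fit_dynamic_eqtl(5 * fx$E - 2, fx$G, fx$t, pcs)
  expect_equal(base$p, rescaled$p, tolerance = 1e-10)
})

test_that("cell-type interaction model equals dynamic model when K is affine in t", {
  fx <- make_dyn_fixture(n = 40, seed = 9, effect = 0.4, noise = 0.4)
  pcs <- matrix(rnorm(40 * 3), 40, 3)
  K <- 0.2 + 0.5 * fx$t
  dyn <- fit_dynamic_eqtl(fx$E, fx$G, fx$t, pcs)
  int <- fit_interaction_eqtl(fx$E, fx$G, K, pcs, mode = "base")
  expect_equal(dyn$p, int$p, tolerance = 1e-10)
  # full proportion matrix whose columns sum to one is singular
  K2 <- runif(40, 0, 1 - K)
  K_all_bad <- cbind(K, K2, 1 - K - K2)  # rows sum to 1
  bad <- fit_interaction_eqtl(fx$E, fx$G, K, pcs, mode = "all_props",
                              K_all = K_all_bad)
  expect_true(bad$singular)
  # dropping the complement (UNK-like) column makes it estimable
  ok <- fit_interaction_eqtl(fx$E, fx$G, K, pcs, mode = "all_props",
                             K_all = K_all_bad[, 1:2])
  expect_false(ok$singular)
  # sample-PC mode uses exactly m PC covariates
  spc <- matrix(rnorm(40 * 4), 40, 4)
  f <- fit_interaction_eqtl(fx$E, fx$G, K, pcs, mode = "sample_pcs",
                            sample_pcs = spc)
  expect_equal(f$df, 40 - (1 + 1 + 4 + 3 + 3 + 1))
})

test_that("null cell-type interaction p-values are uniform", {
  set.seed(77)
  pv <- replicate(800, {
    n <- 30
    G <- rbinom(n, 2, 0.3)
    K <- runif(n)
    E <- rnorm(n)
    fit_interaction_eqtl(E, G, K, NULL, mode = "base")$p
  })
  expect_gt(ks.test(pv, "punif")$p.value, 0.01)
})

test_that("static per-context model recovers a main genotype effect", {
  set.seed(3)
  n <- 40
  G <- rbinom(n, 2, 0.4)
  pcs <- matrix(rnorm(n * 5, 0, 0.2), n, 5)
  E <- 0.5 * G + rnorm(n, 0, 0.01)
  fit <- fit_static_context_eqtl(E, G, pcs, standardize = FALSE)
  expect_lt(abs(fit$beta - 0.5), 2 * fit$se)
  expect_true(is.finite(fit$se))
  zero <- fit_static_context_eqtl(rep(1, n), G, pcs, standardize = FALSE)
  expect_true(zero$singular)
})

test_that("cis enumeration honors window, MAF and expression thresholds", {
  px <- small_panel(n_genes = 40)
  # pseudobulk where every gene passes expression filters comfortably
  counts <- matrix(50, 12, 40,
                   dimnames = list(paste0("s", 1:12),
                                   px$annotation$gene_id))
  pb <- pseudobulk_set(counts, data.frame(line = paste0("line", 1:12),
                                          lineage = "CM", unit = 1, t = 0.1,
                                          n_cells = 5))
  tests <- enumerate_cis_tests(pb, px$panel, px$annotation)
  tss <- px$annotation$tss[match(tests$gene, px$annotation$gene_id)]
  pos <- px$panel$variant_meta[tests$variant, "pos"]
  expect_true(all(abs(pos - tss) <= 50000))
  # boundary variant (exactly 50 kb) of each gene is included if MAF passes
  vp <- px$variant_pos
  boundary <- vp$variant[seq(1, nrow(vp), by = 5)]
  eligible <- boundary[px$panel$variant_meta[boundary, "maf_sample"] >= 0.1]
  expect_true(all(eligible %in% tests$variant))
  # outside-window variants are never tested
  outside <- vp$variant[seq(2, nrow(vp), by = 5)]
  expect_false(any(outside %in% tests$variant))
  # low-MAF variants excluded
  expect_true(all(px$panel$variant_meta[tests$variant, "maf_sample"] >= 0.1))
  # expression thresholds: a gene below 0.1 CPM everywhere is not tested
  counts2 <- counts; counts2[, 1] <- 0
  pb2 <- pseudobulk_set(counts2, pb$sample_meta)
  tests2 <- enumerate_cis_tests(pb2, px$panel, px$annotation)
  expect_false(px$annotation$gene_id[1] %in% tests2$gene)
  # gene reaching thresholds in exactly the minimum number of samples passes
  counts3 <- counts
  counts3[, 2] <- c(rep(6, 10), 0, 0)  # 6 counts in exactly 10 samples
  pb3 <- pseudobulk_set(counts3, pb$sample_meta)
  tests3 <- enumerate_cis_tests(pb3, px$panel, px$annotation)
  expect_true(px$annotation$gene_id[2] %in% tests3$gene)
})

test_that("gene-level Bonferroni and Storey q behave on null and mixtures", {
  # adjusted p = min(1, m * min p)
  fits <- data.frame(gene = c("g1", "g2", "g2"), variant = c("v1", "v2", "v3"),
                     p = c(0.001, 0.02, 0.5), singular = FALSE)
  expect_warning(tab <- gene_level_significance(fits), "fewer than 20")
  expect_equal(tab$p_adj[tab$gene == "g1"], 0.001)
  expect_equal(tab$p_adj[tab$gene == "g2"], 0.04)
  # cap at 1
  fits2 <- data.frame(gene = rep("g", 200), variant = paste0("v", 1:200),
                      p = pmax(runif(200), 0.01), singular = FALSE)
  expect_warning(tab2 <- gene_level_significance(fits2))
  expect_equal(tab2$p_adj, 1)
  # null: pi0 near 1 and no q <= 0.05 discoveries
  set.seed(10)
  nul <- data.frame(gene = paste0("g", 1:1000), variant = "v",
                    p = runif(1000), singular = FALSE)
  tabn <- gene_level_significance(nul)
  expect_gt(attr(tabn, "pi0"), 0.8)
  expect_lte(mean(tabn$q <= 0.05), 0.01)
  # q ordering follows adjusted p ordering
  o <- order(tabn$p_adj)
  expect_true(all(diff(tabn$q[o]) >= -1e-12))
})

test_that("pi1 estimates the non-null fraction", {
  set.seed(123)
  expect_lt(abs(estimate_pi1(runif(1000))), 0.05)
  expect_gt(estimate_pi1(rep(1e-8, 100)), 0.95)
  mix <- c(rbeta(1400, 0.1, 1), runif(600))  # 70/30 mixture
  expect_lt(abs(estimate_pi1(mix) - 0.7), 0.1)
  expect_error(estimate_pi1(numeric(0)), "empty")
  expect_warning(estimate_pi1(runif(10)), "unstable")
})
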