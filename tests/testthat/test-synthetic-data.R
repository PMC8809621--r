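# Generators: genotypes, annotation, differentiation counts, matched bulk,
# and the selective-inference dataset.

test_that("simulated genotypes follow Binomial(2, MAF) and record MAF", {
  g <- simulate_genotypes(1000, 5, maf_low = 0.5, maf_high = 0.5, seed = 3)
  # symmetric binomial: mean dosage 1 within 3 binomial SE
  se <- sqrt(2 * 0.5 * 0.5 / 1000)
  expect_true(all(abs(colMeans(t(g$dosages)) - 1) < 3 * se))
  g0 <- simulate_genotypes(10, 20, maf_low = 0, maf_high = 0, seed = 3)
  expect_true(all(g0$dosages == 0))
  gm <- simulate_genotypes(5, 1e4, maf_low = 0.1, maf_high = 0.5, seed = 3)
  # mean drawn MAF ~ E[U(0.1, 0.5)] = 0.3 within MC error
  expect_lt(abs(mean(gm$variant_meta$maf) - 0.3),
            3 * sqrt(0.4^2 / 12 / 1e4))
  expect_error(simulate_genotypes(10, 5, maf_low = 0.4, maf_high = 0.2),
               "MAF range")
  expect_error(simulate_genotypes(1, 5), "n_lines")
})

test_that("gene annotation places boundary/outside variants and is deterministic", {
  a1 <- simulate_gene_annotation(10, variants_per_gene = 4, seed = 9)
  a2 <- simulate_gene_annotation(10, variants_per_gene = 4, seed = 9)
  expect_identical(a1, a2)
  expect_true(all(a1$annotation$length_kb > 0))
  # first variant per gene sits exactly on the 50 kb boundary, second outside
  tss <- a1$annotation$tss[match(a1$variant_pos$gene_id,
                                 a1$annotation$gene_id)]
  d <- abs(a1$variant_pos$pos - tss)
  per_gene <- split(d, a1$variant_pos$gene_id)
  expect_true(all(vapply(per_gene, function(x) x[1] == 50000, logical(1))))
  expect_true(all(vapply(per_gene, function(x) x[2] > 50000, logical(1))))
  # lengths positive over many draws
  lens <- unlist(lapply(1:100, function(s)
    simulate_gene_annotation(3, seed = s)$annotation$length_kb))
  expect_true(all(lens > 0))
})

test_that("differentiation simulator is deterministic and internally consistent", {
  px <- small_panel(n_genes = 20)
  cfg <- diff_sim_config(n_genes = 20, cells_per_sample = 10, seed = 5)
  d1 <- simulate_differentiation_dataset(cfg, px$panel)
  d2 <- simulate_differentiation_dataset(cfg, px$panel)
  expect_identical(d1$cells$counts, d2$cells$counts)
  m <- d1$cells$cell_meta
  expect_true(all(m$n_umi == rowSums(d1$cells$counts)))
  expect_true(all(m$n_genes_detected == rowSums(d1$cells$counts > 0)))
  expect_true(all(m$pseudotime >= 0 & m$pseudotime <= 1))
  # pseudotime increases with day in expectation within each line
  for (ln in unique(m$line)[1:3]) {
    mm <- aggregate(pseudotime ~ day, data = m[m$line == ln, ], FUN = mean)
    expect_true(all(diff(mm$pseudotime[order(mm$day)]) > -0.05))
  }
  # truth proportions rows sum to 1
  pr <- d1$truth$sample_proportions
  expect_equal(rowSums(pr[, intersect(colnames(pr), dyneqtl:::.cell_types)]),
               rep(1, nrow(pr)), tolerance = 1e-12)
  expect_error(
    simulate_differentiation_dataset(
      diff_sim_config(n_genes = 20, cells_per_sample = 5,
                      effects = data.frame(gene = "nope", variant = "var0001",
                                           lineage = "CM", gamma1 = 1,
                                           gamma2 = 0, gamma3 = 0)),
      px$panel),
    "unknown gene/variant")
})

test_that("matched bulk sums cells exactly and scales by gene length", {
  px <- small_panel(n_genes = 20)
  cfg <- diff_sim_config(n_genes = 20, cells_per_sample = 8, seed = 15)
  d <- simulate_differentiation_dataset(cfg, px$panel)
  ann <- px$annotation[1:20, ]
  bulk <- synthesize_matched_bulk(d$cells, ann)
  # conservation before length scaling
  expect_equal(sum(bulk$counts_raw), sum(d$cells$counts))
  # scaling is per-gene multiplication by length_kb
  len <- ann$length_kb[match(colnames(bulk$counts), ann$gene_id)]
  expect_equal(bulk$counts, sweep(bulk$counts_raw, 2, len, "*"))
  # single-cell sample: bulk row equals that cell's counts times lengths
  one <- subset_cells(d$cells, cells = 1)
  b1 <- synthesize_matched_bulk(one, ann)
  expect_equal(as.numeric(b1$counts), as.numeric(one$counts[1, ] * len))
  pt <- bulk$truth_proportions
  expect_equal(rowSums(pt[, intersect(colnames(pt), dyneqtl:::.cell_types)]),
               rep(1, nrow(pt)), tolerance = 1e-12)
})

test_that("selective-inference generator hits its variance targets", {
  cfg <- selective_sim_config(sigma_beta = 0.1, ratio = 1, seed = 21)
  sim <- simulate_selective_inference_dataset(cfg)
  vd <- variance_decomposition(sim)
  # closed form: sigma_beta^2 * E[2p(1-p)], p ~ U(0.1, 0.5)
  closed <- 0.1^2 * (2 * (0.3 - (0.4^2 / 12 + 0.09)))
  expect_equal(closed, 0.1^2 * 0.393333, tolerance = 1e-4)
  # 3 MC SE: sd(beta^2 * 2p(1-p)) ~ sqrt(2) * sigma_beta^2 * 0.39
  expect_lt(abs(mean(vd$genetic) - closed),
            3 * sqrt(2) * 0.1^2 * 0.3933 / sqrt(1000))
  # per-gene marginal variance 1 by construction, and empirically
  expect_equal(unname(vd$genetic + vd$maturity_individual + vd$error),
               rep(1, nrow(vd)), tolerance = 1e-12)
  # cells within an individual share a_ik: only ~n independent draws of the
  # individual component, so the mean empirical variance fluctuates at the
  # few-percent level (~3 MC SE = 0.07)
  expect_lt(abs(mean(apply(sim$Y, 2, var)) - 1), 0.07)
  # ratio = 0 degenerates: no maturity effect
  s0 <- simulate_selective_inference_dataset(
    selective_sim_config(ratio = 0, n_genes = 100, seed = 4))
  expect_true(all(s0$truth$alpha == 0))
  expect_equal(s0$truth$sigma_alpha2, 0)
})

test_that("cross-gene correlation of simulated expression converges to Sigma", {
  base <- selective_sim_config(n = 6, n_genes = 60, n_cells = 30,
                               sigma = "lowrank", seed = 31)
  small <- simulate_selective_inference_dataset(base)
  big <- simulate_selective_inference_dataset(
    selective_sim_config(n = 6, n_genes = 60, n_cells = 600,
                         sigma = "lowrank", seed = 31))
  frob <- function(sim) {
    resid <- sim$Y -
      tcrossprod(sim$truth$M, sim$truth$alpha) -
      sweep(sim$truth$G[sim$individual, ], 2, sim$truth$beta, "*")
    norm(cor(resid) - sim$truth$Sigma, "F")
  }
  expect_lt(frob(big), frob(small))
})
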