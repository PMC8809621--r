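# Lineage assignment, binning, aggregation, depth filter, TMM and logCPM.

test_that("lineage assignment shares precursors and excludes UNK", {
  cells <- toy_cells()
  cells$cell_meta$cell_type <- c("PROG", "CM", "UNK", "CF")
  m <- assign_lineages(cells)
  expect_equal(unname(m[1, ]), c(TRUE, TRUE))    # precursor in both
  expect_equal(unname(m[2, ]), c(TRUE, FALSE))   # CM terminal
  expect_equal(unname(m[3, ]), c(FALSE, FALSE))  # UNK excluded
  expect_equal(unname(m[4, ]), c(FALSE, TRUE))   # CF terminal
  cells$cell_meta$cell_type[1] <- "whatisthis"
  expect_error(assign_lineages(cells), "unknown cell type")
})

test_that("pseudotime quantile bins match a rank-and-split oracle", {
  b <- bin_pseudotime(1:16, n_bins = 4)
  expect_equal(b, rep(0:3, each = 4))
  expect_warning(b0 <- bin_pseudotime(rep(0.5, 10), 4), "identical")
  expect_equal(b0, rep(0L, 10))
  expect_error(bin_pseudotime(1:3, 4), "fewer cells")
  # ties straddling a boundary: stable rank order oracle
  set.seed(42)
  for (i in 1:20) {
    pt <- sample(round(runif(37), 1))  # many ties
    nb <- sample(2:7, 1)
    got <- bin_pseudotime(pt, nb)
    ord <- order(pt, seq_along(pt))
    oracle <- integer(length(pt))
    oracle[ord] <- as.integer(floor((seq_along(pt) - 1) * nb / length(pt)))
    expect_identical(got, oracle)
    # near-equal sizes and non-decreasing median pseudotime over bins
    expect_lte(diff(range(table(got))), 1)
    med <- tapply(pt, got, median)
    expect_true(all(diff(med[order(as.integer(names(med)))]) >= 0))
  }
})

test_that("aggregation sums counts per group and uses the lower median t", {
  cells <- toy_cells()
  # two cells of line A, day 0/1: force same group via same day
  cells$cell_meta$day <- c(0, 0, 1, 1)
  pb <- aggregate_pseudobulk(cells, "day")
  a0 <- pb$counts["combined|A|0", ]
  expect_equal(unname(a0), unname(cells$counts[1, ] + cells$counts[2, ]))
  expect_equal(pb$sample_meta$lib_size, unname(rowSums(pb$counts)))
  # lower median: {0.1, 0.2, 0.4} -> 0.2
  expect_equal(dyneqtl:::.lower_median(c(0.1, 0.2, 0.4)), 0.2)
  expect_equal(dyneqtl:::.lower_median(c(0.1, 0.4)), 0.1)
})

test_that("day scheme equals per-lineage day schemes on precursor-only cells", {
  px <- small_panel(n_genes = 25)
  cfg <- diff_sim_config(n_genes = 25, cells_per_sample = 12, days = c(0, 1),
                         unk_frac = 0, speed = 0.25, pt_concentration = 40,
                         seed = 12)
  d <- simulate_differentiation_dataset(cfg, px$panel)
  expect_true(all(d$cells$cell_meta$cell_type %in%
                    c("IPSC", "MES", "CMES", "PROG")))
  day <- aggregate_pseudobulk(d$cells, "day")
  lin <- aggregate_pseudobulk(d$cells, "lineage_day")
  for (l in c("CM", "CF")) {
    sub <- lin$counts[lin$sample_meta$lineage == l, , drop = FALSE]
    key <- sub("^(CM|CF)", "combined", rownames(sub))
    expect_equal(unname(sub[order(key), ]),
                 unname(day$counts[order(rownames(day$counts)), ]))
  }
  # count conservation per lineage: totals equal member-cell totals
  member <- assign_lineages(d$cells)
  for (l in c("CM", "CF"))
    expect_equal(sum(lin$counts[lin$sample_meta$lineage == l, ]),
                 sum(d$cells$counts[member[, l], ]))
})

test_that("depth filter removes strictly-below-threshold samples", {
  counts <- rbind(s1 = rep(999.9, 10), s2 = rep(1000, 10),
                  s3 = rep(2000, 10))
  pb <- pseudobulk_set(counts, data.frame(line = c("A", "B", "C"),
                                          lineage = "CM", unit = 1,
                                          t = 0.5, n_cells = 5))
  out <- filter_low_depth(pb, min_lib = 10000)
  expect_equal(rownames(out$counts), c("s2", "s3"))
  expect_equal(attr(out, "removed")$line, "A")
  expect_equal(nrow(filter_low_depth(pb, min_lib = 0)$counts), 3)
  expect_error(filter_low_depth(pb, min_lib = 1e9), "all pseudobulk")
})

test_that("TMM factors behave like edgeR TMMwsp and normalize composition", {
  set.seed(31)
  counts <- matrix(rnbinom(6 * 200, mu = 50, size = 2), nrow = 6)
  f <- compute_tmm_factors(counts)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  expect_equal(unname(f),
               unname(edgeR::calcNormFactors(t(counts), method = "TMMwsp")))
  # identical columns: all factors 1
  same <- matrix(rep(counts[1, ], 4), nrow = 4, byrow = TRUE)
  expect_equal(unname(compute_tmm_factors(same)), rep(1, 4))
  # pure depth scaling (same composition): normalized CPM agrees
  two <- rbind(counts[1, ], counts[1, ] * 2)
  f2 <- compute_tmm_factors(two)
  cpm <- log_cpm(two, f2, log = FALSE)
  expect_equal(cpm[1, ], cpm[2, ], tolerance = 1e-9)
})

test_that("logCPM matches the direct library-size-adapted formula", {
  set.seed(7)
  counts <- matrix(rpois(5 * 40, 20), nrow = 5)
  f <- compute_tmm_factors(counts)
  got <- log_cpm(counts, f, prior = 2)
  lib <- rowSums(counts) * f
  pr <- 2 * lib / mean(lib)
  direct <- log2((counts + pr) / (lib + 2 * pr) * 1e6)
  expect_equal(got, direct, tolerance = 1e-12)
  # independent route: edgeR's own implementation (effective libraries)
  er <- t(edgeR::cpm(t(counts), lib.size = rowSums(counts) * f,
                     log = TRUE, prior.count = 2))
  expect_equal(unname(got), unname(er), tolerance = 1e-9)
  # equal libraries, factor 1: closed form log2((x+2)/(L+4)*1e6)
  eq <- rbind(c(0, 10, 90, 60, 30, 10),
              c(40, 50, 10, 100, 0, 0))  # both libraries are 200
  expect_equal(log_cpm(eq, rep(1, 2), prior = 2),
               log2((eq + 2) / (200 + 4) * 1e6), tolerance = 1e-12)
  # zero counts stay finite; monotone in x
  expect_true(all(is.finite(log_cpm(eq))))
  expect_true(all(diff(log_cpm(matrix(c(0, 5, 50, 500), 1))[1, ]) > 0))
  # unnormalized CPM rows sum to 1e6
  expect_equal(unname(rowSums(log_cpm(counts, log = FALSE))),
               rep(1e6, 5), tolerance = 1e-6)
})

test_that("RPK length normalization yields logTPM through the CPM path", {
  set.seed(8)
  counts <- matrix(rpois(4 * 30, 40), nrow = 4)
  len <- runif(30, 0.5, 5)
  rpk <- length_normalize(counts, len)
  expect_equal(rpk, sweep(counts, 2, len, "/"))
  expect_equal(length_normalize(counts, rep(1, 30)), counts)
  expect_error(length_normalize(counts, c(len[-1], -1)), "positive")
  # doubling one gene's length halves its RPK only
  len2 <- len; len2[3] <- len[3] * 2
  rpk2 <- length_normalize(counts, len2)
  expect_equal(rpk2[, 3], rpk[, 3] / 2)
  expect_equal(rpk2[, -3], rpk[, -3])
})
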