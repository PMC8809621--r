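# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small genotype panel + annotation with variants placed around TSSs
small_panel <- function(n_lines = 19, n_genes = 40, vpg = 5, seed = 101) {
  cached(paste("panel", n_lines, n_genes, vpg, seed), function() {
    g <- simulate_genotypes(n_lines, n_genes * vpg, seed = seed)
    ann <- simulate_gene_annotation(n_genes, variants_per_gene = vpg,
                                    seed = seed)
    list(panel = place_variants(g, ann$variant_pos),
         annotation = ann$annotation, variant_pos = ann$variant_pos)
  })
}

# default-condition differentiation dataset (realistic nuisance structure)
default_dataset <- function(seed = 2024, n_genes = 120,
                            cells_per_sample = 30, effects = NULL) {
  px <- small_panel(n_genes = n_genes)
  cfg <- diff_sim_config(n_genes = n_genes,
                         cells_per_sample = cells_per_sample,
                         effects = effects, seed = seed)
  d <- simulate_differentiation_dataset(cfg, px$panel)
  c(d, px)
}

# model-faithful null: flat expression surface, homogeneous lines; the
# dynamic eQTL model is correctly specified so its null holds exactly
flat_null_dataset <- function(seed = 77, n_genes = 200,
                              cells_per_sample = 40) {
  px <- small_panel(n_genes = n_genes)
  cfg <- diff_sim_config(n_genes = n_genes,
                         cells_per_sample = cells_per_sample,
                         line_effect_sd = 0, speed = 1, lineage_pref = 0.5,
                         marker_frac = 0, slope_sd = 0,
                         lineage_offset_sd = 0, seed = seed)
  d <- simulate_differentiation_dataset(cfg, px$panel)
  c(d, px)
}

# QC'd lineage pseudobulk, normalized, plus line PCs
lineage_pseudobulk <- function(cells, lineage = "CM", n_bins = 16,
                               min_lib = 10000, n_pcs = 5) {
  pb <- aggregate_pseudobulk(cells, "lineage_pseudotime", n_bins = n_bins)
  keep <- pb$sample_meta$lineage == lineage
  pb <- pseudobulk_set(pb$counts[keep, , drop = FALSE],
                       pb$sample_meta[keep, , drop = FALSE])
  pb <- filter_low_depth(pb, min_lib)
  pb <- normalize_pseudobulk(pb)
  list(pb = pb, line_pcs = collapsed_line_pca(pb, n_pcs))
}

run_lineage_scan <- function(dataset, lineage = "CM", qc = TRUE, ...) {
  cells <- if (qc) run_qc(dataset$cells, min_cells = 10, min_genes = 20)
           else dataset$cells
  lp <- lineage_pseudobulk(cells, lineage)
  run_dynamic_eqtl_scan(lp$pb, dataset$panel, dataset$annotation,
                        line_covars = lp$line_pcs, ...)
}

# tiny deterministic cell set for unit tests
toy_cells <- function() {
  counts <- matrix(c(5, 0, 2,
                     1, 3, 0,
                     0, 0, 8,
                     2, 2, 2), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("c", 1:4), paste0("g", 1:3)))
  meta <- data.frame(line = c("A", "A", "B", "B"),
                     day = c(0, 1, 0, 1),
                     pseudotime = c(0.1, 0.4, 0.2, 0.9),
                     cell_type = c("IPSC", "CMES", "MES", "CM"),
                     doublet_prob = c(0.1, 0.2, 0.05, 0.1),
                     assignment = "singlet",
                     mito_fraction = c(0.1, 0.05, 0.2, 0.1))
  cell_expression_set(counts, meta)
}
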