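# Bifurcating differentiation simulator: 19 iPSC-derived lines collected on
# 7 days, two lineages (cardiomyocyte CM, cardiac fibroblast CF) sharing
# precursor stages, with injectable genotype, genotype x time and
# genotype x time^2 effects and a full truth ledger.

#' Configuration for the differentiation simulator
#'
#' Defaults emulate the study design: 19 cell lines collected on days
#' 0, 1, 3, 5, 7, 11 and 15, with line-specific lineage preference and
#' differentiation speed, negative binomial UMI counts, and QC metadata
#' fields including a planted fraction of QC failures.
#'
#' @param n_lines number of cell lines.
#' @param days collection days.
#' @param cells_per_sample cells per (line, day) sample.
#' @param n_genes genes simulated.
#' @param lineage_pref per-line fraction of committed cells entering the CM
#'   branch; `NULL` draws Uniform(0.25, 0.75).
#' @param speed per-line differentiation speed multiplier; `NULL` draws
#'   log-normal with sdlog 0.15 around 1.
#' @param effects effect ledger: data.frame with columns `gene`, `variant`,
#'   `lineage` (`"CM"`, `"CF"` or `"all"`), `gamma1` (genotype main effect on
#'   log expression), `gamma2` (genotype x pseudotime) and `gamma3`
#'   (genotype x pseudotime^2). `NULL` gives a pure-null dataset.
#' @param dispersion shared NB dispersion (1/size); must be > 0.
#' @param depth_meanlog,depth_sdlog log-normal per-cell depth parameters.
#' @param line_effect_sd sd of gene-specific per-line log-expression offsets.
#' @param slope_sd sd of per-gene pseudotime slopes.
#' @param lineage_offset_sd sd of per-gene terminal-branch log offsets.
#' @param marker_frac fraction of genes given a cell-type-specific expression
#'   bump (makes stage/terminal types separable, as marker genes are in real
#'   data).
#' @param bump_amp amplitude of the marker bump on the log scale.
#' @param bifurcation pseudotime beyond which cells commit to a branch.
#' @param qc_fail_frac fraction of cells planted to fail a QC filter.
#' @param unk_frac fraction of cells labelled `UNK` (off-target cell type).
#' @param pt_concentration Beta concentration of the per-day pseudotime
#'   distribution.
#' @param seed integer seed.
#' @return a list of class `diff_sim_config`.
#' @export
diff_sim_config <- function(n_lines = 19,
                            days = c(0, 1, 3, 5, 7, 11, 15),
                            cells_per_sample = 50,
                            n_genes = 200,
                            lineage_pref = NULL,
                            speed = NULL,
                            effects = NULL,
                            dispersion = 0.5,
                            depth_meanlog = log(2500),
                            depth_sdlog = 0.4,
                            line_effect_sd = 0.2,
                            slope_sd = 0.8,
                            lineage_offset_sd = 0.6,
                            marker_frac = 0.3,
                            bump_amp = 1.5,
                            bifurcation = 0.35,
                            qc_fail_frac = 0.05,
                            unk_frac = 0.02,
                            pt_concentration = 8,
                            seed = 1L) {
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (!is.null(lineage_pref) &&
      (any(lineage_pref < 0) || any(lineage_pref > 1)))
    stop("lineage_pref must lie in [0, 1]")
  structure(as.list(environment()), class = "diff_sim_config")
}

.type_from_pseudotime <- function(t, branch) {
  type <- character(length(t))
  type[t < 0.15] <- "IPSC"
  type[t >= 0.15 & t < 0.30] <- "MES"
  type[t >= 0.30 & t < 0.45] <- "CMES"
  type[t >= 0.45 & t < 0.60] <- "PROG"
  term <- t >= 0.60
  type[term] <- ifelse(branch[term] == "CM", "CM", "CF")
  type
}

# midpoint pseudotime of each cell type, used for marker-gene bumps
.type_midpoints <- c(IPSC = 0.075, MES = 0.225, CMES = 0.375, PROG = 0.525,
                     CM = 0.80, CF = 0.80)

#' Simulate a bifurcating single-cell differentiation dataset
#'
#' Per cell, pseudotime is Beta-distributed with a mean that increases with
#' collection day scaled by the line's speed factor; cells past the
#' bifurcation pseudotime commit to the CM or CF branch according to the
#' line's lineage preference; cell types follow fixed pseudotime thresholds
#' (IPSC/MES/CMES/PROG, then terminal CM/CF). Log expression is
#' `a_g + b_g t + marker bump + branch offset + line effect + genetic
#' effects`, where ledger effects `(gamma1 + gamma2 t + gamma3 t^2) * G` are
#' applied to all cells (`lineage = "all"`) or only to terminal cells of the
#' stated branch. Counts are negative binomial around depth-scaled relative
#' expression.
#'
#' @param config a [diff_sim_config()].
#' @param genotypes a [genotype_panel()] whose lines cover the config's
#'   lines (the first `n_lines` panel lines are used; a panel with fewer
#'   lines is an error).
#' @return list with `cells` (a [cell_expression_set()]) and `truth` (line
#'   parameters, per-cell branch, gene parameters, the applied effect ledger,
#'   and per-(line, day) true cell-type proportions).
#' @export
simulate_differentiation_dataset <- function(config, genotypes) {
  stopifnot(is(config, "diff_sim_config"), is(genotypes, "genotype_panel"))
  if (length(genotypes$line_ids) < config$n_lines)
    stop("genotype panel has fewer lines than config$n_lines")
  set.seed(config$seed)
  lines <- genotypes$line_ids[seq_len(config$n_lines)]

  pref <- config$lineage_pref
  if (is.null(pref)) pref <- runif(config$n_lines, 0.25, 0.75)
  if (length(pref) == 1) pref <- rep(pref, config$n_lines)
  speed <- config$speed
  if (is.null(speed)) speed <- rlnorm(config$n_lines, 0, 0.15)
  if (length(speed) == 1) speed <- rep(speed, config$n_lines)

  grid <- expand.grid(day = config$days, line = seq_len(config$n_lines))
  n_cells <- nrow(grid) * config$cells_per_sample
  line_idx <- rep(grid$line, each = config$cells_per_sample)
  day <- rep(grid$day, each = config$cells_per_sample)

  # pseudotime: Beta around a day- and speed-dependent mean
  m <- pmin(pmax(speed[line_idx] * day / max(config$days), 0.02), 0.98)
  kap <- config$pt_concentration
  pt <- rbeta(n_cells, m * kap, (1 - m) * kap)

  branch <- rep("PRE", n_cells)
  committed <- pt >= config$bifurcation
  branch[committed] <- ifelse(
    runif(sum(committed)) < pref[line_idx[committed]], "CM", "CF")
  type <- .type_from_pseudotime(pt, branch)

  # gene parameters
  ng <- config$n_genes
  genes <- sprintf("gene%04d", seq_len(ng))
  a_g <- rnorm(ng, 0, 1)
  b_g <- rnorm(ng, 0, config$slope_sd)
  cm_off <- rnorm(ng, 0, config$lineage_offset_sd)
  cf_off <- rnorm(ng, 0, config$lineage_offset_sd)
  bump_type <- rep(NA_character_, ng)
  n_marker <- round(config$marker_frac * ng)
  if (n_marker > 0)
    bump_type[sample.int(ng, n_marker)] <-
      sample(names(.type_midpoints), n_marker, replace = TRUE)
  line_eff <- matrix(rnorm(config$n_lines * ng, 0, config$line_effect_sd),
                     config$n_lines, ng)

  lam <- outer(rep(1, n_cells), a_g) + outer(pt, b_g)
  is_cm <- branch == "CM"; is_cf <- branch == "CF"
  lam[is_cm, ] <- lam[is_cm, , drop = FALSE] +
    matrix(cm_off, sum(is_cm), ng, byrow = TRUE)
  lam[is_cf, ] <- lam[is_cf, , drop = FALSE] +
    matrix(cf_off, sum(is_cf), ng, byrow = TRUE)
  lam <- lam + line_eff[line_idx, , drop = FALSE]
  for (g in which(!is.na(bump_type))) {
    mid <- .type_midpoints[bump_type[g]]
    w <- exp(-((pt - mid) / 0.12)^2)
    if (bump_type[g] == "CM") w[!is_cm & pt >= 0.60] <- 0
    if (bump_type[g] == "CF") w[!is_cf & pt >= 0.60] <- 0
    lam[, g] <- lam[, g] + config$bump_amp * w
  }

  effects <- config$effects
  if (!is.null(effects) && nrow(effects) > 0) {
    bad_g <- setdiff(effects$gene, genes)
    bad_v <- setdiff(effects$variant, rownames(genotypes$dosages))
    if (length(bad_g) || length(bad_v))
      stop("effect ledger names unknown gene/variant: ",
           paste(c(bad_g, bad_v), collapse = ", "))
    for (r in seq_len(nrow(effects))) {
      e <- effects[r, ]
      G <- genotypes$dosages[e$variant, lines][line_idx]
      eff <- (e$gamma1 + e$gamma2 * pt + e$gamma3 * pt^2) * G
      keep <- switch(as.character(e$lineage),
                     all = rep(TRUE, n_cells),
                     CM = type == "CM",
                     CF = type == "CF",
                     stop("effect lineage must be CM, CF or all"))
      gi <- match(e$gene, genes)
      lam[keep, gi] <- lam[keep, gi] + eff[keep]
    }
  }

  # planted UNK cells and QC failures
  unk <- runif(n_cells) < config$unk_frac
  type[unk] <- "UNK"
  doublet <- rbeta(n_cells, 1.5, 40)
  mito <- rbeta(n_cells, 2, 40)
  assignment <- rep("singlet", n_cells)
  fail <- which(runif(n_cells) < config$qc_fail_frac)
  if (length(fail) > 0) {
    mode <- sample(1:3, length(fail), replace = TRUE)
    doublet[fail[mode == 1]] <- runif(sum(mode == 1), 0.31, 0.9)
    mito[fail[mode == 2]] <- runif(sum(mode == 2), 0.26, 0.6)
    assignment[fail[mode == 3]] <- "doublet_ambiguous"
  }

  depth <- rlnorm(n_cells, config$depth_meanlog, config$depth_sdlog)
  rel <- exp(lam)
  mu <- rel / rowSums(rel) * depth
  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = 1 / config$dispersion),
                   n_cells, ng)
  colnames(counts) <- genes
  rownames(counts) <- sprintf("cell%06d", seq_len(n_cells))

  meta <- data.frame(line = lines[line_idx], day = day, pseudotime = pt,
                     cell_type = type, doublet_prob = doublet,
                     assignment = assignment, mito_fraction = mito)
  cells <- cell_expression_set(counts, meta)

  props <- .cell_type_proportions(meta$line, meta$day, type)
  truth <- list(
    line_params = data.frame(line = lines, lineage_pref = pref, speed = speed),
    cell_branch = branch,
    gene_params = data.frame(gene = genes, a = a_g, b = b_g, cm_off = cm_off,
                             cf_off = cf_off, bump_type = bump_type),
    effects = effects,
    sample_proportions = props,
    planted_qc_fail = fail)
  list(cells = cells, truth = truth)
}

.cell_type_proportions <- function(line, day, type) {
  key <- paste(line, day, sep = "|")
  tab <- unclass(table(key, factor(type, levels = .cell_types)))
  prop <- tab / rowSums(tab)
  info <- do.call(rbind, strsplit(rownames(prop), "|", fixed = TRUE))
  data.frame(line = info[, 1], day = as.numeric(info[, 2]),
             prop, check.names = FALSE, row.names = NULL)
}

#' Synthesize bulk RNA-seq samples matched to a single-cell dataset
#'
#' Sums UMI counts over all cells of each (line, day) sample — all lineages
#' and cell types together, as a bulk library would capture them — then
#' scales each gene by its length in kilobases to mimic read (rather than
#' UMI) counting. True cell-type proportions are recorded per bulk sample.
#'
#' @param cells a [cell_expression_set()] with `line` and `day` metadata.
#' @param annotation gene annotation data.frame with `gene_id` and
#'   `length_kb` covering the dataset's genes.
#' @return list with `counts` (length-scaled sample x gene matrix),
#'   `counts_raw` (plain UMI sums), `sample_meta` and `truth_proportions`.
#' @export
synthesize_matched_bulk <- function(cells, annotation) {
  stopifnot(is(cells, "cell_expression_set"))
  if (nrow(cells$counts) == 0) stop("no cells")
  len <- annotation$length_kb[match(colnames(cells$counts),
                                    annotation$gene_id)]
  if (anyNA(len)) stop("annotation missing genes present in counts")
  key <- paste(cells$cell_meta$line, cells$cell_meta$day, sep = "|")
  raw <- rowsum(cells$counts, key)
  scaled <- sweep(raw, 2, len, "*")
  info <- do.call(rbind, strsplit(rownames(raw), "|", fixed = TRUE))
  meta <- data.frame(line = info[, 1], day = as.numeric(info[, 2]),
                     row.names = rownames(raw))
  props <- .cell_type_proportions(cells$cell_meta$line, cells$cell_meta$day,
                                  cells$cell_meta$cell_type)
  list(counts = scaled, counts_raw = raw, sample_meta = meta,
       truth_proportions = props)
}
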