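# Signature-matrix construction from annotated single cells and cell-type
# proportion estimation in bulk samples by non-negative least squares with
# sum-to-one renormalization, plus a held-out accuracy assessment.

#' Split cells into training and testing groups, stratified by cell type
#'
#' @param cells a [cell_expression_set()] with `cell_type` metadata.
#' @param train_frac training fraction (default 0.6).
#' @param seed integer seed.
#' @return logical vector, TRUE for training cells.
#' @export
split_train_test <- function(cells, train_frac = 0.6, seed = 1L) {
  set.seed(seed)
  type <- cells$cell_meta$cell_type
  train <- logical(length(type))
  for (ty in unique(type)) {
    idx <- which(type == ty)
    train[sample(idx, round(train_frac * length(idx)))] <- TRUE
  }
  train
}

#' Select cell-type marker genes
#'
#' One-vs-rest Wilcoxon rank-sum test per (gene, type) on log1p-CPM cell
#' expression; per type the `top_n` genes by BH-adjusted p (ties broken by
#' absolute log fold change) are taken, the union is intersected with the
#' bulk gene set, and duplicates removed.
#'
#' @param cells training-cell [cell_expression_set()].
#' @param top_n markers per cell type.
#' @param bulk_genes character vector of genes measured in bulk; markers
#'   outside it are dropped.
#' @param types cell types to profile (default all present except UNK).
#' @return character vector of marker gene ids.
#' @export
select_marker_genes <- function(cells, top_n = 25, bulk_genes = NULL,
                                types = NULL) {
  stopifnot(is(cells, "cell_expression_set"))
  if (top_n <= 0) stop("top_n must be positive")
  type <- cells$cell_meta$cell_type
  if (is.null(types)) types <- setdiff(unique(type), "UNK")
  if (length(types) < 2) stop("need at least 2 cell types")
  expr <- log1p(log_cpm(cells$counts, log = FALSE))
  markers <- character(0)
  for (ty in types) {
    grp <- type == ty
    if (sum(grp) < 20)
      warning("cell type ", ty, " has < 20 training cells; ",
              "markers may be unstable")
    pv <- lfc <- numeric(ncol(expr))
    for (g in seq_len(ncol(expr))) {
      pv[g] <- suppressWarnings(
        wilcox.test(expr[grp, g], expr[!grp, g])$p.value)
      lfc[g] <- mean(expr[grp, g]) - mean(expr[!grp, g])
    }
    pv[is.na(pv)] <- 1
    adj <- p.adjust(pv, "BH")
    ord <- order(adj, -abs(lfc))
    markers <- c(markers, colnames(expr)[ord[seq_len(min(top_n,
                                                         ncol(expr)))]])
  }
  markers <- unique(markers)
  if (!is.null(bulk_genes)) markers <- intersect(markers, bulk_genes)
  markers
}

#' Build a cell-type signature matrix
#'
#' Sums counts within each cell type over the training cells, computes
#' TMM-with-singleton-pairing factors, converts to CPM on the full gene
#' set, and restricts rows to the marker genes.
#'
#' @param cells training-cell [cell_expression_set()].
#' @param markers marker gene ids (non-empty).
#' @param types cell types to include (default all present except UNK).
#' @return list of class `signature_matrix`: `S` (markers x types CPM),
#'   `markers`, `types`.
#' @export
build_signature_matrix <- function(cells, markers, types = NULL) {
  stopifnot(is(cells, "cell_expression_set"))
  if (length(markers) == 0) stop("markers must be non-empty")
  type <- cells$cell_meta$cell_type
  if (is.null(types)) types <- setdiff(unique(type), "UNK")
  keep <- type %in% types
  agg <- rowsum(cells$counts[keep, , drop = FALSE], type[keep])
  if (any(rowSums(agg) == 0)) stop("cell type with zero total counts")
  f <- compute_tmm_factors(agg)
  cpm <- log_cpm(agg, f, log = FALSE)    # plain CPM on effective libraries
  miss <- setdiff(markers, colnames(cpm))
  if (length(miss) > 0) stop("markers absent from counts: ",
                             paste(head(miss, 3), collapse = ", "))
  S <- t(cpm[, markers, drop = FALSE])
  structure(list(S = S, markers = markers, types = rownames(agg)),
            class = "signature_matrix")
}

#' Estimate cell-type proportions by non-negative least squares
#'
#' Per bulk sample, solves `min || S f - m ||^2` subject to `f >= 0` and
#' renormalizes `f` to sum to one. The solution is invariant to positive
#' rescaling of the mixture, so any CPM-like scale works as long as the
#' signature and mixtures are on the same kind of scale.
#'
#' @param signature a `signature_matrix` from [build_signature_matrix()].
#' @param bulk sample x gene mixture matrix on a CPM-like scale; subset to
#'   the signature's markers internally (all must be present).
#' @return a samples x types proportion matrix (rows sum to 1).
#' @export
estimate_proportions <- function(signature, bulk) {
  stopifnot(is(signature, "signature_matrix"))
  bulk <- as.matrix(bulk)
  miss <- setdiff(signature$markers, colnames(bulk))
  if (length(miss) > 0)
    stop("bulk is missing signature genes: ",
         paste(head(miss, 3), collapse = ", "))
  M <- bulk[, signature$markers, drop = FALSE]
  out <- matrix(0, nrow(M), length(signature$types),
                dimnames = list(rownames(M), signature$types))
  for (s in seq_len(nrow(M))) {
    m <- as.numeric(M[s, ])
    if (all(m == 0)) stop("all-zero mixture in sample ", s)
    f <- tryCatch(pracma::lsqnonneg(signature$S, m)$x,
                  error = function(e) .nnls_lh(signature$S, m))
    if (sum(f) == 0) f <- rep(1 / length(f), length(f))
    out[s, ] <- f / sum(f)
  }
  out
}

# Lawson-Hanson active-set NNLS, used when pracma's implementation hits its
# fixed iteration cap on nearly-collinear signatures.
.nnls_lh <- function(A, b, tol = 1e-10 * norm(A, "F"), maxit = 50 * ncol(A)) {
  n <- ncol(A)
  passive <- logical(n)
  x <- numeric(n)
  w <- crossprod(A, b - A %*% x)
  it <- 0
  while (any(!passive) && any(w[!passive] > tol) && it < maxit) {
    it <- it + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      if (!any(passive)) { x <- numeric(n); break }
    }
    w <- crossprod(A, b - A %*% x)
  }
  pmax(x, 0)
}

#' Compare inferred and true cell-type proportions
#'
#' @param inferred,truth aligned samples x types proportion matrices
#'   (columns matched by name).
#' @return list: `per_type` (data.frame of Pearson r and RMSE per type; r is
#'   `NA` for constant truth columns) and `mae` (overall mean absolute
#'   error).
#' @export
evaluate_deconvolution <- function(inferred, truth) {
  types <- intersect(colnames(inferred), colnames(truth))
  if (length(types) == 0) stop("no shared cell types")
  inferred <- inferred[, types, drop = FALSE]
  truth <- as.matrix(truth[, types, drop = FALSE])
  per_type <- do.call(rbind, lapply(types, function(ty) {
    r <- if (sd(truth[, ty]) == 0) NA_real_ else
      cor(inferred[, ty], truth[, ty])
    data.frame(type = ty, r = r,
               rmse = sqrt(mean((inferred[, ty] - truth[, ty])^2)))
  }))
  list(per_type = per_type, mae = mean(abs(inferred - truth)))
}

#' Held-out deconvolution assessment on pseudobulk
#'
#' Splits cells 60/40 by type, builds markers and a signature from the
#' training split, aggregates per-(line, day) pseudobulk mixtures from the
#' testing split with the same TMM/CPM normalization, estimates proportions
#' and scores them against the testing cells' true composition.
#'
#' @param cells a [cell_expression_set()].
#' @param top_n markers per type.
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @return list: `eval` (from [evaluate_deconvolution()]), `inferred`,
#'   `truth`, `signature`.
#' @export
assess_deconvolution <- function(cells, top_n = 25, train_frac = 0.6,
                                 seed = 1L) {
  train <- split_train_test(cells, train_frac, seed)
  tr <- subset_cells(cells, train)
  te <- subset_cells(cells, !train)
  keep <- te$cell_meta$cell_type != "UNK"
  te <- subset_cells(te, keep)
  markers <- select_marker_genes(tr, top_n = top_n,
                                 bulk_genes = colnames(cells$counts))
  sig <- build_signature_matrix(tr, markers)
  key <- paste(te$cell_meta$line, te$cell_meta$day, sep = "|")
  mix <- rowsum(te$counts, key)
  f <- compute_tmm_factors(mix)
  mix_cpm <- log_cpm(mix, f, log = FALSE)
  inferred <- estimate_proportions(sig, mix_cpm)
  tab <- unclass(table(key, factor(te$cell_meta$cell_type,
                                   levels = sig$types)))
  truth <- (tab / rowSums(tab))[rownames(inferred), , drop = FALSE]
  list(eval = evaluate_deconvolution(inferred, truth), inferred = inferred,
       truth = truth, signature = sig)
}
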