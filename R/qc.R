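# Cell- and gene-level filters, applied in a fixed order: gene filter first,
# then cell metadata filters, then median/SD outlier removal. "Maximum"/
# "minimum" thresholds are inclusive; the outlier rule ("more than k SD") is
# strict.

.new_qc_report <- function(n_cells, n_genes) {
  structure(list(steps = data.frame(step = character(), dimension = character(),
                                    input = integer(), removed = integer(),
                                    retained = integer(),
                                    threshold = character()),
                 input_cells = n_cells, input_genes = n_genes),
            class = "qc_report")
}

.add_step <- function(report, step, dimension, input, removed, threshold) {
  report$steps <- rbind(report$steps,
                        data.frame(step = step, dimension = dimension,
                                   input = input, removed = removed,
                                   retained = input - removed,
                                   threshold = threshold))
  report
}

#' @export
print.qc_report <- function(x, ...) {
  cat("qc_report:", x$input_cells, "cells,", x$input_genes,
      "genes at input\n")
  print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Remove genes detected in too few cells
#'
#' @param cells a [cell_expression_set()].
#' @param min_cells a gene is kept iff it has a nonzero count in at least
#'   this many cells (default 10).
#' @param report optional `qc_report` to append to.
#' @return filtered `cell_expression_set`, with the updated report in
#'   `attr(, "qc_report")`. Per-cell `n_genes_detected` is recomputed on the
#'   retained genes.
#' @export
filter_genes_min_cells <- function(cells, min_cells = 10, report = NULL) {
  stopifnot(is(cells, "cell_expression_set"))
  if (nrow(cells$counts) == 0 || ncol(cells$counts) == 0)
    stop("empty count matrix")
  detected <- colSums(cells$counts > 0)
  keep <- detected >= min_cells
  if (is.null(report))
    report <- .new_qc_report(nrow(cells$counts), ncol(cells$counts))
  report <- .add_step(report, "gene_min_cells", "genes", length(keep),
                      sum(!keep), paste0("detected in >= ", min_cells,
                                         " cells"))
  out <- subset_cells(cells, genes = keep)
  attr(out, "qc_report") <- report
  out
}

#' Apply cell-level metadata filters
#'
#' A cell is retained iff `doublet_prob <= max_doublet`, its demultiplexing
#' `assignment` is not ambiguous, `mito_fraction <= max_mito`, and
#' `n_genes_detected >= min_genes` (computed on the genes that survived the
#' gene filter). All bounds inclusive.
#'
#' @param cells a [cell_expression_set()] (typically the output of
#'   [filter_genes_min_cells()]).
#' @param max_doublet,max_mito,min_genes thresholds.
#' @param ambiguous_label `assignment` value marking ambiguous cells.
#' @param report optional `qc_report` to append to (defaults to the one
#'   attached to `cells`).
#' @return filtered `cell_expression_set` with updated attached report.
#' @export
apply_cell_filters <- function(cells, max_doublet = 0.3, max_mito = 0.25,
                               min_genes = 300,
                               ambiguous_label = "doublet_ambiguous",
                               report = NULL) {
  stopifnot(is(cells, "cell_expression_set"))
  meta <- cells$cell_meta
  for (f in c("doublet_prob", "assignment", "mito_fraction",
              "n_genes_detected"))
    if (is.null(meta[[f]])) stop("missing metadata field: ", f)
  if (is.null(report)) report <- attr(cells, "qc_report")
  if (is.null(report))
    report <- .new_qc_report(nrow(cells$counts), ncol(cells$counts))
  n0 <- nrow(cells$counts)
  keep <- meta$doublet_prob <= max_doublet &
    meta$assignment != ambiguous_label &
    meta$mito_fraction <= max_mito &
    meta$n_genes_detected >= min_genes
  report <- .add_step(report, "cell_filters", "cells", n0, sum(!keep),
                      sprintf("doublet<=%g, unambiguous, mito<=%g, genes>=%d",
                              max_doublet, max_mito, min_genes))
  out <- subset_cells(cells, cells = keep)
  attr(out, "qc_report") <- report
  out
}

#' Remove cells with outlying feature or read counts
#'
#' A cell is removed when its detected-gene count or its total read (UMI)
#' count lies strictly more than `k_sd` standard deviations from the
#' respective median. The SD is the ordinary standard deviation; setting
#' `robust = TRUE` uses the MAD instead.
#'
#' @param cells a [cell_expression_set()] with at least 3 cells.
#' @param k_sd number of SDs (default 4).
#' @param robust use MAD in place of the SD.
#' @param report optional `qc_report` to append to.
#' @return filtered `cell_expression_set` with updated attached report.
#' @export
remove_outlier_cells <- function(cells, k_sd = 4, robust = FALSE,
                                 report = NULL) {
  stopifnot(is(cells, "cell_expression_set"))
  if (nrow(cells$counts) < 3) stop("need at least 3 cells")
  if (is.null(report)) report <- attr(cells, "qc_report")
  if (is.null(report))
    report <- .new_qc_report(nrow(cells$counts), ncol(cells$counts))
  spread <- if (robust) function(x) stats::mad(x) else sd
  ok <- function(x) {
    s <- spread(x)
    if (s == 0) return(rep(TRUE, length(x)))
    abs(x - median(x)) <= k_sd * s
  }
  keep <- ok(cells$cell_meta$n_genes_detected) & ok(cells$cell_meta$n_umi)
  report <- .add_step(report, "outlier_cells", "cells", nrow(cells$counts),
                      sum(!keep), sprintf("|x - median| <= %g SD", k_sd))
  out <- subset_cells(cells, cells = keep)
  attr(out, "qc_report") <- report
  out
}

#' Run the full QC pass
#'
#' Gene filter, then cell filters, then outlier removal, threading one
#' report through all steps.
#'
#' @inheritParams filter_genes_min_cells
#' @inheritParams apply_cell_filters
#' @inheritParams remove_outlier_cells
#' @return filtered `cell_expression_set`; `attr(, "qc_report")` holds the
#'   ordered per-step removal counts.
#' @export
run_qc <- function(cells, min_cells = 10, max_doublet = 0.3, max_mito = 0.25,
                   min_genes = 300, k_sd = 4, robust = FALSE) {
  out <- filter_genes_min_cells(cells, min_cells)
  out <- apply_cell_filters(out, max_doublet, max_mito, min_genes)
  remove_outlier_cells(out, k_sd, robust)
}
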