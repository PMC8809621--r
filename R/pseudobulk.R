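# Lineage assignment, pseudotime quantile binning and the three pseudobulk
# aggregation schemes.

#' Assign cells to differentiation lineages
#'
#' Precursor cell types (IPSC, MES, CMES, PROG) are assigned jointly to both
#' the cardiomyocyte and cardiac-fibroblast lineages; terminal CM and CF
#' cells belong only to their own lineage; UNK cells are excluded from both.
#'
#' @param cells a [cell_expression_set()] with a `cell_type` metadata column.
#' @return logical matrix cells x 2 with columns `CM` and `CF`.
#' @export
assign_lineages <- function(cells) {
  stopifnot(is(cells, "cell_expression_set"))
  type <- cells$cell_meta$cell_type
  bad <- setdiff(unique(type), .cell_types)
  if (length(bad) > 0)
    stop("unknown cell type label(s): ", paste(bad, collapse = ", "))
  precursor <- type %in% c("IPSC", "MES", "CMES", "PROG")
  cbind(CM = precursor | type == "CM",
        CF = precursor | type == "CF")
}

#' Quantile-bin pseudotime values
#'
#' Cells are ranked by pseudotime with a stable tie-break on input order,
#' and ranks are split into `n_bins` near-equal groups (sizes differ by at
#' most one). Bin indices run 0..n_bins-1 ordered by pseudotime.
#'
#' @param pseudotimes finite numeric vector, pooled across the lineage's
#'   cell lines.
#' @param n_bins number of quantile bins (default 16).
#' @return integer bin index per cell.
#' @export
bin_pseudotime <- function(pseudotimes, n_bins = 16) {
  if (any(!is.finite(pseudotimes))) stop("pseudotimes must be finite")
  if (n_bins < 2) stop("n_bins must be >= 2")
  n <- length(pseudotimes)
  if (n < n_bins) stop("fewer cells (", n, ") than bins (", n_bins, ")")
  if (length(unique(pseudotimes)) == 1) {
    warning("all pseudotimes identical; every cell placed in bin 0")
    return(rep(0L, n))
  }
  ord <- order(pseudotimes, seq_len(n))  # stable
  bin <- integer(n)
  bin[ord] <- as.integer(floor((seq_len(n) - 1) * n_bins / n))
  bin
}

#' Aggregate cells into pseudobulk samples
#'
#' Three schemes: `day` sums all (non-UNK) cells per (line, day);
#' `lineage_day` does the same within each lineage (precursor cells counted
#' in both); `lineage_pseudotime` subsets to a lineage, partitions its cells
#' into `n_bins` pseudotime quantile bins pooled across lines, and sums per
#' (line, bin). The time covariate `t` is the day for day-based schemes and
#' the lower median member-cell pseudotime for the pseudotime scheme.
#'
#' @param cells a [cell_expression_set()].
#' @param scheme one of `"day"`, `"lineage_day"`, `"lineage_pseudotime"`.
#' @param n_bins pseudotime quantile bins (pseudotime scheme only).
#' @return a [pseudobulk_set()]; empty (line, unit) groups are simply absent.
#' @export
aggregate_pseudobulk <- function(cells,
                                 scheme = c("day", "lineage_day",
                                            "lineage_pseudotime"),
                                 n_bins = 16) {
  scheme <- match.arg(scheme)
  stopifnot(is(cells, "cell_expression_set"))
  meta <- cells$cell_meta
  if (scheme == "day") {
    keep <- meta$cell_type != "UNK"
    return(.aggregate_groups(cells, keep, lineage = "combined",
                             unit = meta$day[keep],
                             t = meta$day[keep]))
  }
  member <- assign_lineages(cells)
  parts <- lapply(c("CM", "CF"), function(lin) {
    keep <- member[, lin]
    if (!any(keep)) return(NULL)
    if (scheme == "lineage_day") {
      .aggregate_groups(cells, keep, lineage = lin, unit = meta$day[keep],
                        t = meta$day[keep])
    } else {
      bin <- bin_pseudotime(meta$pseudotime[keep], n_bins)
      .aggregate_groups(cells, keep, lineage = lin, unit = bin,
                        t = meta$pseudotime[keep])
    }
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  pseudobulk_set(do.call(rbind, lapply(parts, `[[`, "counts")),
                 do.call(rbind, lapply(parts, `[[`, "sample_meta")))
}

# lower median: deterministic for even group sizes
.lower_median <- function(x) sort(x)[ceiling(length(x) / 2)]

.aggregate_groups <- function(cells, keep, lineage, unit, t) {
  counts <- cells$counts[keep, , drop = FALSE]
  line <- cells$cell_meta$line[keep]
  key <- paste(line, unit, sep = "|")
  agg <- rowsum(counts, key)
  first <- !duplicated(key)
  km <- data.frame(key = key[first], line = line[first], unit = unit[first])
  km <- km[match(rownames(agg), km$key), ]
  tmed <- vapply(split(t, key), .lower_median, numeric(1))[rownames(agg)]
  ncell <- as.integer(table(key)[rownames(agg)])
  meta <- data.frame(line = km$line, lineage = lineage, unit = km$unit,
                     t = if (identical(unit, t)) km$unit else unname(tmed),
                     n_cells = ncell)
  rownames(agg) <- paste(lineage, rownames(agg), sep = "|")
  pseudobulk_set(agg, meta)
}

#' Filter low-depth pseudobulk samples
#'
#' Removes samples whose library size is strictly less than `min_lib`.
#'
#' @param pb a [pseudobulk_set()].
#' @param min_lib library-size threshold (default 10000).
#' @return filtered `pseudobulk_set`; `attr(, "removed")` lists the removed
#'   samples' (line, lineage, unit).
#' @export
filter_low_depth <- function(pb, min_lib = 10000) {
  stopifnot(is(pb, "pseudobulk_set"))
  keep <- pb$sample_meta$lib_size >= min_lib
  if (!any(keep)) stop("all pseudobulk samples fall below min_lib")
  removed <- pb$sample_meta[!keep, c("line", "lineage", "unit", "lib_size")]
  out <- pseudobulk_set(pb$counts[keep, , drop = FALSE],
                        pb$sample_meta[keep, , drop = FALSE])
  attr(out, "removed") <- removed
  out
}
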