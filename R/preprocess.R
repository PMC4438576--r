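#' Collapse probesets to one row per gene
#'
#' For each gene the single probeset with the highest mean log2 intensity
#' across all samples ("mean best-expressed") is retained and relabeled with
#' the gene symbol.  Ties on the mean are broken by the lexicographically
#' smallest probeset id, so the collapse is deterministic.  Probesets absent
#' from the map are dropped; the count is reported via the
#' `"n_dropped_unmapped"` attribute and a message.
#'
#' @param mat probeset-level expression matrix.
#' @param map named character vector, probeset id -> gene symbol.
#' @return gene-level expression matrix, rows sorted by gene symbol, with
#'   attributes `n_dropped_unmapped` and `chosen_probeset` (named by gene).
#' @export
collapse_probesets <- function(mat, map) {
  abort_if(expr_level(mat) != "probeset",
           "collapse_probesets expects a probeset-level matrix")
  mapped <- intersect(rownames(mat), names(map))
  abort_if(length(mapped) == 0L,
           "no probesets in the matrix are present in the map")
  n_dropped <- nrow(mat) - length(mapped)
  genes <- unname(map[mapped])
  means <- rowMeans(mat[mapped, , drop = FALSE])
  # within each gene: highest mean first, then probeset id ascending
  o <- order(genes, -means, mapped, method = "radix")
  keep <- !duplicated(genes[o])
  sel <- mapped[o][keep]
  out <- mat[sel, , drop = FALSE]
  rownames(out) <- genes[o][keep]
  out <- expression_matrix(out, level = "gene")
  attr(out, "n_dropped_unmapped") <- n_dropped
  attr(out, "chosen_probeset") <- stats::setNames(sel, rownames(out))
  if (n_dropped > 0L)
    message(sprintf("collapse_probesets: dropped %d unmapped probesets",
                    n_dropped))
  out
}

#' Filter genes on expression floor and variance
#'
#' Keeps genes whose maximum log2 intensity over samples reaches
#' `min_max_expr` (a gene expressed in even one sample survives) and whose
#' variance across samples reaches `min_variance`.  Row order is preserved.
#' Defaults: `min_max_expr = log2(64) = 6`, a conventional "expressed" floor
#' for this array family, and `min_variance = 0.01`.
#'
#' @param mat gene-level expression matrix.
#' @param min_max_expr log2 expression floor on the per-gene maximum.
#' @param min_variance floor on the per-gene variance across samples.
#' @return the filtered matrix, with attribute `n_removed`.
#' @export
filter_genes <- function(mat, min_max_expr = 6, min_variance = 0.01) {
  mx <- apply(mat, 1L, max)
  v <- row_vars(mat)
  keep <- mx >= min_max_expr & v >= min_variance
  abort_if(!any(keep), sprintf(
    "all %d genes removed; lower min_max_expr (%.3g) or min_variance (%.3g)",
    nrow(mat), min_max_expr, min_variance))
  out <- mat[keep, , drop = FALSE]
  out <- expression_matrix(out, level = expr_level(mat))
  attr(out, "n_removed") <- sum(!keep)
  out
}
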