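#' Percentile scores of target samples within the reference distribution
#'
#' For each gene and each target sample, the percentile (0-100) of that
#' sample's expression within the pooled reference distribution, with
#' midrank tie handling: `100 * (L + 0.5 * T) / N_ref` where `L` references
#' lie strictly below and `T` tie the value.
#'
#' @param mat expression matrix.
#' @param target_ids target-cohort sample ids.
#' @param ref_ids reference sample ids, non-empty and disjoint from the
#'   target; by default every non-target sample in the matrix.
#' @return genes x target-samples matrix of percentiles.
#' @export
percentile_scores <- function(mat, target_ids,
                              ref_ids = setdiff(colnames(mat), target_ids)) {
  abort_if(length(ref_ids) == 0L, "empty reference set")
  abort_if(length(intersect(target_ids, ref_ids)) > 0L,
           "target and reference samples overlap")
  R <- mat[, ref_ids, drop = FALSE]
  X <- mat[, target_ids, drop = FALSE]
  n_ref <- length(ref_ids)
  P <- matrix(NA_real_, nrow(mat), length(target_ids),
              dimnames = list(rownames(mat), target_ids))
  for (i in seq_len(nrow(mat))) {
    r <- R[i, ]
    x <- X[i, ]
    P[i, ] <- 100 * (colSums(outer(r, x, `<`)) +
                       0.5 * colSums(outer(r, x, `==`))) / n_ref
  }
  P
}

#' Consistency of high expression across the target cohort
#'
#' Counts, per gene, the target samples whose percentile strictly exceeds
#' `threshold`; a gene passes the consistency filter when every target
#' sample does.
#'
#' @param scores a [percentile_scores()] matrix.
#' @param threshold percentile threshold (strict `>`), default 66.
#' @return data frame with columns `gene`, `n_above`, `min_percentile`,
#'   `pass`.
#' @export
consistency_filter <- function(scores, threshold = 66) {
  n_above <- rowSums(scores > threshold)
  data.frame(gene = rownames(scores), n_above = as.integer(n_above),
             min_percentile = apply(scores, 1L, min),
             pass = n_above == ncol(scores), row.names = NULL)
}

#' Rank candidate target genes
#'
#' Ordering key: `n_above` descending, then `avg_percentile` descending,
#' then linear `fold` descending (when present), then gene symbol ascending.
#'
#' @param df data frame with columns `gene`, `n_above`, `avg_percentile`,
#'   and optionally `fold`.
#' @return the data frame reordered, with a `rank` column prepended.
#' @export
rank_targets <- function(df) {
  fold_key <- if ("fold" %in% names(df)) -df$fold else rep(0, nrow(df))
  o <- order(-df$n_above, -df$avg_percentile, fold_key, df$gene,
             method = "radix")
  out <- df[o, , drop = FALSE]
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}

#' Restrict a ranked report to genes with known therapeutic agents
#'
#' Genes absent from the drug-target map are dropped; agents are copied
#' verbatim (comma-joined) for the rest.
#'
#' @param ranked a [rank_targets()] result.
#' @param map named list of agent vectors, see [read_drug_map()].
#' @return the report restricted to mapped genes, with an `agents` column
#'   and re-numbered ranks.
#' @export
annotate_drugs <- function(ranked, map) {
  if (length(map) == 0L) {
    warning("empty drug-target map; drug-target report is empty")
    out <- ranked[0L, , drop = FALSE]
    out$agents <- character(0)
    return(out)
  }
  out <- ranked[ranked$gene %in% names(map), , drop = FALSE]
  out$agents <- vapply(map[out$gene], paste, "", collapse = ", ")
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Drug-target prioritization report
#'
#' The full percentile-based screen: percentile scores of every target
#' sample against the pooled reference, the strict consistency count at
#' `threshold`, average percentile over all target samples, the linear fold
#' of the target cohort versus the pooled rest, and a single moderated-t
#' comparison of target versus pooled rest for the reported p/FDR.  Genes
#' with `n_above` at least `n_above_floor` (default: cohort size minus 2,
#' so near-misses stay visible) are ranked and intersected with the
#' drug-target map.
#'
#' @param mat gene-level expression matrix.
#' @param sheet validated sample sheet.
#' @param drug_map named list of agent vectors, or `NULL` to skip drug
#'   annotation.
#' @param threshold percentile consistency threshold (strict `>`).
#' @param n_above_floor smallest `n_above` retained in the ranked report.
#' @return list of class `"target_report"` with elements `report` (ranked,
#'   drug-annotated), `all_genes` (per-gene statistics for every gene) and
#'   `percentiles` (the score matrix).
#' @export
target_report <- function(mat, sheet, drug_map = NULL, threshold = 66,
                          n_above_floor = NULL) {
  sheet <- validate_sample_sheet(sheet, mat)
  tgt <- target_group(sheet)
  tgt_ids <- sheet$sample_id[sheet$group == tgt]
  ref_ids <- sheet$sample_id[sheet$group != tgt]
  n_above_floor <- n_above_floor %||% max(length(tgt_ids) - 2L, 1L)

  P <- percentile_scores(mat, tgt_ids, ref_ids)
  cons <- consistency_filter(P, threshold)
  st <- gene_stats(mat, tgt_ids, ref_ids)
  # degenerate data (e.g. a noise-free cohort) has no estimable prior; the
  # percentile ranking still stands, with NA p/FDR columns
  prior <- tryCatch(estimate_prior(st$s2, st$df[1L]), error = function(e) NULL)
  mt <- if (is.null(prior)) {
    data.frame(p = rep(NA_real_, nrow(st)))
  } else {
    moderated_t(st$delta, st$s2, st$df[1L], prior,
                length(tgt_ids), length(ref_ids))
  }
  mt$p[!is.na(mt$p) & mt$p == 0] <- NA_real_   # degenerate rows
  fdr <- rep(NA_real_, nrow(st))
  ok <- !is.na(mt$p)
  if (any(ok)) fdr[ok] <- global_fdr(mt$p[ok])
  all_genes <- data.frame(
    gene = cons$gene,
    avg_percentile = rowMeans(P),
    n_above = cons$n_above,
    min_percentile = cons$min_percentile,
    fold = unname(fold_vs_rest(mat, tgt_ids)),
    p = mt$p,
    fdr = fdr,
    row.names = NULL)
  ranked <- rank_targets(all_genes[all_genes$n_above >= n_above_floor, ,
                                   drop = FALSE])
  report <- if (is.null(drug_map)) ranked else annotate_drugs(ranked, drug_map)
  structure(list(report = report, all_genes = all_genes, percentiles = P,
                 threshold = threshold, n_above_floor = n_above_floor,
                 target = tgt),
            class = "target_report")
}

#' @export
print.target_report <- function(x, ...) {
  cat(sprintf("Drug-target report for group '%s': %d candidate genes (n_above >= %d)\n",
              x$target, nrow(x$report), x$n_above_floor))
  print(utils::head(x$report, 20L))
  invisible(x)
}
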