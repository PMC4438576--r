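#' Per-gene two-group summary statistics
#'
#' Mean log2 difference, pooled equal-variance residual variance, and
#' residual degrees of freedom for one pairwise comparison.
#'
#' @param mat expression matrix.
#' @param samples_a,samples_b disjoint character vectors of sample ids, each
#'   with at least two members.  `delta` is `mean(A) - mean(B)`.
#' @return data frame with columns `gene`, `delta`, `s2`, `df` and
#'   attributes `n_a`, `n_b`.
#' @export
gene_stats <- function(mat, samples_a, samples_b) {
  abort_if(length(intersect(samples_a, samples_b)) > 0L,
           "sample groups overlap")
  abort_if(length(samples_a) < 2L || length(samples_b) < 2L,
           "each group needs at least 2 samples")
  missing <- setdiff(c(samples_a, samples_b), colnames(mat))
  abort_if(length(missing) > 0L, "samples absent from matrix: ",
           paste(missing, collapse = ", "))
  a <- mat[, samples_a, drop = FALSE]
  b <- mat[, samples_b, drop = FALSE]
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  df <- length(samples_a) + length(samples_b) - 2L
  s2 <- (rowSums((a - ma)^2) + rowSums((b - mb)^2)) / df
  out <- data.frame(gene = rownames(mat), delta = ma - mb, s2 = s2,
                    df = df, row.names = NULL)
  attr(out, "n_a") <- length(samples_a)
  attr(out, "n_b") <- length(samples_b)
  out
}

# Inverse of the trigamma function by Newton iteration on a monotone scale.
trigamma_inverse <- function(y) {
  abort_if(y <= 0, "trigamma_inverse needs a positive argument")
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif) / x < 1e-12) break
  }
  x
}

#' Estimate the variance prior of the moderated t-statistic
#'
#' Moment matching on `z = log(s2)`: under the scaled-F sampling model the
#' excess spread of `z` beyond `trigamma(df/2)` identifies the prior degrees
#' of freedom `d0` through the trigamma function, and the bias-corrected
#' mean identifies the prior scale `s0_sq`.  A non-positive excess yields an
#' infinite-`d0` prior (all genes share one variance scale).
#'
#' Zero sample variances cannot enter on the log scale; they are replaced by
#' the smallest positive observed variance for the `z` computation only, and
#' the count is recorded in the `n_zero_s2` attribute.
#'
#' @param s2 per-gene residual variances.
#' @param df residual degrees of freedom (scalar).
#' @param min_genes minimum number of positive variances required.
#' @return list with elements `d0` (possibly `Inf`) and `s0_sq`, class
#'   `"variance_prior"`.
#' @export
estimate_prior <- function(s2, df, min_genes = 50L) {
  abort_if(all(s2 <= 0), "all sample variances are zero; degenerate data")
  n_zero <- sum(s2 <= 0)
  abort_if(sum(s2 > 0) < min_genes, sprintf(
    "prior estimation needs >= %d genes with positive variance", min_genes))
  if (n_zero > 0L) {
    message(sprintf("estimate_prior: %d zero variances floored for log scale",
                    n_zero))
    s2[s2 <= 0] <- min(s2[s2 > 0])
  }
  z <- log(s2)
  excess <- stats::var(z) - trigamma(df / 2)
  bias <- digamma(df / 2) - log(df / 2)
  if (excess <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(z) - bias)
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s0_sq <- exp(mean(z) - bias + digamma(d0 / 2) - log(d0 / 2))
  }
  structure(list(d0 = d0, s0_sq = s0_sq, n_zero_s2 = n_zero),
            class = "variance_prior")
}

#' Moderated t-statistic with a scaled-inverse-chi-square variance prior
#'
#' Shrinks each per-gene variance toward the prior scale,
#' `s2_post = (d0 * s0_sq + df * s2) / (d0 + df)` (the limit `s0_sq` when
#' `d0` is infinite), and refers `delta / sqrt(s2_post * (1/n_a + 1/n_b))`
#' to a Student-t distribution on `df + d0` degrees of freedom.
#'
#' Degenerate rows: a zero posterior variance with a non-zero `delta` gives
#' `p = 0` (flagged in the `degenerate` column); with `delta = 0` it gives
#' `t = 0`, `p = 1`.
#'
#' @param delta per-gene mean log2 differences.
#' @param s2 per-gene residual variances.
#' @param df residual degrees of freedom (scalar).
#' @param prior a [estimate_prior()] result, or any list with `d0`, `s0_sq`.
#' @param n_a,n_b group sizes.
#' @return data frame with columns `t_mod`, `df_total`, `p`, `degenerate`.
#' @export
moderated_t <- function(delta, s2, df, prior, n_a, n_b) {
  # d0 = 0 is admitted as the no-moderation limit (classical pooled t)
  abort_if(prior$d0 < 0 || prior$s0_sq < 0, "invalid variance prior")
  d0 <- prior$d0
  s2_post <- if (is.infinite(d0)) rep(prior$s0_sq, length(s2))
             else (d0 * prior$s0_sq + df * s2) / (d0 + df)
  se <- sqrt(s2_post * (1 / n_a + 1 / n_b))
  t_mod <- ifelse(se > 0, delta / se,
                  ifelse(delta == 0, 0, sign(delta) * Inf))
  df_total <- df + d0
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  degenerate <- se == 0 & delta != 0
  # extreme statistics underflow the t tail; keep p strictly positive so the
  # value stays inside the (0, 1] family BH expects (degenerate rows keep 0)
  p <- pmax(p, .Machine$double.xmin)
  p[degenerate] <- 0
  data.frame(t_mod = t_mod, df_total = df_total, p = p,
             degenerate = degenerate)
}

#' Pooled Benjamini-Hochberg false discovery rates
#'
#' BH step-up over a single family, with the usual monotonicity enforcement
#' and cap at 1.  The family pooled here is all genes across all pairwise
#' comparisons, which is how multiple testing is accounted for both within
#' and across groups.
#'
#' @param p p-values in (0, 1].
#' @return adjusted q-values in the input order.
#' @export
global_fdr <- function(p) {
  abort_if(any(!is.finite(p) | p <= 0 | p > 1),
           "p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' All pairwise moderated-t comparisons of the target group
#'
#' Runs one equal-variance two-group moderated-t comparison of the target
#' cohort against every other group, estimating a variance prior per
#' comparison, then adjusts all p-values in one pooled BH family (or within
#' each comparison when `fdr_scope = "per_comparison"`).
#'
#' @param mat gene-level expression matrix.
#' @param sheet validated sample sheet; the flagged group is the target.
#' @param fdr_scope `"global"` (one pooled family, the default) or
#'   `"per_comparison"`.
#' @return a comparison table: data frame with one row per (gene, reference
#'   group) holding `delta` (target minus group mean log2 difference),
#'   `fold = 2^delta`, `t_mod`, `df_total`, `p` and `fdr`; the per-group
#'   priors are in the `"priors"` attribute, the target group name in
#'   `"target"`.
#' @export
diffexp_table <- function(mat, sheet, fdr_scope = c("global", "per_comparison")) {
  fdr_scope <- match.arg(fdr_scope)
  sheet <- validate_sample_sheet(sheet, mat)
  tgt <- target_group(sheet)
  tgt_ids <- sheet$sample_id[sheet$group == tgt]
  refs <- setdiff(unique(sheet$group), tgt)
  abort_if(length(refs) == 0L, "no reference groups in sheet")
  small <- refs[vapply(refs, function(g) sum(sheet$group == g), 0L) < 2L]
  abort_if(length(small) > 0L, "groups with fewer than 2 samples: ",
           paste(small, collapse = ", "))
  priors <- list()
  pieces <- lapply(refs, function(g) {
    ids <- sheet$sample_id[sheet$group == g]
    st <- gene_stats(mat, tgt_ids, ids)
    prior <- estimate_prior(st$s2, st$df[1L])
    priors[[g]] <<- prior
    mt <- moderated_t(st$delta, st$s2, st$df[1L], prior,
                      length(tgt_ids), length(ids))
    data.frame(gene = st$gene, group = g, delta = st$delta,
               fold = 2^st$delta, t_mod = mt$t_mod, df_total = mt$df_total,
               p = mt$p, row.names = NULL)
  })
  tab <- do.call(rbind, pieces)
  tab$fdr <- if (fdr_scope == "global") global_fdr(tab$p)
             else stats::ave(tab$p, tab$group, FUN = global_fdr)
  attr(tab, "priors") <- priors
  attr(tab, "target") <- tgt
  attr(tab, "fdr_scope") <- fdr_scope
  class(tab) <- c("comparison_table", "data.frame")
  tab
}

#' Consensus differential-expression signature
#'
#' A gene enters the signature only if, in every pairwise comparison of the
#' target group against a reference group, it is significant
#' (`fdr <= fdr_max`), its linear fold difference reaches `fold_min` in
#' magnitude (`fold >= fold_min` or `fold <= 1/fold_min`), and the direction
#' of change is identical across all comparisons.  With
#' `direction = "up_only"` only consistently upregulated genes qualify.
#'
#' @param table a [diffexp_table()] result (one row per gene per group).
#' @param fdr_max FDR threshold applied in every comparison.
#' @param fold_min linear fold threshold, symmetric for downregulation.
#' @param direction `"both"` or `"up_only"`.
#' @return data frame with columns `gene`, `direction`, `min_abs_fold`
#'   (smallest per-comparison linear fold magnitude) and `max_fdr`.
#' @export
consensus_signature <- function(table, fdr_max = 0.1, fold_min = 1.5,
                                direction = c("both", "up_only")) {
  direction <- match.arg(direction)
  groups <- sort(unique(table$group))
  k <- length(groups)
  cnt <- table(table$gene)
  abort_if(any(cnt != k),
           "comparison table is incomplete: every gene needs one row per group")
  o <- order(table$gene, table$group, method = "radix")
  genes <- unique(table$gene[o])
  dm <- matrix(table$delta[o], ncol = k, byrow = TRUE)
  fm <- matrix(table$fdr[o], ncol = k, byrow = TRUE)
  afold <- 2^abs(dm)                      # linear fold magnitude
  pass_fdr <- rowSums(fm <= fdr_max) == k
  pass_fold <- rowSums(afold >= fold_min) == k
  up <- rowSums(dm > 0) == k
  down <- rowSums(dm < 0) == k
  consistent <- if (direction == "up_only") up else up | down
  keep <- pass_fdr & pass_fold & consistent
  data.frame(gene = genes[keep],
             direction = ifelse(up[keep], "up", "down"),
             min_abs_fold = apply(afold[keep, , drop = FALSE], 1L, min),
             max_fdr = apply(fm[keep, , drop = FALSE], 1L, max),
             row.names = NULL)
}

#' Linear fold of the target cohort versus all other samples pooled
#'
#' `2 ^ (mean over target samples - mean over all remaining samples)` per
#' gene, the convention used when a single fold-difference is reported for
#' the target cohort.
#'
#' @param mat expression matrix.
#' @param target_ids target-cohort sample ids.
#' @return named numeric vector of linear folds.
#' @export
fold_vs_rest <- function(mat, target_ids) {
  rest <- setdiff(colnames(mat), target_ids)
  abort_if(length(rest) == 0L, "no non-target samples")
  abort_if(length(target_ids) == 0L ||
             !all(target_ids %in% colnames(mat)), "invalid target samples")
  2^(rowMeans(mat[, target_ids, drop = FALSE]) -
       rowMeans(mat[, rest, drop = FALSE]))
}
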