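#' Select the most variant genes
#'
#' Ranks genes by variance across all samples and keeps the top
#' `ceiling(top_frac * nrow)`, preserving input row order.  Ties in the
#' variance ranking are broken by input position, so the selection is
#' deterministic.
#'
#' @param mat expression matrix.
#' @param top_frac fraction of genes to keep, in (0, 1]; the convention for
#'   unbiased sample clustering here is the top 30 percent.
#' @return the row-subset matrix.
#' @export
select_variant_genes <- function(mat, top_frac = 0.30) {
  abort_if(top_frac <= 0 || top_frac > 1, "top_frac must lie in (0, 1]")
  v <- row_vars(mat)
  n_keep <- ceiling(top_frac * nrow(mat))
  top <- order(-v, seq_along(v), method = "radix")[seq_len(n_keep)]
  out <- mat[sort(top), , drop = FALSE]
  expression_matrix(out, level = expr_level(mat))
}

#' Spearman correlation distance between sample profiles
#'
#' `d(i, j) = 1 - rho` where `rho` is the Spearman rank correlation (midrank
#' ties) of the two samples' expression profiles across genes.  Distances
#' are symmetric with zero diagonal and lie in [0, 2].  A constant profile
#' has no defined rank correlation and is an error.
#'
#' @param mat expression matrix with at least 2 genes and 2 samples.
#' @return samples x samples distance matrix.
#' @export
spearman_distance <- function(mat) {
  abort_if(nrow(mat) < 2L || ncol(mat) < 2L,
           "need at least 2 genes and 2 samples")
  sds <- apply(mat, 2L, stats::sd)
  abort_if(any(sds == 0), "constant sample profile(s): ",
           paste(colnames(mat)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(mat, method = "spearman")
  diag(d) <- 0
  d
}

#' Agglomerative complete-linkage clustering
#'
#' Iteratively merges the pair of clusters with the smallest maximum
#' inter-cluster distance, recording merge heights.  When several pairs tie
#' at the minimal height, the pair whose (sorted) smallest member labels are
#' lexicographically smallest is merged, so the tree is identical across
#' platforms.  The result is a standard `hclust` object (merge/height/
#' labels), usable with [stats::cutree()] and [stats::cophenetic()].
#'
#' @param d symmetric non-negative distance matrix with labeled dimnames.
#' @return an object of class `hclust` (method `"complete"`).
#' @export
complete_linkage <- function(d) {
  abort_if(!is.matrix(d) || nrow(d) != ncol(d), "need a square matrix")
  abort_if(any(d < 0), "negative distances")
  abort_if(max(abs(d - t(d))) > 1e-12, "distance matrix is not symmetric")
  n <- nrow(d)
  labels <- rownames(d) %||% as.character(seq_len(n))
  abort_if(n < 2L, "need at least 2 objects")
  D <- d
  diag(D) <- Inf
  # per active cluster: merge code (-leaf or +step) and smallest member label
  code <- -seq_len(n)
  minlab <- labels
  active <- rep(TRUE, n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    mn <- min(D[active, active])
    cand <- which(D == mn & outer(active, active, `&`), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    # deterministic tie-break: lexicographically smallest sorted label pair
    keys <- apply(cand, 1L, function(ij) {
      paste(sort(c(minlab[ij[1L]], minlab[ij[2L]])), collapse = "\r")
    })
    ij <- cand[order(keys)[1L], ]
    i <- ij[[1L]]; j <- ij[[2L]]
    merge[step, ] <- sort(c(code[i], code[j]))
    height[step] <- mn
    # Lance-Williams update for complete linkage: new row is the pairwise max
    newrow <- pmax(D[i, ], D[j, ])
    D[i, ] <- newrow
    D[, i] <- newrow
    D[i, i] <- Inf
    active[j] <- FALSE
    D[j, ] <- Inf
    D[, j] <- Inf
    code[i] <- step
    minlab[i] <- min(minlab[i], minlab[j])
  }
  tree <- list(merge = merge, height = height,
               order = linkage_leaf_order(merge),
               labels = labels, method = "complete",
               call = match.call(), dist.method = "spearman")
  class(tree) <- "hclust"
  tree
}

# leaf ordering by recursive expansion of the merge matrix (left first)
linkage_leaf_order <- function(merge) {
  expand <- function(node) {
    if (node < 0L) return(-node)
    c(expand(merge[node, 1L]), expand(merge[node, 2L]))
  }
  expand(nrow(merge))
}

#' Export a linkage tree as Newick
#'
#' Leaves sit at height 0; the branch length of a child is its parent's
#' merge height minus its own height.  Children are written smaller
#' subtree-minimum label first, so the string is canonical.  The output
#' parses with standard Newick readers.
#'
#' @param tree an `hclust` object, e.g. from [complete_linkage()].
#' @param digits significant digits for branch lengths.
#' @return a single Newick string terminated by `;`.
#' @export
tree_to_newick <- function(tree, digits = 10L) {
  merge <- tree$merge
  height <- tree$height
  labels <- tree$labels
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  node <- function(idx) {
    if (idx < 0L) return(list(str = labels[[-idx]], h = 0,
                              minlab = labels[[-idx]]))
    a <- node(merge[idx, 1L])
    b <- node(merge[idx, 2L])
    if (b$minlab < a$minlab) { tmp <- a; a <- b; b <- tmp }
    h <- height[[idx]]
    list(str = sprintf("(%s:%s,%s:%s)", a$str, fmt(h - a$h),
                       b$str, fmt(h - b$h)),
         h = h, minlab = a$minlab)
  }
  if (nrow(merge) == 0L) return(paste0(labels[[1L]], ";"))
  paste0(node(nrow(merge))$str, ";")
}

#' Cluster memberships at a requested cut
#'
#' @param tree an `hclust` object.
#' @param k number of clusters.
#' @return named integer vector of memberships (via [stats::cutree()]).
#' @export
cut_clusters <- function(tree, k) stats::cutree(tree, k = k)
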