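#' Hypergeometric upper-tail p-value for a gene-set overlap
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of at least
#' `k` hits when drawing a signature of size `n` from a universe of `N`
#' genes of which `K` belong to the term.
#'
#' @param k observed hits (signature genes in the term).
#' @param n signature size within the universe.
#' @param K term size within the universe.
#' @param N universe size.
#' @return upper-tail probability in (0, 1].
#' @export
hypergeom_p <- function(k, n, K, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Conservative one-hit-removed (EASE-style) enrichment p-value
#'
#' The jackknifed variant of the hypergeometric test: one hit is removed
#' from both the overlap and the drawn list, i.e. `P(X >= k - 1)` with a
#' draw of `n - 1`.  Single-hit terms can never be significant (`p = 1`).
#'
#' @inheritParams hypergeom_p
#' @return conservative upper-tail probability; 1 when `k <= 1`.
#' @export
ease_p <- function(k, n, K, N) {
  p <- stats::phyper(k - 2, K, N - K, pmax(n - 1, 0), lower.tail = FALSE)
  p[k < 1] <- 1
  p
}

#' Gene-set over-representation of a signature
#'
#' Tests each term of the collection for over-representation of the
#' signature within the universe using the hypergeometric upper tail (or
#' the conservative EASE variant), adjusts across tested terms by BH, and
#' ranks by fold enrichment `(k/n) / (K/N)` descending.  Terms are
#' intersected with the universe first and tested only when at least
#' `min_term_size` members remain.
#'
#' @param signature character vector of signature genes; must be a subset
#'   of the universe.
#' @param collection a [gene_set_collection()].
#' @param universe character vector of all analyzed genes (typically the
#'   genes surviving the expression/variance pre-filter).
#' @param fdr_max terms at or below this FDR are flagged `enriched`.
#' @param min_term_size smallest in-universe term size tested.
#' @param method `"hypergeometric"` (default) or `"ease"`.
#' @return data frame with one row per tested term: `term_id`, `term_name`,
#'   `k`, `n`, `K`, `N`, `fold_enrichment`, `p`, `fdr`, `enriched`.
#' @export
enrich <- function(signature, collection, universe, fdr_max = 0.005,
                   min_term_size = 3L,
                   method = c("hypergeometric", "ease")) {
  method <- match.arg(method)
  signature <- unique(signature)
  universe <- unique(universe)
  offenders <- setdiff(signature, universe)
  abort_if(length(offenders) > 0L, "signature genes absent from universe: ",
           paste(offenders, collapse = ", "))
  n <- length(signature)
  N <- length(universe)
  members <- lapply(collection, intersect, universe)
  K <- lengths(members)
  tested <- K >= min_term_size
  members <- members[tested]
  K <- K[tested]
  k <- vapply(members, function(m) length(intersect(m, signature)), 0L)
  p <- if (method == "ease") ease_p(k, n, K, N) else hypergeom_p(k, n, K, N)
  nm <- attr(collection, "term_names") %||%
    stats::setNames(names(collection), names(collection))
  out <- data.frame(term_id = names(members),
                    term_name = unname(nm[names(members)]),
                    k = k, n = n, K = unname(K), N = N,
                    fold_enrichment = (k / n) / (K / N),
                    p = unname(p), row.names = NULL)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$fdr <= fdr_max
  out <- out[order(-out$fold_enrichment, out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
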