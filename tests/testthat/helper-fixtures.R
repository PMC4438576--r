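# shared in-code fixtures

# compact cohort for module-level tests: 5 reference groups, ~400 genes
small_cohort <- function(seed = 7, ...) {
  defaults <- list(
    seed = seed, n_genes = 400L, n_signature = 20L, n_decoy = 10L,
    n_drug_targets = 4L, planted_set_size = 8L, n_background_sets = 6L,
    reference_sizes = c(A = 6L, B = 5L, C = 8L, D = 7L, E = 6L))
  generate_cohort(do.call(synth_config, utils::modifyList(defaults, list(...))))
}

# tiny labeled expression matrix
toy_matrix <- function(values, features, samples, level = "gene") {
  expression_matrix(matrix(values, nrow = length(features), byrow = TRUE,
                           dimnames = list(features, samples)),
                    level = level)
}

# two-group sample sheet around a matrix's columns
toy_sheet <- function(mat, n_target) {
  n <- ncol(mat)
  data.frame(sample_id = colnames(mat),
             group = rep(c("TGT", "REF"), c(n_target, n - n_target)),
             is_target = rep(c(TRUE, FALSE), c(n_target, n - n_target)))
}

# brute-force complete linkage: at every step recompute all inter-cluster
# maxima from the original distance matrix (independent of the
# Lance-Williams update used by the implementation), same label tie-break
brute_complete_linkage <- function(d) {
  labels <- rownames(d)
  clusters <- lapply(seq_along(labels), function(i) i)
  codes <- -seq_along(labels)
  merge <- matrix(0L, length(labels) - 1L, 2L)
  height <- numeric(length(labels) - 1L)
  for (step in seq_len(length(labels) - 1L)) {
    best <- NULL
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1L):length(clusters)) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        key <- paste(sort(c(min(labels[clusters[[i]]]),
                            min(labels[clusters[[j]]]))), collapse = "\r")
        if (is.null(best) || h < best$h || (h == best$h && key < best$key)) {
          best <- list(i = i, j = j, h = h, key = key)
        }
      }
    }
    merge[step, ] <- sort(c(codes[[best$i]], codes[[best$j]]))
    height[step] <- best$h
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    codes[[best$i]] <- step
    clusters[[best$j]] <- NULL
    codes <- codes[-best$j]
  }
  structure(list(merge = merge, height = height,
                 order = seq_along(labels), labels = labels,
                 method = "complete"), class = "hclust")
}

random_distance_matrix <- function(n, labels = sprintf("S%02d", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  d[upper.tri(d)] <- stats::runif(n * (n - 1) / 2, 0.05, 2)
  d + t(d)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "targetsig", mustWork = TRUE)
}
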